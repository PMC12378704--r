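#' Build a pipeline configuration
#'
#' All thresholds default to the study settings: 1,000 permutations,
#' q < 0.05, top 5% by Z-score, 3-nt flanks, groups = chromosome x strand.
#'
#' @param fasta Genome FASTA path (or `NULL` when `genome` is supplied to
#'   [run_pipeline()] directly).
#' @param gtf Optional gene-model GTF path.
#' @param out_dir Output directory.
#' @param pattern An `im_pattern`.
#' @param flank Flank length for alignment (default 3).
#' @param engine Alignment engine, `"builtin"` or `"external"`.
#' @param external_cmd External aligner command.
#' @param pseudocount PSSM pseudocount.
#' @param B Permutations per sequence.
#' @param q_threshold BH threshold.
#' @param top_frac Selected fraction of all scanned candidates.
#' @param promoter_window `c(upstream, downstream)` for annotation.
#' @param group_by `"chrom_strand"` (default) or `"all"` (single alignment
#'   group, for small fixtures).
#' @param immune_genes,housekeeping_genes Optional paths to one-symbol-per-
#'   line gene lists used for class annotation and enrichment.
#' @param annotate Run the annotation stage (requires `gtf`).
#' @param seed Base seed; every stochastic stage derives its own seed from it.
#' @return A list of class `im_config`.
#' @export
pipeline_config <- function(fasta = NULL, gtf = NULL, out_dir = tempfile("imprior_"),
                            pattern = motif_pattern(), flank = 3L,
                            engine = "builtin", external_cmd = "mafft",
                            pseudocount = 0.25, B = 1000L,
                            q_threshold = 0.05, top_frac = 0.05,
                            promoter_window = c(2000L, 200L),
                            group_by = c("chrom_strand", "all"),
                            immune_genes = NULL, housekeeping_genes = NULL,
                            annotate = !is.null(gtf), seed = 1L) {
  group_by <- match.arg(group_by)
  cfg <- list(fasta = fasta, gtf = gtf, out_dir = out_dir, pattern = pattern,
              flank = flank, engine = engine, external_cmd = external_cmd,
              pseudocount = pseudocount, B = as.integer(B),
              q_threshold = q_threshold, top_frac = top_frac,
              promoter_window = promoter_window, group_by = group_by,
              immune_genes = immune_genes,
              housekeeping_genes = housekeeping_genes,
              annotate = annotate, seed = as.integer(seed))
  class(cfg) <- "im_config"
  cfg
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys are an
#' error, missing keys take the defaults. `pattern` may be given as a list
#' of [motif_pattern()] arguments.
#'
#' @param path YAML path.
#' @return An `im_config`.
#' @export
load_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) stop_input("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(raw$pattern)) raw$pattern <- do.call(motif_pattern, raw$pattern)
  if (!is.null(raw$promoter_window)) raw$promoter_window <- as.integer(raw$promoter_window)
  do.call(pipeline_config, raw)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full prioritization pipeline
#'
#' Stages, in order: scan both strands for motif matches; extract flanked
#' sequences; align each (chromosome x strand) group; build the group PSSM;
#' score every match and assign permutation significance; adjust p-values
#' globally (BH) and compute Z-scores; select the top fraction; optionally
#' annotate against gene models and test gene-class enrichment. Every
#' stage's table is written under `out_dir` and the run is summarized in a
#' deterministic JSON report, so reruns with the same seed are
#' byte-identical.
#'
#' @param config An `im_config` (or YAML path).
#' @param genome Optional pre-loaded `im_genome` (overrides `config$fasta`).
#' @param models Optional pre-loaded `im_gene_models` (overrides `config$gtf`).
#' @return Invisibly, a list: `matches`, `candidates` (scored table),
#'   `selected`, `annotated` (or `NULL`), `enrichment` (or `NULL`),
#'   `pssms`, `report`, `out_dir`.
#' @export
run_pipeline <- function(config, genome = NULL, models = NULL) {
  if (is.character(config)) config <- load_pipeline_config(config)
  stopifnot(inherits(config, "im_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) message("[imprior] ", sprintf(...))

  if (is.null(genome)) {
    if (is.null(config$fasta)) stop_input("no genome: set 'fasta' in the config or pass 'genome'")
    genome <- read_genome(config$fasta)
  }
  if (config$annotate && is.null(models) && is.null(config$gtf)) {
    stop_input("annotation requested but no gene models: set 'gtf' in the config or pass 'models'")
  }

  log_stage("scan: %d chromosome(s)", length(genome))
  matches <- scan_motifs(genome, config$pattern)
  write_matches_bed(matches, file.path(config$out_dir, "matches.bed"))
  if (nrow(matches) == 0) stop_input("scan found no motif matches; nothing to prioritize")

  log_stage("align: extracting %d-nt flanks and aligning", config$flank)
  flanked <- extract_flanked(matches, genome, flank = config$flank)
  group_key <- if (config$group_by == "all") {
    rep("all", nrow(flanked))
  } else {
    paste0(flanked$chrom, "(", flanked$strand, ")")
  }
  groups <- split(seq_len(nrow(flanked)), group_key)

  candidates <- flanked
  candidates$group <- group_key
  candidates$score <- NA_real_
  candidates$p <- NA_real_
  candidates$z <- NA_real_
  candidates$null_mean <- NA_real_
  candidates$null_sd <- NA_real_
  pssms <- list()
  stage_seed <- config$seed %% 1000000L  # per-row seeds stay well under 2^31
  for (gname in names(groups)) {
    idx <- groups[[gname]]
    idx <- idx[order(flanked$chrom[idx], flanked$start[idx])]  # genomic order
    aln <- align_group(flanked$full_seq[idx], ids = flanked$id[idx],
                       engine = config$engine,
                       external_cmd = config$external_cmd)
    safe <- gsub("[^A-Za-z0-9_.-]", "_", gname)
    write_alignment(aln, file.path(config$out_dir, paste0("aligned_", safe, ".fa")))
    pssm <- build_pssm(aln, pseudocount = config$pseudocount)
    pssms[[gname]] <- pssm
    for (j in seq_along(idx)) {
      res <- permutation_test(pssm, aln$rows[[j]], B = config$B,
                              seed = stage_seed * 1000L + idx[j])
      candidates$score[idx[j]] <- res$score
      candidates$p[idx[j]] <- res$p
      candidates$z[idx[j]] <- res$z
      candidates$null_mean[idx[j]] <- res$null$mean
      candidates$null_sd[idx[j]] <- res$null$sd
    }
  }

  log_stage("significance: BH over %d candidates", nrow(candidates))
  candidates$q <- bh_adjust(candidates$p)
  candidates$selected <- select_candidates(candidates,
                                           q_threshold = config$q_threshold,
                                           top_frac = config$top_frac)
  cand_out <- candidates[, c("id", "chrom", "start", "end", "strand", "seq",
                             "group", "score", "p", "q", "z", "null_mean",
                             "null_sd", "selected")]
  write_tsv(cand_out, file.path(config$out_dir, "candidates.tsv"))
  selected <- cand_out[cand_out$selected, , drop = FALSE]
  write_tsv(selected, file.path(config$out_dir, "selected.tsv"))

  annotated <- NULL
  enrichment <- NULL
  if (config$annotate) {
    log_stage("annotate: %d selected candidates", nrow(selected))
    if (is.null(models)) models <- read_gene_models(config$gtf)
    immune <- if (!is.null(config$immune_genes)) readLines(config$immune_genes) else character(0)
    hk <- if (!is.null(config$housekeeping_genes)) readLines(config$housekeeping_genes) else character(0)
    annotated <- annotate_candidates(selected, models,
                                     promoter_window = config$promoter_window,
                                     immune_set = immune, housekeeping_set = hk)
    write_tsv(annotated, file.path(config$out_dir, "annotated.tsv"))
    if (length(immune) > 0 && length(hk) > 0) {
      enrichment <- gene_class_enrichment(
        annotated, immune, hk,
        background_genes = S4Vectors::mcols(models$genes)$symbol)
    }
  }

  report <- list(
    config = list(pattern = unclass(config$pattern), flank = config$flank,
                  engine = config$engine, pseudocount = config$pseudocount,
                  B = config$B, q_threshold = config$q_threshold,
                  top_frac = config$top_frac, group_by = config$group_by,
                  promoter_window = config$promoter_window, seed = config$seed),
    counts = list(
      scanned = nrow(matches),
      scanned_forward = sum(matches$strand == "+"),
      scanned_reverse = sum(matches$strand == "-"),
      groups = length(groups),
      significant_q = sum(candidates$q < config$q_threshold),
      selected = nrow(selected),
      annotated = if (is.null(annotated)) 0L else nrow(annotated)
    ),
    enrichment = if (is.null(enrichment)) NULL else {
      list(odds_ratio = enrichment$odds_ratio, p = enrichment$p)
    }
  )
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  log_stage("done: %d scanned, %d selected", nrow(matches), nrow(selected))
  invisible(list(matches = matches, candidates = cand_out, selected = selected,
                 annotated = annotated, enrichment = enrichment, pssms = pssms,
                 report = report, out_dir = config$out_dir))
}
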