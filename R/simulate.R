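# Loop sampler used by sample_im_like: loops may contain C and G but never
# CC or GG dinucleotides, and never C at the loop edges. This keeps the
# implanted C runs exactly three long and leaves no C run on either strand
# beyond the four designed ones, so implant coordinates are exact scanner
# truth on both strands.
sample_loop <- function(len) {
  out <- character(len)
  for (i in seq_len(len)) {
    pool <- DNA_BASES
    if (i == 1L || i == len) pool <- setdiff(pool, "C")
    if (i > 1L && out[i - 1L] %in% c("C", "G")) pool <- setdiff(pool, out[i - 1L])
    out[i] <- sample(pool, 1L)
  }
  paste(out, collapse = "")
}

#' Sample an i-motif-like sequence from the (C3 N1-12)3 C3 grammar
#'
#' @param loop_lens Either `NULL` (each loop length drawn uniformly from
#'   `loop_len_range`) or an integer vector of the three loop lengths.
#' @param loop_len_range Bounds for random loop lengths (default 1-12).
#' @param loop_seqs Optional fixed loop strings (overrides sampling; used
#'   to build narrow-consensus implant families).
#' @param seed Optional integer seed.
#' @return A DNA string matching the default motif pattern (length 15-48).
#' @export
sample_im_like <- function(loop_lens = NULL, loop_len_range = c(1L, 12L),
                           loop_seqs = NULL, seed = NULL) {
  with_seed(seed, {
    if (is.null(loop_seqs)) {
      if (is.null(loop_lens)) {
        loop_lens <- sample(loop_len_range[1]:loop_len_range[2], 3L, replace = TRUE)
      }
      stopifnot(length(loop_lens) == 3L, all(loop_lens >= 1L), all(loop_lens <= 12L))
      loop_seqs <- vapply(loop_lens, sample_loop, character(1))
    }
    paste0("CCC", loop_seqs[1], "CCC", loop_seqs[2], "CCC", loop_seqs[3], "CCC")
  })
}

#' Sample a G4-like decoy sequence
#'
#' The reverse complement of an i-motif-like draw: four G3 runs with 1-12 nt
#' loops, the grammar of the guanine-rich negative controls.
#'
#' @inheritParams sample_im_like
#' @return A G-rich DNA string.
#' @export
sample_g4_like <- function(loop_lens = NULL, loop_len_range = c(1L, 12L),
                           seed = NULL) {
  revcomp(sample_im_like(loop_lens = loop_lens, loop_len_range = loop_len_range,
                         seed = seed))
}

# Background free of pattern matches on BOTH strands: never a third
# consecutive C (plus strand) nor a third consecutive G (minus strand).
ccc_free_background <- function(len) {
  out <- character(len)
  for (i in seq_len(len)) {
    pool <- DNA_BASES
    if (i > 2L && out[i - 1L] == out[i - 2L] && out[i - 1L] %in% c("C", "G")) {
      pool <- setdiff(pool, out[i - 1L])
    }
    out[i] <- sample(pool, 1L)
  }
  paste(out, collapse = "")
}

#' Simulate a fixture genome with implanted motifs
#'
#' Generates a background sequence (CCC/GGG-run-free by default, so the
#' only scanner matches on either strand are the implants), implants
#' `n_implants` motif draws at non-overlapping positions with non-C/G guard
#' bases at the boundaries (half on the minus strand, inserted as reverse
#' complements), and lays a toy gene track over the chromosome in which a
#' configurable fraction of implants fall inside immune-labelled genes.
#'
#' @param genome_length Chromosome length in bp (default 60000).
#' @param n_implants Number of implanted motifs (default 50).
#' @param chrom Chromosome name (default `"chrS1"`).
#' @param background `"ccc_free"` (no spurious matches) or `"uniform"`.
#' @param implant_sampler Function returning one implant sequence
#'   (default [sample_im_like()]).
#' @param frac_minus Fraction of implants placed on the minus strand
#'   (default 0.5).
#' @param n_immune_genes,n_housekeeping_genes Toy gene counts (defaults 8, 8).
#' @param frac_implants_in_immune Fraction of implants covered by immune
#'   genes (default 0.5).
#' @param seed Optional integer seed; fixed seeds give byte-identical output.
#' @param dir Optional output directory; when given, writes `genome.fa`,
#'   `truth.bed`, `genes.gtf`, `immune_genes.txt`, `housekeeping_genes.txt`.
#' @return A list: `genome` (`im_genome`), `truth` (`im_matches`-shaped
#'   data.frame of implants), `models` (`im_gene_models`), `gene_classes`
#'   (list of `immune` and `housekeeping` symbol vectors), and `paths`
#'   (when `dir` was given).
#' @export
simulate_genome <- function(genome_length = 60000L, n_implants = 50L,
                            chrom = "chrS1",
                            background = c("ccc_free", "uniform"),
                            implant_sampler = sample_im_like,
                            frac_minus = 0.5,
                            n_immune_genes = 8L, n_housekeeping_genes = 8L,
                            frac_implants_in_immune = 0.5,
                            seed = NULL, dir = NULL) {
  background <- match.arg(background)
  with_seed(seed, {
    bg <- if (background == "ccc_free") {
      ccc_free_background(genome_length)
    } else {
      paste(sample(DNA_BASES, genome_length, replace = TRUE), collapse = "")
    }
    chars <- str_chars(bg)
    truth <- NULL
    # reserve an implant-free tail for the off-implant toy genes
    n_cover_target <- min(n_immune_genes, round(frac_implants_in_immune * n_implants))
    n_extra <- (n_immune_genes - n_cover_target) + n_housekeeping_genes
    gw <- 120L
    reserve <- if (n_extra > 0L) n_extra * (gw + 40L) + 100L else 0L
    usable <- genome_length - reserve
    if (n_implants > 0L) {
      max_len <- 48L
      slot <- usable %/% n_implants
      if (slot < max_len + 4L) {
        stop_input(sprintf("genome of length %d too short for %d implants",
                           genome_length, n_implants))
      }
      n_minus <- floor(frac_minus * n_implants)
      strands <- sample(c(rep("-", n_minus), rep("+", n_implants - n_minus)))
      rec <- vector("list", n_implants)
      for (i in seq_len(n_implants)) {
        implant <- implant_sampler()
        len <- nchar(implant)
        slot_start <- (i - 1L) * slot            # 0-based slot origin
        off <- sample.int(slot - len - 2L, 1L)   # leaves >= 1 guard each side
        st <- slot_start + off                   # 0-based implant start
        inserted <- if (strands[i] == "-") revcomp(implant) else implant
        chars[(st + 1L):(st + len)] <- str_chars(inserted)
        chars[st] <- sample(c("A", "T"), 1L)             # guard bases
        chars[st + len + 1L] <- sample(c("A", "T"), 1L)
        rec[[i]] <- data.frame(chrom = chrom, start = st, end = st + len,
                               strand = strands[i], seq = implant,
                               stringsAsFactors = FALSE)
      }
      truth <- do.call(rbind, rec)
      truth <- truth[order(truth$start), , drop = FALSE]
      rownames(truth) <- NULL
      truth$id <- sprintf("%s:%d-%d(%s)", truth$chrom, truth$start,
                          truth$end, truth$strand)
      class(truth) <- c("im_matches", "data.frame")
    } else {
      truth <- data.frame(chrom = character(0), start = integer(0),
                          end = integer(0), strand = character(0),
                          seq = character(0), id = character(0),
                          stringsAsFactors = FALSE)
      class(truth) <- c("im_matches", "data.frame")
    }
    genome <- genome_seq(stats::setNames(paste(chars, collapse = ""), chrom))

    # toy gene track: immune genes straddle a chosen subset of implants,
    # housekeeping genes sit in the implant-free tail
    n_cover <- if (nrow(truth) > 0L) n_cover_target else 0L
    covered <- if (n_cover > 0L) sort(sample(seq_len(nrow(truth)), n_cover)) else integer(0)
    genes <- list()
    for (j in seq_along(covered)) {
      tr <- truth[covered[j], ]
      gs <- max(1L, tr$start - 200L)
      ge <- min(genome_length, tr$end + 200L)
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = sprintf("IMM%02d", j), symbol = sprintf("IMMUNE%02d", j),
        chrom = chrom, start = gs + 1L, end = ge,
        strand = sample(c("+", "-"), 1L), stringsAsFactors = FALSE)
    }
    # leftover immune genes (no implant) and housekeeping genes in the
    # reserved implant-free tail
    extra_imm <- n_immune_genes - length(covered)
    n_extra <- extra_imm + n_housekeeping_genes
    if (n_extra > 0L) {
      anchor <- genome_length - n_extra * (gw + 40L) - 60L
      if (anchor < 1L) stop_input("genome too short for the requested gene track")
      for (j in seq_len(n_extra)) {
        gs <- anchor + (j - 1L) * (gw + 40L)
        lbl <- if (j <= extra_imm) {
          c(sprintf("IMM%02d", length(covered) + j), sprintf("IMMUNE%02d", length(covered) + j))
        } else {
          k <- j - extra_imm
          c(sprintf("HK%02d", k), sprintf("HOUSE%02d", k))
        }
        genes[[length(genes) + 1L]] <- data.frame(
          gene_id = lbl[1], symbol = lbl[2], chrom = chrom,
          start = gs + 1L, end = gs + gw,
          strand = sample(c("+", "-"), 1L), stringsAsFactors = FALSE)
      }
    }
    genes_df <- do.call(rbind, genes)
    # two terminal exons per gene; the middle is intron
    exons <- do.call(rbind, lapply(seq_len(nrow(genes_df)), function(i) {
      g <- genes_df[i, ]
      w <- max(10L, (g$end - g$start + 1L) %/% 5L)
      data.frame(gene_id = rep(g$gene_id, 2L), chrom = g$chrom,
                 start = c(g$start, g$end - w + 1L),
                 end = c(g$start + w - 1L, g$end),
                 strand = g$strand, stringsAsFactors = FALSE)
    }))
    models <- gene_models(genes_df, exons = exons)
    classes <- list(
      immune = genes_df$symbol[startsWith(genes_df$gene_id, "IMM")],
      housekeeping = genes_df$symbol[startsWith(genes_df$gene_id, "HK")]
    )
    out <- list(genome = genome, truth = truth, models = models,
                genes = genes_df, exons = exons, gene_classes = classes)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      paths <- list(
        fasta = file.path(dir, "genome.fa"),
        truth_bed = file.path(dir, "truth.bed"),
        gtf = file.path(dir, "genes.gtf"),
        immune = file.path(dir, "immune_genes.txt"),
        housekeeping = file.path(dir, "housekeeping_genes.txt")
      )
      write_genome(genome, paths$fasta)
      write_matches_bed(truth, paths$truth_bed)
      write_toy_gtf(genes_df, exons, paths$gtf)
      writeLines(classes$immune, paths$immune)
      writeLines(classes$housekeeping, paths$housekeeping)
      out$paths <- paths
    }
    out
  })
}

#' Write a toy gene track as GTF
#'
#' Emits `gene`, `transcript`, and `exon` features with `gene_id`,
#' `transcript_id`, and `gene_name` attributes, readable by
#' [read_gene_models()] and standard GTF parsers.
#'
#' @param genes_df Gene data.frame (`gene_id`, `symbol`, `chrom`, `start`,
#'   `end`, `strand`; 1-based closed coordinates).
#' @param exons Exon data.frame (`gene_id`, `chrom`, `start`, `end`, `strand`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_toy_gtf <- function(genes_df, exons, path) {
  attr_of <- function(gid, sym) {
    sprintf('gene_id "%s"; transcript_id "%s.t1"; gene_name "%s";', gid, gid, sym)
  }
  sym_of <- stats::setNames(genes_df$symbol, genes_df$gene_id)
  lines <- character(0)
  for (i in seq_len(nrow(genes_df))) {
    g <- genes_df[i, ]
    a <- attr_of(g$gene_id, g$symbol)
    lines <- c(lines,
               paste(g$chrom, "imprior", "gene", g$start, g$end, ".", g$strand, ".", a, sep = "\t"),
               paste(g$chrom, "imprior", "transcript", g$start, g$end, ".", g$strand, ".", a, sep = "\t"))
  }
  for (i in seq_len(nrow(exons))) {
    e <- exons[i, ]
    a <- attr_of(e$gene_id, sym_of[[e$gene_id]])
    lines <- c(lines,
               paste(e$chrom, "imprior", "exon", e$start, e$end, ".", e$strand, ".", a, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
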