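#' Construct a gene model set
#'
#' @param genes Data.frame with columns `gene_id`, `symbol`, `chrom`,
#'   `start`, `end` (1-based closed), `strand`, and optionally `type`.
#' @param exons Optional data.frame with `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param utr5,utr3 Optional data.frames in the same shape as `exons`.
#' @return A list of class `im_gene_models` holding `GRanges` tracks.
#' @export
gene_models <- function(genes, exons = NULL, utr5 = NULL, utr3 = NULL) {
  as_gr <- function(df, need_gene = TRUE) {
    if (is.null(df) || nrow(df) == 0) return(GenomicRanges::GRanges())
    gr <- GenomicRanges::GRanges(
      seqnames = df$chrom,
      ranges = IRanges::IRanges(start = df$start, end = df$end),
      strand = df$strand
    )
    if (need_gene) S4Vectors::mcols(gr)$gene_id <- df$gene_id
    gr
  }
  stopifnot(all(c("gene_id", "symbol", "chrom", "start", "end", "strand") %in% names(genes)))
  gr_genes <- as_gr(genes)
  S4Vectors::mcols(gr_genes)$symbol <- genes$symbol
  structure(list(genes = gr_genes, exons = as_gr(exons),
                 utr5 = as_gr(utr5), utr3 = as_gr(utr3)),
            class = "im_gene_models")
}

#' Read gene models from a GTF file
#'
#' Accepts GENCODE-style feature types: `gene`, `exon`, and UTRs typed
#' either `five_prime_utr`/`three_prime_utr` or `5UTR`/`3UTR`. Gene symbols
#' come from `gene_name`, falling back to `gene_id`.
#'
#' @param path GTF path.
#' @return An `im_gene_models`.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  sym <- if ("gene_name" %in% names(mc)) mc$gene_name else mc$gene_id
  sym[is.na(sym)] <- mc$gene_id[is.na(sym)]
  to_df <- function(sel) {
    if (!any(sel)) return(NULL)
    data.frame(gene_id = mc$gene_id[sel], symbol = sym[sel],
               chrom = as.character(GenomicRanges::seqnames(gr)[sel]),
               start = GenomicRanges::start(gr)[sel],
               end = GenomicRanges::end(gr)[sel],
               strand = as.character(GenomicRanges::strand(gr)[sel]),
               stringsAsFactors = FALSE)
  }
  type <- as.character(mc$type)
  genes <- to_df(type == "gene")
  if (is.null(genes)) stop_input("GTF contains no 'gene' features")
  gene_models(genes,
              exons = to_df(type == "exon"),
              utr5 = to_df(type %in% c("five_prime_utr", "5UTR")),
              utr3 = to_df(type %in% c("three_prime_utr", "3UTR")))
}

#' Annotate candidates with genes, genic regions, and gene classes
#'
#' Candidates overlapping a gene body are labelled mode `"correct"`
#' (distance 0); all others get the nearest gene and its genomic distance
#' (mode `"nearest"`). The genic region is assigned with fixed precedence
#' promoter > 5'UTR > 3'UTR > exon > intron > distal_intergenic, the
#' promoter being a strand-aware window around the annotated TSS. Gene
#' class is `"immune"` if the symbol is in `immune_set`, else
#' `"housekeeping"` if in `housekeeping_set`, else `"other"`.
#'
#' @param candidates Data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), `strand`.
#' @param models An `im_gene_models`.
#' @param promoter_window `c(upstream, downstream)` in bp around the TSS
#'   (default 2000, 200).
#' @param immune_set,housekeeping_set Optional character vectors of symbols.
#' @return `candidates` with added columns `gene_symbol`, `mode`,
#'   `distance`, `region`, `gene_class`. Candidates on chromosomes absent
#'   from the gene set are labelled `distal_intergenic` with `NA` distance
#'   (a warning is raised).
#' @export
annotate_candidates <- function(candidates, models,
                                promoter_window = c(2000L, 200L),
                                immune_set = character(0),
                                housekeeping_set = character(0)) {
  n <- nrow(candidates)
  out <- candidates
  out$gene_symbol <- NA_character_
  out$mode <- NA_character_
  out$distance <- NA_real_
  out$region <- "distal_intergenic"
  out$gene_class <- "other"
  if (n == 0) return(out)
  cand <- GenomicRanges::GRanges(
    seqnames = candidates$chrom,
    ranges = IRanges::IRanges(start = candidates$start + 1L, end = candidates$end)
  )
  genes <- models$genes
  shared <- as.character(GenomicRanges::seqnames(cand)) %in%
    as.character(unique(GenomicRanges::seqnames(genes)))
  if (!all(shared)) {
    warning(sprintf("%d candidate(s) on chromosomes absent from the gene set; labelled distal_intergenic",
                    sum(!shared)))
  }
  # gene assignment: overlap first, else nearest
  ov <- suppressWarnings(GenomicRanges::findOverlaps(cand, genes, ignore.strand = TRUE))
  if (length(ov) > 0) {
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    w <- GenomicRanges::width(IRanges::pintersect(cand[qh], genes[sh]))
    ord <- order(qh, -w, sh)
    first <- !duplicated(qh[ord])
    hit_q <- qh[ord][first]; hit_s <- sh[ord][first]
    out$gene_symbol[hit_q] <- S4Vectors::mcols(genes)$symbol[hit_s]
    out$mode[hit_q] <- "correct"
    out$distance[hit_q] <- 0
  }
  need <- which(is.na(out$mode) & shared)
  if (length(need) > 0 && length(genes) > 0) {
    dn <- suppressWarnings(GenomicRanges::distanceToNearest(cand[need], genes, ignore.strand = TRUE))
    qh <- S4Vectors::queryHits(dn); sh <- S4Vectors::subjectHits(dn)
    out$gene_symbol[need[qh]] <- S4Vectors::mcols(genes)$symbol[sh]
    out$mode[need[qh]] <- "nearest"
    out$distance[need[qh]] <- S4Vectors::mcols(dn)$distance
  }
  # genic region by precedence
  prom <- GenomicRanges::promoters(genes, upstream = promoter_window[1],
                                   downstream = promoter_window[2])
  prom <- GenomicRanges::trim(prom)
  hits_any <- function(track) {
    if (length(track) == 0) return(rep(FALSE, n))
    suppressWarnings(IRanges::overlapsAny(cand, track, ignore.strand = TRUE))
  }
  in_prom <- hits_any(prom)
  in_utr5 <- hits_any(models$utr5)
  in_utr3 <- hits_any(models$utr3)
  in_exon <- hits_any(models$exons)
  in_gene <- !is.na(out$mode) & out$mode == "correct"
  out$region <- ifelse(in_prom, "promoter",
                ifelse(in_utr5, "5UTR",
                ifelse(in_utr3, "3UTR",
                ifelse(in_exon, "exon",
                ifelse(in_gene, "intron", "distal_intergenic")))))
  out$region[!shared] <- "distal_intergenic"
  out$gene_class <- assign_gene_class(out$gene_symbol, immune_set, housekeeping_set)
  out
}

#' Classify gene symbols into immune / housekeeping / other
#'
#' Symbols present in both sets are called immune (the two curated lists
#' are deduplicated against each other with immune precedence).
#'
#' @param symbols Character vector (NA allowed).
#' @param immune_set,housekeeping_set Character vectors of symbols.
#' @return Character vector of classes.
#' @export
assign_gene_class <- function(symbols, immune_set, housekeeping_set) {
  cls <- rep("other", length(symbols))
  cls[symbols %in% housekeeping_set] <- "housekeeping"
  cls[symbols %in% immune_set] <- "immune"
  cls[is.na(symbols)] <- "other"
  cls
}

#' Fisher's exact test for a 2x2 table
#'
#' Conditional (hypergeometric) two-sided test with the conditional MLE
#' odds ratio and its 95% confidence interval. A table with a zero margin
#' is degenerate: `p = 1` and the odds ratio is undefined (`NA`, flagged).
#'
#' @param table 2x2 matrix of non-negative integers.
#' @return A list: `odds_ratio`, `ci95` (length 2), `p`, `degenerate`.
#' @examples
#' fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2))
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop_input("a 2x2 table is required")
  if (any(table < 0) || any(table != round(table))) {
    stop_input("table entries must be non-negative integers")
  }
  if (sum(table) == 0) stop_input("at least one margin must be positive")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    return(list(odds_ratio = NA_real_, ci95 = c(NA_real_, NA_real_),
                p = 1, degenerate = TRUE))
  }
  ft <- stats::fisher.test(table)
  list(odds_ratio = unname(ft$estimate), ci95 = as.numeric(ft$conf.int),
       p = ft$p.value, degenerate = FALSE)
}

#' Gene-class enrichment among candidate genes
#'
#' Builds the 2x2 contingency table (immune vs housekeeping) x (hit by a
#' candidate vs background only) over deduplicated gene symbols and applies
#' Fisher's exact test.
#'
#' @param annotated Annotated candidate data.frame (needs `gene_symbol`).
#' @param immune_set,housekeeping_set Non-empty character vectors of symbols.
#' @param background_genes Character vector: the gene universe.
#' @return A list: `table` (2x2), plus the `fisher_exact_2x2` fields.
#' @export
gene_class_enrichment <- function(annotated, immune_set, housekeeping_set,
                                  background_genes) {
  if (length(immune_set) == 0 || length(housekeeping_set) == 0) {
    stop_input("immune and housekeeping gene sets must be non-empty")
  }
  immune_set <- unique(immune_set)
  housekeeping_set <- unique(setdiff(housekeeping_set, immune_set))
  background_genes <- unique(background_genes)
  cand_genes <- unique(annotated$gene_symbol[!is.na(annotated$gene_symbol)])
  imm_bg <- intersect(immune_set, background_genes)
  hk_bg <- intersect(housekeeping_set, background_genes)
  tab <- matrix(c(length(intersect(imm_bg, cand_genes)),
                  length(setdiff(imm_bg, cand_genes)),
                  length(intersect(hk_bg, cand_genes)),
                  length(setdiff(hk_bg, cand_genes))),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("immune", "housekeeping"),
                                c("candidate", "background_only")))
  res <- fisher_exact_2x2(tab)
  c(list(table = tab), res)
}
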