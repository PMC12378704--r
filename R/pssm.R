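#' Build a position-specific similarity matrix from an alignment
#'
#' Per column, the frequency of each nucleotide is computed over non-gap
#' characters only, and the score is the log2 ratio of the pseudocount-
#' adjusted frequency to the background expectation:
#' `score(b, i) = log2(((count_b + pc) / (n_nongap + 4 pc)) / bg_b)`.
#' Columns consisting entirely of gaps get all-zero scores and are flagged
#' in `degenerate_cols`.
#'
#' @param aln An `im_alignment` or a character vector of equal-width gapped rows.
#' @param pseudocount Per-nucleotide pseudocount (default 0.25; 0 gives the
#'   raw log ratio, with `-Inf` for absent bases, which the positive-sum
#'   scoring rule ignores).
#' @param background Expected frequencies for A/C/G/T (default uniform 0.25).
#' @return A list of class `im_pssm`: `width`, `freqs` (4 x width raw
#'   proportions), `scores` (4 x width), `pseudocount`, `background`,
#'   `n_seqs`, `degenerate_cols`.
#' @examples
#' p <- build_pssm(c("CCCA", "CCCA", "CCCG", "CCCT"), pseudocount = 0)
#' p$scores["C", 1]  # log2(1/0.25) = 2
#' @export
build_pssm <- function(aln, pseudocount = 0.25,
                       background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  rows <- if (inherits(aln, "im_alignment")) aln$rows else aln
  if (length(rows) == 0) stop_input("alignment is empty")
  if (length(unique(nchar(rows))) != 1L) stop_input("alignment rows have unequal widths")
  stopifnot(pseudocount >= 0, length(background) == 4, all(background > 0))
  background <- stats::setNames(as.numeric(background), DNA_BASES)
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  W <- ncol(mat)
  counts <- vapply(seq_len(W), function(j) {
    tabulate(match(mat[, j], DNA_BASES), nbins = 4L)
  }, numeric(4))
  counts <- matrix(counts, nrow = 4, dimnames = list(DNA_BASES, NULL))
  nongap <- colSums(counts)
  degenerate <- nongap == 0
  freqs <- sweep(counts, 2, pmax(nongap, 1), "/")
  freqs[, degenerate] <- NA_real_
  adj <- sweep(counts + pseudocount, 2, nongap + 4 * pseudocount, "/")
  scores <- log2(adj / background)
  scores[, degenerate] <- 0
  structure(list(width = W, freqs = freqs, scores = scores,
                 pseudocount = pseudocount, background = background,
                 n_seqs = length(rows),
                 degenerate_cols = which(degenerate)),
            class = "im_pssm")
}

row_col_scores <- function(pssm, row) {
  chars <- str_chars(row)
  if (length(chars) != pssm$width) {
    stop_input(sprintf("row width %d does not match PSSM width %d",
                       length(chars), pssm$width))
  }
  idx <- match(chars, DNA_BASES)
  s <- rep(0, pssm$width)
  ok <- !is.na(idx)
  s[ok] <- pssm$scores[cbind(idx[ok], which(ok))]
  s
}

#' Positive-sum PSSM score of an aligned row
#'
#' Sums the strictly positive per-column scores of the row's residues.
#' Gap columns contribute 0 (no gap penalties) and negative column scores
#' are disregarded, so the score is never negative and longer matches are
#' not penalized.
#'
#' @param pssm An `im_pssm`.
#' @param row A gapped string of the PSSM's width.
#' @return A list: `value` (score, >= 0) and `positions_used` (number of
#'   columns contributing positively).
#' @export
score_aligned_row <- function(pssm, row) {
  s <- row_col_scores(pssm, row)
  pos <- s > 0
  list(value = sum(s[pos]), positions_used = sum(pos))
}

#' Sliding positive-sum score of an ungapped sequence against a PSSM
#'
#' Considers every integer offset of the sequence against the matrix
#' (overhangs allowed; positions outside the matrix contribute 0) and
#' returns the maximum positive-sum score over offsets.
#'
#' @param pssm An `im_pssm`.
#' @param seq Ungapped DNA string.
#' @return A list: `value` (max score), `positions_used` at the best offset,
#'   and `offset` (0 means sequence position 1 on matrix column 1; the
#'   smallest best offset wins ties).
#' @export
score_sliding <- function(pssm, seq) {
  if (nchar(seq) == 0) stop_input("sequence is empty")
  check_dna(seq, allow_n = FALSE, what = "sequence")
  L <- nchar(seq)
  W <- pssm$width
  idx <- match(str_chars(seq), DNA_BASES)
  best <- list(value = 0, positions_used = 0L, offset = 0L)
  first <- TRUE
  for (off in (1L - L):(W - 1L)) {
    cols <- seq_len(L) + off
    in_mat <- cols >= 1L & cols <= W
    s <- pssm$scores[cbind(idx[in_mat], cols[in_mat])]
    pos <- s > 0
    val <- sum(s[pos])
    if (first || val > best$value) {
      best <- list(value = val, positions_used = sum(pos), offset = off)
      first <- FALSE
    }
  }
  best
}

#' Per-column maximum consensus as a percentage
#'
#' The raw (pseudocount-free) maximum nucleotide proportion per column,
#' rescaled to 0-100; 100 marks a fully conserved column. All-gap columns
#' give `NA`.
#'
#' @param pssm An `im_pssm`.
#' @return Numeric vector of length `pssm$width` in `[0, 100]` (or `NA`).
#' @export
max_column_consensus <- function(pssm) {
  out <- apply(pssm$freqs, 2, function(f) if (anyNA(f)) NA_real_ else max(f) * 100)
  as.numeric(out)
}

#' Majority consensus sequence of a PSSM
#'
#' @param pssm An `im_pssm`.
#' @return Single consensus string (ties go to the first base in A,C,G,T
#'   order; all-gap columns are skipped).
#' @export
consensus_seq <- function(pssm) {
  keep <- !seq_len(pssm$width) %in% pssm$degenerate_cols
  paste(DNA_BASES[apply(pssm$freqs[, keep, drop = FALSE], 2, which.max)],
        collapse = "")
}
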