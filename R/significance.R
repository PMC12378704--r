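#' Uniform random shuffle of a sequence's characters
#'
#' @param seq A string.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return A string with the same length and character composition.
#' @export
shuffle_sequence <- function(seq, seed = NULL) {
  chars <- str_chars(seq)
  with_seed(seed, paste(sample(chars), collapse = ""))
}

# B shuffled-row positive-sum scores for one gapped row; residues are
# permuted within the row's own non-gap columns so the gap structure is
# held fixed.
permutation_scores <- function(pssm, row, B) {
  chars <- str_chars(row)
  if (length(chars) != pssm$width) {
    stop_input(sprintf("row width %d does not match PSSM width %d",
                       length(chars), pssm$width))
  }
  pos <- which(chars != "-")
  if (length(pos) == 0) return(rep(0, B))
  res_idx <- match(chars[pos], DNA_BASES)
  n <- length(pos)
  perm <- vapply(seq_len(B), function(b) res_idx[sample.int(n)], integer(n))
  sc <- pssm$scores[cbind(as.vector(perm), rep(pos, times = B))]
  sc <- matrix(pmax(sc, 0), nrow = n)
  colSums(sc)
}

#' Permutation significance of an aligned row's PSSM score
#'
#' Builds a null distribution of the positive-sum score from `B` random
#' within-row shuffles of the non-gap residues (gap structure fixed), then
#' summarizes the observed score against it with a Z-score and a one-sided
#' t-type p-value.
#'
#' Two t scalings are available. `"calibrated"` (default) treats the
#' observed score as one draw from the null and uses
#' `t = (S - mean) / (sd * sqrt(1 + 1/B))` with `B - 1` degrees of freedom,
#' which is uniform under the null. `"mean_se"` compares the observed score
#' to the null *mean* with `t = (S - mean) / (sd / sqrt(B))`, a much more
#' aggressive filter.
#'
#' Degenerate nulls (`sd = 0`, e.g. a homopolymer row whose shuffles are all
#' identical) give `z = 0` and `p = 1` if the observed score does not exceed
#' the null mean, else the permutation resolution floor `1/(B + 1)`.
#'
#' @param pssm An `im_pssm`.
#' @param row Gapped string of the PSSM's width.
#' @param B Number of permutations (default 1000).
#' @param seed Optional integer seed.
#' @param t_scale `"calibrated"` or `"mean_se"`.
#' @return A list: `p`, `z`, `t`, `score` (observed), and `null`
#'   (`B`, `mean`, `sd`).
#' @export
permutation_test <- function(pssm, row, B = 1000L, seed = NULL,
                             t_scale = c("calibrated", "mean_se")) {
  t_scale <- match.arg(t_scale)
  stopifnot(B >= 2L)
  s_obs <- score_aligned_row(pssm, row)$value
  null <- with_seed(seed, permutation_scores(pssm, row, B))
  m <- mean(null)
  s <- stats::sd(null)
  if (s == 0) {
    z <- 0
    tt <- NA_real_
    p <- if (s_obs <= m) 1 else 1 / (B + 1)
  } else {
    z <- (s_obs - m) / s
    se <- if (t_scale == "calibrated") s * sqrt(1 + 1 / B) else s / sqrt(B)
    tt <- (s_obs - m) / se
    p <- stats::pt(tt, df = B - 1L, lower.tail = FALSE)
  }
  list(p = p, z = z, t = tt, score = s_obs,
       null = list(B = as.integer(B), mean = m, sd = s))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment; order is preserved back to the input
#' positions.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop_input("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Select high-confidence candidates
#'
#' Keeps the `floor(top_frac * n_total)` highest-Z candidates among those
#' passing the FDR filter `q < q_threshold`. `n_total` defaults to the
#' number of rows of `candidates` and should be the total number of scanned
#' candidates when selection is applied to a subset. Ties in Z are broken by
#' score, then genomic coordinate (chrom, start, strand), so selection is
#' deterministic.
#'
#' @param candidates Data.frame with columns `q`, `z`, `score` and (for tie
#'   breaks) `chrom`, `start`, `strand` if available.
#' @param q_threshold FDR threshold (default 0.05).
#' @param top_frac Fraction of `n_total` to retain (default 0.05).
#' @param n_total Total candidate count the fraction refers to.
#' @return Logical vector marking selected rows, in input order.
#' @export
select_candidates <- function(candidates, q_threshold = 0.05, top_frac = 0.05,
                              n_total = nrow(candidates)) {
  n <- nrow(candidates)
  selected <- rep(FALSE, n)
  if (n == 0) return(selected)
  k <- floor(top_frac * n_total)
  eligible <- which(candidates$q < q_threshold)
  if (k <= 0 || length(eligible) == 0) return(selected)
  chrom <- if ("chrom" %in% names(candidates)) candidates$chrom[eligible] else rep("", length(eligible))
  start <- if ("start" %in% names(candidates)) candidates$start[eligible] else seq_along(eligible)
  strand <- if ("strand" %in% names(candidates)) candidates$strand[eligible] else rep("", length(eligible))
  ord <- order(-candidates$z[eligible], -candidates$score[eligible],
               chrom, start, strand)
  keep <- eligible[ord][seq_len(min(k, length(eligible)))]
  selected[keep] <- TRUE
  selected
}
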