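# Independent reference implementations used as oracles.

# full dynamic-programming edit distance
lev_oracle <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  D <- matrix(0L, n + 1L, m + 1L)
  D[, 1] <- 0:n
  D[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1L, j + 1L] <- min(D[i, j + 1L] + 1L,
                               D[i + 1L, j] + 1L,
                               D[i, j] + (x[i] != y[j]))
    }
  }
  D[n + 1L, m + 1L]
}

# literal Benjamini-Hochberg step-up
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(p[o][i:m] * m / (i:m)))
  }, numeric(1))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# two-sided Fisher p by exhaustive hypergeometric enumeration at fixed margins
fisher_p_oracle <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0L, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force sliding positive-sum score over all offsets
sliding_oracle <- function(pssm, seq) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  W <- pssm$width
  best <- -Inf
  for (off in (1L - L):(W - 1L)) {
    tot <- 0
    for (j in seq_len(L)) {
      col <- j + off
      if (col >= 1L && col <= W) {
        s <- pssm$scores[chars[j], col]
        if (s > 0) tot <- tot + s
      }
    }
    best <- max(best, tot)
  }
  best
}

# brute-force gap distance between a candidate interval (0-based half-open)
# and a set of genes (1-based closed), GenomicRanges distance convention
nearest_gap_oracle <- function(c_start0, c_end0, genes) {
  cs <- c_start0 + 1L; ce <- c_end0         # 1-based closed
  gaps <- vapply(seq_len(nrow(genes)), function(i) {
    gs <- genes$start[i]; ge <- genes$end[i]
    if (ce >= gs && cs <= ge) return(0L)
    as.integer(max(gs - ce, cs - ge) - 1L)
  }, integer(1))
  min(gaps)
}

# quick random DNA string
rand_dna <- function(len, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, len, replace = TRUE), collapse = "")
}
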