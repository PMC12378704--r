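#' Extract matches with flanking context
#'
#' Adds up to `flank` reference nucleotides on each side of every match, in
#' motif orientation: for minus-strand matches the 5' flank is the reverse
#' complement of the reference bases immediately 3' of the interval, and vice
#' versa. Flanks are truncated at contig boundaries.
#'
#' @param matches An `im_matches` data.frame.
#' @param genome An `im_genome`.
#' @param flank Maximum flank length (default 3).
#' @return `matches` with added columns `flank5`, `flank3`, `full_seq`.
#' @export
extract_flanked <- function(matches, genome, flank = 3L) {
  if (!inherits(genome, "im_genome")) genome <- genome_seq(genome)
  stopifnot(flank >= 0L)
  n <- nrow(matches)
  flank5 <- flank3 <- character(n)
  for (i in seq_len(n)) {
    s <- unclass(genome)[[matches$chrom[i]]]
    if (is.null(s)) stop_input("chromosome not in genome: ", matches$chrom[i])
    L <- nchar(s)
    st <- matches$start[i]; en <- matches$end[i]
    if (st < 0 || en > L || st >= en) {
      stop_input(sprintf("match coordinates [%d,%d) outside contig %s (length %d)",
                         st, en, matches$chrom[i], L))
    }
    left <- substr(s, max(1L, st - flank + 1L), st)        # ref bases before
    right <- substr(s, en + 1L, min(L, en + flank))        # ref bases after
    if (matches$strand[i] == "-") {
      flank5[i] <- revcomp(right)
      flank3[i] <- revcomp(left)
    } else {
      flank5[i] <- left
      flank3[i] <- right
    }
  }
  matches$flank5 <- flank5
  matches$flank3 <- flank3
  matches$full_seq <- paste0(flank5, matches$seq, flank3)
  matches
}

degap <- function(x) gsub("-", "", x, fixed = TRUE)

# Jaccard-based k-mer distance used for the guide tree; sequences shorter
# than k fall back to exact-identity distance.
kmer_dist_matrix <- function(seqs, k = 3L) {
  sets <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(s)
    unique(substring(s, 1:(n - k + 1L), k:n))
  })
  n <- length(seqs)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      inter <- length(intersect(sets[[i]], sets[[j]]))
      uni <- length(union(sets[[i]], sets[[j]]))
      D[i, j] <- D[j, i] <- 1 - inter / uni
    }
  }
  D
}

PROFILE_ALPHA <- c("A", "C", "G", "T", "-")

profile_freqs <- function(rows) {
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  apply(mat, 2, function(col) {
    tabulate(match(col, PROFILE_ALPHA), nbins = 5L) / length(col)
  })
}

# Needleman-Wunsch profile-profile alignment with linear gap penalty.
# Column score is the expected pair score under the two column frequency
# profiles (match/mismatch on bases, `gap` against a base, 0 for gap-gap).
# Tie-break: diagonal > up (gap in B) > left (gap in A), so the result is
# deterministic.
align_profiles <- function(rowsA, rowsB, match = 1, mismatch = -1, gap = -2) {
  FA <- profile_freqs(rowsA)  # 5 x W1
  FB <- profile_freqs(rowsB)  # 5 x W2
  W1 <- ncol(FA); W2 <- ncol(FB)
  M <- matrix(mismatch, 5, 5, dimnames = list(PROFILE_ALPHA, PROFILE_ALPHA))
  diag(M) <- match
  M[5, ] <- gap; M[, 5] <- gap; M[5, 5] <- 0
  S <- t(FA) %*% M %*% FB
  gA <- gap * (1 - FA[5, ])   # cost of a new gap column against A's column
  gB <- gap * (1 - FB[5, ])
  H <- matrix(0, W1 + 1L, W2 + 1L)
  P <- matrix(0L, W1 + 1L, W2 + 1L)   # 1 diag, 2 up, 3 left
  H[, 1] <- c(0, cumsum(gA)); P[2:(W1 + 1L), 1] <- 2L
  H[1, ] <- c(0, cumsum(gB)); P[1, 2:(W2 + 1L)] <- 3L
  for (i in seq_len(W1)) {
    Hi <- H[i, ]       # previous row
    Hc <- H[i + 1L, ]  # current row (being filled)
    Pi <- P[i + 1L, ]
    for (j in seq_len(W2)) {
      d <- Hi[j] + S[i, j]
      u <- Hi[j + 1L] + gA[i]
      l <- Hc[j] + gB[j]
      if (d >= u && d >= l) { Hc[j + 1L] <- d; Pi[j + 1L] <- 1L }
      else if (u >= l) { Hc[j + 1L] <- u; Pi[j + 1L] <- 2L }
      else { Hc[j + 1L] <- l; Pi[j + 1L] <- 3L }
    }
    H[i + 1L, ] <- Hc
    P[i + 1L, ] <- Pi
  }
  # traceback: record which source column (or gap) each merged column uses
  i <- W1; j <- W2
  takeA <- integer(0); takeB <- integer(0)
  while (i > 0L || j > 0L) {
    mv <- P[i + 1L, j + 1L]
    if (mv == 1L) { takeA <- c(i, takeA); takeB <- c(j, takeB); i <- i - 1L; j <- j - 1L }
    else if (mv == 2L) { takeA <- c(i, takeA); takeB <- c(0L, takeB); i <- i - 1L }
    else { takeA <- c(0L, takeA); takeB <- c(j, takeB); j <- j - 1L }
  }
  expand <- function(rows, take) {
    mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
    out <- matrix("-", nrow(mat), length(take))
    out[, take > 0L] <- mat[, take[take > 0L], drop = FALSE]
    apply(out, 1, paste, collapse = "")
  }
  c(expand(rowsA, takeA), expand(rowsB, takeB))
}

builtin_align <- function(seqs, k = 3L, match = 1, mismatch = -1, gap = -2) {
  n <- length(seqs)
  if (n == 1L) return(seqs)
  if (n == 2L) {
    ali <- align_profiles(seqs[1], seqs[2], match, mismatch, gap)
    return(ali)
  }
  D <- kmer_dist_matrix(seqs, k)
  hc <- stats::hclust(stats::as.dist(D), method = "average")  # UPGMA guide tree
  profiles <- vector("list", n - 1L)
  members <- vector("list", n - 1L)
  getp <- function(id) {
    if (id < 0L) list(rows = seqs[-id], idx = -id)
    else list(rows = profiles[[id]], idx = members[[id]])
  }
  for (m in seq_len(n - 1L)) {
    a <- getp(hc$merge[m, 1]); b <- getp(hc$merge[m, 2])
    profiles[[m]] <- align_profiles(a$rows, b$rows, match, mismatch, gap)
    members[[m]] <- c(a$idx, b$idx)
  }
  rows <- profiles[[n - 1L]]
  rows[order(members[[n - 1L]])]   # restore input order
}

external_align <- function(seqs, ids, cmd = "mafft", args = c("--quiet", "--auto")) {
  if (Sys.which(cmd) == "") {
    stop_input(sprintf(paste0("external alignment engine '%s' not found on PATH; ",
                              "re-run with engine = \"builtin\""), cmd))
  }
  fin <- tempfile(fileext = ".fa"); fout <- tempfile(fileext = ".fa")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- ids
  Biostrings::writeXStringSet(ss, fin)
  status <- system2(cmd, c(args, shQuote(fin)), stdout = fout, stderr = FALSE)
  if (status != 0) stop_input(sprintf("external aligner '%s' exited with status %d", cmd, status))
  out <- Biostrings::readDNAStringSet(fout)
  rows <- toupper(as.character(out))
  rows[match(ids, names(out))]
}

#' Align a group of flanked match sequences
#'
#' The builtin engine is a deterministic progressive aligner: a UPGMA guide
#' tree on shared 3-mer Jaccard distance, then profile-profile global
#' alignment with match +1, mismatch -1, linear gap -2. The external engine
#' shells out to an aligner that reads and writes FASTA (default `mafft`).
#'
#' @param seqs Character vector of ungapped DNA sequences (input order is
#'   preserved in the output rows).
#' @param ids Optional row identifiers (default `seq_along(seqs)` as strings).
#' @param engine `"builtin"` or `"external"`.
#' @param external_cmd Command for the external engine.
#' @param match,mismatch,gap Builtin scoring parameters.
#' @return A list of class `im_alignment`: `rows` (gapped strings), `ids`,
#'   `width`, `engine`.
#' @examples
#' align_group(c("CCCAACCC", "CCCACCC"))
#' @export
align_group <- function(seqs, ids = NULL, engine = c("builtin", "external"),
                        external_cmd = "mafft",
                        match = 1, mismatch = -1, gap = -2) {
  engine <- match.arg(engine)
  if (length(seqs) < 1L) stop_input("at least one sequence is required")
  check_dna(seqs, allow_n = FALSE, what = "alignment input")
  if (is.null(ids)) ids <- as.character(seq_along(seqs))
  stopifnot(length(ids) == length(seqs), !anyDuplicated(ids))
  rows <- if (engine == "builtin") {
    builtin_align(seqs, match = match, mismatch = mismatch, gap = gap)
  } else {
    external_align(seqs, ids, cmd = external_cmd)
  }
  bad <- degap(rows) != seqs
  if (any(bad)) {
    stop(sprintf("alignment corrupted %d row(s): de-gapping does not reproduce the input",
                 sum(bad)))
  }
  structure(list(rows = stats::setNames(rows, ids), ids = ids,
                 width = nchar(rows[1]), engine = engine),
            class = "im_alignment")
}

#' Write an alignment as gapped FASTA
#' @param aln An `im_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  ss <- Biostrings::BStringSet(aln$rows)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a gapped FASTA alignment
#' @param path Aligned FASTA path.
#' @param engine Engine label to record (default `"external"`).
#' @return An `im_alignment`.
#' @export
read_alignment <- function(path, engine = "external") {
  ss <- Biostrings::readBStringSet(path)
  rows <- toupper(as.character(ss))
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop_input("alignment rows have unequal widths")
  structure(list(rows = rows, ids = names(rows), width = w, engine = engine),
            class = "im_alignment")
}
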