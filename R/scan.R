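#' Define a C-run motif pattern
#'
#' The default pattern is (C3 N1-12)3 C3: four runs of three cytosines
#' separated by three loops of 1-12 arbitrary nucleotides, the canonical
#' i-motif-forming grammar.
#'
#' @param run_base Single nucleotide forming the runs (default `"C"`).
#' @param run_len Length of each run (default 3).
#' @param n_runs Number of runs (default 4).
#' @param loop_min,loop_max Loop length bounds (defaults 1 and 12).
#' @return A list of class `im_pattern`.
#' @examples
#' motif_pattern()
#' @export
motif_pattern <- function(run_base = "C", run_len = 3L, n_runs = 4L,
                          loop_min = 1L, loop_max = 12L) {
  stopifnot(run_base %in% DNA_BASES, run_len >= 1L, n_runs >= 2L,
            loop_min >= 1L, loop_min <= loop_max)
  structure(list(run_base = run_base, run_len = as.integer(run_len),
                 n_runs = as.integer(n_runs), loop_min = as.integer(loop_min),
                 loop_max = as.integer(loop_max)),
            class = "im_pattern")
}

#' Regular expression for a motif pattern
#'
#' Loops are restricted to A/C/G/T, so a match can never span an N base.
#'
#' @param pattern An `im_pattern`.
#' @return A single regex string (greedy quantifiers).
#' @export
pattern_regex <- function(pattern = motif_pattern()) {
  run <- strrep(pattern$run_base, pattern$run_len)
  loop <- sprintf("[ACGT]{%d,%d}", pattern$loop_min, pattern$loop_max)
  sprintf("(?:%s%s){%d}%s", run, loop, pattern$n_runs - 1L, run)
}

#' Analytic match length bounds for a pattern
#'
#' @param pattern An `im_pattern`.
#' @return Named integer vector `c(min, max)`.
#' @examples
#' match_length_bounds(motif_pattern())  # 15, 48
#' @export
match_length_bounds <- function(pattern = motif_pattern()) {
  core <- pattern$n_runs * pattern$run_len
  c(min = core + (pattern$n_runs - 1L) * pattern$loop_min,
    max = core + (pattern$n_runs - 1L) * pattern$loop_max)
}

scan_one_strand <- function(seq, rx) {
  m <- gregexpr(rx, seq, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(start = integer(0), end = integer(0),
                      seq = character(0), stringsAsFactors = FALSE))
  }
  len <- attr(m, "match.length")
  data.frame(start = as.integer(m) - 1L,              # 0-based half-open
             end = as.integer(m) - 1L + len,
             seq = substring(seq, m, m + len - 1L),
             stringsAsFactors = FALSE)
}

#' Scan a genome for motif matches on both strands
#'
#' Matching is non-overlapping, leftmost, and greedy (standard regex engine
#' semantics) on each strand independently. Reverse-strand hits are found by
#' scanning the reverse complement and mapped back to reference coordinates;
#' their `seq` is reported in motif orientation (the minus-strand sequence).
#' Matches can never contain N, which is not cytosine-compatible.
#'
#' @param genome An `im_genome` (or named character vector of A/C/G/T/N).
#' @param pattern An `im_pattern`.
#' @param chroms Optional subset of chromosomes to scan.
#' @return A data.frame of class `im_matches` with columns `chrom`, `start`,
#'   `end` (0-based half-open reference coordinates), `strand` (`"+"`/`"-"`),
#'   and `seq`, sorted by chromosome, start, strand.
#' @examples
#' scan_motifs(genome_seq(c(chr = "GGGTGGGTGGGTGGG")))
#' @export
scan_motifs <- function(genome, pattern = motif_pattern(), chroms = NULL) {
  if (!inherits(genome, "im_genome")) genome <- genome_seq(genome)
  if (!is.null(chroms)) genome <- genome_seq(unclass(genome)[chroms])
  rx <- pattern_regex(pattern)
  out <- lapply(names(genome), function(chrom) {
    s <- unclass(genome)[[chrom]]
    L <- nchar(s)
    fwd <- scan_one_strand(s, rx)
    if (nrow(fwd) > 0) {
      fwd$chrom <- chrom
      fwd$strand <- "+"
    }
    rev <- scan_one_strand(revcomp(s), rx)
    if (nrow(rev) > 0) {
      # start_ref = L - end_rc (0-based half-open interval mirror)
      tmp <- rev
      rev$start <- L - tmp$end
      rev$end <- L - tmp$start
      rev$chrom <- chrom
      rev$strand <- "-"
    }
    rbind(fwd, rev)
  })
  out <- do.call(rbind, out[vapply(out, nrow, 1L) > 0])
  if (is.null(out) || nrow(out) == 0) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      seq = character(0), stringsAsFactors = FALSE)
  } else {
    out <- out[, c("chrom", "start", "end", "strand", "seq")]
    out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
    rownames(out) <- NULL
    out$id <- sprintf("%s:%d-%d(%s)", out$chrom, out$start, out$end, out$strand)
  }
  class(out) <- c("im_matches", "data.frame")
  out
}

#' Summarize motif matches by chromosome and strand
#'
#' @param matches An `im_matches` data.frame.
#' @return A list with `total`, a `by_group` count table (chrom x strand),
#'   and `length_stats` (mean/median/sd/min/max of match lengths; `NA` and
#'   `undefined = TRUE` when there are no matches).
#' @export
summarize_matches <- function(matches) {
  total <- nrow(matches)
  if (total == 0) {
    return(list(total = 0L,
                by_group = data.frame(chrom = character(0), strand = character(0),
                                      n = integer(0)),
                length_stats = list(mean = NA_real_, median = NA_real_,
                                    sd = NA_real_, min = NA_integer_,
                                    max = NA_integer_, undefined = TRUE)))
  }
  lens <- matches$end - matches$start
  by_group <- as.data.frame(table(chrom = matches$chrom, strand = matches$strand),
                            stringsAsFactors = FALSE)
  names(by_group)[3] <- "n"
  by_group <- by_group[by_group$n > 0, , drop = FALSE]
  rownames(by_group) <- NULL
  list(total = total,
       by_group = by_group,
       length_stats = list(mean = mean(lens), median = stats::median(lens),
                           sd = stats::sd(lens), min = min(lens),
                           max = max(lens), undefined = FALSE))
}

matches_to_granges <- function(matches) {
  GenomicRanges::GRanges(
    seqnames = matches$chrom,
    ranges = IRanges::IRanges(start = matches$start + 1L, end = matches$end),
    strand = matches$strand,
    name = matches$id,
    score = 0L
  )
}

#' Write matches as BED6
#'
#' Coordinates in the BED file are 0-based half-open, as the format requires.
#'
#' @param matches An `im_matches` data.frame.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_matches_bed <- function(matches, path) {
  if (nrow(matches) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  rtracklayer::export(matches_to_granges(matches), path, format = "BED")
  invisible(path)
}

#' Read a BED6 file of matches and recover sequences from a genome
#'
#' @param path BED path.
#' @param genome An `im_genome` used to re-extract match sequences.
#' @return An `im_matches` data.frame.
#' @export
read_matches_bed <- function(path, genome) {
  gr <- rtracklayer::import(path, format = "BED")
  matches <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  matches$seq <- extract_match_seq(matches, genome)
  matches$id <- sprintf("%s:%d-%d(%s)", matches$chrom, matches$start,
                        matches$end, matches$strand)
  class(matches) <- c("im_matches", "data.frame")
  matches
}

#' Re-extract match sequences from the reference (motif orientation)
#'
#' @param matches An `im_matches`-like data.frame (chrom/start/end/strand).
#' @param genome An `im_genome`.
#' @return Character vector of sequences in motif orientation.
#' @export
extract_match_seq <- function(matches, genome) {
  if (!inherits(genome, "im_genome")) genome <- genome_seq(genome)
  vapply(seq_len(nrow(matches)), function(i) {
    s <- unclass(genome)[[matches$chrom[i]]]
    frag <- substr(s, matches$start[i] + 1L, matches$end[i])
    if (matches$strand[i] == "-") revcomp(frag) else frag
  }, character(1))
}
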