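test_that("match length bounds follow the run/loop arithmetic", {
  expect_identical(match_length_bounds(motif_pattern()), c(min = 15L, max = 48L))
  expect_identical(match_length_bounds(motif_pattern(loop_min = 1, loop_max = 1)),
                   c(min = 15L, max = 15L))
  # two-run pattern: enumerate every loop length and scan the generated string
  p2 <- motif_pattern(n_runs = 2)
  lens <- vapply(1:12, function(l) {
    m <- scan_motifs(genome_seq(c(chr = paste0("CCC", strrep("A", l), "CCC"))), p2)
    m$end[1] - m$start[1]
  }, integer(1))
  expect_identical(range(lens), c(7L, 18L))
  expect_identical(match_length_bounds(p2), c(min = 7L, max = 18L))
})

test_that("scanning finds motifs on both strands in reference coordinates", {
  m <- scan_motifs(genome_seq(c(chr = "CCCACCCACCCACCC")))
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 0L)
  expect_equal(m$end, 15L)
  expect_equal(m$strand, "+")
  expect_equal(m$seq, "CCCACCCACCCACCC")

  expect_equal(nrow(scan_motifs(genome_seq(c(chr = "ATATATATATATATAT")))), 0L)

  m <- scan_motifs(genome_seq(c(chr = "GGGTGGGTGGGTGGG")))
  expect_equal(nrow(m), 1L)
  expect_equal(m$strand, "-")
  expect_equal(m$seq, "CCCACCCACCCACCC")
  expect_equal(c(m$start, m$end), c(0L, 15L))

  # offset minus-strand hit maps back through start_ref = L - end_rc
  g <- genome_seq(c(chr = paste0("TTTT", "GGGTGGGTGGGTGGG", "AA")))
  m <- scan_motifs(g)
  expect_equal(c(m$start, m$end, m$strand), c("4", "19", "-"))
})

test_that("matches spanning N are never reported and bad alphabets error", {
  expect_equal(nrow(scan_motifs(genome_seq(c(chr = "CCCNCCCACCCACCC")))), 0L)
  expect_error(genome_seq(c(chr = "CCCRCCCACCCACCC")), "alphabet")
})

test_that("reported matches re-extract exactly from the reference", {
  sim <- simulate_genome(genome_length = 25000, n_implants = 20, seed = 101)
  m <- scan_motifs(sim$genome)
  expect_identical(extract_match_seq(m, sim$genome), m$seq)
  lens <- m$end - m$start
  b <- match_length_bounds(motif_pattern())
  expect_true(all(lens >= b["min"] & lens <= b["max"]))
  # per-strand matches are non-overlapping
  for (s in c("+", "-")) {
    ms <- m[m$strand == s, ]
    ms <- ms[order(ms$start), ]
    if (nrow(ms) > 1) expect_true(all(ms$start[-1] >= ms$end[-nrow(ms)]))
  }
})

test_that("scanning the reverse-complemented genome mirrors strands", {
  sim <- simulate_genome(genome_length = 15000, n_implants = 12, seed = 77)
  g <- sim$genome
  m <- scan_motifs(g)
  g_rc <- genome_seq(setNames(revcomp(unclass(g)), names(g)))
  m_rc <- scan_motifs(g_rc)
  L <- nchar(unclass(g)[[1]])
  flip <- data.frame(chrom = m$chrom, start = L - m$end, end = L - m$start,
                     strand = ifelse(m$strand == "+", "-", "+"), seq = m$seq,
                     stringsAsFactors = FALSE)
  flip <- flip[order(flip$start, flip$strand), ]
  got <- m_rc[order(m_rc$start, m_rc$strand),
              c("chrom", "start", "end", "strand", "seq")]
  rownames(flip) <- rownames(got) <- NULL
  expect_equal(as.data.frame(got), flip)
})

test_that("fixture scans recover exactly the implanted truth set", {
  sim <- simulate_genome(genome_length = 30000, n_implants = 25, seed = 5)
  m <- scan_motifs(sim$genome)
  cols <- c("chrom", "start", "end", "strand", "seq")
  expect_equal(as.data.frame(m[, cols]), as.data.frame(sim$truth[, cols]))
})

test_that("match summaries count per group and describe lengths", {
  m <- data.frame(chrom = "c", start = c(0L, 20L, 40L), end = c(15L, 36L, 57L),
                  strand = c("+", "+", "-"), seq = "x")
  s <- summarize_matches(m)
  expect_equal(s$total, 3L)
  expect_equal(s$length_stats$mean, 16)
  expect_equal(s$length_stats$median, 16)
  expect_equal(sum(s$by_group$n), 3L)
  s0 <- summarize_matches(m[0, ])
  expect_equal(s0$total, 0L)
  expect_true(s0$length_stats$undefined)
})

test_that("BED round trip preserves coordinates and strand", {
  sim <- simulate_genome(genome_length = 12000, n_implants = 8, seed = 31)
  m <- scan_motifs(sim$genome)
  bed <- tempfile(fileext = ".bed")
  write_matches_bed(m, bed)
  back <- read_matches_bed(bed, sim$genome)
  cols <- c("chrom", "start", "end", "strand", "seq")
  expect_equal(as.data.frame(back[order(back$start), cols]),
               as.data.frame(m[order(m$start), cols]))
})
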