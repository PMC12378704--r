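toy_models <- function() {
  genes <- data.frame(
    gene_id = c("G1", "G2", "G3"),
    symbol = c("ALPHA", "BETA", "GAMMA"),
    chrom = "chr1",
    start = c(1000L, 2600L, 9000L),
    end = c(2000L, 3000L, 9500L),
    strand = c("+", "+", "-"),
    stringsAsFactors = FALSE
  )
  exons <- data.frame(
    gene_id = c("G1", "G1", "G2", "G3"),
    chrom = "chr1",
    start = c(1000L, 1900L, 2600L, 9000L),
    end = c(1100L, 2000L, 2700L, 9100L),
    strand = c("+", "+", "+", "-"),
    stringsAsFactors = FALSE
  )
  utr5 <- data.frame(gene_id = "G1", chrom = "chr1", start = 1000L, end = 1050L,
                     strand = "+", stringsAsFactors = FALSE)
  utr3 <- data.frame(gene_id = "G1", chrom = "chr1", start = 1950L, end = 2000L,
                     strand = "+", stringsAsFactors = FALSE)
  gene_models(genes, exons = exons, utr5 = utr5, utr3 = utr3)
}

cand_df <- function(start0, end0, chrom = "chr1") {
  data.frame(chrom = chrom, start = start0, end = end0, strand = "+",
             stringsAsFactors = FALSE)
}

test_that("candidates get one mode and one region by the fixed precedence", {
  m <- toy_models()
  # deep inside G1, not touching exons/UTRs/promoters -> intron, correct
  a <- annotate_candidates(cand_df(1500L, 1520L), m,
                           promoter_window = c(100L, 50L))
  expect_equal(a$mode, "correct")
  expect_equal(a$distance, 0)
  expect_equal(a$region, "intron")
  expect_equal(a$gene_symbol, "ALPHA")

  # 500 bp upstream of the only nearby gene with a tiny promoter window
  b <- annotate_candidates(cand_df(8479L, 8499L), m,
                           promoter_window = c(100L, 0L))
  expect_equal(b$mode, "nearest")
  expect_equal(b$distance, 500)
  expect_equal(b$gene_symbol, "GAMMA")

  # overlaps an exon of G1 AND the promoter window of G2 -> promoter wins
  cc <- annotate_candidates(cand_df(1950L, 1980L), m,
                            promoter_window = c(2000L, 200L))
  expect_equal(cc$region, "promoter")
  expect_equal(cc$mode, "correct")

  # exon beats intron when no promoter/UTR overlaps
  d <- annotate_candidates(cand_df(1060L, 1080L), m,
                           promoter_window = c(10L, 5L))
  expect_equal(d$region, "exon")

  # 5' UTR beats exon
  e <- annotate_candidates(cand_df(1010L, 1030L), m,
                           promoter_window = c(5L, 0L))
  expect_equal(e$region, "5UTR")
})

test_that("chromosomes absent from the gene set warn and fall to intergenic", {
  m <- toy_models()
  expect_warning(
    out <- annotate_candidates(cand_df(100L, 120L, chrom = "chrZ"), m),
    "absent")
  expect_equal(out$region, "distal_intergenic")
  expect_true(is.na(out$distance))
})

test_that("nearest-gene distances match a brute-force gap oracle", {
  set.seed(19)
  genes <- data.frame(
    gene_id = sprintf("G%02d", 1:40),
    symbol = sprintf("S%02d", 1:40),
    chrom = "chr1",
    start = sort(sample(seq(1000L, 200000L, by = 50L), 40)),
    stringsAsFactors = FALSE
  )
  genes$end <- genes$start + sample(200:2000, 40, replace = TRUE)
  genes$strand <- sample(c("+", "-"), 40, replace = TRUE)
  m <- gene_models(genes)
  starts <- sample(1000:220000, 30)
  cands <- cand_df(starts, starts + 25L)
  out <- annotate_candidates(cands, m, promoter_window = c(1L, 0L))
  for (i in seq_len(30)) {
    gap <- nearest_gap_oracle(cands$start[i], cands$end[i], genes)
    expect_equal(out$distance[i], gap)
    expect_equal(out$mode[i] == "correct", gap == 0L)
  }
  expect_true(all(out$mode %in% c("correct", "nearest")))
  expect_true(all(out$region %in% c("promoter", "5UTR", "3UTR", "exon",
                                    "intron", "distal_intergenic")))
})

test_that("Fisher's exact test matches hypergeometric enumeration", {
  sym <- fisher_exact_2x2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(sym$odds_ratio, 1, tolerance = 1e-6)
  expect_equal(sym$p, 1)

  diag5 <- fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2))
  expect_equal(diag5$p, 2 / 252, tolerance = 1e-12)

  set.seed(23)
  for (rep in 1:50) {
    tab <- matrix(sample(0:12, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    res <- fisher_exact_2x2(tab)
    expect_equal(res$p, fisher_p_oracle(tab), tolerance = 1e-8)
    expect_equal(res$p, fisher_exact_2x2(t(tab))$p, tolerance = 1e-12)
  }

  deg <- fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 1)
  expect_error(fisher_exact_2x2(matrix(c(1, 2, 3), 1)), "2x2")
  expect_error(fisher_exact_2x2(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("gene-class enrichment recovers fixture truth", {
  # all implants inside immune genes, housekeeping genes empty
  sim <- simulate_genome(genome_length = 30000, n_implants = 8, seed = 55,
                         n_immune_genes = 8, n_housekeeping_genes = 8,
                         frac_implants_in_immune = 1)
  ann <- annotate_candidates(sim$truth, sim$models,
                             immune_set = sim$gene_classes$immune,
                             housekeeping_set = sim$gene_classes$housekeeping)
  enr <- gene_class_enrichment(ann, sim$gene_classes$immune,
                               sim$gene_classes$housekeeping,
                               background_genes = sim$genes$symbol)
  expect_equal(enr$table["housekeeping", "candidate"], 0L)
  expect_gt(enr$table["immune", "candidate"], 0L)
  expect_lt(enr$p, 0.01)
  expect_gt(enr$odds_ratio, 10)

  # proportional hits give an odds ratio near 1
  ann_prop <- data.frame(gene_symbol = c(paste0("I", 1:5), paste0("H", 1:5)))
  enr_prop <- gene_class_enrichment(ann_prop, paste0("I", 1:10), paste0("H", 1:10),
                                    background_genes = c(paste0("I", 1:10),
                                                         paste0("H", 1:10)))
  expect_equal(enr_prop$p, 1)

  # no candidates at all -> degenerate margin flagged
  enr_empty <- gene_class_enrichment(data.frame(gene_symbol = NA_character_),
                                     paste0("I", 1:3), paste0("H", 1:3),
                                     background_genes = c(paste0("I", 1:3),
                                                          paste0("H", 1:3)))
  expect_true(enr_empty$degenerate)

  expect_error(gene_class_enrichment(ann_prop, character(0), "H1", "H1"),
               "non-empty")
})

test_that("GTF round trip reproduces the toy gene models", {
  sim <- simulate_genome(genome_length = 20000, n_implants = 8, seed = 91)
  gtf <- tempfile(fileext = ".gtf")
  write_toy_gtf(sim$genes, sim$exons, gtf)
  models <- read_gene_models(gtf)
  expect_equal(length(models$genes), nrow(sim$genes))
  expect_setequal(S4Vectors::mcols(models$genes)$symbol, sim$genes$symbol)
  expect_equal(length(models$exons), nrow(sim$exons))
})
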