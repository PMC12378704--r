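test_that("edit distance matches the DP oracle and is a metric", {
  expect_equal(levenshtein("CCCA", "CCCA"), 0L)
  expect_equal(levenshtein("CCCA", "CCCG"), 1L)
  expect_equal(levenshtein("", "ACGT"), 4L)
  set.seed(29)
  for (rep in 1:50) {
    a <- rand_dna(sample(1:25, 1))
    b <- rand_dna(sample(1:25, 1))
    c <- rand_dna(sample(1:25, 1))
    expect_equal(levenshtein(a, b), lev_oracle(a, b))
    expect_equal(levenshtein(a, b), levenshtein(b, a))
    expect_lte(levenshtein(a, c), levenshtein(a, b) + levenshtein(b, c))
  }
})

test_that("k-mer Jaccard similarity follows the set definition", {
  expect_equal(jaccard_kmer("CCCACCC", "CCCACCC"), 1)
  expect_equal(jaccard_kmer("CCCA", "CCCC"), 0.5)
  expect_equal(jaccard_kmer("AAAA", "GGGG"), 0)
  expect_error(jaccard_kmer("AC", "ACGT"), "shorter than k")
  set.seed(37)
  for (rep in 1:40) {
    a <- rand_dna(sample(3:20, 1))
    b <- rand_dna(sample(3:20, 1))
    j <- jaccard_kmer(a, b)
    expect_gte(j, 0); expect_lte(j, 1)
    sa <- unique(substring(a, 1:(nchar(a) - 2), 3:nchar(a)))
    sb <- unique(substring(b, 1:(nchar(b) - 2), 3:nchar(b)))
    expect_equal(j == 1, setequal(sa, sb))
  }
})

test_that("similarity triage separates C-rich candidates from G-rich decoys", {
  set.seed(41)
  # C-rich draws with A/T loops vs their G-rich reverse complements: the two
  # families share no C- or G-containing k-mers, so separation is exact
  at_im <- function() {
    loops <- replicate(3, rand_dna(sample(1:12, 1), bases = c("A", "T")))
    paste0("CCC", loops[1], "CCC", loops[2], "CCC", loops[3], "CCC")
  }
  positives <- replicate(40, at_im())
  negatives <- revcomp(replicate(40, at_im()))
  candidates <- replicate(30, at_im())

  lev <- classify_by_similarity(candidates, positives, negatives,
                                metric = "levenshtein")
  expect_true(all(lev$labels$label == "positive"))

  jac <- classify_by_similarity(candidates, positives, negatives,
                                metric = "jaccard")
  expect_true(all(jac$labels$label == "positive"))
  expect_equal(jac$auc, 1.0)
  expect_true(jac$cutoff > 0 && jac$cutoff < 1)
  expect_true(all(jac$labels$best_pos > jac$cutoff))

  # identical to a positive control -> positive
  one <- classify_by_similarity(positives[1], positives, negatives,
                                metric = "levenshtein")
  expect_equal(one$labels$label, "positive")

  # equidistant -> conservative negative call
  tie <- classify_by_similarity("AAAA", "AAAT", "AAAG", metric = "levenshtein")
  expect_equal(tie$labels$label, "negative")
})

test_that("rank-sum test agrees with the exact and approximate references", {
  r <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(r$W, 0)
  expect_equal(r$p, 1 / 3)
  expect_equal(r$method, "exact")

  same <- wilcoxon_rank_sum(c(1, 2, 3), c(3, 1, 2))
  expect_equal(same$p, 1)

  set.seed(43)
  # exact branch vs wilcox.test on tie-free small samples
  for (rep in 1:150) {
    n <- sample(2:5, 1); m <- sample(2:5, 1)
    x <- rnorm(n); y <- rnorm(m)
    ref <- suppressWarnings(wilcox.test(x, y))
    got <- wilcoxon_rank_sum(x, y)
    expect_equal(got$W, unname(ref$statistic))
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
  # normal-approximation branch vs wilcox.test with continuity correction
  for (rep in 1:50) {
    n <- sample(8:20, 1); m <- sample(8:20, 1)
    x <- sample(1:10, n, replace = TRUE)   # ties on purpose
    y <- sample(1:10, m, replace = TRUE) + sample(0:2, m, replace = TRUE)
    ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    got <- wilcoxon_rank_sum(x, y)
    expect_equal(got$method, "normal")
    expect_equal(got$W, unname(ref$statistic))
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("generated negative sequences are CCC-free and reproducible", {
  neg <- generate_negative_sequences(300, seed = 47)
  expect_false(any(grepl("CCC", neg, fixed = TRUE)))
  expect_true(all(nchar(neg) >= 15 & nchar(neg) <= 50))
  expect_identical(neg, generate_negative_sequences(300, seed = 47))
  expect_false(identical(neg, generate_negative_sequences(300, seed = 48)))
})

test_that("composition features are proportions plus length", {
  f <- extract_features(c("CCCC", "ACGT"))
  expect_equal(f$freq_C, c(1, 0.25))
  expect_equal(f$freq_A[2], 0.25)
  expect_equal(f$length, c(4L, 4L))
  expect_error(extract_features("ACGN"), "alphabet")
  set.seed(53)
  seqs <- vapply(sample(5:60, 50, replace = TRUE), rand_dna, character(1))
  ff <- extract_features(seqs)
  expect_equal(rowSums(ff[, 1:4]), rep(1, 50), tolerance = 1e-9)
})

test_that("the composition classifier separates motif-like from negatives", {
  # short-loop motif draws are at least 50% cytosine while CCC-free random
  # negatives hover near 25%, so a freq_C threshold separates the classes
  set.seed(59)
  pos <- replicate(150, sample_im_like(loop_len_range = c(1, 4)))
  neg <- generate_negative_sequences(150)
  feat <- extract_features(c(pos, neg))
  lab <- factor(rep(c("iM", "background"), c(150, 150)),
                levels = c("iM", "background"))
  res <- train_and_evaluate_classifier(feat, lab, ntree = 300, seed = 61)
  expect_gte(res$accuracy, 0.95)
  expect_gte(res$auc, 0.99)
  expect_equal(names(res$feature_importance)[1], "freq_C")
  expect_true(res$chosen_mtry %in% 1:5)
  expect_equal(sum(res$confusion_matrix), 90)   # held-out 30%

  # the realistic mixed task (G-rich decoys plus CCC-free randoms) still
  # ranks cytosine frequency as the dominant feature
  set.seed(62)
  pos2 <- replicate(150, sample_im_like())
  neg2 <- c(replicate(75, sample_g4_like()), generate_negative_sequences(75))
  res_mixed <- train_and_evaluate_classifier(
    extract_features(c(pos2, neg2)),
    factor(rep(c("iM", "background"), each = 150), levels = c("iM", "background")),
    ntree = 300, seed = 63)
  expect_gte(res_mixed$accuracy, 0.9)
  expect_equal(names(res_mixed$feature_importance)[1], "freq_C")

  # bit-identical reproducibility at a fixed seed
  res2 <- train_and_evaluate_classifier(feat, lab, ntree = 300, seed = 61)
  expect_identical(res$accuracy, res2$accuracy)
  expect_identical(res$auc, res2$auc)
  expect_identical(res$feature_importance, res2$feature_importance)

  # permuted labels collapse accuracy to the class prior
  set.seed(67)
  perm <- sample(lab)
  res_perm <- train_and_evaluate_classifier(feat, perm, ntree = 200, seed = 71)
  expect_lt(abs(res_perm$accuracy - 0.5), 0.1 + 1e-9)

  expect_error(
    train_and_evaluate_classifier(feat, factor(rep("iM", 300))),
    "two classes")
})
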