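#' Levenshtein (unit-cost edit) distance
#'
#' @param a,b Character vectors of strings.
#' @return If both are scalars, a single integer; otherwise the
#'   `length(a)` x `length(b)` integer distance matrix.
#' @examples
#' levenshtein("CCCA", "CCCG")
#' @export
levenshtein <- function(a, b) {
  d <- utils::adist(a, b)
  if (length(a) == 1L && length(b) == 1L) return(as.integer(d[1, 1]))
  storage.mode(d) <- "integer"
  d
}

kmer_set <- function(x, k) {
  n <- nchar(x)
  if (n < k) stop_input(sprintf("sequence of length %d is shorter than k = %d", n, k))
  unique(substring(x, 1:(n - k + 1L), k:n))
}

#' Jaccard similarity over distinct k-mers
#'
#' @param a,b Strings with at least `k` characters.
#' @param k k-mer length (default 3).
#' @return Similarity in `[0, 1]`.
#' @examples
#' jaccard_kmer("CCCA", "CCCC")  # {CCC,CCA} vs {CCC} -> 0.5
#' @export
jaccard_kmer <- function(a, b, k = 3L) {
  sa <- kmer_set(a, k)
  sb <- kmer_set(b, k)
  length(intersect(sa, sb)) / length(union(sa, sb))
}

max_jaccard_to_set <- function(seqs, set, k = 3L) {
  set_kmers <- lapply(set, kmer_set, k = k)
  vapply(seqs, function(s) {
    ks <- kmer_set(s, k)
    max(vapply(set_kmers, function(t) {
      length(intersect(ks, t)) / length(union(ks, t))
    }, numeric(1)))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Similarity triage of candidates against positive and negative controls
#'
#' Each candidate gets its best similarity to the positive set and to the
#' negative set (Levenshtein: smaller distance is more similar; Jaccard:
#' larger is more similar) and is labelled `"positive"` when strictly closer
#' to the positives; ties go to `"negative"` (conservative). For the
#' Jaccard metric a ROC over the max-similarity-to-positives score, with
#' candidates as the positive class and the negative controls as the
#' negative class, yields an AUC and the Youden-J optimal cutoff.
#'
#' @param candidates Character vector of candidate sequences.
#' @param positives,negatives Non-empty character vectors of control
#'   sequences.
#' @param metric `"levenshtein"` or `"jaccard"`.
#' @param k k-mer length for the Jaccard metric.
#' @return A list: `labels` data.frame (`seq`, `best_pos`, `best_neg`,
#'   `label`), and for Jaccard additionally `auc` and `cutoff`.
#' @export
classify_by_similarity <- function(candidates, positives, negatives,
                                   metric = c("levenshtein", "jaccard"),
                                   k = 3L) {
  metric <- match.arg(metric)
  if (length(positives) == 0 || length(negatives) == 0) {
    stop_input("control sets must be non-empty")
  }
  if (length(candidates) == 0) {
    return(list(labels = data.frame(seq = character(0), best_pos = numeric(0),
                                    best_neg = numeric(0), label = character(0))))
  }
  if (metric == "levenshtein") {
    best_pos <- apply(utils::adist(candidates, positives), 1, min)
    best_neg <- apply(utils::adist(candidates, negatives), 1, min)
    label <- ifelse(best_pos < best_neg, "positive", "negative")
    return(list(labels = data.frame(seq = candidates, best_pos = best_pos,
                                    best_neg = best_neg, label = label,
                                    stringsAsFactors = FALSE)))
  }
  best_pos <- max_jaccard_to_set(candidates, positives, k)
  best_neg <- max_jaccard_to_set(candidates, negatives, k)
  label <- ifelse(best_pos > best_neg, "positive", "negative")
  neg_score <- max_jaccard_to_set(negatives, positives, k)
  response <- c(rep(1L, length(candidates)), rep(0L, length(negatives)))
  predictor <- c(best_pos, neg_score)
  roc <- pROC::roc(response, predictor, direction = "<", quiet = TRUE)
  cut <- pROC::coords(roc, "best", best.method = "youden",
                      ret = "threshold", transpose = FALSE)
  list(labels = data.frame(seq = candidates, best_pos = best_pos,
                           best_neg = best_neg, label = label,
                           stringsAsFactors = FALSE),
       auc = as.numeric(pROC::auc(roc)),
       cutoff = as.numeric(cut$threshold[1]))
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' `W` is the rank-sum statistic of `x` in the Mann-Whitney convention
#' (sum of `x` ranks minus `n(n+1)/2`). For `n + m <= 10` the two-sided
#' p-value is computed by exact enumeration of all label assignments (ties
#' included); otherwise the normal approximation with tie correction and,
#' optionally, a 0.5 continuity correction is used. Identical samples give
#' `p = 1`.
#'
#' @param x,y Non-empty numeric vectors.
#' @param continuity Apply the continuity correction in the normal
#'   approximation (default `TRUE`).
#' @return A list: `W`, `p`, `method`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4))  # W = 0, p = 1/3
#' @export
wilcoxon_rank_sum <- function(x, y, continuity = TRUE) {
  if (length(x) == 0 || length(y) == 0) stop_input("both samples must be non-empty")
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  if (n + m <= 10L) {
    idx <- utils::combn(n + m, n)
    U_all <- colSums(matrix(r[idx], nrow = n)) - n * (n + 1) / 2
    eps <- 1e-9
    pl <- mean(U_all <= W + eps)
    pu <- mean(U_all >= W - eps)
    return(list(W = W, p = min(1, 2 * min(pl, pu)), method = "exact"))
  }
  N <- n + m
  ties <- table(r)
  sigma2 <- (n * m / 12) * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(list(W = W, p = 1, method = "normal"))
  zz <- W - n * m / 2
  if (continuity) zz <- zz - sign(zz) * 0.5
  zz <- zz / sqrt(sigma2)
  p <- min(1, 2 * min(stats::pnorm(zz), stats::pnorm(zz, lower.tail = FALSE)))
  list(W = W, p = p, method = "normal")
}

#' Generate random CCC-free negative sequences
#'
#' Per-position sampling with a two-base memory: a third consecutive C is
#' never emitted, so no sequence contains the "CCC" triplet. Lengths are
#' uniform on `len_range`.
#'
#' @param n Number of sequences (default 1000).
#' @param len_range Length bounds (default `c(15, 50)`).
#' @param seed Optional integer seed.
#' @return Character vector of DNA strings.
#' @export
generate_negative_sequences <- function(n = 1000L, len_range = c(15L, 50L),
                                        seed = NULL) {
  stopifnot(n >= 1L, len_range[1] >= 3L, len_range[1] <= len_range[2])
  with_seed(seed, {
    lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
    vapply(lens, function(L) {
      out <- character(L)
      for (i in seq_len(L)) {
        pool <- if (i > 2L && out[i - 1L] == "C" && out[i - 2L] == "C") {
          c("A", "G", "T")
        } else DNA_BASES
        out[i] <- sample(pool, 1L)
      }
      paste(out, collapse = "")
    }, character(1))
  })
}

#' Nucleotide composition features
#'
#' @param seqs Character vector of non-empty A/C/G/T strings.
#' @return Data.frame with `freq_A`, `freq_C`, `freq_G`, `freq_T`
#'   (proportions summing to 1) and `length`.
#' @export
extract_features <- function(seqs) {
  if (any(nchar(seqs) == 0)) stop_input("sequences must be non-empty")
  check_dna(seqs, allow_n = FALSE, what = "feature input")
  counts <- t(vapply(strsplit(seqs, "", fixed = TRUE), function(ch) {
    tabulate(match(ch, DNA_BASES), nbins = 4L)
  }, numeric(4)))
  lens <- nchar(seqs)
  out <- as.data.frame(counts / lens)
  names(out) <- paste0("freq_", DNA_BASES)
  out$length <- as.integer(lens)
  out
}

stratified_indices <- function(labels, frac) {
  unlist(lapply(levels(labels), function(lv) {
    idx <- which(labels == lv)
    sample(idx, floor(frac * length(idx)))
  }), use.names = FALSE)
}

#' Train and evaluate the composition random-forest classifier
#'
#' Stratified 70/30 train/test split; the `mtry` grid is tuned by k-fold
#' cross-validated accuracy on the training set (ties to the smallest
#' `mtry`), the forest is refit on the full training set at the chosen
#' `mtry`, and all metrics are computed on the held-out test set.
#'
#' @param features Data.frame of numeric features (e.g. from
#'   [extract_features()]).
#' @param labels Factor (or coercible) with exactly two classes.
#' @param positive_class Level treated as positive for
#'   sensitivity/specificity/AUC (default: first level of `labels`).
#' @param split Training fraction (default 0.7).
#' @param folds Cross-validation folds (default 10).
#' @param mtry_grid Candidate `mtry` values (default 1 to
#'   `min(5, ncol(features))`).
#' @param ntree Trees per forest (default 500).
#' @param seed Optional integer seed; fixed seeds reproduce every metric
#'   bit-identically.
#' @return A list: `accuracy`, `sensitivity`, `specificity`,
#'   `balanced_accuracy`, `auc`, `confusion_matrix`, `feature_importance`
#'   (mean decrease in Gini, sorted), `chosen_mtry`, `cv_accuracy`,
#'   `model`.
#' @export
train_and_evaluate_classifier <- function(features, labels,
                                          positive_class = NULL,
                                          split = 0.7, folds = 10L,
                                          mtry_grid = NULL, ntree = 500L,
                                          seed = NULL) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L) {
    stop_input("exactly two classes are required; got ", nlevels(labels))
  }
  stopifnot(nrow(features) == length(labels))
  if (is.null(positive_class)) positive_class <- levels(labels)[1]
  stopifnot(positive_class %in% levels(labels))
  if (is.null(mtry_grid)) mtry_grid <- seq_len(min(5L, ncol(features)))
  mtry_grid <- mtry_grid[mtry_grid >= 1 & mtry_grid <= ncol(features)]
  x <- as.data.frame(features)
  with_seed(seed, {
    train_idx <- sort(stratified_indices(labels, split))
    xtr <- x[train_idx, , drop = FALSE]; ytr <- droplevels(labels[train_idx])
    xte <- x[-train_idx, , drop = FALSE]; yte <- labels[-train_idx]
    if (nlevels(ytr) != 2L) stop_input("training split lost a class; provide more data")
    # stratified CV folds on the training set
    fold_id <- integer(length(ytr))
    for (lv in levels(ytr)) {
      idx <- sample(which(ytr == lv))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
    cv_acc <- vapply(mtry_grid, function(mt) {
      hits <- vapply(seq_len(folds), function(f) {
        tr <- fold_id != f
        if (nlevels(droplevels(ytr[tr])) < 2L) return(NA_real_)
        fit <- randomForest::randomForest(xtr[tr, , drop = FALSE], ytr[tr],
                                          mtry = mt, ntree = ntree)
        pred <- stats::predict(fit, xtr[!tr, , drop = FALSE])
        c(sum(pred == ytr[!tr]), sum(!tr))
      }, numeric(2))
      sum(hits[1, ], na.rm = TRUE) / sum(hits[2, ], na.rm = TRUE)
    }, numeric(1))
    chosen <- mtry_grid[which.max(cv_acc)]
    fit <- randomForest::randomForest(xtr, ytr, mtry = chosen, ntree = ntree,
                                      importance = TRUE)
    pred <- stats::predict(fit, xte)
    prob <- stats::predict(fit, xte, type = "prob")[, positive_class]
    cm <- table(truth = yte, predicted = factor(pred, levels = levels(labels)))
    pos <- positive_class
    neg <- setdiff(levels(labels), pos)
    tp <- cm[pos, pos]; fn <- sum(cm[pos, ]) - tp
    tn <- cm[neg, neg]; fp <- sum(cm[neg, ]) - tn
    sens <- tp / (tp + fn)
    spec <- tn / (tn + fp)
    auc <- as.numeric(pROC::auc(pROC::roc(
      response = yte == pos, predictor = prob, direction = "<", quiet = TRUE)))
    imp <- fit$importance[, "MeanDecreaseGini"]
    list(accuracy = (tp + tn) / sum(cm),
         sensitivity = sens,
         specificity = spec,
         balanced_accuracy = (sens + spec) / 2,
         auc = auc,
         confusion_matrix = cm,
         feature_importance = sort(imp, decreasing = TRUE),
         chosen_mtry = chosen,
         cv_accuracy = stats::setNames(cv_acc, mtry_grid),
         model = fit)
  })
}
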