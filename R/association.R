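#' Two-sided Mann-Whitney U test
#'
#' Rank-sum U statistic (midranks for ties) for group `x` against group `y`,
#' with the exact two-sided p-value by enumeration when both groups have at
#' most 8 observations and there are no ties, and the normal approximation
#' with tie and continuity corrections otherwise. The exact/approximate
#' switch keeps toy worked examples exact while dataset-scale scans stay
#' fast.
#'
#' @param x,y numeric vectors, both non-empty.
#' @return a one-row tibble with `u` (U for `x`), `p_value`, `n1`, `n2`,
#'   `exact`.
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) stop_value("both groups must be non-empty")
  if (anyNA(x) || anyNA(y)) stop_value("NA values not allowed")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  exact <- n1 <= 8 && n2 <= 8 && !ties
  p <- stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                          correct = TRUE)$p.value
  tibble(u = u, p_value = min(p, 1), n1 = n1, n2 = n2, exact = exact)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted values `q_(i) = min_{j >= i} p_(j) * m / j`, mapped back
#' to the input order and capped at 1.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return vector of q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    stop_value("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Position-wise differential contact testing
#'
#' At every matrix position `(i, j)`, `i < j`, compares the distribution of
#' values in label-1 (transcribing) cells against label-0 cells with the
#' two-sided Mann-Whitney U test, then controls the FDR over all tested
#' positions with Benjamini-Hochberg. The diagonal is excluded and results
#' are reported for the upper triangle (maps mirror by symmetry; see
#' [differential_matrix()]).
#'
#' @param tensor a [distance_tensor()] with complete slices.
#' @param labels binary vector of length `n`, both classes present.
#' @param threshold FDR significance threshold (conventionally 0.05 for
#'   position-wise maps).
#' @return a `chromafactor_differential` tibble with columns `bin_i`,
#'   `bin_j`, `statistic`, `p_raw`, `q_fdr`, `significant`; attributes
#'   `scope = "position"`, `threshold`, `group_sizes`, `b`.
#' @export
positionwise_differential <- function(tensor, labels, threshold = 0.05) {
  stopifnot(inherits(tensor, "distance_tensor"))
  labels <- assert_binary_labels(labels)
  n <- n_cells(tensor); b <- n_bins(tensor)
  if (length(labels) != n) stop_value("labels must have length n = %d", n)
  if (anyNA(tensor$data)) stop_value("tensor has NA entries; impute first")
  g1 <- labels == 1L; g0 <- !g1
  ut <- which(upper.tri(matrix(0, b, b)), arr.ind = TRUE)
  res <- purrr::map_dfr(seq_len(nrow(ut)), function(r) {
    i <- ut[r, 1]; j <- ut[r, 2]
    v <- tensor$data[i, j, ]
    mw <- mann_whitney_u(v[g1], v[g0])
    tibble(bin_i = i, bin_j = j, statistic = mw$u, p_raw = mw$p_value)
  })
  res$q_fdr <- bh_fdr(res$p_raw)
  res$significant <- res$q_fdr < threshold
  tibble::new_tibble(res, scope = "position", threshold = threshold,
                     group_sizes = c(n1 = sum(g1), n2 = sum(g0)), b = b,
                     class = "chromafactor_differential")
}

#' Component-wise differential weight testing
#'
#' Tests each component's weight distribution in transcribing versus
#' non-transcribing cells (two-sided Mann-Whitney U), BH-corrected over the
#' `k` components. The conventional component-wise threshold is FDR < 0.1.
#'
#' @param H `k x n` weight matrix.
#' @param labels binary vector of length `n`.
#' @param threshold FDR significance threshold.
#' @return a `chromafactor_differential` tibble with columns `component`,
#'   `statistic`, `p_raw`, `q_fdr`, `significant`.
#' @export
componentwise_differential <- function(H, labels, threshold = 0.1) {
  if (!is.matrix(H)) stop_value("H must be a k x n matrix")
  labels <- assert_binary_labels(labels)
  if (length(labels) != ncol(H)) stop_value("labels must have length ncol(H)")
  g1 <- labels == 1L
  res <- purrr::map_dfr(seq_len(nrow(H)), function(j) {
    mw <- mann_whitney_u(H[j, g1], H[j, !g1])
    tibble(component = j, statistic = mw$u, p_raw = mw$p_value)
  })
  res$q_fdr <- bh_fdr(res$p_raw)
  res$significant <- res$q_fdr < threshold
  tibble::new_tibble(res, scope = "component", threshold = threshold,
                     group_sizes = c(n1 = sum(g1), n2 = sum(!g1)),
                     class = "chromafactor_differential")
}

#' Expand a position-wise differential result to a symmetric matrix
#'
#' @param result a position-scope `chromafactor_differential`.
#' @param value which column to place in the matrix (`"q_fdr"`, `"p_raw"`,
#'   `"statistic"` or `"significant"`).
#' @return a symmetric `b x b` matrix with `NA` on the diagonal.
#' @export
differential_matrix <- function(result, value = "q_fdr") {
  stopifnot(inherits(result, "chromafactor_differential"))
  if (!identical(attr(result, "scope"), "position")) {
    stop_value("differential_matrix needs a position-scope result")
  }
  b <- attr(result, "b")
  m <- matrix(NA_real_, b, b)
  m[cbind(result$bin_i, result$bin_j)] <- as.numeric(result[[value]])
  m[cbind(result$bin_j, result$bin_i)] <- as.numeric(result[[value]])
  m
}

#' Plot a position-wise differential result
#'
#' Heatmap of `-log10(q)` with significant positions outlined.
#'
#' @param object a position-scope `chromafactor_differential`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.chromafactor_differential <- function(object, ...) {
  if (identical(attr(object, "scope"), "position")) {
    df <- as_tibble(object)
    ggplot2::ggplot(df, ggplot2::aes(.data$bin_i, .data$bin_j)) +
      ggplot2::geom_tile(ggplot2::aes(fill = -log10(.data$q_fdr))) +
      ggplot2::geom_tile(data = dplyr::filter(df, .data$significant),
                         fill = NA, colour = "white", linewidth = 0.3) +
      ggplot2::scale_y_reverse() +
      ggplot2::coord_fixed() +
      ggplot2::labs(x = "bin", y = "bin", fill = "-log10(q)")
  } else {
    ggplot2::ggplot(as_tibble(object),
                    ggplot2::aes(factor(.data$component), -log10(.data$q_fdr),
                                 fill = .data$significant)) +
      ggplot2::geom_col() +
      ggplot2::geom_hline(yintercept = -log10(attr(object, "threshold")),
                          linetype = "dashed") +
      ggplot2::labs(x = "component", y = "-log10(q)")
  }
}

#' Balance classes by downsampling the majority
#'
#' Uniformly downsamples the majority class without replacement to the
#' minority size, so chance accuracy is exactly 0.5 downstream.
#'
#' @param labels binary vector.
#' @param seed integer seed.
#' @return sorted integer indices of the retained cells.
#' @export
balanced_subset <- function(labels, seed = 1) {
  labels <- assert_binary_labels(labels)
  i1 <- which(labels == 1L); i0 <- which(labels == 0L)
  m <- min(length(i1), length(i0))
  old <- .Random.seed_exists()
  set.seed(child_seed(seed, 21))
  keep <- c(if (length(i1) > m) sample(i1, m) else i1,
            if (length(i0) > m) sample(i0, m) else i0)
  restore_seed(old)
  sort(keep)
}

#' Random-forest prediction of transcription from component weights
#'
#' Trains an ensemble-of-trees classifier (100 trees, Gini impurity,
#' `sqrt(d)` candidate features per split, unlimited depth) on a stratified
#' `train_frac` split of a *balanced* dataset and reports held-out accuracy
#' and normalized impurity-based feature importances. Balance the labels
#' with [balanced_subset()] first; chance performance is then 0.5 and any
#' excess is signal.
#'
#' @param features `n x d` numeric matrix (e.g. `t(fit$weights)`).
#' @param labels balanced binary vector of length `n`.
#' @param train_frac training fraction of each class.
#' @param seed integer seed (split + forest).
#' @return an object of class `chromafactor_classifier`: list with
#'   `accuracy`, `feature_importances` (sums to 1), `split`, `balanced`,
#'   `permutation_null` (NULL until [permutation_test()]).
#' @export
fit_rf_classifier <- function(features, labels, train_frac = 0.7, seed = 1) {
  features <- as.matrix(features)
  labels <- assert_binary_labels(labels)
  n <- nrow(features)
  if (length(labels) != n) stop_value("labels must match nrow(features)")
  if (n < 10) stop_value("need at least 10 cells")
  if (sum(labels == 1L) != sum(labels == 0L)) {
    stop_value("labels must be balanced; apply balanced_subset() first")
  }
  old <- .Random.seed_exists()
  set.seed(child_seed(seed, 22))
  train <- unlist(lapply(c(0L, 1L), function(cl) {
    idx <- which(labels == cl)
    sample(idx, round(train_frac * length(idx)))
  }))
  test <- setdiff(seq_len(n), train)
  fit <- randomForest::randomForest(
    x = features[train, , drop = FALSE], y = factor(labels[train], c(0, 1)),
    ntree = 100)
  pred <- stats::predict(fit, features[test, , drop = FALSE])
  restore_seed(old)
  acc <- mean(pred == factor(labels[test], c(0, 1)))
  imp <- as.numeric(randomForest::importance(fit, type = 2))
  imp <- if (sum(imp) > 0) imp / sum(imp) else rep(1 / length(imp), length(imp))
  structure(list(accuracy = acc, feature_importances = imp,
                 split = list(train_frac = train_frac, seed = seed),
                 balanced = TRUE, n = n, d = ncol(features),
                 permutation_null = NULL),
            class = "chromafactor_classifier")
}

#' @export
#' @method print chromafactor_classifier
print.chromafactor_classifier <- function(x, ...) {
  cat(sprintf("<chromafactor_classifier> held-out accuracy %.3f (n=%d, d=%d, balanced)\n",
              x$accuracy, x$n, x$d))
  if (!is.null(x$permutation_null)) {
    cat(sprintf("  permutation null: mean %.3f +/- %.3f over %d shuffles, p = %.4g\n",
                x$permutation_null$mean, x$permutation_null$sd,
                length(x$permutation_null$null_accuracies),
                x$permutation_null$p_value))
  }
  invisible(x)
}

#' @rdname fit_rf_classifier
#' @param x a `chromafactor_classifier`.
#' @param ... unused.
#' @export
glance.chromafactor_classifier <- function(x, ...) {
  tibble(accuracy = x$accuracy, n = x$n, d = x$d,
         train_frac = x$split$train_frac,
         permutation_p = if (is.null(x$permutation_null)) NA_real_
                         else x$permutation_null$p_value)
}

#' @rdname fit_rf_classifier
#' @export
tidy.chromafactor_classifier <- function(x, ...) {
  tibble(feature = seq_along(x$feature_importances),
         importance = x$feature_importances)
}

#' Label-permutation null for the classifier
#'
#' Refits the classifier `n_perm` times with labels randomly reassigned
#' among cells (class proportions preserved) and reports the null accuracy
#' distribution and the one-sided p-value
#' `(#\{null >= observed\} + 1) / (n_perm + 1)`. On a balanced dataset the
#' null centers on 0.5; a real structural signal stands far above it.
#'
#' @param features,labels,train_frac,seed as in [fit_rf_classifier()].
#' @param n_perm number of label shuffles (>= 1).
#' @return a `chromafactor_classifier` whose `permutation_null` holds
#'   `null_accuracies`, `mean`, `sd`, `p_value` and `observed`.
#' @export
permutation_test <- function(features, labels, n_perm = 10, seed = 1,
                             train_frac = 0.7) {
  if (!is_scalar_number(n_perm) || n_perm < 1) stop_value("n_perm must be >= 1")
  report <- fit_rf_classifier(features, labels, train_frac, seed)
  labels <- assert_binary_labels(labels)
  null_acc <- vapply(seq_len(n_perm), function(i) {
    old <- .Random.seed_exists()
    set.seed(child_seed(seed, 100 + i))
    shuffled <- sample(labels)   # a permutation preserves class proportions
    restore_seed(old)
    fit_rf_classifier(features, shuffled, train_frac,
                      seed = child_seed(seed, 200 + i))$accuracy
  }, numeric(1))
  report$permutation_null <- list(
    null_accuracies = null_acc, mean = mean(null_acc),
    sd = stats::sd(null_acc),
    p_value = (sum(null_acc >= report$accuracy) + 1) / (n_perm + 1),
    observed = report$accuracy)
  report
}

# Mean 5-fold cross-validated balanced random-forest accuracy; used by the
# k-selection transcription metric. Stratified folds on a balanced subset.
cv_balanced_rf_accuracy <- function(features, labels, n_folds = 5, seed = 1) {
  labels <- assert_binary_labels(labels)
  keep <- balanced_subset(labels, seed = seed)
  features <- as.matrix(features)[keep, , drop = FALSE]
  labels <- labels[keep]
  old <- .Random.seed_exists()
  set.seed(child_seed(seed, 23))
  fold <- integer(length(labels))
  for (cl in c(0L, 1L)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  accs <- vapply(seq_len(n_folds), function(f) {
    tr <- fold != f
    fit <- randomForest::randomForest(
      x = features[tr, , drop = FALSE], y = factor(labels[tr], c(0, 1)),
      ntree = 100)
    mean(stats::predict(fit, features[!tr, , drop = FALSE]) ==
           factor(labels[!tr], c(0, 1)))
  }, numeric(1))
  restore_seed(old)
  mean(accs)
}
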