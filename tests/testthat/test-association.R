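test_that("worked Mann-Whitney example: complete separation of 3 vs 3", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$u, 0)
  expect_true(res$exact)
  expect_equal(res$p_value, 0.1)  # 2/20 most-extreme assignments
  expect_equal(mann_whitney_u(c(1, 2), c(1, 2))$p_value, 1.0)
  expect_error(mann_whitney_u(1:3, numeric(0)),
               class = "chromafactor_value_error")
})

test_that("exact p-values agree with exhaustive enumeration for all small
           tie-free rank configurations", {
  for (n1 in 2:6) for (n2 in 2:6) {
    N <- n1 + n2
    subsets <- utils::combn(N, n1)
    # every distinct tie-free input is a choice of ranks for group x
    for (col in seq_len(ncol(subsets))) {
      x <- as.numeric(subsets[, col])
      y <- as.numeric(setdiff(seq_len(N), subsets[, col]))
      res <- mann_whitney_u(x, y)
      expect_true(res$exact)
      expect_equal(res$p_value, enumerate_mwu_p(x, y), tolerance = 1e-12)
    }
  }
})

test_that("swapping groups reflects U about its null mean, p unchanged", {
  set.seed(3)
  x <- rnorm(12); y <- rnorm(15) + 0.5
  a <- mann_whitney_u(x, y)
  b <- mann_whitney_u(y, x)
  expect_equal(a$u - 12 * 15 / 2, -(b$u - 12 * 15 / 2))
  expect_equal(a$p_value, b$p_value)
})

test_that("large or tied samples switch to the corrected approximation", {
  set.seed(4)
  x <- rnorm(50); y <- rnorm(60)
  res <- mann_whitney_u(x, y)
  expect_false(res$exact)
  expect_equal(res$p_value,
               stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
  tied <- mann_whitney_u(c(1, 2, 2), c(2, 3, 4))
  expect_false(tied$exact)
})

test_that("BH adjustment matches the worked example and brute force", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)

  set.seed(6)
  for (i in 1:1000) {
    p <- runif(sample(1:50, 1))^sample(c(1, 2, 3), 1)
    expect_equal(bh_fdr(p), brute_force_bh(p), tolerance = 1e-12)
  }

  # order equivariance
  p <- runif(20)
  perm <- sample(20)
  expect_equal(bh_fdr(p[perm]), bh_fdr(p)[perm])
  expect_error(bh_fdr(c(0.1, 1.2)), class = "chromafactor_value_error")
})

test_that("position-wise testing flags the shifted block and controls the null", {
  b <- 6; n <- 400
  block <- rbind(cbind(matrix(1, 3, 3), matrix(0, 3, 3)), matrix(0, 3, 6))
  block <- (block + t(block)) > 0; diag(block) <- FALSE
  hits <- 0; null_rates <- numeric(10)
  for (r in 1:10) {
    set.seed(100 + r)
    labels <- rep(c(1L, 0L), each = n / 2)
    dat <- array(0, c(b, b, n))
    for (c in seq_len(n)) {
      m <- matrix(abs(rnorm(b * b, 0.5, 0.15)), b)
      m <- (m + t(m)) / 2; diag(m) <- 0
      if (labels[c] == 1L) m[block] <- m[block] + 0.3
      dat[, , c] <- m
    }
    tensor <- distance_tensor(dat)
    res <- positionwise_differential(tensor, labels, threshold = 0.05)
    in_block <- res$significant[block[cbind(res$bin_i, res$bin_j)]]
    hits <- hits + mean(in_block)
    null <- positionwise_differential(tensor, sample(labels), threshold = 0.05)
    null_rates[r] <- mean(null$significant)
  }
  expect_gte(hits / 10, 0.9)          # sensitivity in the shifted block
  expect_lte(mean(null_rates), 0.05)  # false discovery control

  tensor1 <- distance_tensor(array(two_block_matrix(4, 2), c(4, 4, 6)))
  expect_error(positionwise_differential(tensor1, rep(1L, 6)),
               class = "chromafactor_value_error")
})

test_that("component-wise testing has power and reduces to raw p at k = 1", {
  cfg <- synthetic_config(b = 8, k_true = 3, n = 800, seed = 30)
  H <- sample_weight_matrix(cfg)
  lab <- generate_transcription_labels(H, 2, label_effect = 2, seed = 30)
  res <- componentwise_differential(H, lab, threshold = 0.1)
  expect_true(res$significant[2])
  expect_equal(attr(res, "scope"), "component")

  res1 <- componentwise_differential(H[2, , drop = FALSE], lab)
  expect_equal(res1$p_raw, res1$q_fdr)
})

test_that("balanced subsetting equalizes classes deterministically", {
  labels <- c(rep(1L, 30), rep(0L, 70))
  idx <- balanced_subset(labels, seed = 1)
  expect_equal(length(idx), 60)
  expect_equal(sum(labels[idx] == 1), 30)
  expect_equal(sum(labels[idx] == 0), 30)
  expect_identical(balanced_subset(labels, seed = 1), idx)

  even <- rep(c(0L, 1L), 25)
  expect_identical(balanced_subset(even, seed = 9), seq_along(even))
  expect_error(balanced_subset(rep(0L, 10)),
               class = "chromafactor_value_error")
})

test_that("random forest detects a planted predictive feature", {
  set.seed(40)
  n <- 400
  labels <- rep(c(0L, 1L), each = n / 2)
  features <- matrix(rnorm(n * 5), n, 5)
  features[, 1] <- labels + rnorm(n, sd = 0.05)
  rep_ <- fit_rf_classifier(features, labels, seed = 2)
  expect_gte(rep_$accuracy, 0.95)
  expect_equal(which.max(rep_$feature_importances), 1L)
  expect_equal(sum(rep_$feature_importances), 1, tolerance = 1e-9)

  # shuffled labels: chance performance
  set.seed(41)
  null_rep <- fit_rf_classifier(features, sample(labels), seed = 2)
  expect_lt(abs(null_rep$accuracy - 0.5), 0.08)

  # determinism
  again <- fit_rf_classifier(features, labels, seed = 2)
  expect_identical(again$accuracy, rep_$accuracy)
  expect_identical(again$feature_importances, rep_$feature_importances)

  expect_error(fit_rf_classifier(features, c(rep(0L, 150), rep(1L, 250))),
               class = "chromafactor_value_error")
})

test_that("permutation test gives the floor p-value for strong signal and a
           centered null otherwise", {
  set.seed(50)
  n <- 200
  labels <- rep(c(0L, 1L), each = n / 2)
  features <- matrix(rnorm(n * 4), n, 4)
  features[, 2] <- labels * 2 + rnorm(n, sd = 0.1)
  rep_ <- permutation_test(features, labels, n_perm = 10, seed = 3)
  expect_equal(rep_$permutation_null$p_value, 1 / 11)
  expect_lt(max(rep_$permutation_null$null_accuracies), rep_$accuracy)

  null_feats <- matrix(rnorm(n * 4), n, 4)
  null_rep <- permutation_test(null_feats, labels, n_perm = 19, seed = 4)
  expect_equal(null_rep$permutation_null$mean, 0.5, tolerance = 0.05)
  expect_error(permutation_test(features, labels, n_perm = 0),
               class = "chromafactor_value_error")
})
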