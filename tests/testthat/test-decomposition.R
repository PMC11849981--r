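test_that("flatten/unflatten are exact inverses with row-major columns", {
  dat <- array(0, c(2, 2, 1))
  dat[1, 2, 1] <- dat[2, 1, 1] <- 3
  V <- flatten_tensor(distance_tensor(dat))
  expect_equal(V[, 1], c(0, 3, 3, 0))

  ds <- simulate_dataset(synthetic_config(b = 5, k_true = 2, n = 7,
                                          noise_sd = 0.05, seed = 2,
                                          template_spec = list(
                                            list(type = "block", p = 2),
                                            list(type = "stripe", g = 4))))
  V2 <- flatten_tensor(ds$tensor)
  expect_equal(unflatten_matrix(V2, 5), ds$tensor$data)

  one <- distance_tensor(ds$tensor$data[, , 1])
  expect_equal(ncol(flatten_tensor(one)), 1)
})

test_that("noiseless planted factors are recovered at the true k", {
  cfg <- synthetic_config(b = 8, k_true = 2, n = 20, noise_sd = 0, seed = 3,
                          template_spec = list(list(type = "block", p = 4),
                                               list(type = "stripe", g = 6)))
  ds <- simulate_dataset(cfg)
  V <- flatten_tensor(ds$tensor)
  fit <- fit_decomposition(V, 2)
  expect_gte(variance_explained(V, fit), 0.99)
  expect_true(all(matched_template_cors(fit, ds$W_true) >= 0.95))
})

test_that("rank-1 data yields a proportional template and constant weights", {
  m <- two_block_matrix(6, 3)
  tensor <- distance_tensor(array(rep(m, 4), c(6, 6, 4)))
  fit <- fit_decomposition(flatten_tensor(tensor), 1)
  tmpl <- fit$templates[, , 1]
  off <- !diag(6)
  expect_gt(cor(tmpl[off], m[off]), 0.999)
  w <- fit$weights[1, ]
  expect_lt(diff(range(w)) / mean(w), 1e-6)
})

test_that("input validation rejects bad V and k", {
  V <- matrix(1, 4, 3)
  V[2, 2] <- -0.1
  expect_error(fit_decomposition(V, 1), class = "chromafactor_value_error")
  expect_error(fit_decomposition(matrix(NA_real_, 4, 3), 1),
               class = "chromafactor_value_error")
  expect_error(fit_decomposition(matrix(1, 4, 3), 5),
               class = "chromafactor_value_error")
  expect_error(fit_decomposition(matrix(1, 5, 3), 1),
               class = "chromafactor_value_error")  # not a perfect square
})

test_that("reconstruction follows the weighted template sum", {
  ds <- small_synthetic(noise_sd = 0)
  V <- flatten_tensor(ds$tensor)
  fit <- fit_decomposition(V, 3)

  # unit / zero weight columns reconstruct a template or nothing
  fit2 <- fit
  fit2$weights[, 1] <- c(0, 1, 0)
  expect_equal(reconstruct_cell(fit2, 1), fit$templates[, , 2])
  fit2$weights[, 2] <- 0
  expect_equal(reconstruct_cell(fit2, 2), matrix(0, 16, 16))

  # exact planted factors reconstruct every slice to within 1e-6
  exact <- structure(list(templates = ds$W_true, weights = ds$H_true,
                          k = 3L, b = 16L, n = ds$tensor |> dim() |> tail(1)),
                     class = "chromafactor_fit")
  for (c in c(3, 99)) {
    truth <- ds$tensor$data[, , c]
    expect_lt(chromafactor:::fnorm(reconstruct_cell(exact, c) - truth) /
                chromafactor:::fnorm(truth), 1e-6)
  }

  # fitted noiseless cells reconstruct to high relative accuracy
  for (c in c(1, 50)) {
    rec <- reconstruct_cell(fit, c)
    truth <- ds$tensor$data[, , c]
    expect_lt(chromafactor:::fnorm(rec - truth) / chromafactor:::fnorm(truth),
              1e-3)
    expect_equal(rec, t(rec))
    expect_true(all(rec >= 0))
  }
  expect_error(reconstruct_cell(fit, 0), class = "chromafactor_index_error")
  expect_error(reconstruct_cell(fit, fit$n + 1),
               class = "chromafactor_index_error")
})

test_that("variance explained behaves across exact, null and nested fits", {
  ds <- small_synthetic(noise_sd = 0)
  V <- flatten_tensor(ds$tensor)
  fit3 <- fit_decomposition(V, 3)
  expect_gte(variance_explained(V, fit3), 0.999)

  null_fit <- fit3
  null_fit$weights[] <- 0
  expect_equal(variance_explained(V, null_fit), 0)

  fit1 <- fit_decomposition(V, 1)
  expect_lt(variance_explained(V, fit1), variance_explained(V, fit3))
  expect_error(variance_explained(matrix(0, 4, 2), fit3),
               class = "chromafactor_value_error")
})

test_that("factors are non-negative and fits are bit-identical", {
  ds <- small_synthetic()
  V <- flatten_tensor(ds$tensor)
  a <- fit_decomposition(V, 4)
  b <- fit_decomposition(V, 4)
  expect_gte(min(a$templates), 0)
  expect_gte(min(a$weights), 0)
  expect_identical(a$templates, b$templates)
  expect_identical(a$weights, b$weights)
  r1 <- fit_decomposition(V, 4, init = "random", seed = 9)
  r2 <- fit_decomposition(V, 4, init = "random", seed = 9)
  expect_identical(r1$weights, r2$weights)
})

test_that("reconstruction error is monotone in capacity within tolerance", {
  ds <- small_synthetic()
  V <- flatten_tensor(ds$tensor)
  errs <- vapply(1:8, function(k) fit_decomposition(V, k)$reconstruction_error,
                 numeric(1))
  slack <- 0.01 * chromafactor:::fnorm(V)
  expect_true(all(diff(errs) <= slack))
})

test_that("rank-1 fit matches a dense grid-search oracle", {
  # b^2 = 4, n = 3: best rank-1 non-negative approximation by brute force
  # over scaled outer products of the (non-negative) leading singular pair
  set.seed(17)
  V <- matrix(runif(12, 0.1, 1), 4, 3)
  sv <- svd(V)
  u <- abs(sv$u[, 1]); v <- abs(sv$v[, 1])
  grid <- seq(0.5, 1.5, by = 0.001) * sv$d[1]
  oracle_err <- min(vapply(grid, function(s) {
    chromafactor:::fnorm(V - (u * s) %*% t(v))
  }, numeric(1)))
  fit <- fit_decomposition(V, 1)
  expect_lte(fit$reconstruction_error, oracle_err * 1.01)
})

test_that("templates are symmetrized with the discrepancy recorded", {
  ds <- small_synthetic()
  fit <- fit_decomposition(flatten_tensor(ds$tensor), 3)
  for (j in 1:3) {
    expect_equal(fit$templates[, , j], t(fit$templates[, , j]))
  }
  expect_gte(fit$asymmetry_norm, 0)
  expect_lt(fit$asymmetry_norm, 0.05)
})

test_that("model persistence round-trips byte-identically", {
  ds <- small_synthetic()
  fit <- fit_decomposition(flatten_tensor(ds$tensor), 3)
  dir <- withr::local_tempdir()
  write_decomposition(fit, dir)
  back <- read_decomposition(dir)
  expect_identical(back$templates, fit$templates)
  expect_identical(back$weights, fit$weights)
  expect_equal(back$reconstruction_error, fit$reconstruction_error)
})

test_that("tidiers expose weights and model summary", {
  ds <- small_synthetic()
  fit <- fit_decomposition(flatten_tensor(ds$tensor), 3)
  td <- tidy(fit)
  expect_equal(nrow(td), fit$k * fit$n)
  expect_equal(td$weight[td$cell_index == 2],
               unname(fit$weights[, 2]))
  gl <- glance(fit)
  expect_equal(gl$k, 3)
  expect_gte(gl$variance_explained, 0.99)
})
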