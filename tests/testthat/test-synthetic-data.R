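test_that("block template has the constructed within/cross structure", {
  cfg <- synthetic_config(b = 8, k_true = 1,
                          template_spec = list(list(type = "block", p = 4)))
  W <- make_block_templates(cfg)
  m <- W[, , 1]
  expect_equal(dim(m), c(8, 8))
  expect_equal(diag(m), rep(0, 8))
  expect_equal(m, t(m))
  expect_equal(max(m), 0.9)
  within <- m[1:4, 1:4][upper.tri(matrix(0, 4, 4))]
  cross <- m[1:4, 5:8]
  expect_true(all(within < min(cross)))
  expect_equal(unique(as.vector(cross)), 0.9)
  expect_equal(unique(within), 0.1)
})

test_that("stripe template elevates its row and column over background", {
  cfg <- synthetic_config(b = 8, k_true = 1,
                          template_spec = list(list(type = "stripe", g = 3)))
  m <- make_block_templates(cfg)[, , 1]
  expect_true(all(m[3, -3] > m[1, 2]))
  expect_equal(m[3, -3], m[-3, 3])
})

test_that("redundant motifs and out-of-range positions are rejected", {
  cfg <- synthetic_config(b = 8, k_true = 2,
                          template_spec = list(list(type = "block", p = 4),
                                               list(type = "block", p = 4)))
  expect_error(make_block_templates(cfg), "redundant")
  cfg2 <- synthetic_config(b = 8, k_true = 1,
                           template_spec = list(list(type = "block", p = 9)))
  expect_error(make_block_templates(cfg2), class = "chromafactor_range_error")
})

test_that("default motif library is pairwise separated for larger k", {
  cfg <- synthetic_config(b = 32, k_true = 5)
  W <- make_block_templates(cfg)
  off <- !diag(32)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_lt(cor(W[, , i][off], W[, , j][off]), 0.8)
  }
})

test_that("weight matrix honours sparsity, support and determinism", {
  cfg <- synthetic_config(b = 8, k_true = 3, n = 100, weight_sparsity = 1,
                          seed = 2)
  H <- sample_weight_matrix(cfg)
  expect_true(all(H > 0))

  cfg3 <- synthetic_config(b = 8, k_true = 3, n = 3000, weight_sparsity = 1 / 3,
                           seed = 2)
  H3 <- sample_weight_matrix(cfg3)
  expect_true(all(H3 >= 0))
  expect_true(all(colSums(H3) > 0))
  expect_equal(mean(H3 > 0), 1 / 3, tolerance = 0.03 * 3)

  expect_identical(sample_weight_matrix(cfg3), H3)
  expect_error(synthetic_config(weight_sparsity = 0),
               class = "chromafactor_value_error")
})

test_that("noiseless tensor slices equal the planted mixture exactly", {
  cfg <- synthetic_config(b = 8, k_true = 2, n = 10, noise_sd = 0, seed = 4,
                          template_spec = list(list(type = "block", p = 4),
                                               list(type = "stripe", g = 6)))
  W <- make_block_templates(cfg)
  H <- sample_weight_matrix(cfg)
  ds <- generate_distance_tensor(W, H, noise_sd = 0, seed = 4)
  for (c in c(1, 5, 10)) {
    mix <- W[, , 1] * H[1, c] + W[, , 2] * H[2, c]
    expect_equal(ds$tensor$data[, , c], mix, tolerance = 1e-12)
  }
  # unit-weight column reproduces a single template
  e2 <- matrix(c(0, 1), 2, 1)
  ds2 <- generate_distance_tensor(W, cbind(e2), noise_sd = 0, seed = 1)
  expect_equal(ds2$tensor$data[, , 1], W[, , 2], tolerance = 1e-12)
  expect_error(generate_distance_tensor(W, H, noise_sd = -1),
               class = "chromafactor_value_error")
})

test_that("noiseless flattened tensor has numerical rank k_true", {
  ds <- simulate_dataset(synthetic_config(b = 12, k_true = 3, n = 40,
                                          noise_sd = 0, seed = 9))
  sv <- svd(flatten_tensor(ds$tensor))$d
  expect_equal(sum(sv > 1e-8 * sv[1]), 3)
})

test_that("dropout masks whole loci at the rounded per-cell count", {
  cfg <- synthetic_config(b = 10, k_true = 2, n = 20, noise_sd = 0,
                          dropout_frac = 0.2, seed = 6,
                          template_spec = list(list(type = "block", p = 5),
                                               list(type = "stripe", g = 8)))
  W <- make_block_templates(cfg)
  H <- sample_weight_matrix(cfg)
  ds <- generate_distance_tensor(W, H, noise_sd = 0, dropout_frac = 0.2,
                                 seed = 6)
  expect_equal(unname(rowSums(ds$missing_mask)), rep(2, 20))
  for (c in 1:3) {
    drop <- which(ds$missing_mask[c, ])
    expect_true(all(is.na(ds$tensor$data[drop, , c])))
    expect_true(all(is.na(ds$tensor$data[, drop, c])))
    keep <- setdiff(1:10, drop)
    expect_false(anyNA(ds$tensor$data[keep, keep, c]))
  }
})

test_that("transcription labels couple to the targeted components", {
  ds <- small_synthetic()
  H <- ds$H_true

  # effect 0: prevalence 0.5 regardless of the weights
  H_big <- matrix(seq(0.1, 1, length.out = 2 * 5000), 2)
  lab0 <- generate_transcription_labels(H_big, 1, label_effect = 0, seed = 8)
  expect_equal(mean(lab0), 0.5, tolerance = 0.02)

  # saturation: huge effect gives a deterministic threshold on the score
  lab_inf <- generate_transcription_labels(H, 2, label_effect = 50, seed = 8)
  s <- H[2, ]
  z <- (s - mean(s)) / sd(s)
  agree <- mean(lab_inf == as.integer(z > median(z)))
  expect_gt(agree, 0.97)

  # determinism
  expect_identical(generate_transcription_labels(H, 2, 2, seed = 3),
                   generate_transcription_labels(H, 2, 2, seed = 3))
  expect_error(generate_transcription_labels(H, integer(0), 1),
               class = "chromafactor_value_error")
})

test_that("label-weight coupling strengthens with the effect size", {
  cfg <- synthetic_config(b = 8, k_true = 3, n = 2000, seed = 12)
  H <- sample_weight_matrix(cfg)
  s <- colMeans(H[2:3, , drop = FALSE])
  cors <- vapply(c(0.5, 1, 2), function(eff) {
    lab <- generate_transcription_labels(H, 2:3, eff, seed = 12)
    cor(lab, s)
  }, numeric(1))
  expect_true(all(cors > 0))
  expect_true(all(diff(cors) > 0))
})

test_that("MDS embedding reproduces Euclidean-embeddable distances", {
  # exact 3D point set embeds exactly
  set.seed(31)
  pts <- matrix(rnorm(8 * 3), 8, 3)
  m <- as.matrix(dist(pts)); dimnames(m) <- NULL
  tensor <- distance_tensor(array(m, c(8, 8, 1)))
  coords <- embed_to_coordinates(tensor)
  d2 <- as.matrix(dist(coords[1, , ])); dimnames(d2) <- NULL
  expect_equal(d2, m, tolerance = 1e-6)

  # b = 2: two points separated by exactly the given distance
  m2 <- matrix(c(0, 3.7, 3.7, 0), 2, 2)
  c2 <- embed_to_coordinates(distance_tensor(array(m2, c(2, 2, 1))))
  expect_equal(sqrt(sum((c2[1, 1, ] - c2[1, 2, ])^2)), 3.7, tolerance = 1e-9)

  # template-mixture matrices are nearly Euclidean: correlation >= 0.8
  ds <- simulate_dataset(synthetic_config(b = 32, k_true = 3, n = 5,
                                          noise_sd = 0.02, seed = 13))
  coords <- embed_to_coordinates(ds$tensor)
  for (c in 1:5) {
    d <- as.matrix(dist(coords[c, , ]))
    ut <- upper.tri(d)
    expect_gt(cor(d[ut], ds$tensor$data[, , c][ut]), 0.8)
  }

  bad <- simulate_dataset(synthetic_config(b = 8, k_true = 2, n = 3,
                                           dropout_frac = 0.25, seed = 2))
  expect_error(embed_to_coordinates(bad$tensor),
               class = "chromafactor_value_error")
})

test_that("generators are pure functions of config and seed", {
  cfg <- synthetic_config(b = 12, k_true = 3, n = 30, noise_sd = 0.05,
                          dropout_frac = 0.1, label_components = 1,
                          seed = 77)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$H_true, b$H_true)
  expect_identical(a$tensor$data, b$tensor$data)
  expect_identical(a$labels, b$labels)
  expect_identical(a$missing_mask, b$missing_mask)
})

test_that("synthetic dataset round-trips through its ground-truth sidecar", {
  ds <- simulate_dataset(synthetic_config(b = 8, k_true = 2, n = 12,
                                          noise_sd = 0.05, seed = 3,
                                          label_components = 1), embed = TRUE)
  dir <- withr::local_tempdir()
  write_synthetic_dataset(ds, dir)
  man <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                             simplifyVector = TRUE)
  expect_equal(man$b, 8)
  expect_equal(man$k_true, 2)
  H_back <- as.matrix(utils::read.table(file.path(dir, man$H_true)))
  expect_equal(unname(H_back), ds$H_true, tolerance = 1e-15)
  ens <- read_coordinate_table(file.path(dir, man$coordinates))
  expect_equal(dim(ens$coords), c(12, 8, 3))
})
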