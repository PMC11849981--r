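test_that("insulation profile reproduces the hand-computed two-block values", {
  m <- two_block_matrix(8, 4)
  prof <- insulation_profile(m, window = 2)
  # cross block at the junction averages pure cross-domain entries
  expect_equal(prof$value[4], 0.9)
  expect_equal(which.max(prof$value), 4)
  expect_equal(sum(prof$value == 0.9, na.rm = TRUE), 1)
  expect_equal(prof$value[2], 0.1)
  expect_equal(prof$value[3], 0.5)  # mixed 2x2 block: (0.1+0.9+0.1+0.9)/4
  expect_true(is.na(prof$value[8]))

  const <- matrix(0.4, 6, 6); diag(const) <- 0
  pc <- insulation_profile(const, window = 1)
  expect_true(all(pc$value[!is.na(pc$value)] == 0.4))

  expect_error(insulation_profile(m, window = 8),
               class = "chromafactor_value_error")
  expect_error(insulation_profile(m, window = 4),
               class = "chromafactor_value_error")
})

test_that("boundary calling finds strict interior maxima above threshold", {
  m <- two_block_matrix(8, 4)
  calls <- call_boundaries(insulation_profile(m, 2), threshold = 0.05)
  expect_equal(calls$position, 4L)
  expect_equal(calls$value, 0.9)

  # all below threshold -> no calls
  low <- call_boundaries(insulation_profile(m / 100, 2), threshold = 0.05)
  expect_equal(nrow(low), 0)

  # flat profile has no strict maxima
  const <- matrix(0.4, 8, 8); diag(const) <- 0
  expect_equal(nrow(call_boundaries(insulation_profile(const, 2))), 0)

  # plateaus contribute their leftmost bin
  prof <- chromafactor:::new_track(c(0.1, 0.5, 0.5, 0.1, 0.1, NA), 2,
                                   "insulation", "toy")
  pl <- call_boundaries(prof, 0.05)
  expect_equal(pl$position, 2L)

  di <- directionality_index(m / max(m), 2)
  expect_error(call_boundaries(di), class = "chromafactor_value_error")
})

test_that("adding a sub-threshold baseline keeps boundary calls", {
  m <- two_block_matrix(8, 4, within = 0.01, cross = 0.2)
  base <- call_boundaries(insulation_profile(m, 2), 0.05)
  shifted <- call_boundaries(insulation_profile(m + 0.02 * (1 - diag(8)), 2),
                             0.05)
  expect_equal(shifted$position, base$position)
})

test_that("directionality index matches the worked chi-square example", {
  # bin 1 has no upstream contacts (A = 0) and downstream similarity 20
  S <- matrix(0, 6, 6)
  S[1, 2] <- S[2, 1] <- 12
  S[1, 3] <- S[3, 1] <- 8
  di <- directionality_index(S, window = 2, input = "contact")
  expect_equal(di$value[1], 20)  # E = 10; (0-10)^2/10 + (20-10)^2/10

  # symmetric banding: A = B wherever both windows are complete -> zero;
  # edge bins keep the sign of their untruncated side
  band <- outer(1:8, 1:8, function(i, j) exp(-abs(i - j)))
  diag(band) <- 0
  di_band <- directionality_index(band, 3, "contact")$value
  expect_true(all(di_band[4:5] == 0))
  expect_gt(di_band[1], 0)
  expect_lt(di_band[8], 0)
})

test_that("tracks are equivariant under bin-order reversal", {
  ds <- small_synthetic()
  fit <- fit_decomposition(flatten_tensor(ds$tensor), 3)
  M <- fit$templates[, , 1]
  M <- M / max(M)
  rev_idx <- rev(seq_len(nrow(M)))
  Mr <- M[rev_idx, rev_idx]

  # insulation: profile of reversed matrix is the reversed profile
  # (window blocks mirror across the junction between i and i+1, so bin i
  # maps to bin b - i)
  w <- 2
  ins <- insulation_profile(M, w)$value
  insr <- insulation_profile(Mr, w)$value
  b <- nrow(M)
  for (i in seq_len(b - 1)) {
    expect_equal(insr[b - i], ins[i], tolerance = 1e-12)
  }

  # directionality: reversed and negated
  di <- directionality_index(M, w)$value
  dir_ <- directionality_index(Mr, w)$value
  expect_equal(dir_, -rev(di), tolerance = 1e-12)
})

test_that("planted boundaries are recovered within one bin across windows", {
  for (w in 2:4) {
    m <- two_block_matrix(12, 7)
    calls <- call_boundaries(insulation_profile(m, w), 0.05)
    expect_equal(nrow(calls), 1)
    expect_lte(abs(calls$position - 7), 1)
  }
})

test_that("dominant component labels use argmax with documented tie rules", {
  H <- cbind(c(0.1, 0.9), c(0.5, 0.5), c(0, 0), c(0.3, 0.1))
  expect_identical(dominant_component_labels(H), c(2L, 1L, -1L, 1L))
  expect_error(dominant_component_labels(cbind(c(-1, 0))),
               class = "chromafactor_value_error")
})

test_that("weight embedding is shaped, seeded and separates clusters", {
  set.seed(20)
  H <- cbind(matrix(abs(rnorm(3 * 50, 0, 0.05)), 3) + c(1, 0, 0),
             matrix(abs(rnorm(3 * 50, 0, 0.05)), 3) + c(0, 0, 1))
  emb <- embed_weights(H, n_neighbors = 5, seed = 2)
  expect_equal(nrow(emb), 100)
  expect_equal(ncol(as.matrix(emb[, c("dim1", "dim2")])), 2)

  emb2 <- embed_weights(H, n_neighbors = 5, seed = 2)
  expect_identical(emb$dim1, emb2$dim1)

  truth <- rep(1:2, each = 50)
  sil <- cluster::silhouette(truth, dist(as.matrix(emb[, c("dim1", "dim2")])))
  expect_gt(mean(sil[, "sil_width"]), 0.5)

  expect_error(embed_weights(H[, 1:5], n_neighbors = 5),
               class = "chromafactor_value_error")
})

test_that("peak colocalization counts matches within tolerance", {
  m <- two_block_matrix(12, 5)
  calls <- call_boundaries(insulation_profile(m, 2), 0.05)
  expect_equal(calls$position, 5L)

  peaks <- tibble::tibble(bin = c(5L, 6L, 9L),
                          intensity = c(10, 8, 3),
                          protein = c("CTCF", "CP190", "Rad21"))
  exact <- peak_colocalization(calls, peaks, tolerance_bins = 0)
  expect_equal(exact$per_protein$n_matched[exact$per_protein$protein == "CTCF"], 1L)
  expect_equal(exact$per_protein$n_matched[exact$per_protein$protein == "CP190"], 0L)

  near <- peak_colocalization(calls, peaks, tolerance_bins = 1)
  expect_equal(near$per_boundary$combination, "CP190+CTCF")

  empty <- peak_colocalization(calls, peaks[0, ], tolerance_bins = 1)
  expect_equal(nrow(empty$per_protein), 0)
})

test_that("BED-like peak tables map to bins keeping the strongest peak", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tname\tscore",
               "chr2L\t100\t300\tCTCF\t5",
               "chr2L\t250\t350\tCTCF\t9",
               "chr2L\t900\t1100\tRad21\t4"),
             path)
  peaks <- read_peak_track(path, bin_size = 500, region_start = 0, b = 4)
  ctcf <- peaks[peaks$protein == "CTCF", ]
  expect_equal(ctcf$bin, 1L)       # both midpoints fall in bin 1
  expect_equal(ctcf$intensity, 9)  # strongest peak kept
  expect_equal(peaks$bin[peaks$protein == "Rad21"], 3L)
})
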