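#' Configuration for the synthetic single-molecule generator
#'
#' Describes a ground-truthed synthetic ensemble with the additive
#' template-mixture structure the decomposition assumes: each cell's
#' normalized distance map is a non-negative weighted sum of `k_true`
#' structural templates plus truncated Gaussian noise, with optional
#' whole-locus dropout and binary transcription labels coupled to a subset
#' of the component weights.
#'
#' @param b bin count (>= 4).
#' @param k_true planted component count, `1 <= k_true <= b`.
#' @param n cell count.
#' @param template_spec list of motif descriptors, each a list with `type`
#'   one of `"block"` (two-domain boundary, field `p`: last bin of the first
#'   block, 1-based), `"stripe"` (field `g`: stripe bin), `"checker"`
#'   (compartment checkerboard, field `q`: period in bins). `NULL` picks a
#'   default library of well-separated motifs for `k_true`.
#' @param weight_sparsity fraction of components active per cell, in (0, 1].
#' @param noise_sd additive Gaussian noise sd (units of normalized distance).
#' @param dropout_frac per-cell fraction of loci set missing, in [0, 1).
#' @param label_components integer vector of component indices (1-based)
#'   driving the transcription labels; `NULL` disables labels.
#' @param label_effect log-odds slope coupling labels to the mean
#'   standardized weight of `label_components`.
#' @param seed integer seed; every generator below is a pure function of
#'   (config, seed).
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(b = 32, k_true = 3, n = 500, template_spec = NULL,
                             weight_sparsity = 0.7, noise_sd = 0.05,
                             dropout_frac = 0, label_components = NULL,
                             label_effect = 1, seed = 1) {
  if (!is_scalar_number(b) || b < 4) stop_value("b must be an integer >= 4")
  if (!is_scalar_number(k_true) || k_true < 1 || k_true > b) {
    stop_value("k_true must satisfy 1 <= k_true <= b")
  }
  if (!is_scalar_number(n) || n < 1) stop_value("n must be >= 1")
  if (!is_scalar_number(weight_sparsity) || weight_sparsity <= 0 ||
      weight_sparsity > 1) {
    stop_value("weight_sparsity must be in (0, 1]")
  }
  if (!is_scalar_number(noise_sd) || noise_sd < 0) {
    stop_value("noise_sd must be non-negative")
  }
  if (!is_scalar_number(dropout_frac) || dropout_frac < 0 || dropout_frac >= 1) {
    stop_value("dropout_frac must be in [0, 1)")
  }
  b <- as.integer(b); k_true <- as.integer(k_true); n <- as.integer(n)
  if (is.null(template_spec)) template_spec <- default_template_spec(b, k_true)
  if (length(template_spec) != k_true) {
    stop_value("template_spec must list exactly k_true = %d motifs", k_true)
  }
  if (!is.null(label_components)) {
    label_components <- as.integer(label_components)
    if (!length(label_components) ||
        any(label_components < 1L | label_components > k_true)) {
      stop_value("label_components must be a non-empty subset of 1..k_true")
    }
  }
  structure(list(b = b, k_true = k_true, n = n, template_spec = template_spec,
                 weight_sparsity = weight_sparsity, noise_sd = noise_sd,
                 dropout_frac = dropout_frac,
                 label_components = label_components,
                 label_effect = label_effect, seed = as.integer(seed)),
            class = "synthetic_config")
}

# Default motif library: a two-block boundary, a stripe, a checkerboard,
# then further boundaries at distinct positions. Positions chosen so the
# pairwise template correlations stay well below the 0.8 redundancy guard.
default_template_spec <- function(b, k_true) {
  base <- list(
    list(type = "block", p = floor(b / 2)),
    list(type = "stripe", g = max(2L, floor(b / 4))),
    list(type = "checker", q = max(2L, floor(b / 8))))
  if (k_true <= 3) return(base[seq_len(k_true)])
  extra_p <- setdiff(floor(seq(b / 5, 4 * b / 5, length.out = k_true)),
                     floor(b / 2))
  c(base, lapply(extra_p[seq_len(k_true - 3)],
                 function(p) list(type = "block", p = as.integer(p))))
}

# Single-motif template constructors. Background distance 0.1, elevated
# (cross-domain / far) distance 0.9, matching a max-normalized map in which
# compact within-domain contacts are short and cross-domain ones long.
motif_matrix <- function(b, motif) {
  bg <- 0.1; hi <- 0.9
  m <- switch(
    motif$type,
    block = {
      p <- motif$p
      if (!is_scalar_number(p) || p < 1 || p >= b) {
        stop_range("block boundary p = %s out of range [1, %d)", format(p), b)
      }
      grp <- as.integer(seq_len(b) > p)
      matrix(ifelse(outer(grp, grp, `==`), bg, hi), b, b)
    },
    stripe = {
      g <- motif$g
      if (!is_scalar_number(g) || g < 1 || g > b) {
        stop_range("stripe bin g = %s out of range [1, %d]", format(g), b)
      }
      m <- matrix(bg, b, b)
      m[g, ] <- hi; m[, g] <- hi
      m
    },
    checker = {
      q <- motif$q
      if (!is_scalar_number(q) || q < 1 || 2 * q > b) {
        stop_range("checker period q = %s out of range [1, %d]", format(q), floor(b / 2))
      }
      comp <- (ceiling(seq_len(b) / q) - 1L) %% 2L
      matrix(ifelse(outer(comp, comp, `==`), bg, hi), b, b)
    },
    stop_value("unknown motif type '%s'", motif$type))
  diag(m) <- 0
  m
}

#' Build the planted template library
#'
#' Constructs one non-negative, symmetric, zero-diagonal template per motif
#' in the config, on the normalized-distance scale (background 0.1,
#' elevated 0.9). Near-duplicate motifs are rejected: distinct
#' templates must have pairwise Pearson correlation < 0.8 on their
#' off-diagonal entries, so the planted factorization is identifiable.
#'
#' @param config a [synthetic_config()].
#' @return a `b x b x k_true` array.
#' @export
make_block_templates <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  b <- config$b; k <- config$k_true
  W <- array(0, c(b, b, k))
  for (j in seq_len(k)) W[, , j] <- motif_matrix(b, config$template_spec[[j]])
  if (k >= 2) {
    off <- !diag(b)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      r <- stats::cor(W[, , i][off], W[, , j][off])
      if (is.na(r) || r >= 0.8) {
        stop_value("templates %d and %d are redundant (correlation %.2f >= 0.8)",
                   i, j, r)
      }
    }
  }
  W
}

#' Sample the planted per-cell weight matrix
#'
#' Each cell activates `k_true * weight_sparsity` components in expectation
#' (stochastic rounding of the target count, floored at one so no cell is
#' empty); the active set is drawn uniformly and active weights are
#' Uniform(0.2, 1.2). The expected non-zero fraction per column therefore
#' equals `weight_sparsity` whenever `k_true * weight_sparsity >= 1`.
#'
#' @param config a [synthetic_config()].
#' @return a non-negative `k_true x n` matrix.
#' @export
sample_weight_matrix <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  k <- config$k_true; n <- config$n
  old <- .Random.seed_exists()
  set.seed(child_seed(config$seed, 1))
  target <- k * config$weight_sparsity
  n_active <- pmax(1L, floor(target) +
                     stats::rbinom(n, 1, target - floor(target)))
  H <- matrix(0, k, n)
  for (c in seq_len(n)) {
    act <- sample.int(k, n_active[c])
    H[act, c] <- stats::runif(length(act), 0.2, 1.2)
  }
  restore_seed(old)
  H
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Generate the synthetic distance tensor from planted factors
#'
#' Slice `i` is `sum_k W[, , k] * H[k, i]` plus additive Gaussian noise
#' truncated at zero, re-symmetrized, with the diagonal zeroed. Dropout
#' removes whole loci (the row and column of the cell's matrix become `NA`
#' and the locus is flagged in the missingness mask), mirroring how imaging
#' misses a probe; exactly `round(dropout_frac * b)` loci are dropped per
#' cell.
#'
#' @param W_true `b x b x k` template array.
#' @param H_true `k x n` weight matrix.
#' @param noise_sd non-negative noise scale.
#' @param dropout_frac per-cell dropped-locus fraction in [0, 1).
#' @param seed integer seed.
#' @return an object of class `synthetic_dataset`: list with `tensor`
#'   (a [distance_tensor()]), `W_true`, `H_true`, `labels` (NULL here),
#'   `coords` (NULL here), `missing_mask`.
#' @export
generate_distance_tensor <- function(W_true, H_true, noise_sd = 0,
                                     dropout_frac = 0, seed = 1) {
  if (!is.array(W_true) || length(dim(W_true)) != 3L) {
    stop_value("W_true must be b x b x k")
  }
  b <- dim(W_true)[1]; k <- dim(W_true)[3]
  if (!is.matrix(H_true) || nrow(H_true) != k) {
    stop_value("H_true must be k x n with k = %d", k)
  }
  if (!is_scalar_number(noise_sd) || noise_sd < 0) {
    stop_value("noise_sd must be non-negative")
  }
  if (dropout_frac < 0 || dropout_frac >= 1) {
    stop_value("dropout_frac must be in [0, 1)")
  }
  n <- ncol(H_true)
  Wf <- matrix(W_true, b * b, k)   # column-major flatten; templates symmetric
  old <- .Random.seed_exists()
  set.seed(child_seed(seed, 2))
  dat <- array(0, c(b, b, n))
  for (c in seq_len(n)) {
    s <- matrix(Wf %*% H_true[, c], b, b)
    if (noise_sd > 0) {
      e <- matrix(stats::rnorm(b * b, sd = noise_sd), b, b)
      s <- pmax(s + e, 0)
    }
    s <- (s + t(s)) / 2
    diag(s) <- 0
    dat[, , c] <- s
  }
  n_drop <- round(dropout_frac * b)
  mask <- matrix(FALSE, n, b)
  if (n_drop > 0) {
    for (c in seq_len(n)) {
      drop <- sample.int(b, n_drop)
      mask[c, drop] <- TRUE
      dat[drop, , c] <- NA_real_
      dat[, drop, c] <- NA_real_
    }
  }
  restore_seed(old)
  tensor <- distance_tensor(dat, normalized = TRUE,
                            normalization_mode = "per_cell_max",
                            missing_mask = if (n_drop > 0) mask)
  structure(list(tensor = tensor, W_true = W_true, H_true = H_true,
                 labels = NULL, coords = NULL, missing_mask = mask),
            class = "synthetic_dataset")
}

#' Couple binary transcription labels to component weights
#'
#' Emulates a matched nascent-transcription readout:
#' `P(label = 1 | cell i) = plogis(label_effect * z_i + a)` where `z_i` is
#' the column-standardized mean of `H_true` over `label_components` and the
#' intercept `a` is calibrated by bisection so the expected positive
#' fraction is 0.5 (+/- 0.01), matching the balanced designs used downstream.
#'
#' @param H_true `k x n` weight matrix.
#' @param label_components non-empty integer vector of component rows
#'   (1-based).
#' @param label_effect log-odds slope; 0 decouples labels from structure.
#' @param seed integer seed.
#' @return integer 0/1 vector of length `n`.
#' @export
generate_transcription_labels <- function(H_true, label_components,
                                          label_effect = 1, seed = 1) {
  if (is.null(label_components) || !length(label_components)) {
    stop_value("label_components must be non-empty")
  }
  label_components <- as.integer(label_components)
  if (any(label_components < 1L | label_components > nrow(H_true))) {
    stop_value("label_components out of range 1..%d", nrow(H_true))
  }
  s <- colMeans(H_true[label_components, , drop = FALSE])
  z <- if (stats::sd(s) > 0) (s - mean(s)) / stats::sd(s) else rep(0, length(s))
  # bisection on the intercept for prevalence 0.5
  f <- function(a) mean(stats::plogis(label_effect * z + a)) - 0.5
  a <- stats::uniroot(f, lower = -50, upper = 50, tol = 1e-6)$root
  p <- stats::plogis(label_effect * z + a)
  old <- .Random.seed_exists()
  set.seed(child_seed(seed, 3))
  lab <- as.integer(stats::runif(length(p)) < p)
  restore_seed(old)
  lab
}

#' Embed distance matrices back into 3D coordinates
#'
#' Classical multidimensional scaling of each cell's distance matrix to 3
#' dimensions, producing a coordinate ensemble whose recomputed pairwise
#' distances approximate the input maps (exactly so for Euclidean-embeddable
#' matrices). Used to exercise the coordinate-input path end to end.
#'
#' @param dataset a `synthetic_dataset` or [distance_tensor()] with complete
#'   (non-NA) slices.
#' @param seed unused randomness guard (classical MDS is deterministic);
#'   kept so all generators share the (input, seed) contract.
#' @return an `n x b x 3` coordinate array.
#' @export
embed_to_coordinates <- function(dataset, seed = 1) {
  tensor <- if (inherits(dataset, "synthetic_dataset")) dataset$tensor else dataset
  stopifnot(inherits(tensor, "distance_tensor"))
  if (anyNA(tensor$data)) {
    stop_value("cannot embed matrices with NA entries; impute or drop first")
  }
  b <- n_bins(tensor); n <- n_cells(tensor)
  coords <- array(0, c(n, b, 3))
  k_mds <- min(3L, b - 1L)
  for (c in seq_len(n)) {
    xy <- suppressWarnings(stats::cmdscale(tensor$data[, , c], k = k_mds))
    if (ncol(xy) < 3) xy <- cbind(xy, matrix(0, b, 3 - ncol(xy)))
    coords[c, , ] <- xy
  }
  coords
}

#' Simulate a full ground-truthed ensemble
#'
#' Convenience wrapper chaining [make_block_templates()],
#' [sample_weight_matrix()], [generate_distance_tensor()],
#' [generate_transcription_labels()] and (optionally)
#' [embed_to_coordinates()]. When dropout is requested the coordinates are
#' embedded from the pre-dropout maps and the dropped loci are then set
#' missing, mirroring a probe that was never detected.
#'
#' @param config a [synthetic_config()].
#' @param embed logical; also produce 3D coordinates?
#' @return a `synthetic_dataset` with `tensor`, `W_true`, `H_true`,
#'   `labels`, `coords`, `missing_mask`.
#' @export
simulate_dataset <- function(config, embed = FALSE) {
  stopifnot(inherits(config, "synthetic_config"))
  W <- make_block_templates(config)
  H <- sample_weight_matrix(config)
  full <- generate_distance_tensor(W, H, noise_sd = config$noise_sd,
                                   dropout_frac = 0, seed = config$seed)
  coords <- if (embed || config$dropout_frac > 0) {
    embed_to_coordinates(full, seed = config$seed)
  }
  ds <- generate_distance_tensor(W, H, noise_sd = config$noise_sd,
                                 dropout_frac = config$dropout_frac,
                                 seed = config$seed)
  if (!is.null(coords) && any(ds$missing_mask)) {
    for (ax in 1:3) {
      a <- coords[, , ax]; a[ds$missing_mask] <- NA_real_; coords[, , ax] <- a
    }
  }
  ds$coords <- if (embed) coords
  if (!is.null(config$label_components)) {
    ds$labels <- generate_transcription_labels(
      H, config$label_components, config$label_effect, config$seed)
  }
  ds
}

#' @export
#' @method print synthetic_dataset
print.synthetic_dataset <- function(x, ...) {
  d <- dim(x$tensor$data)
  cat(sprintf("<synthetic_dataset> b=%d, n=%d, k_true=%d%s%s\n",
              d[1], d[3], dim(x$W_true)[3],
              if (!is.null(x$labels)) ", with labels" else "",
              if (!is.null(x$coords)) ", with coords" else ""))
  invisible(x)
}

#' Write a synthetic dataset with its ground-truth sidecar
#'
#' Writes the coordinate table (if coordinates are present) or the tensor
#' directory, plus TSVs for the planted `W_true` (flattened `b^2 x k`),
#' `H_true`, labels and missingness mask, and a JSON manifest naming them.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  b <- dim(dataset$W_true)[1]; k <- dim(dataset$W_true)[3]
  files <- list(W_true = "W_true.tsv", H_true = "H_true.tsv",
                mask = "missing_mask.tsv")
  write_matrix_tsv(matrix(aperm(dataset$W_true, c(2, 1, 3)), b * b, k),
                   file.path(dir, files$W_true))
  write_matrix_tsv(dataset$H_true, file.path(dir, files$H_true))
  write_matrix_tsv(dataset$missing_mask * 1, file.path(dir, files$mask))
  if (!is.null(dataset$labels)) {
    files$labels <- "labels.tsv"
    utils::write.table(
      data.frame(cell_id = dataset$tensor$cell_ids, label = dataset$labels),
      file.path(dir, files$labels), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(dataset$coords)) {
    files$coordinates <- "coordinates.tsv"
    ens <- cell_ensemble(dataset$coords, cell_ids = dataset$tensor$cell_ids)
    write_coordinate_table(ens, file.path(dir, files$coordinates))
  } else {
    files$tensor <- "tensor"
    write_tensor(dataset$tensor, file.path(dir, files$tensor))
  }
  man <- c(list(b = b, k_true = k, n = n_cells(dataset$tensor),
                flatten = "row_major"), files)
  jsonlite::write_json(man, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
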