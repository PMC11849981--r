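#' Flatten a distance tensor to the cells-in-columns matrix
#'
#' Column `c` of the result is slice `c` of the tensor in row-major order
#' (for the symmetric maps handled here row- and column-major coincide;
#' row-major is the recorded contract). Inverse of [unflatten_matrix()].
#'
#' @param tensor a [distance_tensor()] with complete slices.
#' @return a `b^2 x n` non-negative matrix.
#' @export
flatten_tensor <- function(tensor) {
  stopifnot(inherits(tensor, "distance_tensor"))
  b <- n_bins(tensor); n <- n_cells(tensor)
  V <- matrix(0, b * b, n)
  for (c in seq_len(n)) V[, c] <- as.vector(t(tensor$data[, , c]))
  V
}

#' @rdname flatten_tensor
#' @param V a `b^2 x n` matrix.
#' @param b bin count.
#' @param ... forwarded to [distance_tensor()] when rebuilding the container.
#' @export
unflatten_matrix <- function(V, b, ...) {
  if (nrow(V) != b * b) stop_value("V must have b^2 = %d rows", b * b)
  n <- ncol(V)
  dat <- array(0, c(b, b, n))
  for (c in seq_len(n)) dat[, , c] <- matrix(V[, c], b, b, byrow = TRUE)
  dat
}

# NNDSVDa initialization: deterministic, SVD-based, non-negative; zeros are
# filled with the data mean so multiplicative updates are not trapped.
nndsvd_init <- function(V, k) {
  sv <- svd(V, nu = k, nv = k)
  W <- matrix(0, nrow(V), k); H <- matrix(0, k, ncol(V))
  W[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  H[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  if (k >= 2) for (j in 2:k) {
    u <- sv$u[, j]; v <- sv$v[, j]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    nup <- sqrt(sum(up^2)); nun <- sqrt(sum(un^2))
    nvp <- sqrt(sum(vp^2)); nvn <- sqrt(sum(vn^2))
    if (nup * nvp >= nun * nvn) {
      s <- nup * nvp
      if (s > 0) {
        W[, j] <- sqrt(sv$d[j] * s) * up / nup
        H[j, ] <- sqrt(sv$d[j] * s) * vp / nvp
      }
    } else {
      s <- nun * nvn
      W[, j] <- sqrt(sv$d[j] * s) * un / nun
      H[j, ] <- sqrt(sv$d[j] * s) * vn / nvn
    }
  }
  mn <- mean(V)
  W[W <= 0] <- mn; H[H <= 0] <- mn
  list(W = W, H = H)
}

random_init <- function(V, k, seed) {
  old <- .Random.seed_exists()
  set.seed(child_seed(seed, 7))
  scale <- sqrt(mean(V) / k)
  W <- matrix(abs(stats::rnorm(nrow(V) * k)), nrow(V), k) * scale
  H <- matrix(abs(stats::rnorm(k * ncol(V))), k, ncol(V)) * scale
  restore_seed(old)
  list(W = W, H = H)
}

# HALS coordinate descent for
#   min 0.5*||V - WH||_F^2 + 0.5*l2*(||W||^2 + ||H||^2),  W, H >= 0.
# One iteration sweeps every column of W and every row of H in fixed order
# (deterministic given the initialization). Convergence: relative drop in
# reconstruction error (w.r.t. the initial error) below `tolerance`,
# checked every 10 iterations.
nmf_solve <- function(V, k, init, tolerance, max_iter, l2) {
  W <- init$W; H <- init$H
  eps <- 1e-12
  err0 <- fnorm(V - W %*% H)
  err_prev <- err0
  converged <- FALSE
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    A <- V %*% t(H)            # b^2 x k
    B <- H %*% t(H)            # k x k
    for (j in seq_len(k)) {
      denom <- B[j, j] + l2
      if (denom < eps) denom <- eps
      wj <- W[, j] + (A[, j] - W %*% B[, j]) / denom
      W[, j] <- pmax(wj, 0)
    }
    C <- crossprod(W, V)       # k x n
    D <- crossprod(W)          # k x k
    for (j in seq_len(k)) {
      denom <- D[j, j] + l2
      if (denom < eps) denom <- eps
      hj <- H[j, ] + (C[j, ] - D[j, ] %*% H) / denom
      H[j, ] <- pmax(hj, 0)
    }
    n_iter <- it
    if (it %% 10L == 0L) {
      err <- fnorm(V - W %*% H)
      if (err0 > 0 && (err_prev - err) / err0 < tolerance) {
        converged <- TRUE
        break
      }
      err_prev <- err
    }
  }
  list(W = W, H = H, n_iter = n_iter, converged = converged,
       error = fnorm(V - W %*% H))
}

#' Fit the non-negative matrix factorization of a cell ensemble
#'
#' Factorizes the flattened dataset `V` (`b^2 x n`, cells in columns) as
#' `V ~ W H` with `W >= 0` (`b^2 x k`) and `H >= 0` (`k x n`), minimizing the
#' Frobenius reconstruction error (optionally ridge-penalized) by
#' multiplicative updates from a deterministic NNDSVD initialization. The
#' fitted basis columns are reshaped into `b x b` *templates* -- recurrent
#' chromatin-organization patterns -- and symmetrized as
#' `(W_k + t(W_k)) / 2`; the pre-symmetrization discrepancy is recorded in
#' `asymmetry_norm`. Column `i` of `H` gives each template's weight in cell
#' `i`, so cell `i` is reconstructed as `sum_k W_k H[k, i]`.
#'
#' @param V `b^2 x n` non-negative matrix (see [flatten_tensor()]), or a
#'   [distance_tensor()].
#' @param k number of components; 20 is the conventional default for a
#'   single locus.
#' @param tolerance relative-error-change stopping tolerance.
#' @param max_iter maximum update iterations.
#' @param seed integer seed; only consulted for `init = "random"`.
#' @param init `"nndsvd"` (deterministic, default) or `"random"`.
#' @param l2 element-wise L2 (ridge) penalty strength; default 0.
#' @param init_factors optional list with explicit starting `W` (`b^2 x k`)
#'   and `H` (`k x n`), overriding `init`; used internally for warm starts.
#' @return an object of class `chromafactor_fit` with `templates`
#'   (`b x b x k`), `weights` (`k x n`), `k`, `b`, `n`, `solver_meta`,
#'   `reconstruction_error` and `asymmetry_norm`.
#' @export
fit_decomposition <- function(V, k = 20, tolerance = 1e-4, max_iter = 200,
                              seed = 1, init = c("nndsvd", "random"), l2 = 0,
                              init_factors = NULL) {
  init <- match.arg(init)
  if (is.list(init_factors)) init <- "warm"
  cell_ids <- NULL
  if (inherits(V, "distance_tensor")) {
    cell_ids <- V$cell_ids
    V <- flatten_tensor(V)
  }
  if (!is.matrix(V) || !is.numeric(V)) stop_value("V must be a numeric matrix")
  if (anyNA(V) || any(!is.finite(V))) stop_value("V must be finite with no NA")
  if (any(V < 0)) stop_value("V must be non-negative")
  b <- sqrt(nrow(V))
  if (b != floor(b)) stop_value("nrow(V) must be a perfect square (b^2)")
  b <- as.integer(b); n <- ncol(V)
  if (!is_scalar_number(k) || k < 1 || k > min(nrow(V), n)) {
    stop_value("k must satisfy 1 <= k <= min(b^2, n) = %d", min(nrow(V), n))
  }
  k <- as.integer(k)
  ini <- if (is.list(init_factors)) init_factors
         else if (init == "nndsvd") nndsvd_init(V, k)
         else random_init(V, k, seed)
  sol <- nmf_solve(V, k, ini, tolerance, max_iter, l2)
  templates <- array(0, c(b, b, k))
  asym <- 0
  for (j in seq_len(k)) {
    Tj <- matrix(sol$W[, j], b, b, byrow = TRUE)
    nTj <- fnorm(Tj)
    if (nTj > 0) asym <- max(asym, fnorm(Tj - t(Tj)) / nTj)
    templates[, , j] <- (Tj + t(Tj)) / 2
  }
  structure(
    list(templates = templates, weights = sol$H, k = k, b = b, n = n,
         cell_ids = cell_ids %||% paste0("cell_", seq_len(n)),
         solver_meta = list(init_scheme = init, tolerance = tolerance,
                            max_iter = max_iter, regularization = l2,
                            seed = seed, n_iter_run = sol$n_iter,
                            converged = sol$converged, v_norm = fnorm(V)),
         reconstruction_error = sol$error, asymmetry_norm = asym),
    class = "chromafactor_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
#' @method print chromafactor_fit
print.chromafactor_fit <- function(x, ...) {
  cat(sprintf(
    "<chromafactor_fit> k=%d components, b=%d bins, n=%d cells\n  error %.4g (%s after %d iterations), asymmetry %.3g\n",
    x$k, x$b, x$n, x$reconstruction_error,
    if (x$solver_meta$converged) "converged" else "not converged",
    x$solver_meta$n_iter_run, x$asymmetry_norm))
  invisible(x)
}

flat_templates <- function(fit) {
  matrix(vapply(seq_len(fit$k),
                function(j) as.vector(t(fit$templates[, , j])),
                numeric(fit$b^2)),
         ncol = fit$k)
}

#' Reconstruct one cell's denoised map from the fitted factors
#'
#' @param fit a `chromafactor_fit`.
#' @param cell_index cell column, 1-based.
#' @return a symmetric non-negative `b x b` matrix
#'   `sum_k templates[, , k] * weights[k, cell_index]`.
#' @export
reconstruct_cell <- function(fit, cell_index) {
  stopifnot(inherits(fit, "chromafactor_fit"))
  if (!is_scalar_number(cell_index) || cell_index < 1 || cell_index > fit$n) {
    stop_index("cell_index must be in 1..%d", fit$n)
  }
  m <- matrix(0, fit$b, fit$b)
  for (j in seq_len(fit$k)) {
    m <- m + fit$templates[, , j] * fit$weights[j, cell_index]
  }
  m
}

#' Fraction of dataset variance captured by the factorization
#'
#' `1 - ||V - WH||_F^2 / ||V||_F^2`, clipped to `[0, 1]`, computed from the
#' fit's (symmetrized) templates.
#'
#' @param V the `b^2 x n` data matrix or [distance_tensor()] the model was
#'   fitted to.
#' @param fit a `chromafactor_fit`.
#' @return a number in `[0, 1]`.
#' @export
variance_explained <- function(V, fit) {
  stopifnot(inherits(fit, "chromafactor_fit"))
  if (inherits(V, "distance_tensor")) V <- flatten_tensor(V)
  vn <- fnorm(V)
  if (vn == 0) stop_value("V is all zeros; variance explained undefined")
  resid <- fnorm(V - flat_templates(fit) %*% fit$weights)
  min(max(1 - resid^2 / vn^2, 0), 1)
}

#' Broom-style tidiers for a fitted decomposition
#'
#' `tidy()` returns the per-cell component weights in long form; `glance()`
#' a one-row model summary.
#'
#' @param x a `chromafactor_fit`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.chromafactor_fit <- function(x, ...) {
  tibble(cell_id = rep(x$cell_ids, each = x$k),
         cell_index = rep(seq_len(x$n), each = x$k),
         component = rep(seq_len(x$k), times = x$n),
         weight = as.vector(x$weights))
}

#' @rdname tidy.chromafactor_fit
#' @export
glance.chromafactor_fit <- function(x, ...) {
  ve <- 1 - x$reconstruction_error^2 / x$solver_meta$v_norm^2
  tibble(k = x$k, b = x$b, n = x$n,
         reconstruction_error = x$reconstruction_error,
         variance_explained = min(max(ve, 0), 1),
         asymmetry_norm = x$asymmetry_norm,
         n_iter = x$solver_meta$n_iter_run,
         converged = x$solver_meta$converged)
}

#' Plot fitted templates as heatmaps
#'
#' @param object a `chromafactor_fit`.
#' @param components which templates to draw (default all).
#' @param ... unused.
#' @return a ggplot object, one facet per template.
#' @export
autoplot.chromafactor_fit <- function(object, components = seq_len(object$k), ...) {
  df <- purrr::map_dfr(components, function(j) {
    m <- object$templates[, , j]
    tibble(component = j, bin_i = rep(seq_len(object$b), times = object$b),
           bin_j = rep(seq_len(object$b), each = object$b),
           value = as.vector(m))
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$bin_i, .data$bin_j, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "magma", direction = -1) +
    ggplot2::facet_wrap(~component, labeller = ggplot2::label_both) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "bin", y = "bin", fill = "distance")
}

#' Persist / load a fitted decomposition as plain text
#'
#' A JSON manifest plus one TSV per template and a weights TSV, written with
#' 17 significant digits so `read_decomposition(write_decomposition(fit))`
#' is byte-identical.
#'
#' @param fit a `chromafactor_fit`.
#' @param dir directory.
#' @return `dir` invisibly / the reloaded fit.
#' @export
write_decomposition <- function(fit, dir) {
  stopifnot(inherits(fit, "chromafactor_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (j in seq_len(fit$k)) {
    write_matrix_tsv(fit$templates[, , j],
                     file.path(dir, sprintf("template_%03d.tsv", j)))
  }
  write_matrix_tsv(fit$weights, file.path(dir, "weights.tsv"))
  man <- list(k = fit$k, b = fit$b, n = fit$n, cell_ids = fit$cell_ids,
              solver_meta = fit$solver_meta,
              reconstruction_error = fit$reconstruction_error,
              asymmetry_norm = fit$asymmetry_norm)
  jsonlite::write_json(man, file.path(dir, "model.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_decomposition
#' @export
read_decomposition <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "model.json"), simplifyVector = TRUE)
  templates <- array(0, c(man$b, man$b, man$k))
  for (j in seq_len(man$k)) {
    templates[, , j] <- read_matrix_tsv(
      file.path(dir, sprintf("template_%03d.tsv", j)))
  }
  structure(
    list(templates = templates,
         weights = read_matrix_tsv(file.path(dir, "weights.tsv")),
         k = man$k, b = man$b, n = man$n, cell_ids = man$cell_ids,
         solver_meta = as.list(man$solver_meta),
         reconstruction_error = man$reconstruction_error,
         asymmetry_norm = man$asymmetry_norm),
    class = "chromafactor_fit")
}
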