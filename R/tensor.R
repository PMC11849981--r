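#' Distance tensor: a stack of per-cell pairwise distance matrices
#'
#' The central container of the package: a `b x b x n` array in which slice
#' `[, , c]` holds the all-by-all pairwise distance (or contact) matrix of
#' cell `c`. Every slice must be symmetric with a zero diagonal and
#' non-negative entries; loci dropped during imaging may be recorded as `NA`
#' rows/columns together with a per-cell missingness mask.
#'
#' @param data numeric `b x b x n` array (a single `b x b` matrix is promoted
#'   to `n = 1`).
#' @param normalized logical; has the tensor been max-normalized?
#' @param normalization_mode one of `"none"`, `"per_cell_max"`, `"global_max"`.
#' @param cell_ids optional character vector of length `n`.
#' @param missing_mask optional `n x b` logical matrix marking dropped loci
#'   (their rows/columns may be `NA` in `data`).
#'
#' @return an object of class `distance_tensor` with elements `data`,
#'   `normalized`, `normalization_mode`, `cell_ids`, `missing_mask`.
#' @export
#' @examples
#' m <- matrix(c(0, 1, 1, 0), 2, 2)
#' distance_tensor(array(m, c(2, 2, 3)))
distance_tensor <- function(data, normalized = FALSE,
                            normalization_mode = c("none", "per_cell_max", "global_max"),
                            cell_ids = NULL, missing_mask = NULL) {
  normalization_mode <- match.arg(normalization_mode)
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L || dim(data)[1] != dim(data)[2]) {
    stop_value("data must be a b x b x n array")
  }
  b <- dim(data)[1]; n <- dim(data)[3]
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(n))
  if (length(cell_ids) != n) stop_value("cell_ids must have length n = %d", n)
  for (c in seq_len(n)) {
    s <- data[, , c]
    obs <- !is.na(s)
    if (!is.null(missing_mask)) {
      drop <- missing_mask[c, ]
      exp_obs <- !(outer(drop, drop, `|`))
      if (any(is.na(s) & exp_obs)) {
        stop_value("cell %d has NA entries outside its missingness mask", c)
      }
    } else if (anyNA(s)) {
      stop_value("cell %d contains NA but no missing_mask was given", c)
    }
    if (any(s[obs] < 0)) stop_value("cell %d has negative distances", c)
    if (max(abs(s - t(s)), na.rm = TRUE) > 1e-9) {
      stop_value("slice %d is not symmetric (tolerance 1e-9)", c)
    }
    d <- diag(s)
    if (any(d[!is.na(d)] != 0)) stop_value("slice %d has a non-zero diagonal", c)
  }
  structure(
    list(data = data, normalized = isTRUE(normalized),
         normalization_mode = normalization_mode,
         cell_ids = as.character(cell_ids), missing_mask = missing_mask),
    class = "distance_tensor")
}

#' @export
#' @method print distance_tensor
print.distance_tensor <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<distance_tensor> %d bins x %d cells (normalized: %s, mode: %s)\n",
              d[1], d[3], x$normalized, x$normalization_mode))
  invisible(x)
}

#' @export
dim.distance_tensor <- function(x) dim(x$data)

n_bins <- function(tensor) dim(tensor$data)[1]
n_cells <- function(tensor) dim(tensor$data)[3]

#' Tidy a distance tensor into a long tibble
#'
#' @param x a [distance_tensor()].
#' @param ... unused.
#' @return a tibble with columns `cell_id`, `bin_i`, `bin_j` (upper triangle,
#'   `bin_i < bin_j`) and `distance`.
#' @export
tidy.distance_tensor <- function(x, ...) {
  b <- n_bins(x); n <- n_cells(x)
  ut <- which(upper.tri(matrix(0, b, b)), arr.ind = TRUE)
  purrr::map_dfr(seq_len(n), function(c) {
    tibble(cell_id = x$cell_ids[c], bin_i = ut[, 1], bin_j = ut[, 2],
           distance = x$data[, , c][ut])
  })
}

#' Max-normalize a distance tensor
#'
#' Divides distances by the maximum observed distance so downstream thresholds
#' (e.g. the 0.05 insulation cutoff) are scale-free. Two conventions are
#' supported: `per_cell_max` scales each cell's map by its own maximum (every
#' slice then has maximum 1), `global_max` scales all maps by the dataset-wide
#' maximum. The applied mode is recorded in the result and re-normalizing with
#' the same mode is a no-op.
#'
#' @param tensor a [distance_tensor()].
#' @param mode `"per_cell_max"` (default) or `"global_max"`.
#' @return a normalized [distance_tensor()].
#' @export
normalize_max <- function(tensor, mode = c("per_cell_max", "global_max")) {
  mode <- match.arg(mode)
  stopifnot(inherits(tensor, "distance_tensor"))
  if (tensor$normalized && identical(tensor$normalization_mode, mode)) {
    return(tensor)
  }
  dat <- tensor$data
  n <- dim(dat)[3]
  if (mode == "per_cell_max") {
    for (c in seq_len(n)) {
      mx <- max(dat[, , c], na.rm = TRUE)
      if (!is.finite(mx) || mx <= 0) {
        stop_value("cell %d is all zeros; cannot per-cell max-normalize", c)
      }
      dat[, , c] <- dat[, , c] / mx
    }
  } else {
    mx <- max(dat, na.rm = TRUE)
    if (!is.finite(mx) || mx <= 0) stop_value("tensor has no positive entry")
    dat <- dat / mx
  }
  distance_tensor(dat, normalized = TRUE, normalization_mode = mode,
                  cell_ids = tensor$cell_ids, missing_mask = tensor$missing_mask)
}

#' Persist / load a distance tensor as plain text
#'
#' Writes a directory with a JSON manifest (`b`, `n`, normalization mode,
#' cell ids) and the flattened `b^2 x n` matrix as TSV with 17 significant
#' digits, so a load is bit-identical to what was saved.
#'
#' @param tensor a [distance_tensor()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly (`write_tensor`); a [distance_tensor()]
#'   (`read_tensor`).
#' @export
write_tensor <- function(tensor, dir) {
  stopifnot(inherits(tensor, "distance_tensor"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- list(b = n_bins(tensor), n = n_cells(tensor),
              normalized = tensor$normalized,
              normalization_mode = tensor$normalization_mode,
              cell_ids = tensor$cell_ids, layout = "flattened_row_major")
  jsonlite::write_json(man, file.path(dir, "tensor.json"), auto_unbox = TRUE)
  write_matrix_tsv(flatten_tensor(tensor), file.path(dir, "tensor.tsv"))
  if (!is.null(tensor$missing_mask)) {
    write_matrix_tsv(tensor$missing_mask * 1, file.path(dir, "missing_mask.tsv"))
  }
  invisible(dir)
}

#' @rdname write_tensor
#' @export
read_tensor <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "tensor.json"), simplifyVector = TRUE)
  V <- read_matrix_tsv(file.path(dir, "tensor.tsv"))
  dat <- unflatten_matrix(V, man$b)
  mask <- NULL
  mp <- file.path(dir, "missing_mask.tsv")
  if (file.exists(mp)) mask <- read_matrix_tsv(mp) > 0
  distance_tensor(dat, normalized = man$normalized,
                  normalization_mode = man$normalization_mode,
                  cell_ids = man$cell_ids, missing_mask = mask)
}
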