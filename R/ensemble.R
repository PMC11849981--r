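#' Cell ensemble: per-cell 3D locus coordinates with missingness
#'
#' Holds the raw single-molecule imaging data: for each of `n` cells the 3D
#' coordinates (nm) of `b` consecutive genomic loci, a missingness mask for
#' loci whose probe was not detected, and optional per-gene binary
#' transcription labels measured in the same cells.
#'
#' @param coords numeric `n x b x 3` array (nm); dropped loci are `NA` in all
#'   three axes.
#' @param missing_mask optional `n x b` logical; defaults to
#'   `is.na(coords[, , 1])`. A locus is missing iff all three coordinates are
#'   absent.
#' @param cell_ids optional length-`n` identifiers.
#' @param labels optional named list of length-`n` binary vectors, one per
#'   gene.
#' @param bin_size optional genomic span per bin (bp), metadata only.
#'
#' @return an object of class `cell_ensemble`.
#' @export
cell_ensemble <- function(coords, missing_mask = NULL, cell_ids = NULL,
                          labels = NULL, bin_size = NULL) {
  if (!is.array(coords) || length(dim(coords)) != 3L || dim(coords)[3] != 3L) {
    stop_value("coords must be an n x b x 3 array")
  }
  n <- dim(coords)[1]; b <- dim(coords)[2]
  if (n < 1L || b < 2L) stop_value("need n >= 1 cells and b >= 2 loci")
  na_any <- apply(is.na(coords), c(1, 2), any)
  na_all <- apply(is.na(coords), c(1, 2), all)
  if (any(na_any & !na_all)) {
    stop_value("a locus must be missing in all three axes or none")
  }
  if (is.null(missing_mask)) missing_mask <- na_all
  if (!identical(dim(missing_mask), c(n, b)) || !is.logical(missing_mask)) {
    stop_value("missing_mask must be an n x b logical matrix")
  }
  if (!identical(unname(missing_mask), unname(na_all))) {
    stop_value("missing_mask inconsistent with NA pattern of coords")
  }
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(n))
  if (length(cell_ids) != n) stop_value("cell_ids must have length n")
  if (!is.null(labels)) {
    if (is.null(names(labels)) || !is.list(labels)) {
      stop_value("labels must be a named list of per-gene binary vectors")
    }
    labels <- lapply(labels, function(v) {
      if (length(v) != n) stop_value("each label vector must have length n")
      assert_binary_labels(v, require_both = FALSE)
    })
  }
  structure(list(coords = coords, missing_mask = missing_mask,
                 cell_ids = as.character(cell_ids), labels = labels,
                 bin_size = bin_size),
            class = "cell_ensemble")
}

#' @export
#' @method print cell_ensemble
print.cell_ensemble <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<cell_ensemble> %d cells x %d loci (%.1f%% coordinates missing)\n",
              d[1], d[2], 100 * mean(x$missing_mask)))
  if (!is.null(x$labels)) {
    cat("  labels:", paste(names(x$labels), collapse = ", "), "\n")
  }
  invisible(x)
}

n_loci <- function(ensemble) dim(ensemble$coords)[2]

#' Tidy a cell ensemble into the coordinate-table layout
#'
#' @param x a [cell_ensemble()].
#' @param ... unused.
#' @return a tibble with columns `cell_id`, `locus_index` (1-based), `x`,
#'   `y`, `z` and one `label_<gene>` column per gene; missing loci have `NA`
#'   coordinates.
#' @export
tidy.cell_ensemble <- function(x, ...) {
  n <- dim(x$coords)[1]; b <- dim(x$coords)[2]
  # flatten each axis before the tibble() call: inside tibble() the column
  # named `x` would shadow the ensemble object
  axis_vec <- function(ax) as.vector(t(matrix(x$coords[, , ax], n, b)))
  xs <- axis_vec(1); ys <- axis_vec(2); zs <- axis_vec(3)
  out <- tibble(
    cell_id = rep(x$cell_ids, each = b),
    locus_index = rep(seq_len(b), times = n),
    x = xs, y = ys, z = zs)
  if (!is.null(x$labels)) {
    for (g in names(x$labels)) {
      out[[paste0("label_", g)]] <- rep(x$labels[[g]], each = b)
    }
  }
  out
}

#' Read a single-molecule coordinate table
#'
#' Ingests the plain-text layout used throughout the package: a TSV with
#' header columns `cell_id`, `locus_index`, `x`, `y`, `z` and optional
#' `label_<gene>` columns, one row per cell and locus. An empty field or NaN
#' in the coordinates marks the locus as missing. Every cell must cover the
#' same contiguous set of locus indices; cells are kept in order of first
#' appearance.
#'
#' @param path TSV file path.
#' @param bin_size optional genomic bin span (bp) to attach as metadata.
#' @return a [cell_ensemble()].
#' @export
read_coordinate_table <- function(path, bin_size = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = NA, na.strings = c("", "NA", "NaN", "nan"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("cell_id", "locus_index", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop_format("coordinate table must have columns %s", paste(need, collapse = ", "))
  }
  df$cell_id <- as.character(df$cell_id)
  cells <- unique(df$cell_id)
  n <- length(cells)
  if (anyDuplicated(df[c("cell_id", "locus_index")])) {
    stop_format("duplicate (cell_id, locus_index) rows")
  }
  counts <- table(df$cell_id)
  if (length(unique(as.integer(counts))) != 1L) {
    stop_format("ragged locus counts across cells")
  }
  b <- as.integer(counts[[1]])
  # locus_index may be 0- or 1-based in the file; require contiguity per cell
  li0 <- sort(unique(df$locus_index[df$cell_id == cells[1]]))
  if (!identical(as.integer(li0), as.integer(seq(min(li0), length.out = b)))) {
    stop_format("locus_index must be contiguous per cell")
  }
  offset <- as.integer(min(li0))
  coords <- array(NA_real_, c(n, b, 3))
  ord <- match(df$cell_id, cells)
  loci <- as.integer(df$locus_index) - offset + 1L
  if (any(loci < 1L | loci > b)) stop_format("locus_index out of range")
  for (ax in 1:3) {
    coords[cbind(ord, loci, ax)] <- as.numeric(df[[c("x", "y", "z")[ax]]])
  }
  # a partially-missing locus (e.g. x present, y empty) is treated as missing
  na_any <- apply(is.na(coords), c(1, 2), any)
  for (ax in 1:3) {
    a <- coords[, , ax]; a[na_any] <- NA_real_; coords[, , ax] <- a
  }
  labels <- NULL
  lab_cols <- grep("^label_", names(df), value = TRUE)
  if (length(lab_cols)) {
    first_rows <- !duplicated(df$cell_id)
    labels <- lapply(lab_cols, function(cl) as.integer(df[[cl]][first_rows]))
    names(labels) <- sub("^label_", "", lab_cols)
  }
  cell_ensemble(coords, cell_ids = cells, labels = labels, bin_size = bin_size)
}

#' Write a cell ensemble to the coordinate-table format
#'
#' @param ensemble a [cell_ensemble()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_coordinate_table <- function(ensemble, path) {
  df <- tidy.cell_ensemble(ensemble)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) ifelse(is.na(v), "", num17(v)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Quality-control filter on per-cell missingness
#'
#' Removes cells whose fraction of missing loci exceeds `max_missing_frac`
#' (strictly greater; a cell exactly at the threshold is retained). This is
#' the standard imaging QC step: chromatin traces with most probes undetected
#' carry little usable geometry.
#'
#' @param ensemble a [cell_ensemble()].
#' @param max_missing_frac maximum tolerated missing fraction in `[0, 1)`;
#'   typical choices are 0.8 for a short locus and 0.25 for a long one.
#' @return the filtered [cell_ensemble()], order preserved, labels subset
#'   accordingly.
#' @export
filter_cells_by_missingness <- function(ensemble, max_missing_frac) {
  stopifnot(inherits(ensemble, "cell_ensemble"))
  if (!is_scalar_number(max_missing_frac) || max_missing_frac < 0 ||
      max_missing_frac >= 1) {
    stop_value("max_missing_frac must be in [0, 1)")
  }
  frac <- rowMeans(ensemble$missing_mask)
  keep <- which(frac <= max_missing_frac)
  if (!length(keep)) {
    stop_value("all %d cells exceed missing fraction %.3g",
               length(frac), max_missing_frac)
  }
  cell_ensemble(
    ensemble$coords[keep, , , drop = FALSE],
    cell_ids = ensemble$cell_ids[keep],
    labels = if (!is.null(ensemble$labels)) lapply(ensemble$labels, `[`, keep),
    bin_size = ensemble$bin_size)
}

#' Impute missing loci by linear interpolation along the trace
#'
#' Each coordinate axis is interpolated independently along the locus index
#' between the nearest observed flanking loci; leading/trailing missing runs
#' are filled with the nearest observed value (constant extrapolation).
#' Observed coordinates are never altered.
#'
#' @param ensemble a [cell_ensemble()]; every cell needs at least 2 observed
#'   loci (filter first).
#' @return a [cell_ensemble()] with an all-false mask.
#' @export
impute_linear <- function(ensemble) {
  stopifnot(inherits(ensemble, "cell_ensemble"))
  coords <- ensemble$coords
  n <- dim(coords)[1]; b <- dim(coords)[2]
  for (c in seq_len(n)) {
    obs <- which(!ensemble$missing_mask[c, ])
    if (length(obs) < 2L) {
      stop_value("cell %d has fewer than 2 observed loci; filter before imputing", c)
    }
    if (length(obs) == b) next
    for (ax in 1:3) {
      v <- coords[c, , ax]
      coords[c, , ax] <- stats::approx(obs, v[obs], xout = seq_len(b),
                                       method = "linear", rule = 2)$y
      coords[c, obs, ax] <- v[obs]  # bit-for-bit preservation of observed values
    }
  }
  cell_ensemble(coords, cell_ids = ensemble$cell_ids,
                labels = ensemble$labels, bin_size = ensemble$bin_size)
}

#' Compute the per-cell pairwise distance tensor
#'
#' Entry `(i, j)` of slice `c` is the Euclidean distance (nm) between loci
#' `i` and `j` of cell `c`.
#'
#' @param ensemble a fully-observed [cell_ensemble()] (impute first).
#' @return an unnormalized [distance_tensor()].
#' @export
compute_distance_tensor <- function(ensemble) {
  stopifnot(inherits(ensemble, "cell_ensemble"))
  if (any(ensemble$missing_mask)) {
    stop_value("ensemble has missing coordinates; run impute_linear() first")
  }
  n <- dim(ensemble$coords)[1]; b <- dim(ensemble$coords)[2]
  dat <- array(0, c(b, b, n))
  for (c in seq_len(n)) {
    m <- as.matrix(stats::dist(ensemble$coords[c, , ]))
    dimnames(m) <- NULL
    diag(m) <- 0
    dat[, , c] <- (m + t(m)) / 2
  }
  distance_tensor(dat, normalized = FALSE, normalization_mode = "none",
                  cell_ids = ensemble$cell_ids)
}

#' One-call preprocessing pipeline
#'
#' `read -> filter -> impute -> distances -> normalize`, the standard path
#' from a coordinate table to an analysis-ready tensor.
#'
#' @param path coordinate-table TSV.
#' @param max_missing_frac QC threshold, see [filter_cells_by_missingness()].
#' @param norm normalization mode, see [normalize_max()].
#' @param bin_size optional bp per bin.
#' @return a list with the normalized `tensor`, the retained `ensemble`, and
#'   `labels` (named list or NULL).
#' @export
preprocess_coordinates <- function(path, max_missing_frac = 0.8,
                                   norm = c("per_cell_max", "global_max"),
                                   bin_size = NULL) {
  norm <- match.arg(norm)
  ens <- read_coordinate_table(path, bin_size = bin_size)
  ens <- filter_cells_by_missingness(ens, max_missing_frac)
  ens <- impute_linear(ens)
  tensor <- normalize_max(compute_distance_tensor(ens), mode = norm)
  list(tensor = tensor, ensemble = ens, labels = ens$labels)
}
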