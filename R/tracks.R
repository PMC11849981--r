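new_track <- function(values, window, kind, source) {
  tibble::new_tibble(
    tibble(bin = seq_along(values), value = values),
    window = as.integer(window), kind = kind, source = source,
    class = "chromafactor_track")
}

#' Sliding-window insulation profile of a matrix
#'
#' For each bin `i` the profile value is the mean of the cross-window block
#' `M[(i - window + 1):i, (i + 1):(i + window)]`, intersected with valid
#' indices; bins whose block is empty (the last bin) are undefined (`NA`).
#' On max-normalized *distance* maps a domain boundary separates two compact
#' blocks by long cross-block distances, so boundaries appear as local
#' maxima of this profile.
#'
#' @param M symmetric non-negative `b x b` matrix (template or median map).
#' @param window window half-width in bins; `1 <= window < b/2`.
#' @param source free-text provenance recorded on the track.
#' @return a `chromafactor_track` tibble with columns `bin`, `value`.
#' @export
insulation_profile <- function(M, window = 5, source = "matrix") {
  b <- check_square(M)
  if (!is_scalar_number(window) || window < 1 || window >= b / 2) {
    stop_value("window must satisfy 1 <= window < b/2 = %.1f", b / 2)
  }
  window <- as.integer(window)
  vals <- rep(NA_real_, b)
  for (i in seq_len(b)) {
    if (i + 1L > b) next  # empty cross block: undefined
    rows <- max(1L, i - window + 1L):i
    cols <- seq(i + 1L, min(b, i + window))
    vals[i] <- mean(M[rows, cols, drop = FALSE])
  }
  new_track(vals, window, "insulation", source)
}

check_square <- function(M) {
  if (!is.matrix(M) || nrow(M) != ncol(M)) stop_value("M must be square")
  if (anyNA(M)) stop_value("M must not contain NA")
  if (max(abs(M - t(M))) > 1e-8) stop_value("M must be symmetric")
  nrow(M)
}

#' Call boundaries from an insulation profile
#'
#' Boundary positions are interior strict local maxima of the profile
#' (plateaus contribute their leftmost bin) whose value exceeds `threshold`.
#' The default 0.05 threshold assumes max-normalized maps, where it is
#' scale-free.
#'
#' @param profile an insulation `chromafactor_track`.
#' @param threshold minimum insulation value for a call.
#' @return a `chromafactor_boundaries` tibble with columns `position`,
#'   `value`; attributes `threshold` and `profile`.
#' @export
call_boundaries <- function(profile, threshold = 0.05) {
  stopifnot(inherits(profile, "chromafactor_track"))
  if (!identical(attr(profile, "kind"), "insulation")) {
    stop_value("boundary calling expects an insulation track")
  }
  def <- which(!is.na(profile$value))
  v <- profile$value[def]
  pos <- integer(0); val <- numeric(0)
  if (length(v) >= 3) {
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in seq_along(r$values)) {
      if (j == 1L || j == length(r$values)) next  # interior maxima only
      if (r$values[j] > r$values[j - 1L] && r$values[j] > r$values[j + 1L] &&
          r$values[j] > threshold) {
        pos <- c(pos, def[starts[j]])   # plateau: leftmost bin
        val <- c(val, r$values[j])
      }
    }
  }
  tibble::new_tibble(tibble(position = pos, value = val),
                     threshold = threshold, profile = profile,
                     class = "chromafactor_boundaries")
}

#' Directionality index of a matrix
#'
#' The signed chi-square-like statistic of upstream-versus-downstream
#' interaction bias per bin: with `A` the summed similarity to the `window`
#' upstream bins, `B` to the downstream bins (truncated at the edges) and
#' `E = (A + B) / 2`,
#' `DI(i) = sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E)`, and 0 when
#' `A = B` or `E = 0`. Sharp sign transitions mark domain boundaries. The
#' statistic expects contact-like input, so max-normalized *distance* maps
#' are first transformed to similarity `s = 1 - m` (requires entries in
#' `[0, 1]`); pass `input = "contact"` to skip the transform.
#'
#' @param M symmetric `b x b` matrix.
#' @param window number of flanking bins summed on each side (>= 1).
#' @param input `"distance"` (default; transform `1 - m`) or `"contact"`.
#' @param source provenance string.
#' @return a `chromafactor_track` tibble, kind `"directionality"`.
#' @export
directionality_index <- function(M, window = 5, input = c("distance", "contact"),
                                 source = "matrix") {
  input <- match.arg(input)
  b <- check_square(M)
  if (!is_scalar_number(window) || window < 1) stop_value("window must be >= 1")
  window <- as.integer(window)
  S <- if (input == "distance") {
    if (max(M) > 1 + 1e-9) {
      stop_value("distance input must be max-normalized (entries <= 1)")
    }
    1 - M
  } else M
  vals <- numeric(b)
  for (i in seq_len(b)) {
    up <- seq(max(1L, i - window), i - 1L)
    dn <- seq(i + 1L, min(b, i + window))
    A <- if (i > 1L) sum(S[i, up]) else 0
    B <- if (i < b) sum(S[i, dn]) else 0
    E <- (A + B) / 2
    vals[i] <- if (E == 0 || A == B) 0 else {
      sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E)
    }
  }
  new_track(vals, window, "directionality", source)
}

#' Label cells by their dominant component
#'
#' @param H non-negative `k x n` weight matrix.
#' @return integer vector of length `n`: the 1-based component with the
#'   largest weight in each cell (ties break to the smallest index); cells
#'   with an all-zero column get the sentinel `-1`.
#' @export
dominant_component_labels <- function(H) {
  if (!is.matrix(H) || any(H < 0)) stop_value("H must be a non-negative matrix")
  out <- apply(H, 2, function(col) if (all(col == 0)) -1L else which.max(col))
  as.integer(out)
}

#' 2D manifold embedding of the per-cell weights
#'
#' UMAP embedding of the columns of `H` (one point per cell), with
#' `n_neighbors = 5` as the conventional setting for these datasets and all
#' other backend parameters at their defaults. Deterministic given `seed`
#' (single-threaded layout optimization).
#'
#' @param H `k x n` weight matrix.
#' @param n_neighbors UMAP neighborhood size; must be `< n`.
#' @param seed integer seed.
#' @return a `chromafactor_embedding` tibble with columns `cell_index`,
#'   `dim1`, `dim2`; attribute `backend` records the implementation.
#' @export
embed_weights <- function(H, n_neighbors = 5, seed = 1) {
  if (!is.matrix(H)) stop_value("H must be a matrix")
  n <- ncol(H)
  if (n <= n_neighbors) stop_value("need n > n_neighbors (= %d)", n_neighbors)
  old <- .Random.seed_exists()
  set.seed(child_seed(seed, 11))
  emb <- uwot::umap(t(H), n_neighbors = n_neighbors, n_threads = 1,
                    n_sgd_threads = 1)
  restore_seed(old)
  tibble::new_tibble(
    tibble(cell_index = seq_len(n), dim1 = emb[, 1], dim2 = emb[, 2]),
    backend = paste0("uwot ", as.character(utils::packageVersion("uwot"))),
    n_neighbors = as.integer(n_neighbors), seed = as.integer(seed),
    class = "chromafactor_embedding")
}

#' Plot a weight embedding colored by dominant component
#'
#' @param object a `chromafactor_embedding`.
#' @param labels optional per-cell labels for coloring (e.g.
#'   [dominant_component_labels()] output or transcription states).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.chromafactor_embedding <- function(object, labels = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(labels)) df$label <- factor(labels)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2)) +
    ggplot2::labs(x = "UMAP 1", y = "UMAP 2")
  if (is.null(labels)) p + ggplot2::geom_point(size = 0.7)
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$label), size = 0.7) +
    ggplot2::labs(colour = "group")
}

#' Plot insulation / directionality tracks
#'
#' @param object a `chromafactor_track`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.chromafactor_track <- function(object, ...) {
  kind <- attr(object, "kind")
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(.data$bin, .data$value)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "bin", y = kind,
                  title = sprintf("%s (window %d, %s)", kind,
                                  attr(object, "window"), attr(object, "source")))
}

#' Read a BED-like protein peak table and map it to bins
#'
#' Expects a TSV with columns `chrom`, `start`, `end`, `name` (protein) and
#' `score` (intensity). Peak midpoints are mapped to 1-based bins via
#' `bin_size` and `region_start`; for each protein and bin only the
#' strongest peak intensity is kept.
#'
#' @param path TSV/BED file path (with header).
#' @param bin_size genomic span per bin (bp).
#' @param region_start genomic start coordinate of bin 1 (bp).
#' @param b optional bin count; peaks outside `[1, b]` are dropped.
#' @return a `peak_track` tibble with columns `bin`, `intensity`, `protein`.
#' @export
read_peak_track <- function(path, bin_size, region_start = 0, b = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "name", "score")
  if (!all(need %in% names(df))) {
    stop_format("peak table needs columns %s", paste(need, collapse = ", "))
  }
  out <- tibble(
    bin = floor(((df$start + df$end) / 2 - region_start) / bin_size) + 1L,
    intensity = as.numeric(df$score),
    protein = as.character(df$name))
  if (!is.null(b)) out <- dplyr::filter(out, .data$bin >= 1, .data$bin <= b)
  out <- out |>
    dplyr::group_by(.data$protein, .data$bin) |>
    dplyr::summarise(intensity = max(.data$intensity), .groups = "drop") |>
    dplyr::select("bin", "intensity", "protein")
  tibble::new_tibble(out, class = "peak_track")
}

#' Colocalization of called boundaries with protein peaks
#'
#' A boundary matches a protein if any peak of that protein lies within
#' `tolerance_bins` bins of it. Returns per-protein match counts and, per
#' boundary, the combination of co-binding proteins (e.g. distinguishing
#' boundaries bound by CTCF and CP190 but not Rad21).
#'
#' @param calls a `chromafactor_boundaries` tibble.
#' @param peaks a `peak_track` tibble (`bin`, `intensity`, `protein`).
#' @param tolerance_bins non-negative matching tolerance.
#' @return a list of class `chromafactor_coloc` with tibbles `per_protein`
#'   (`protein`, `n_matched`, `n_boundaries`) and `per_boundary`
#'   (`position`, one logical column per protein, `combination`).
#' @export
peak_colocalization <- function(calls, peaks, tolerance_bins = 1) {
  stopifnot(inherits(calls, "chromafactor_boundaries"))
  if (!is_scalar_number(tolerance_bins) || tolerance_bins < 0) {
    stop_value("tolerance_bins must be >= 0")
  }
  proteins <- sort(unique(peaks$protein))
  nb <- nrow(calls)
  per_boundary <- tibble(position = calls$position)
  for (p in proteins) {
    pb <- peaks$bin[peaks$protein == p]
    per_boundary[[p]] <- vapply(calls$position, function(x) {
      length(pb) > 0 && min(abs(pb - x)) <= tolerance_bins
    }, logical(1), USE.NAMES = FALSE)
  }
  per_boundary$combination <- vapply(seq_len(nb), function(i) {
    hit <- proteins[vapply(proteins, function(p) isTRUE(per_boundary[[p]][i]),
                           logical(1))]
    if (length(hit)) paste(hit, collapse = "+") else "none"
  }, character(1))
  per_protein <- tibble(
    protein = proteins,
    n_matched = vapply(proteins, function(p) sum(per_boundary[[p]]),
                       integer(1), USE.NAMES = FALSE),
    n_boundaries = nb)
  structure(list(per_protein = per_protein, per_boundary = per_boundary,
                 tolerance_bins = tolerance_bins),
            class = "chromafactor_coloc")
}

#' @export
#' @method print chromafactor_coloc
print.chromafactor_coloc <- function(x, ...) {
  cat(sprintf("<chromafactor_coloc> %d boundaries vs %d proteins (tolerance %d bins)\n",
              nrow(x$per_boundary), nrow(x$per_protein), x$tolerance_bins))
  print(x$per_protein)
  invisible(x)
}
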