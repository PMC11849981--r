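#' Assign high- and low-contribution cell groups
#'
#' Scores each cell over the selected components (default: mean of the
#' selected rows of `H`; `"any_component"` instead takes a cell that is in
#' the top fraction for at least one selected component) and forms
#' * `high`: transcribing cells in the top `quantile` fraction of scores
#'   among transcribing cells, and
#' * `low`: non-transcribing cells in the bottom `quantile` fraction among
#'   non-transcribing cells.
#' Up to ties, `ceiling(quantile * n_class)` cells are selected per class;
#' boundary cells with scores exactly at the cut are included. These are the
#' subpopulations proposed to drive bulk contact trends.
#'
#' @param H `k x n` non-negative weight matrix.
#' @param labels binary transcription vector of length `n`.
#' @param components non-empty integer vector of component indices (1-based),
#'   typically the significant set from [componentwise_differential()].
#' @param quantile selected fraction per class, in (0, 1); 0.5 = top/bottom
#'   halves.
#' @param aggregation `"mean_weight"` (default) or `"any_component"`.
#' @return an object of class `chromafactor_groups`: list with
#'   `high_indices`, `low_indices`, `components_used`, `aggregation`,
#'   `quantile`, `fraction_of_population`, `scores`.
#' @export
assign_contribution_groups <- function(H, labels, components, quantile = 0.5,
                                       aggregation = c("mean_weight", "any_component")) {
  aggregation <- match.arg(aggregation)
  if (!is.matrix(H)) stop_value("H must be a k x n matrix")
  if (is.null(components) || !length(components)) {
    stop_value("components must be non-empty")
  }
  components <- as.integer(components)
  if (any(components < 1L | components > nrow(H))) {
    stop_value("components out of range 1..%d", nrow(H))
  }
  labels <- assert_binary_labels(labels)
  if (length(labels) != ncol(H)) stop_value("labels must have length ncol(H)")
  if (!is_scalar_number(quantile) || quantile <= 0 || quantile >= 1) {
    stop_value("quantile must be in (0, 1)")
  }
  pos <- which(labels == 1L); neg <- which(labels == 0L)
  scores <- colMeans(H[components, , drop = FALSE])
  top_cut <- function(s, q) sort(s, decreasing = TRUE)[ceiling(q * length(s))]
  bot_cut <- function(s, q) sort(s)[ceiling(q * length(s))]
  if (aggregation == "mean_weight") {
    high <- pos[scores[pos] >= top_cut(scores[pos], quantile)]
    low <- neg[scores[neg] <= bot_cut(scores[neg], quantile)]
  } else {
    in_top <- matrix(FALSE, length(components), ncol(H))
    in_bot <- matrix(FALSE, length(components), ncol(H))
    for (ci in seq_along(components)) {
      w <- H[components[ci], ]
      in_top[ci, ] <- w >= top_cut(w[pos], quantile)
      in_bot[ci, ] <- w <= bot_cut(w[neg], quantile)
    }
    high <- pos[colSums(in_top[, pos, drop = FALSE]) > 0]
    low <- neg[colSums(in_bot[, neg, drop = FALSE]) > 0]
  }
  structure(
    list(high_indices = sort(high), low_indices = sort(low),
         components_used = components, aggregation = aggregation,
         quantile = quantile,
         fraction_of_population = (length(high) + length(low)) / ncol(H),
         scores = scores),
    class = "chromafactor_groups")
}

#' @export
#' @method print chromafactor_groups
print.chromafactor_groups <- function(x, ...) {
  cat(sprintf(
    "<chromafactor_groups> %d high / %d low contribution cells (%.1f%% of population; components %s, %s, q=%.2f)\n",
    length(x$high_indices), length(x$low_indices),
    100 * x$fraction_of_population,
    paste(x$components_used, collapse = ","), x$aggregation, x$quantile))
  invisible(x)
}

#' @rdname assign_contribution_groups
#' @param x a `chromafactor_groups`.
#' @param ... unused.
#' @return `tidy()`: a tibble with `cell_index`, `group`
#'   (`"high"`/`"low"`/`"other"`), `score`.
#' @export
tidy.chromafactor_groups <- function(x, ...) {
  n <- length(x$scores)
  grp <- rep("other", n)
  grp[x$high_indices] <- "high"
  grp[x$low_indices] <- "low"
  tibble(cell_index = seq_len(n), group = grp, score = x$scores)
}

#' Element-wise median map over a set of cells
#'
#' @param tensor a [distance_tensor()].
#' @param indices non-empty cell indices.
#' @return a symmetric `b x b` matrix with zero diagonal.
#' @export
median_distance_map <- function(tensor, indices) {
  stopifnot(inherits(tensor, "distance_tensor"))
  indices <- as.integer(indices)
  if (!length(indices)) stop_value("indices must be non-empty")
  if (any(indices < 1L | indices > n_cells(tensor))) {
    stop_index("cell indices out of range")
  }
  m <- apply(tensor$data[, , indices, drop = FALSE], c(1, 2), stats::median)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

#' Element-wise difference of two maps
#'
#' `map_a - map_b`; used for transcribing-minus-non-transcribing and
#' high-minus-low contrasts (entries may be negative).
#'
#' @param map_a,map_b equally-shaped matrices.
#' @return a matrix of the same shape.
#' @export
difference_map <- function(map_a, map_b) {
  if (!identical(dim(map_a), dim(map_b))) stop_value("maps must have the same shape")
  map_a - map_b
}

#' Per-cell mean distance between an anchor and target bins
#'
#' For each selected cell, the mean of `tensor[anchor_bin, t, cell]` over
#' the target bins -- e.g. a promoter anchor against its nearby enhancers.
#'
#' @param tensor a [distance_tensor()].
#' @param anchor_bin single bin index (1-based).
#' @param target_bins bin indices; must not contain the anchor (the
#'   self-distance is 0 by construction and would bias the mean).
#' @param indices non-empty cell indices.
#' @return a list with `per_cell` (tibble `cell_index`, `mean_distance`) and
#'   `group_mean`.
#' @export
locus_pair_distances <- function(tensor, anchor_bin, target_bins, indices) {
  stopifnot(inherits(tensor, "distance_tensor"))
  b <- n_bins(tensor)
  anchor_bin <- as.integer(anchor_bin); target_bins <- as.integer(target_bins)
  indices <- as.integer(indices)
  if (!length(indices)) stop_value("indices must be non-empty")
  if (anchor_bin < 1L || anchor_bin > b || any(target_bins < 1L | target_bins > b)) {
    stop_value("bins out of range 1..%d", b)
  }
  if (anchor_bin %in% target_bins) {
    stop_value("anchor_bin must not be among target_bins")
  }
  vals <- vapply(indices, function(c) {
    mean(tensor$data[anchor_bin, target_bins, c])
  }, numeric(1))
  list(per_cell = tibble(cell_index = indices, mean_distance = vals),
       group_mean = mean(vals))
}

#' Contrast high- and low-contribution subpopulations
#'
#' Convenience wrapper computing the two groups' median maps, their
#' difference, and (optionally) anchor-target distances, the quantities
#' used to show that a small subpopulation carries the bulk contact trend.
#'
#' @param tensor a [distance_tensor()].
#' @param groups a `chromafactor_groups`.
#' @param anchor_bin,target_bins optional, see [locus_pair_distances()].
#' @return a list with `median_high`, `median_low`, `difference`, and (when
#'   bins are given) `distances_high`, `distances_low`.
#' @export
contrast_groups <- function(tensor, groups, anchor_bin = NULL,
                            target_bins = NULL) {
  stopifnot(inherits(groups, "chromafactor_groups"))
  out <- list(
    median_high = median_distance_map(tensor, groups$high_indices),
    median_low = median_distance_map(tensor, groups$low_indices))
  out$difference <- difference_map(out$median_high, out$median_low)
  if (!is.null(anchor_bin) && !is.null(target_bins)) {
    out$distances_high <- locus_pair_distances(tensor, anchor_bin, target_bins,
                                               groups$high_indices)
    out$distances_low <- locus_pair_distances(tensor, anchor_bin, target_bins,
                                              groups$low_indices)
  }
  out
}
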