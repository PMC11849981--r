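#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map_int map2 imap
NULL

# Internal: consistent error helpers -----------------------------------------

stop_value <- function(msg, ...) abort(sprintf(msg, ...), class = "chromafactor_value_error")
stop_format <- function(msg, ...) abort(sprintf(msg, ...), class = "chromafactor_format_error")
stop_range <- function(msg, ...) abort(sprintf(msg, ...), class = "chromafactor_range_error")
stop_index <- function(msg, ...) abort(sprintf(msg, ...), class = "chromafactor_index_error")

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

assert_binary_labels <- function(labels, require_both = TRUE) {
  if (is.logical(labels)) labels <- as.integer(labels)
  if (!is.numeric(labels) || !all(labels %in% c(0, 1))) {
    stop_value("labels must be a binary (0/1) vector")
  }
  labels <- as.integer(labels)
  if (require_both && length(unique(labels)) < 2L) {
    stop_value("both label classes (0 and 1) must be present")
  }
  labels
}

# Frobenius norm
fnorm <- function(x) sqrt(sum(x^2))

# Format numbers for bit-stable TSV round trips (17 significant digits).
num17 <- function(x) sprintf("%.17g", x)

write_matrix_tsv <- function(m, path) {
  ch <- matrix(num17(m), nrow = nrow(m))
  utils::write.table(ch, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

read_matrix_tsv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                                   colClasses = "numeric"))
  dimnames(m) <- NULL
  m
}

# Derive a child seed; kept well below .Machine$integer.max.
child_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}
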