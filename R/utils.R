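# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Wraps [withr::with_seed()] so every stochastic operation in the package
#' takes an explicit integer seed and leaves the global RNG state untouched.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

stop_tls <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' Validate a per-cell spatial table
#'
#' Checks that a data frame carries the required per-cell columns
#' (`cell_id`, `x_um`, `y_um`, `cell_type`) with unique cell ids and finite
#' micron coordinates.
#'
#' @param cells data frame of cells.
#' @param require_zone if `TRUE`, a `zone` column must also be present.
#' @return the validated table, invisibly coerced to a tibble.
#' @export
validate_cell_table <- function(cells, require_zone = FALSE) {
  required <- c("cell_id", "x_um", "y_um", "cell_type")
  if (require_zone) required <- c(required, "zone")
  missing <- setdiff(required, names(cells))
  if (length(missing) > 0L) {
    stop_tls("cell table is missing required column(s): %s",
             paste(missing, collapse = ", "))
  }
  if (anyDuplicated(cells$cell_id)) {
    stop_tls("cell table has duplicated cell_id values")
  }
  if (!all(is.finite(cells$x_um)) || !all(is.finite(cells$y_um))) {
    stop_tls("cell coordinates must be finite")
  }
  tibble::as_tibble(cells)
}

# k nearest reference points for each query point (Euclidean, microns).
# Returns list(idx = n x k matrix, dist = n x k matrix). Wraps RANN::nn2.
knn_query <- function(query_xy, ref_xy, k) {
  stopifnot(k >= 1L, nrow(ref_xy) >= k)
  res <- RANN::nn2(data = ref_xy, query = query_xy, k = k)
  list(idx = res$nn.idx, dist = res$nn.dists)
}

# Trimmed mean matching the stated semantics: drop the extreme `trim`
# fraction on each tail (base R mean(trim=) behaviour).
trimmed_mean <- function(x, trim) {
  if (length(x) == 0L) return(0)
  mean(x, trim = trim)
}

# Stable integer-coded factor of a character vector (sorted unique levels).
type_factor <- function(x) factor(x, levels = sort(unique(x)))
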