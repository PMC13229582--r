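#' Voxel-by-time state matrix
#'
#' Container for a multi-voxel time series: rows are voxels, columns are
#' timepoints, so column `t` is the state vector \eqn{s_t}. Carries the
#' repetition time and a flag recording whether the values have been
#' z-normalised to SD units.
#'
#' @param values numeric matrix, voxels x timepoints.
#' @param tr_seconds repetition time between consecutive columns, seconds.
#' @param normalized logical; `TRUE` once the matrix is in SD units.
#' @return An object of class `state_matrix`: the matrix with `tr_seconds`
#'   and `normalized` attributes.
#' @examples
#' m <- state_matrix(matrix(rnorm(20), 4, 5), tr_seconds = 2)
#' dim(m)
#' @export
state_matrix <- function(values, tr_seconds = 2, normalized = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_param("`values` must be a numeric matrix (voxels x timepoints)")
  }
  if (any(!is.finite(values))) {
    stop_param("state matrix contains non-finite values")
  }
  check_scalar(tr_seconds, "tr_seconds", lower = 1e-9)
  structure(values,
            tr_seconds = as.numeric(tr_seconds),
            normalized = isTRUE(normalized),
            class = c("state_matrix", "matrix", "array"))
}

#' @export
print.state_matrix <- function(x, ...) {
  cat(sprintf("<state_matrix> %d voxels x %d timepoints, TR = %gs%s\n",
              nrow(x), ncol(x), attr(x, "tr_seconds"),
              if (isTRUE(attr(x, "normalized"))) ", z-normalized" else ""))
  invisible(x)
}

# Rebuild a state_matrix around new values, carrying metadata over.
restate <- function(values, template, normalized = NULL) {
  state_matrix(values,
               tr_seconds = attr(template, "tr_seconds") %||% 2,
               normalized = if (is.null(normalized)) {
                 isTRUE(attr(template, "normalized"))
               } else normalized)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tr_of <- function(x, tr_seconds = NULL) {
  tr <- tr_seconds %||% attr(x, "tr_seconds")
  if (is.null(tr)) stop_param("repetition time unknown: supply `tr_seconds`")
  as.numeric(tr)
}

#' ROI mask as a voxel index set
#'
#' A region of interest inside a 3-D image grid, stored as unique 1-based
#' linear voxel indices in R's native column-major (x-fastest) order. All
#' extraction in the package uses ascending linear index order, so masked
#' matrices are reproducible across runs and platforms.
#'
#' @param indices integer vector of 1-based linear voxel indices.
#' @param grid_dim integer length-3 grid dimensions.
#' @param label region name.
#' @param space free-text space tag (e.g. `"subject"` or `"template"`).
#' @return An object of class `roi_mask` with fields `indices` (sorted),
#'   `grid_dim`, `label`, `space` and `n_voxels`.
#' @export
roi_mask <- function(indices, grid_dim, label = "ROI", space = "subject") {
  if (length(grid_dim) != 3L || any(grid_dim < 1) ||
      any(grid_dim != round(grid_dim))) {
    stop_param("`grid_dim` must be three positive integers")
  }
  indices <- as.integer(indices)
  if (length(indices) == 0L) stop_param("empty ROI mask")
  if (anyDuplicated(indices)) stop_param("ROI mask indices must be unique")
  if (any(indices < 1L) || any(indices > prod(grid_dim))) {
    stop_param("ROI mask indices fall outside the image grid")
  }
  structure(list(indices = sort(indices),
                 grid_dim = as.integer(grid_dim),
                 label = as.character(label),
                 space = as.character(space),
                 n_voxels = length(indices)),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> '%s' (%s space): %d voxels in %s grid\n",
              x$label, x$space, x$n_voxels,
              paste(x$grid_dim, collapse = "x")))
  invisible(x)
}
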