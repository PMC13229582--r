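#' Read a six-column motion-parameter file
#'
#' Whitespace-delimited realignment parameters: three translations (mm)
#' then three rotations (degrees), one row per functional volume.
#'
#' @param path file path.
#' @return Numeric timepoints x 6 matrix with the standard column names.
#' @export
read_motion <- function(path) {
  tab <- read.table(path, header = FALSE)
  if (ncol(tab) != 6L) {
    stop_param(sprintf("motion file %s has %d columns, expected 6",
                       path, ncol(tab)))
  }
  m <- as.matrix(tab)
  if (!is.numeric(m) || any(!is.finite(m))) {
    stop_param(sprintf("motion file %s has non-numeric entries", path))
  }
  colnames(m) <- c("trans_x", "trans_y", "trans_z",
                   "rot_x", "rot_y", "rot_z")
  m
}

#' @rdname read_motion
#' @param motion timepoints x 6 matrix to write.
#' @export
write_motion <- function(motion, path) {
  write.table(format(as.matrix(motion), scientific = FALSE), path,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ROI mask from a NIfTI label image
#'
#' The image must contain integer labels; voxels equal to `label_value`
#' (or any non-zero voxel when `label_value` is `NULL`) form the mask, in
#' ascending linear-index (column-major, x fastest) order.
#'
#' @param path NIfTI file path.
#' @param label_value label to extract; `NULL` selects all non-zero voxels.
#' @param label name stored on the mask.
#' @return A [roi_mask()].
#' @export
read_roi_mask <- function(path, label_value = NULL, label = "ROI") {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4L] == 1L) {
    arr <- arr[, , , 1L]
  }
  if (length(dim(arr)) != 3L) {
    stop_param(sprintf("mask image %s is not 3-D", path))
  }
  if (any(abs(arr - round(arr)) > 1e-6)) {
    stop_param(sprintf("mask image %s has non-integer labels", path))
  }
  idx <- if (is.null(label_value)) which(arr != 0) else {
    which(round(arr) == label_value)
  }
  if (length(idx) == 0L) stop_param("mask selects no voxels")
  roi_mask(idx, dim(arr), label = label)
}

#' Write an ROI mask as a NIfTI label image
#'
#' @param mask a [roi_mask()].
#' @param path output NIfTI path.
#' @param label_value integer written into the mask voxels.
#' @export
write_roi_mask <- function(mask, path, label_value = 1L) {
  stopifnot(inherits(mask, "roi_mask"))
  arr <- array(0L, dim = mask$grid_dim)
  arr[mask$indices] <- as.integer(label_value)
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

#' The packaged 16-region default-mode-network label list
#'
#' Label values and region names for a 16-region DMN definition (medial
#' frontal, anterior and posterior cingulate, precuneus, angular gyrus,
#' middle temporal and hippocampal regions, bilaterally). Shipped so that
#' tests and examples can build toy label images without downloading an
#' atlas; users analysing real data supply their own co-registered label
#' image whose values follow any mapping they document.
#'
#' @return Data frame with columns `label`, `region`, `hemisphere`
#'   (16 rows).
#' @export
dmn_roi_labels <- function() {
  read.csv(system.file("extdata", "dmn_rois.csv", package = "statevel"),
           stringsAsFactors = FALSE)
}

#' Read a 4-D functional NIfTI series
#'
#' @param path NIfTI file path.
#' @param tr_override repetition time in seconds to use instead of the
#'   header value (for files whose header lies).
#' @return List with `data` (4-D array) and `tr_seconds`.
#' @export
read_functional <- function(path, tr_override = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L) {
    stop_param(sprintf("functional image %s is not 4-D", path))
  }
  tr <- if (!is.null(tr_override)) {
    check_scalar(tr_override, "tr_override", lower = 1e-9)
  } else {
    pd <- RNifti::pixdim(img)
    if (length(pd) < 4L || !is.finite(pd[4L]) || pd[4L] <= 0) {
      stop_param("TR missing from NIfTI header; supply `tr_override`")
    }
    pd[4L]
  }
  list(data = arr, tr_seconds = as.numeric(tr))
}

#' Write a 4-D functional NIfTI series
#'
#' @param data 4-D numeric array.
#' @param path output path.
#' @param tr_seconds repetition time written into the header.
#' @export
write_functional <- function(data, path, tr_seconds = 2) {
  if (length(dim(data)) != 4L) stop_param("`data` must be 4-D")
  img <- RNifti::asNifti(data)
  pd <- RNifti::pixdim(img)
  pd[4L] <- tr_seconds
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Serialize a state matrix (compressed) and read it back
#'
#' @param matrix_ a [state_matrix()].
#' @param path output path (`.rds`).
#' @export
write_state_matrix <- function(matrix_, path) {
  stopifnot(inherits(matrix_, "state_matrix"))
  saveRDS(matrix_, path, compress = "gzip")
  invisible(path)
}

#' @rdname write_state_matrix
#' @export
read_state_matrix <- function(path) {
  out <- readRDS(path)
  if (!inherits(out, "state_matrix")) stop_param("not a state_matrix file")
  out
}
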