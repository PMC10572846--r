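#' Dynamic PET image
#'
#' A 4D activity volume with its frame schedule and voxel geometry. The
#' fourth array dimension indexes frames and must match the schedule.
#'
#' @param data 4D numeric array of activity concentrations (Bq/mL).
#' @param schedule An [frame_schedule()] with one entry per frame.
#' @param voxel_size_mm Voxel edge lengths in mm (length 3, all > 0).
#' @param affine Optional 4x4 grid-to-world matrix (defaults to a diagonal
#'   affine built from `voxel_size_mm`).
#' @return An object of class `fpet_dynimg`.
#' @export
dynamic_image <- function(data, schedule, voxel_size_mm, affine = NULL) {
  stopifnot(inherits(schedule, "fpet_schedule"))
  d <- dim(data)
  if (length(d) != 4L) stop("data must be a 4D array (x, y, z, frame)")
  if (d[4L] != length(schedule$start))
    stop(sprintf("frame-count mismatch: image has %d frames, schedule has %d",
                 d[4L], length(schedule$start)))
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("voxel_size_mm must be 3 positive lengths")
  if (is.null(affine)) affine <- diag(c(voxel_size_mm, 1))
  structure(
    list(data = data, schedule = schedule, voxel_size_mm = voxel_size_mm,
         affine = affine),
    class = "fpet_dynimg"
  )
}

#' @export
print.fpet_dynimg <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "Dynamic PET image: %d x %d x %d voxels (%.3g x %.3g x %.3g mm), %d frames over [%g, %g] min\n",
    d[1L], d[2L], d[3L], x$voxel_size_mm[1L], x$voxel_size_mm[2L],
    x$voxel_size_mm[3L], d[4L], x$schedule$start[1L],
    x$schedule$end[length(x$schedule$end)]
  ))
  invisible(x)
}

#' Volume-of-interest mask
#'
#' A boolean 3D mask aligned to an image grid, with a role label and a
#' record of any dilation applied.
#'
#' @param voxels Logical 3D array.
#' @param label Mask role, e.g. `"vessel"`, `"background"`, `"brain"`.
#' @param dilation_mm Millimetres of dilation already applied (default 0).
#' @return An object of class `fpet_mask`.
#' @export
voi_mask <- function(voxels, label = "vessel", dilation_mm = 0) {
  if (!is.logical(voxels)) voxels <- array(voxels != 0, dim(voxels))
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array")
  structure(
    list(voxels = voxels, label = label, dilation_mm = dilation_mm),
    class = "fpet_mask"
  )
}

#' @export
print.fpet_mask <- function(x, ...) {
  cat(sprintf("VOI mask '%s': %d voxels%s\n", x$label, sum(x$voxels),
              if (x$dilation_mm > 0) sprintf(" (dilated %g mm)", x$dilation_mm) else ""))
  invisible(x)
}

# Frame-wise mean over a logical mask; returns one value per frame.
mask_tac <- function(dyn, mask) {
  stopifnot(inherits(dyn, "fpet_dynimg"))
  vox <- if (inherits(mask, "fpet_mask")) mask$voxels else mask
  d <- dim(dyn$data)
  if (!all(dim(vox) == d[1:3])) stop("mask shape must match the image grid")
  flat <- matrix(dyn$data, nrow = prod(d[1:3]), ncol = d[4L])
  colMeans(flat[as.vector(vox), , drop = FALSE])
}
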