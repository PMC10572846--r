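# Image-derived input function: early-window vessel image, threshold
# segmentation, physical-space dilation, background correction and PVC
# scaling of the blood curve.

#' Mean image over an early acquisition window
#'
#' During the first minute after the bolus the blood pool dominates the
#' image, giving a well-defined picture of the vessels. This computes the
#' duration-weighted mean of all frames overlapping the window (partial
#' overlaps weighted by the overlapping duration).
#'
#' @param dyn An [dynamic_image()].
#' @param window Length-2 numeric, minutes (default `c(0, 1)`).
#' @return A list of class `fpet_early` with `volume` (3D array, Bq/mL) and
#'   `window`.
#' @export
make_early_image <- function(dyn, window = c(0, 1)) {
  stopifnot(inherits(dyn, "fpet_dynimg"), length(window) == 2L)
  ov <- pmin(dyn$schedule$end, window[2L]) - pmax(dyn$schedule$start, window[1L])
  w <- pmax(ov, 0)
  if (sum(w) <= 0)
    stop("no frames overlap the early window [", window[1L], ", ", window[2L], "] min")
  w <- w / sum(w)
  d <- dim(dyn$data)
  flat <- matrix(dyn$data, nrow = prod(d[1:3]), ncol = d[4L])
  vol <- array(as.vector(flat %*% w), dim = d[1:3])
  structure(list(volume = vol, window = window), class = "fpet_early")
}

#' Threshold segmentation of blood vessels
#'
#' Thresholds the early-window image at a fraction of its maximum and keeps
#' the largest 6-connected component, yielding the vessel VOI.
#'
#' @param early An `fpet_early` from [make_early_image()].
#' @param threshold_fraction Fraction of the image maximum in `(0, 1)`
#'   (default 0.5).
#' @return An [voi_mask()] labelled `"vessel"`.
#' @export
segment_vessels <- function(early, threshold_fraction = 0.5) {
  stopifnot(inherits(early, "fpet_early"))
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("threshold_fraction must lie in (0, 1)")
  vol <- early$volume
  mx <- max(vol)
  thr <- threshold_fraction * mx
  sel <- vol >= thr
  if (!any(sel))
    stop(sprintf("empty vessel mask: image maximum %.4g, threshold %.4g", mx, thr))
  if (all(sel))
    warning("uniform early image: every voxel passes the threshold")
  lab <- cpp_label3d(as.vector(sel), dim(vol))
  counts <- tabulate(lab)
  keep <- which.max(counts)
  voi_mask(array(lab == keep, dim(vol)), label = "vessel")
}

#' Dilate a mask in physical space
#'
#' Morphological dilation with a ball of the given physical radius,
#' honouring anisotropic voxel sizes: a voxel joins the mask if its centre
#' lies within `radius_mm` of the centre of any mask voxel.
#'
#' @param m An [voi_mask()].
#' @param radius_mm Dilation radius in mm (>= 0); 0 is the identity.
#' @param voxel_size_mm Voxel edge lengths in mm (length 3).
#' @return The dilated [voi_mask()] with `dilation_mm` updated.
#' @export
dilate_mask <- function(m, radius_mm, voxel_size_mm) {
  stopifnot(inherits(m, "fpet_mask"))
  if (radius_mm < 0) stop("radius_mm must be >= 0")
  if (radius_mm == 0) return(m)
  vs <- as.numeric(voxel_size_mm)
  r <- floor(radius_mm / vs)
  offs <- expand.grid(
    dx = -r[1L]:r[1L], dy = -r[2L]:r[2L], dz = -r[3L]:r[3L]
  )
  dist2 <- (offs$dx * vs[1L])^2 + (offs$dy * vs[2L])^2 + (offs$dz * vs[3L])^2
  offs <- offs[dist2 <= radius_mm^2 + 1e-9, , drop = FALSE]
  d <- dim(m$voxels)
  out <- array(FALSE, d)
  idx <- which(m$voxels, arr.ind = TRUE)
  for (k in seq_len(nrow(offs))) {
    x <- idx[, 1L] + offs$dx[k]
    y <- idx[, 2L] + offs$dy[k]
    z <- idx[, 3L] + offs$dz[k]
    ok <- x >= 1L & x <= d[1L] & y >= 1L & y <= d[2L] & z >= 1L & z <= d[3L]
    out[cbind(x[ok], y[ok], z[ok])] <- TRUE
  }
  voi_mask(out, label = m$label, dilation_mm = m$dilation_mm + radius_mm)
}

#' Extract the image-derived input function
#'
#' Computes the blood curve from the dynamic image as
#' `Ca = (mean over vessel VOI - mean over background VOI) / PVC` per frame,
#' assigns values to frame midpoints, and re-grids them linearly onto a fine
#' uniform grid (anchored at 0). Negative post-subtraction values are
#' clipped to zero; the count is recorded on the returned object.
#'
#' @param dyn An [dynamic_image()].
#' @param vessel Vessel [voi_mask()] (typically dilated).
#' @param bkg Optional background [voi_mask()]; `NULL` means no background
#'   subtraction.
#' @param pvc Partial-volume correction constant (> 0, default 1).
#' @param grid_step_s Spacing of the output grid in seconds (default 1).
#' @param t2 Session boundary carried onto the result (default 20 min).
#' @return An [input_function()] with the fine-grid curve and `pvc` stored.
#' @export
extract_idif <- function(dyn, vessel, bkg = NULL, pvc = 1, grid_step_s = 1,
                         t2 = 20) {
  stopifnot(inherits(dyn, "fpet_dynimg"), inherits(vessel, "fpet_mask"))
  if (pvc <= 0) stop("pvc must be > 0")
  if (!any(vessel$voxels)) stop("vessel mask is empty")
  v <- mask_tac(dyn, vessel)
  b <- 0
  if (!is.null(bkg)) {
    if (!any(bkg$voxels)) stop("background mask is empty")
    if (any(vessel$voxels & bkg$voxels))
      stop("vessel and background masks must be disjoint")
    b <- mask_tac(dyn, bkg)
    if (mean(b > v) > 0.5)
      warning("background mean exceeds vessel mean on most frames; VOIs look implausible")
  }
  ca_frames <- (v - b) / pvc
  mids <- frame_mid(dyn$schedule)
  tend <- dyn$schedule$end[length(dyn$schedule$end)]
  grid <- seq(0, tend, by = grid_step_s / 60)
  ca <- stats::approx(mids, ca_frames, xout = grid, rule = 2)$y
  n_neg <- sum(ca < 0)
  ca[ca < 0] <- 0
  out <- input_function(grid, ca, t2 = t2, pvc = pvc)
  attr(out, "n_clipped") <- n_neg
  out
}
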