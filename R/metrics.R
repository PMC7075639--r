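# Scalar z-line architecture metrics.

#' Orientational order parameter
#'
#' Maximum eigenvalue of the mean nematic tensor
#' `T = < 2 r r^T - I >` over unit vectors `r = (cos theta, sin theta)`:
#' 1 for perfectly aligned orientations, 0 for an isotropic set. For the
#' 2-D nematic tensor this is `sqrt(<cos 2theta>^2 + <sin 2theta>^2)`.
#'
#' @param angles numeric vector of nematic angles in radians; `NA`s are
#'   dropped.
#' @return scalar in `[0, 1]`, or `NA` (with a warning) for empty input.
#' @export
oop <- function(angles) {
  angles <- angles[is.finite(angles)]
  if (length(angles) == 0L) {
    warning("no valid angles: OOP is undefined")
    return(NA_real_)
  }
  sqrt(mean(cos(2 * angles))^2 + mean(sin(2 * angles))^2)
}

#' Director (dominant orientation) of a set of nematic angles
#'
#' The eigenvector angle of the maximum eigenvalue of the mean nematic
#' tensor, canonicalized to `[0, pi)`.
#'
#' @param angles numeric vector of nematic angles in radians.
#' @return angle in `[0, pi)`, `NA` if the tensor is degenerate or the
#'   input empty.
#' @export
director_angle <- function(angles) {
  angles <- angles[is.finite(angles)]
  if (length(angles) == 0L) return(NA_real_)
  mc <- mean(cos(2 * angles)); ms <- mean(sin(2 * angles))
  if (sqrt(mc^2 + ms^2) < 1e-9) return(NA_real_)
  canonical_angle(0.5 * atan2(ms, mc))
}

#' Sarcomere-based stress estimate along the major axis
#'
#' Sarcomeres produce force approximately perpendicular to their z-lines,
#' so at each z-line pixel the force direction is `theta_i + pi/2`. The
#' normalized stress along the x (major) axis is
#' `sigma_x = sum_i cos^2(theta_i + pi/2) / N_T`,
#' where `N_T` is the total number of pixels in the cell area. Input images
#' are assumed pre-aligned with the major axis along x; use `major_axis`
#' to rotate the frame otherwise.
#'
#' @param zline_angles orientations of the z-line pixels (radians), length
#'   `N_z`.
#' @param n_z number of z-line pixels; must equal `length(zline_angles)`.
#' @param n_total total pixels in the cell area, `N_T >= N_z`, positive.
#' @param major_axis major-axis angle in radians (default 0); angles are
#'   rotated so the estimate is taken along this axis.
#' @return scalar in `[0, N_z / N_T]`.
#' @export
estimate_stress <- function(zline_angles, n_z = length(zline_angles),
                            n_total, major_axis = 0) {
  if (n_total <= 0) stop("`n_total` must be positive")
  if (n_z != length(zline_angles))
    stop("`n_z` must equal the number of z-line angles")
  if (n_total < n_z) stop("`n_total` must be >= `n_z`")
  if (n_z == 0L) return(0)
  th <- zline_angles - major_axis
  sum(cos(th + pi / 2)^2) / n_total
}

#' Sarcomere spacing from z-line projections onto the actin director
#'
#' Per populated grid tile, z-line pixel positions are projected onto the
#' tile's actin director (the fibril direction); the projections are binned
#' at one pixel and the dominant spacing taken as the first off-origin peak
#' of the binned-count autocorrelation. Tiles with fewer than two z-line
#' pixels, or without a stable peak, are skipped. The pooled distribution
#' over tiles is returned.
#'
#' @param zline_skeleton a [binary_skeleton()] of z-line pixels.
#' @param grid a `director_grid` from the actin channel.
#' @param min_lag_px smallest admissible spacing in pixels (default 4).
#' @param peak_frac minimum autocorrelation peak height as a fraction of
#'   the zero-lag value (default 0.3).
#' @return numeric vector of spacings in micrometres (possibly empty).
#' @export
sarcomere_spacing <- function(zline_skeleton, grid, min_lag_px = 4,
                              peak_frac = 0.3) {
  stopifnot(is_binary_skeleton(zline_skeleton), inherits(grid, "director_grid"))
  if (!any(grid$populated)) stop("no populated grid tiles")
  res <- zline_skeleton$resolution
  dims <- dim(zline_skeleton$mask)
  spacings <- numeric(0)
  for (gi in seq_len(nrow(grid$director))) {
    for (gj in seq_len(ncol(grid$director))) {
      if (!grid$populated[gi, gj] || grid$degenerate[gi, gj]) next
      rs <- ((gi - 1L) * grid$grid_px + 1L):min(gi * grid$grid_px, dims[1])
      cs <- ((gj - 1L) * grid$grid_px + 1L):min(gj * grid$grid_px, dims[2])
      sub <- zline_skeleton$mask[rs, cs, drop = FALSE]
      pts <- which(sub, arr.ind = TRUE)
      if (nrow(pts) < 2L) next
      th <- grid$director[gi, gj]
      # projection onto the director in the y-up frame
      t_proj <- pts[, 2] * cos(th) - pts[, 1] * sin(th)
      lag <- first_autocorr_peak(t_proj, min_lag_px, peak_frac)
      if (!is.na(lag)) spacings <- c(spacings, lag / res)
    }
  }
  spacings
}

# First off-origin local maximum of the autocorrelation of 1-px binned
# point counts; NA when no peak passes the prominence floor.
first_autocorr_peak <- function(t_proj, min_lag_px, peak_frac) {
  t0 <- floor(min(t_proj))
  bins <- floor(t_proj - t0) + 1L
  counts <- tabulate(bins)
  L <- length(counts)
  if (L < min_lag_px + 2L) return(NA_real_)
  max_lag <- L - 1L
  ac <- vapply(0:max_lag, function(l)
    sum(counts[seq_len(L - l)] * counts[seq_len(L - l) + l]), numeric(1))
  ac <- c(ac, 0)                       # allow a peak at the last lag
  c0 <- ac[1]
  if (c0 <= 0) return(NA_real_)
  for (l in seq(max(min_lag_px, 2L), max_lag)) {
    v <- ac[l + 1L]
    if (v >= peak_frac * c0 && v > ac[l] && v >= ac[l + 2L])
      return(as.numeric(l))
  }
  NA_real_
}

#' Nuclei density per square millimetre
#'
#' Sums nuclei counts across all fields of view of a coverslip and divides
#' by the total imaged area.
#'
#' @param nuclei_counts integer vector, one count per field of view.
#' @param field_areas_mm2 areas in square millimetres, same length.
#' @return nuclei per mm^2, or `NA` (with a warning) for empty input.
#' @export
nuclei_density <- function(nuclei_counts, field_areas_mm2) {
  if (length(nuclei_counts) != length(field_areas_mm2))
    stop("counts and areas must have equal length")
  if (length(nuclei_counts) == 0L) {
    warning("no fields: nuclei density undefined")
    return(NA_real_)
  }
  if (any(field_areas_mm2 <= 0)) stop("areas must be positive")
  sum(nuclei_counts) / sum(field_areas_mm2)
}

#' Count nuclei in a DAPI-like channel
#'
#' Gaussian blur, global Otsu threshold, hole filling, watershed splitting
#' of touching blobs, and a component-area floor.
#'
#' @param nuclei_image a [gray_image()] with channel `"nuclei"`.
#' @param blur_sigma Gaussian scale in pixels (default 2).
#' @param min_area_px minimum component area (default 30 px, roughly a
#'   third of a nucleus cross-section at 6 px/um).
#' @return integer count (0 for a blank image).
#' @export
count_nuclei <- function(nuclei_image, blur_sigma = 2, min_area_px = 30) {
  stopifnot(is_gray_image(nuclei_image))
  px <- nuclei_image$pixels
  if (max(px) == min(px)) return(0L)
  px <- (px - min(px)) / (max(px) - min(px))
  sm <- EBImage::imageData(EBImage::gblur(EBImage::Image(px), sigma = blur_sigma))
  thr <- EBImage::otsu(EBImage::Image(sm))
  mask <- sm > thr
  mask <- EBImage::fillHull(EBImage::Image(mask * 1)) > 0
  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  ws <- EBImage::watershed(dm)
  labs <- as.integer(EBImage::imageData(ws))
  sizes <- tabulate(labs[labs > 0])
  sum(sizes >= min_area_px)
}
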