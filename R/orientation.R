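#' Least-mean-square (structure tensor) orientation estimation
#'
#' Estimates the per-pixel dominant structure orientation from image
#' gradients: the gradient outer products are summed over a square window
#' and the ridge direction is the dominant-gradient direction rotated by
#' pi/2, canonicalized to `[0, pi)`. Pixels whose window gradient energy
#' falls below `energy_floor` times the image maximum are marked invalid
#' (flat regions carry no orientation signal).
#'
#' @param image a [gray_image()]. For actin channels the image should first
#'   be Gaussian-filtered and normalized to zero mean and unit standard
#'   deviation (see [normalize_image()]); the pipeline does this.
#' @param window_px odd window edge (>= 3) over which gradient products are
#'   summed.
#' @param energy_floor validity floor as a fraction of the maximum window
#'   gradient energy (default 0.01).
#' @return an [orientation_field()].
#' @export
estimate_orientation <- function(image, window_px = 9, energy_floor = 0.01) {
  stopifnot(is_gray_image(image) || is.matrix(image))
  px <- if (is_gray_image(image)) image$pixels else image
  if (window_px %% 2 != 1 || window_px < 3)
    stop("`window_px` must be odd and >= 3")
  gx <- d_col(px)
  gy <- -d_row(px)                    # y-up frame
  jxx <- box_sum_replicate(gx * gx, window_px)
  jxy <- box_sum_replicate(gx * gy, window_px)
  jyy <- box_sum_replicate(gy * gy, window_px)
  energy <- jxx + jyy
  emax <- max(energy)
  valid <- if (emax > 0) energy >= energy_floor * emax
           else matrix(FALSE, nrow(px), ncol(px))
  # dominant gradient direction, rotated by pi/2 to get the ridge direction
  theta <- canonical_angle(0.5 * atan2(2 * jxy, jxx - jyy) + pi / 2)
  theta[!valid] <- NA_real_
  orientation_field(theta, valid)
}

#' Gaussian filter and z-score normalization for actin images
#'
#' The actin channel is smoothed with a Gaussian kernel and normalized to
#' zero mean and unit standard deviation before orientation estimation.
#'
#' @param image a [gray_image()].
#' @param sigma Gaussian scale in pixels.
#' @return a plain numeric matrix (z-scored intensities may be negative,
#'   so the result is no longer a valid `gray_image`).
#' @export
normalize_image <- function(image, sigma = 2) {
  stopifnot(is_gray_image(image))
  sm <- gauss_blur(image$pixels, sigma)
  s <- stats::sd(sm)
  if (s == 0) return(matrix(0, nrow(sm), ncol(sm)))
  (sm - mean(sm)) / s
}
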