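#' White top-hat contrast enhancement
#'
#' Subtracts the morphological opening with a disc structuring element,
#' keeping bright structures thinner than the disc (striations) and
#' suppressing broad background. Values are nonnegative by construction.
#'
#' @param image a [gray_image()].
#' @param radius_px disc radius in pixels (>= 1); must be smaller than the
#'   image.
#' @return a [gray_image()].
#' @export
tophat_enhance <- function(image, radius_px = 6) {
  stopifnot(is_gray_image(image))
  if (radius_px < 1) stop("`radius_px` must be >= 1")
  if (2 * radius_px + 1 > min(dim(image$pixels)))
    stop("structuring element larger than the image")
  brush <- EBImage::makeBrush(2 * as.integer(radius_px) + 1, shape = "disc")
  out <- EBImage::imageData(EBImage::whiteTopHat(image$pixels, brush))
  out[out < 0] <- 0
  gray_image(out, image$resolution, image$channel)
}

#' Background removal by surface interpolation
#'
#' Estimates the slowly varying background as a low percentile per block of
#' `grid_px` x `grid_px` pixels, interpolates the block estimates bilinearly
#' to a full-resolution surface, subtracts it and clips at zero. Foreground
#' striations, being sparse within a block, do not pull the percentile up.
#'
#' @param image a [gray_image()].
#' @param grid_px block edge in pixels (>= 8).
#' @param percentile background quantile per block (default 0.1).
#' @return a [gray_image()].
#' @export
remove_background <- function(image, grid_px = 32, percentile = 0.1) {
  stopifnot(is_gray_image(image))
  if (grid_px < 8) stop("`grid_px` must be >= 8")
  px <- image$pixels
  if (max(px) == min(px)) {
    warning("degenerate (constant) image: background removal returns zeros")
    return(gray_image(matrix(0, nrow(px), ncol(px)),
                      image$resolution, image$channel))
  }
  nr <- nrow(px); nc <- ncol(px)
  row_breaks <- unique(c(seq(1L, nr + 1L, by = grid_px), nr + 1L))
  col_breaks <- unique(c(seq(1L, nc + 1L, by = grid_px), nc + 1L))
  n_br <- length(row_breaks) - 1L
  n_bc <- length(col_breaks) - 1L
  bg <- matrix(0, n_br, n_bc)
  rc <- numeric(n_br); cc <- numeric(n_bc)
  for (i in seq_len(n_br)) {
    rs <- row_breaks[i]:(row_breaks[i + 1L] - 1L)
    rc[i] <- mean(rs)
    for (j in seq_len(n_bc)) {
      cs <- col_breaks[j]:(col_breaks[j + 1L] - 1L)
      if (i == 1L) cc[j] <- mean(cs)
      bg[i, j] <- stats::quantile(px[rs, cs], percentile, names = FALSE)
    }
  }
  surface <- bilinear_expand(bg, rc, cc, nr, nc)
  out <- px - surface
  out[out < 0] <- 0
  gray_image(out, image$resolution, image$channel)
}

# Bilinear interpolation of block-centre estimates to full resolution,
# with linear extrapolation beyond the outer centres.
bilinear_expand <- function(values, row_centres, col_centres, nr, nc) {
  interp_rows <- function(v, centres, n) {
    if (length(centres) == 1L) return(rep(v, n))
    out <- stats::approx(centres, v, xout = seq_len(n), rule = 2)$y
    k <- length(centres)
    lo <- seq_len(n) < centres[1]
    hi <- seq_len(n) > centres[k]
    slope1 <- (v[2] - v[1]) / (centres[2] - centres[1])
    slopek <- (v[k] - v[k - 1]) / (centres[k] - centres[k - 1])
    out[lo] <- v[1] + slope1 * (which(lo) - centres[1])
    out[hi] <- v[k] + slopek * (which(hi) - centres[k])
    out
  }
  # interpolate along rows for each block column, then along columns
  tall <- sapply(seq_len(ncol(values)), function(j)
    interp_rows(values[, j], row_centres, nr))
  tall <- matrix(tall, nrow = nr)
  t(sapply(seq_len(nr), function(i)
    interp_rows(tall[i, ], col_centres, nc)))
}

#' Adaptive (local mean) thresholding
#'
#' A pixel is foreground iff its intensity exceeds the local mean over a
#' square window plus `offset`. Window means near the border are taken over
#' the in-bounds part of the window.
#'
#' @param image a [gray_image()].
#' @param window_px odd window edge in pixels (>= 3).
#' @param offset additive offset on the local mean.
#' @return a logical matrix.
#' @export
binarize_adaptive <- function(image, window_px = 49, offset = 0.01) {
  stopifnot(is_gray_image(image))
  if (window_px %% 2 != 1 || window_px < 3)
    stop("`window_px` must be odd and >= 3")
  px <- image$pixels
  px > box_mean(px, window_px) + offset
}
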