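#' Grayscale micrograph container
#'
#' Wraps a single-channel fluorescence image together with its pixel
#' resolution and a channel tag. All pipeline functions consume and return
#' this container so that physical units (micrometres) are carried along
#' with the pixel data.
#'
#' Coordinate convention: images are stored as base-R matrices indexed
#' `[row, column]` with row 1 at the top (raster frame). All angles in the
#' package are measured counter-clockwise from the +x (column) axis in a
#' y-up mathematical frame; the conversion from the y-down raster frame is
#' handled internally wherever directions are computed from pixel offsets.
#'
#' @param pixels numeric matrix of nonnegative, finite intensities; at least
#'   16 x 16.
#' @param resolution pixels per micrometre (scalar > 0). Defaults to 6, the
#'   nominal resolution of a 40x oil objective on the imaging setup this
#'   pipeline targets.
#' @param channel one of `"alpha_actinin"`, `"actin"`, `"nuclei"`.
#' @return an object of class `gray_image`.
#' @export
gray_image <- function(pixels, resolution = 6,
                       channel = c("alpha_actinin", "actin", "nuclei")) {
  channel <- match.arg(channel)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (nrow(pixels) < 16 || ncol(pixels) < 16)
    stop("image must be at least 16 x 16 pixels")
  if (any(!is.finite(pixels)))
    stop("image contains non-finite values")
  if (any(pixels < 0))
    stop("image contains negative intensities")
  if (!is.numeric(resolution) || length(resolution) != 1 || resolution <= 0)
    stop("`resolution` must be a positive scalar (pixels per micrometre)")
  structure(list(pixels = pixels, resolution = resolution, channel = channel),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d px, %.3g px/um, channel = %s\n",
              nrow(x$pixels), ncol(x$pixels), x$resolution, x$channel))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

is_gray_image <- function(x) inherits(x, "gray_image")

#' One-pixel-wide binary skeleton
#'
#' @param mask logical matrix; TRUE marks skeleton pixels.
#' @param resolution pixels per micrometre.
#' @param provenance `"raw_alpha_actinin"` for the skeleton of the full
#'   alpha-actinin stain, `"zline_only"` after actin-guided segmentation.
#' @return an object of class `binary_skeleton`.
#' @export
binary_skeleton <- function(mask, resolution = 6,
                            provenance = c("raw_alpha_actinin", "zline_only")) {
  provenance <- match.arg(provenance)
  if (!is.matrix(mask) || !is.logical(mask))
    stop("`mask` must be a logical matrix")
  if (any(is.na(mask))) stop("`mask` must not contain NA")
  structure(list(mask = mask, resolution = resolution, provenance = provenance),
            class = "binary_skeleton")
}

#' @export
print.binary_skeleton <- function(x, ...) {
  cat(sprintf("<binary_skeleton> %d x %d px, %d foreground px, provenance = %s\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), x$provenance))
  invisible(x)
}

is_binary_skeleton <- function(x) inherits(x, "binary_skeleton")

#' Per-pixel nematic orientation field
#'
#' Angles are nematic (theta and theta + pi denote the same orientation) and
#' canonicalized to `[0, pi)`. Invalid pixels (flat windows, below the
#' gradient-energy floor) carry `NA` in `theta` and FALSE in `valid`; they
#' are never consumed downstream.
#'
#' @param theta numeric matrix of angles in radians.
#' @param valid logical matrix, same shape.
#' @return an object of class `orientation_field`.
#' @export
orientation_field <- function(theta, valid = !is.na(theta)) {
  if (!is.matrix(theta)) stop("`theta` must be a matrix")
  if (!is.matrix(valid) || !is.logical(valid) || !identical(dim(valid), dim(theta)))
    stop("`valid` must be a logical matrix with the same shape as `theta`")
  theta[valid] <- canonical_angle(theta[valid])
  theta[!valid] <- NA_real_
  structure(list(theta = theta, valid = valid), class = "orientation_field")
}

#' @export
print.orientation_field <- function(x, ...) {
  cat(sprintf("<orientation_field> %d x %d px, %.1f%% valid\n",
              nrow(x$theta), ncol(x$theta), 100 * mean(x$valid)))
  invisible(x)
}

is_orientation_field <- function(x) inherits(x, "orientation_field")

#' Canonicalize nematic angles to [0, pi)
#'
#' @param theta numeric vector of angles in radians.
#' @return angles folded into `[0, pi)`.
#' @export
canonical_angle <- function(theta) {
  out <- theta %% pi
  # %% can return pi itself through floating-point rounding near pi
  out[out >= pi] <- 0
  out
}
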