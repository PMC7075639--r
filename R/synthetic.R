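# Synthetic test inputs: segment fixtures with exact ground truth and
# two-channel tissue phantoms emulating striations, off-target staining
# and camera noise.

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
with_rng_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Specification of a segment fixture
#'
#' Describes a stack of short straight segments emulating z-lines of
#' neighboring myofibrils: each segment continues the previous one along
#' the line direction, laterally shifted by `lateral_shift_px`. A shift of
#' at most one pixel makes consecutive segments continuous; a shift of two
#' or more breaks continuity.
#'
#' @param n_segments number of segments (default 4).
#' @param segment_len_px pixels per segment (default 7).
#' @param lateral_shift_px lateral shift between consecutive segments
#'   (>= 0).
#' @param rotation_deg rotation of the whole construction (0 = vertical
#'   segments).
#' @param gap_px extra gap along the line direction between consecutive
#'   segments (default 0; any positive gap breaks continuity).
#' @param margin_px border margin around the construction.
#' @return an object of class `segment_fixture_spec`.
#' @export
segment_fixture_spec <- function(n_segments = 4, segment_len_px = 7,
                                 lateral_shift_px = 1, rotation_deg = 0,
                                 gap_px = 0, margin_px = 4) {
  if (n_segments < 1 || segment_len_px < 1) stop("invalid segment spec")
  if (lateral_shift_px < 0) stop("`lateral_shift_px` must be >= 0")
  if (gap_px < 0) stop("`gap_px` must be >= 0")
  structure(list(n_segments = n_segments, segment_len_px = segment_len_px,
                 lateral_shift_px = lateral_shift_px,
                 rotation_deg = rotation_deg, gap_px = gap_px,
                 margin_px = margin_px),
            class = "segment_fixture_spec")
}

#' Generate a segment fixture with ground truth
#'
#' Rasterizes the segments of a [segment_fixture_spec()], sets the
#' orientation field to the segment direction on segment pixels, and builds
#' the ground-truth grouping: consecutive segments belong to the same
#' continuous line iff the lateral shift is at most one pixel and the gap
#' is zero.
#'
#' @param spec a [segment_fixture_spec()].
#' @param resolution pixels per micrometre for the skeleton.
#' @return list with `skeleton` ([binary_skeleton()]), `field`
#'   ([orientation_field()]), `truth` (a `line_set`), `theta` (the segment
#'   orientation), and `spec`.
#' @export
make_segment_fixture <- function(spec = segment_fixture_spec(),
                                 resolution = 6) {
  stopifnot(inherits(spec, "segment_fixture_spec"))
  a <- spec$rotation_deg * pi / 180
  # raster direction along the line (rotation 0: down the rows)
  d <- c(cos(a), sin(a))
  # nematic orientation of the segments in the y-up frame
  theta <- canonical_angle(atan2(-d[1], d[2]))

  # Bresenham-style rasterization: one pixel per step of the dominant
  # (major) raster axis, so every segment has exactly segment_len_px
  # pixels; the lateral shift is applied along the minor axis.
  maj <- if (abs(d[1]) >= abs(d[2])) 1L else 2L
  mnr <- 3L - maj
  slope <- d[mnr] / d[maj]
  step_len <- spec$segment_len_px + spec$gap_px
  seg_pixels <- vector("list", spec$n_segments)
  for (j in seq_len(spec$n_segments)) {
    t0 <- (j - 1L) * step_len
    tt <- t0 + seq_len(spec$segment_len_px) - 1L
    p_maj <- tt
    p_mnr <- round(tt * slope + (j - 1L) * spec$lateral_shift_px)
    pts <- matrix(0L, spec$segment_len_px, 2)
    pts[, maj] <- as.integer(p_maj)
    pts[, mnr] <- as.integer(p_mnr)
    seg_pixels[[j]] <- pts
  }
  all_pts <- do.call(rbind, seg_pixels)
  if (nrow(unique(all_pts)) != nrow(all_pts))
    stop("segments overlap; adjust the fixture spec")
  m <- spec$margin_px
  r_off <- m + 1L - min(all_pts[, 1])
  c_off <- m + 1L - min(all_pts[, 2])
  nr <- max(all_pts[, 1]) + r_off + m
  nc <- max(all_pts[, 2]) + c_off + m
  mask <- matrix(FALSE, nr, nc)
  th <- matrix(NA_real_, nr, nc)
  for (j in seq_len(spec$n_segments)) {
    seg_pixels[[j]][, 1] <- seg_pixels[[j]][, 1] + r_off
    seg_pixels[[j]][, 2] <- seg_pixels[[j]][, 2] + c_off
    mask[seg_pixels[[j]]] <- TRUE
    th[seg_pixels[[j]]] <- theta
  }

  # ground truth: consecutive segments are continuous iff their rasterized
  # junction pixels are 8-adjacent; at rotation 0 this is exactly the rule
  # that a lateral shift of at most one pixel (and no gap) is continuous
  truth_lines <- list()
  chain <- seg_pixels[[1]]
  for (j in seq_len(spec$n_segments)[-1]) {
    last_px <- chain[nrow(chain), ]
    first_px <- seg_pixels[[j]][1, ]
    if (max(abs(first_px - last_px)) <= 1L) {
      chain <- rbind(chain, seg_pixels[[j]])
    } else {
      truth_lines[[length(truth_lines) + 1L]] <-
        new_continuous_line(chain, resolution)
      chain <- seg_pixels[[j]]
    }
  }
  truth_lines[[length(truth_lines) + 1L]] <- new_continuous_line(chain, resolution)
  truth <- structure(list(lines = truth_lines, resolution = resolution,
                          image_id = "segment_fixture"),
                     class = "line_set")
  list(skeleton = binary_skeleton(mask, resolution, "zline_only"),
       field = orientation_field(th),
       truth = truth, theta = theta, spec = spec)
}

#' Specification of a two-channel tissue phantom
#'
#' The phantom emulates the image model of alpha-actinin stained striated
#' tissue with an actin co-stain: actin fibrils run along a direction
#' field; mature myofibril bands carry periodic z-line bars perpendicular
#' to the fibrils (sarcomere lattice); immature bands carry off-target
#' staining parallel to the fibrils (stress-fiber-like); both channels are
#' blurred by a Gaussian PSF and corrupted by Poisson shot noise plus
#' Gaussian read noise.
#'
#' @param size image edge in pixels (square), default 192.
#' @param resolution pixels per micrometre, default 6 (the imaging regime
#'   the pipeline targets).
#' @param fibril_angle fibril direction in radians (y-up frame), default 0.
#' @param direction `"constant"` or `"varying"` (smooth sinusoidal
#'   modulation of the fibril angle, amplitude `vary_amp_rad`).
#' @param vary_amp_rad amplitude of the direction modulation (default 0.2).
#' @param spacing_um sarcomere spacing (z-line lattice period), default 2.
#' @param zline_len_um z-line (band) length perpendicular to fibrils,
#'   default 2.
#' @param registration_jitter_px lateral phase jitter between bands,
#'   default 1.
#' @param offtarget_fraction target fraction of alpha-actinin pixels that
#'   are off-target (in `[0, 1)`), default 0.
#' @param boundary_staining add a cell-boundary ring of off-target stain.
#' @param psf_sigma Gaussian PSF sigma in pixels, default 1.
#' @param poisson_gain expected photons at unit intensity (0 disables shot
#'   noise), default 200.
#' @param gaussian_sigma read-noise standard deviation, default 0.01.
#' @param seed mandatory RNG seed for reproducibility.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = 192, resolution = 6, fibril_angle = 0,
                         direction = c("constant", "varying"),
                         vary_amp_rad = 0.2,
                         spacing_um = 2, zline_len_um = 2,
                         registration_jitter_px = 1,
                         offtarget_fraction = 0, boundary_staining = FALSE,
                         psf_sigma = 1, poisson_gain = 200,
                         gaussian_sigma = 0.01, seed) {
  direction <- match.arg(direction)
  if (missing(seed) || is.null(seed)) stop("`seed` is mandatory")
  if (offtarget_fraction < 0 || offtarget_fraction >= 1)
    stop("`offtarget_fraction` must be in [0, 1)")
  if (psf_sigma < 0 || poisson_gain < 0 || gaussian_sigma < 0)
    stop("noise rates must be >= 0")
  structure(list(size = size, resolution = resolution,
                 fibril_angle = fibril_angle, direction = direction,
                 vary_amp_rad = vary_amp_rad, spacing_um = spacing_um,
                 zline_len_um = zline_len_um,
                 registration_jitter_px = registration_jitter_px,
                 offtarget_fraction = offtarget_fraction,
                 boundary_staining = boundary_staining,
                 psf_sigma = psf_sigma, poisson_gain = poisson_gain,
                 gaussian_sigma = gaussian_sigma, seed = seed),
            class = "phantom_spec")
}

#' Generate a two-channel tissue phantom with ground truth
#'
#' @param spec a [phantom_spec()].
#' @return list with `actin` and `actinin` ([gray_image()]s), `truth`
#'   (unblurred logical masks `zline` and `offtarget`, plus the generative
#'   `spacing_px` and `fibril_angle`), and `spec`.
#' @export
make_tissue_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_rng_seed(spec$seed, {
    n <- spec$size
    res <- spec$resolution
    spacing_px <- spec$spacing_um * res
    band_px <- round(spec$zline_len_um * res)

    rr <- matrix(seq_len(n), n, n)
    cc <- matrix(seq_len(n), n, n, byrow = TRUE)
    x <- cc; y <- -rr                       # y-up frame
    phi <- spec$fibril_angle
    if (spec$direction == "varying") {
      phi <- phi + spec$vary_amp_rad *
        sin(2 * pi * cc / n) * cos(2 * pi * rr / n)
    } else {
      phi <- matrix(phi, n, n)
    }
    # coordinates along (t) and across (s) the fibrils
    t_co <- x * cos(phi) + y * sin(phi)
    s_co <- -x * sin(phi) + y * cos(phi)

    # actin channel: periodic fibril stripes across s at ~1 um pitch
    # (typical myofibril width), resolvable at the default PSF
    pitch <- res
    actin_clean <- 0.25 + 0.6 * (0.5 + 0.5 * cos(2 * pi * s_co / pitch))^2

    # myofibril bands across s; mature bands carry z-line bars, immature
    # bands carry a fibril-parallel off-target line
    s_min <- min(s_co)
    band_idx <- floor((s_co - s_min) / band_px)
    n_bands <- max(band_idx) + 1L
    # the stated off-target fraction is realized exactly in band counts
    # (randomly placed); per-pixel rates then track it closely
    n_imm <- round(spec$offtarget_fraction * n_bands)
    immature <- logical(n_bands)
    immature[sample.int(n_bands, n_imm)] <- TRUE
    # well-formed tissue: z-lines of neighboring myofibrils are laterally
    # registered up to a small jitter around a common lattice phase
    phase <- stats::runif(1, 0, spacing_px) +
      stats::rnorm(n_bands, 0, spec$registration_jitter_px)

    zline_mask <- matrix(FALSE, n, n)
    off_mask <- matrix(FALSE, n, n)
    bar_halfwidth <- 0.75
    for (b in seq_len(n_bands) - 1L) {
      in_band <- band_idx == b
      if (!any(in_band)) next
      if (immature[b + 1L]) {
        centre <- s_min + (b + 0.5) * band_px
        off_mask[in_band & abs(s_co - centre) <= bar_halfwidth] <- TRUE
      } else {
        tmod <- (t_co - phase[b + 1L]) %% spacing_px
        near <- pmin(tmod, spacing_px - tmod) <= bar_halfwidth
        # a half-pixel margin keeps bars from touching an off-target line
        # in an adjacent immature band
        s_rel <- (s_co - s_min) - b * band_px
        zline_mask[in_band & near & s_rel >= 0.5 & s_rel <= band_px - 0.5] <- TRUE
      }
    }
    if (spec$boundary_staining) {
      inset <- 6L
      ring <- (rr == inset | rr == n - inset | cc == inset | cc == n - inset) &
        rr >= inset & rr <= n - inset & cc >= inset & cc <= n - inset
      off_mask[ring] <- TRUE
    }

    actinin_clean <- 0.08 + 0.9 * (zline_mask | off_mask)

    blur <- function(m) if (spec$psf_sigma > 0) gauss_blur(m, spec$psf_sigma) else m
    actin_img <- gray_image(pmax(blur(actin_clean), 0), res, "actin")
    actinin_img <- gray_image(pmax(blur(actinin_clean), 0), res, "alpha_actinin")
    actin_img <- add_noise(actin_img, spec$poisson_gain, spec$gaussian_sigma,
                           seed = NULL)
    actinin_img <- add_noise(actinin_img, spec$poisson_gain,
                             spec$gaussian_sigma, seed = NULL)

    list(actin = actin_img, actinin = actinin_img,
         truth = list(zline = zline_mask, offtarget = off_mask,
                      spacing_px = spacing_px,
                      fibril_angle = spec$fibril_angle,
                      offtarget_fraction = spec$offtarget_fraction),
         spec = spec)
  })
}

#' Add microscope-like noise to an image
#'
#' Poisson shot noise (photon count at `poisson_gain` expected photons per
#' unit intensity, rescaled back) followed by additive Gaussian read noise,
#' clipped at zero. With both rates zero the image is returned unchanged.
#'
#' @param image a [gray_image()].
#' @param poisson_gain photons per unit intensity (0 disables).
#' @param gaussian_sigma read-noise standard deviation (0 disables).
#' @param seed RNG seed; `NULL` uses (and advances) the current RNG state,
#'   which is how [make_tissue_phantom()] calls it under its own seed.
#' @return a [gray_image()].
#' @export
add_noise <- function(image, poisson_gain = 200, gaussian_sigma = 0.01,
                      seed = NULL) {
  stopifnot(is_gray_image(image))
  if (poisson_gain < 0 || gaussian_sigma < 0) stop("noise rates must be >= 0")
  run <- function() {
    px <- image$pixels
    if (poisson_gain > 0)
      px <- matrix(stats::rpois(length(px), px * poisson_gain) / poisson_gain,
                   nrow(px), ncol(px))
    if (gaussian_sigma > 0)
      px <- px + matrix(stats::rnorm(length(px), 0, gaussian_sigma),
                        nrow(px), ncol(px))
    px[px < 0] <- 0
    gray_image(px, image$resolution, image$channel)
  }
  if (is.null(seed)) run() else with_rng_seed(seed, run())
}
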