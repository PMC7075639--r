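# Actin-guided segmentation: classify alpha-actinin skeleton pixels as
# z-lines (perpendicular to local actin) or off-target staining (parallel
# to local actin).

#' Local actin directors on a square grid
#'
#' Tiles the image into non-overlapping `grid_um` x `grid_um` micrometre
#' tiles anchored at the top-left corner (edge tiles may be partial) and
#' computes, per tile, the mean nematic tensor over the valid actin unit
#' vectors `r = (cos theta, sin theta)`:
#' `T = < 2 r r^T - I >`. The tile director is the eigenvector of the
#' maximum eigenvalue of T, canonicalized to `[0, pi)`. The default tile
#' edge of 5 um fits the z-lines of two sarcomeres in cardiomyocytes.
#'
#' @param actin_field an [orientation_field()] from the actin channel.
#' @param grid_um tile edge in micrometres (> 0), default 5.
#' @param resolution pixels per micrometre.
#' @return an object of class `director_grid` with per-tile director angle,
#'   maximum eigenvalue (in `[0, 1]`), populated flag (any valid actin
#'   pixels) and degenerate flag (isotropic tile, eigenvalue ~ 0).
#' @export
compute_director_grid <- function(actin_field, grid_um = 5, resolution = 6) {
  stopifnot(is_orientation_field(actin_field))
  if (grid_um <= 0) stop("`grid_um` must be > 0")
  dims <- dim(actin_field$theta)
  grid_px <- max(1L, as.integer(round(grid_um * resolution)))
  if (grid_px > max(dims)) {
    warning("grid larger than image: using a single grid tile")
    grid_px <- max(dims)
  }
  n_gr <- ceiling(dims[1] / grid_px)
  n_gc <- ceiling(dims[2] / grid_px)
  director <- matrix(NA_real_, n_gr, n_gc)
  eigmax <- matrix(NA_real_, n_gr, n_gc)
  populated <- matrix(FALSE, n_gr, n_gc)
  degenerate <- matrix(FALSE, n_gr, n_gc)
  for (gi in seq_len(n_gr)) {
    rs <- ((gi - 1L) * grid_px + 1L):min(gi * grid_px, dims[1])
    for (gj in seq_len(n_gc)) {
      cs <- ((gj - 1L) * grid_px + 1L):min(gj * grid_px, dims[2])
      th <- actin_field$theta[rs, cs]
      ok <- actin_field$valid[rs, cs]
      th <- th[ok]
      if (length(th) == 0L) next
      populated[gi, gj] <- TRUE
      # mean nematic tensor: T = [[<cos 2t>, <sin 2t>], [<sin 2t>, -<cos 2t>]]
      mc <- mean(cos(2 * th))
      ms <- mean(sin(2 * th))
      ev <- sqrt(mc^2 + ms^2)
      eigmax[gi, gj] <- ev
      if (ev < 1e-9) {
        degenerate[gi, gj] <- TRUE
      } else {
        director[gi, gj] <- canonical_angle(0.5 * atan2(ms, mc))
      }
    }
  }
  structure(list(grid_px = grid_px, director = director, eigmax = eigmax,
                 populated = populated, degenerate = degenerate,
                 dims = dims, resolution = resolution),
            class = "director_grid")
}

#' @export
print.director_grid <- function(x, ...) {
  cat(sprintf("<director_grid> %d x %d tiles of %d px, %d populated\n",
              nrow(x$director), ncol(x$director), x$grid_px,
              sum(x$populated)))
  invisible(x)
}

# Tile indices for pixel coordinates.
grid_tile_of <- function(rows, cols, grid_px) {
  cbind((rows - 1L) %/% grid_px + 1L, (cols - 1L) %/% grid_px + 1L)
}

#' Alignment score between an actin director and a z-line orientation
#'
#' `gamma = |cos(theta_actin - theta_zline)|`. The absolute value enforces
#' nematic symmetry: orientations are pseudo-vectors, so the sign of the
#' underlying dot product is arbitrary. Gamma is 1 for parallel and 0 for
#' perpendicular orientations.
#'
#' @param actin_director angle in radians.
#' @param zline_angle angle in radians.
#' @return scalar (vectorized) in `[0, 1]`.
#' @export
gamma_score <- function(actin_director, zline_angle) {
  if (any(!is.finite(actin_director)) || any(!is.finite(zline_angle)))
    stop("angles must be finite")
  abs(cos(actin_director - zline_angle))
}

#' Segment off-target staining from the alpha-actinin skeleton
#'
#' Each skeleton pixel is scored against the actin director of its grid
#' tile with [gamma_score()]. Pixels at least as parallel as the threshold
#' (`gamma >= gamma_threshold`) are classified off-target; the rest are
#' z-lines. Pixels in unpopulated or degenerate tiles, or without a valid
#' own orientation, are left unassigned and excluded from both counts.
#'
#' @param skeleton a [binary_skeleton()] of the alpha-actinin stain.
#' @param skel_field an [orientation_field()] giving each skeleton pixel's
#'   own orientation.
#' @param grid a `director_grid` from [compute_director_grid()].
#' @param gamma_threshold classification threshold, default 0.7.
#' @return an object of class `segmentation_result` with the z-line
#'   skeleton (provenance `"zline_only"`), the off-target and unassigned
#'   masks, the per-pixel gamma map, and the counts `n_alpha` (assigned
#'   skeleton pixels) and `n_z` (z-line pixels).
#' @export
segment_offtarget <- function(skeleton, skel_field, grid,
                              gamma_threshold = 0.7) {
  stopifnot(is_binary_skeleton(skeleton), is_orientation_field(skel_field),
            inherits(grid, "director_grid"))
  dims <- dim(skeleton$mask)
  if (!identical(dims, dim(skel_field$theta)))
    stop("skeleton and orientation field shapes disagree")
  if (!identical(dims, grid$dims))
    stop("skeleton and director grid shapes disagree")
  if (gamma_threshold < 0 || gamma_threshold > 1)
    stop("`gamma_threshold` must be in [0, 1]")

  zline <- matrix(FALSE, dims[1], dims[2])
  offtarget <- matrix(FALSE, dims[1], dims[2])
  unassigned <- matrix(FALSE, dims[1], dims[2])
  gamma_map <- matrix(NA_real_, dims[1], dims[2])

  idx <- which(skeleton$mask, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    tiles <- grid_tile_of(idx[, 1], idx[, 2], grid$grid_px)
    tile_lin <- cbind(tiles[, 1], tiles[, 2])
    own_theta <- skel_field$theta[idx]
    own_valid <- skel_field$valid[idx]
    dir_theta <- grid$director[tile_lin]
    usable <- own_valid & grid$populated[tile_lin] & !grid$degenerate[tile_lin]
    g <- rep(NA_real_, nrow(idx))
    g[usable] <- gamma_score(dir_theta[usable], own_theta[usable])
    gamma_map[idx[usable, , drop = FALSE]] <- g[usable]
    off <- usable & g >= gamma_threshold
    zl <- usable & g < gamma_threshold
    offtarget[idx[off, , drop = FALSE]] <- TRUE
    zline[idx[zl, , drop = FALSE]] <- TRUE
    unassigned[idx[!usable, , drop = FALSE]] <- TRUE
  }

  structure(list(
    zline_skeleton = binary_skeleton(zline, skeleton$resolution, "zline_only"),
    offtarget_mask = offtarget,
    unassigned_mask = unassigned,
    gamma_map = gamma_map,
    gamma_threshold = gamma_threshold,
    n_alpha = sum(zline) + sum(offtarget),
    n_z = sum(zline)),
    class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "<segmentation_result> n_alpha = %d, n_z = %d, off-target = %d, unassigned = %d\n",
    x$n_alpha, x$n_z, x$n_alpha - x$n_z, sum(x$unassigned_mask)))
  invisible(x)
}

#' Z-line fraction
#'
#' The fraction `N_z / N_alpha` of assigned alpha-actinin skeleton pixels
#' that survive actin-guided segmentation: 1 when every pixel is
#' approximately perpendicular to its local actin fibrils, 0 when none is.
#'
#' @param result a `segmentation_result`.
#' @return scalar in `[0, 1]`, or `NA` (with a warning) when no skeleton
#'   pixel could be assigned.
#' @export
zline_fraction <- function(result) {
  stopifnot(inherits(result, "segmentation_result"))
  if (result$n_alpha == 0) {
    warning("no assigned skeleton pixels: z-line fraction is undefined")
    return(NA_real_)
  }
  result$n_z / result$n_alpha
}
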