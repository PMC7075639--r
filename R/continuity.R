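# Continuous z-line detection: orientation-aware linking of skeleton
# pixels into simple paths, then length measurement.
#
# Compass directions are indexed k = 0..7 at angles k * pi/4 measured
# counter-clockwise from +x in the y-up frame, i.e. k = 0 is the right
# neighbor, k = 2 the upper neighbor. In raster (row, col) offsets:
compass_dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
compass_dc <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)

# Nearest compass index to an angle; ties round half-up for determinism.
nearest_compass <- function(angle) {
  as.integer(floor((angle %% (2 * pi)) / (pi / 4) + 0.5)) %% 8L
}

#' Candidate neighbors of a z-line pixel
#'
#' Of the eight neighbors of a pixel, the two lying in the compass
#' directions nearest to `theta + pi/2` and `theta - pi/2` (perpendicular
#' to the z-line) are excluded; the remaining (at most six, fewer at image
#' borders) are candidates for linking.
#'
#' @param pixel integer vector `c(row, col)`.
#' @param theta the pixel's nematic orientation in radians.
#' @param dims image dimensions `c(nrow, ncol)`; used to drop out-of-bounds
#'   neighbors. `NULL` keeps all.
#' @return matrix with columns row, col of candidate coordinates.
#' @export
candidate_neighbors <- function(pixel, theta, dims = NULL) {
  if (!is.finite(theta)) stop("`theta` must be a valid angle")
  keep <- setdiff(0:7, excluded_compass(theta))
  rr <- pixel[1] + compass_dr[keep + 1L]
  cc <- pixel[2] + compass_dc[keep + 1L]
  if (!is.null(dims)) {
    ok <- rr >= 1 & rr <= dims[1] & cc >= 1 & cc <= dims[2]
    rr <- rr[ok]; cc <- cc[ok]
  }
  cbind(row = rr, col = cc)
}

excluded_compass <- function(theta) {
  k <- nearest_compass(theta + pi / 2)
  c(k, (k + 4L) %% 8L)
}

#' Preferred-neighbor links between z-line skeleton pixels
#'
#' For each skeleton pixel the candidate neighbors (see
#' [candidate_neighbors()]) are split into two half-planes along the pixel's
#' own orientation (+theta and -theta sides). On each side the occupied
#' candidate whose orientation is most parallel to the pixel's own
#' (maximum `|cos(theta_self - theta_neighbor)|`) is preferred; ties are
#' broken in favour of the straighter geometric continuation (step
#' direction closest to the line direction) and then by lexicographic
#' coordinate. A link is retained only when the preference is mutual,
#' which guarantees maximum vertex degree 2 and hence simple paths.
#'
#' @param skeleton a [binary_skeleton()] (normally the z-line skeleton).
#' @param field an [orientation_field()] valid on the skeleton pixels.
#' @param min_cos optional angular floor: candidates with
#'   `|cos(delta theta)| < min_cos` are not linkable. The default 0 imposes
#'   no floor beyond the perpendicular-candidate exclusion.
#' @return a list with `pixels` (n x 2 coordinates, lexicographic order),
#'   `edges` (m x 2 pixel indices, each edge once), and `weights`
#'   (`|cos(delta theta)|` per edge).
#' @export
link_neighbors <- function(skeleton, field, min_cos = 0) {
  stopifnot(is_binary_skeleton(skeleton), is_orientation_field(field))
  if (!identical(dim(skeleton$mask), dim(field$theta)))
    stop("skeleton and orientation field shapes disagree")
  dims <- dim(skeleton$mask)
  idx <- which(skeleton$mask, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    ord <- order(idx[, 1], idx[, 2])
    idx <- idx[ord, , drop = FALSE]
  }
  n <- nrow(idx)
  out <- list(pixels = idx, edges = matrix(integer(0), 0, 2),
              weights = numeric(0))
  if (n == 0L) return(out)

  pix_id <- matrix(0L, dims[1], dims[2])
  pix_id[idx] <- seq_len(n)
  theta <- field$theta[idx]
  valid <- field$valid[idx]

  # pref[i, side]: index of the preferred neighbor of i on side 1 (+theta)
  # or side 2 (-theta); 0 = none.
  pref <- matrix(0L, n, 2)
  for (i in seq_len(n)) {
    if (!valid[i]) next
    th <- theta[i]
    excl <- excluded_compass(th)
    best_score <- c(-Inf, -Inf)
    best_straight <- c(-Inf, -Inf)
    for (k in setdiff(0:7, excl)) {
      r <- idx[i, 1] + compass_dr[k + 1L]
      c <- idx[i, 2] + compass_dc[k + 1L]
      if (r < 1 || r > dims[1] || c < 1 || c > dims[2]) next
      j <- pix_id[r, c]
      if (j == 0L || !valid[j]) next
      step_angle <- k * pi / 4
      side_dot <- cos(step_angle - th)
      side <- if (side_dot >= 0) 1L else 2L
      score <- abs(cos(th - theta[j]))
      if (score < min_cos) next
      straight <- abs(side_dot)
      better <- score > best_score[side] + 1e-12 ||
        (abs(score - best_score[side]) <= 1e-12 &&
           (straight > best_straight[side] + 1e-12 ||
              (abs(straight - best_straight[side]) <= 1e-12 &&
                 pref[i, side] != 0L && j < pref[i, side])))
      if (pref[i, side] == 0L || better) {
        pref[i, side] <- j
        best_score[side] <- score
        best_straight[side] <- straight
      }
    }
  }

  # mutual links only, each stored once (i < j)
  e_from <- integer(0); e_to <- integer(0)
  for (i in seq_len(n)) {
    for (s in 1:2) {
      j <- pref[i, s]
      if (j > i && any(pref[j, ] == i)) {
        e_from <- c(e_from, i)
        e_to <- c(e_to, j)
      }
    }
  }
  out$edges <- cbind(e_from, e_to)
  out$weights <- abs(cos(theta[e_from] - theta[e_to]))
  out
}

#' Group mutual links into continuous z-lines
#'
#' Connected chains under the mutual links of [link_neighbors()] become
#' continuous lines. Since vertex degree is at most 2, components are
#' simple paths or cycles; a cycle is broken at its weakest link (smallest
#' `|cos(delta theta)|`, ties by smallest pixel index). Each path is
#' ordered starting from its lexicographically smallest endpoint, so the
#' output is deterministic. Every skeleton pixel appears in exactly one
#' line (isolated pixels are single-pixel lines).
#'
#' @param links result of [link_neighbors()].
#' @param resolution pixels per micrometre.
#' @param image_id optional identifier carried into the line set.
#' @return an object of class `line_set`: a list of lines, each with an
#'   ordered `path` (n x 2), `pixel_count`, `geometric_length_px` and
#'   `length_um`.
#' @export
group_lines <- function(links, resolution = 6, image_id = NA_character_) {
  n <- nrow(links$pixels)
  lines <- list()
  if (n > 0L) {
    g <- igraph::make_empty_graph(n, directed = FALSE)
    if (nrow(links$edges) > 0)
      g <- igraph::add_edges(g, t(links$edges))
    # break cycles at the weakest link
    comp <- igraph::components(g)
    for (ci in seq_len(comp$no)) {
      verts <- which(comp$membership == ci)
      sub_edges <- which(links$edges[, 1] %in% verts)
      if (length(sub_edges) >= length(verts) && length(verts) > 2) {
        w <- links$weights[sub_edges]
        weakest <- sub_edges[order(w, links$edges[sub_edges, 1],
                                   links$edges[sub_edges, 2])][1]
        g <- igraph::delete_edges(
          g, igraph::get_edge_ids(g, links$edges[weakest, ]))
      }
    }
    comp <- igraph::components(g)
    deg <- igraph::degree(g)
    adj <- igraph::as_adj_list(g)
    for (ci in seq_len(comp$no)) {
      verts <- which(comp$membership == ci)
      if (length(verts) == 1L) {
        path_v <- verts
      } else {
        ends <- verts[deg[verts] <= 1]
        start <- ends[order(links$pixels[ends, 1], links$pixels[ends, 2])][1]
        path_v <- integer(length(verts))
        path_v[1] <- start
        prev <- 0L
        for (k in seq_len(length(verts) - 1L)) {
          nbs <- as.integer(adj[[path_v[k]]])
          nxt <- setdiff(nbs, prev)
          prev <- path_v[k]
          path_v[k + 1L] <- nxt[1]
        }
      }
      path <- links$pixels[path_v, , drop = FALSE]
      lines[[length(lines) + 1L]] <- new_continuous_line(path, resolution)
    }
    # deterministic order: by first path pixel
    firsts <- t(vapply(lines, function(l) l$path[1, ], numeric(2)))
    lines <- lines[order(firsts[, 1], firsts[, 2])]
  }
  structure(list(lines = lines, resolution = resolution,
                 image_id = image_id),
            class = "line_set")
}

new_continuous_line <- function(path, resolution) {
  path <- matrix(as.integer(path), ncol = 2,
                 dimnames = list(NULL, c("row", "col")))
  geom <- 0
  if (nrow(path) > 1) {
    d <- diff(path)
    geom <- sum(sqrt(d[, 1]^2 + d[, 2]^2))
  }
  structure(list(path = path, pixel_count = nrow(path),
                 geometric_length_px = geom,
                 length_um = geom / resolution),
            class = "continuous_line")
}

#' @export
print.line_set <- function(x, ...) {
  counts <- vapply(x$lines, `[[`, numeric(1), "pixel_count")
  cat(sprintf("<line_set> %d lines, %d pixels total\n",
              length(x$lines), sum(counts)))
  invisible(x)
}

#' Line length table
#'
#' @param lines a `line_set` from [group_lines()].
#' @return data.frame with `pixel_count`, `geometric_length_px` and
#'   `length_um` per line.
#' @export
line_lengths <- function(lines) {
  stopifnot(inherits(lines, "line_set"))
  data.frame(
    pixel_count = vapply(lines$lines, `[[`, numeric(1), "pixel_count"),
    geometric_length_px = vapply(lines$lines, `[[`, numeric(1),
                                 "geometric_length_px"),
    length_um = vapply(lines$lines, `[[`, numeric(1), "length_um"))
}

#' Median continuous z-line length
#'
#' Median of `length_um` over lines with at least `min_pixels` pixels.
#' The median (not the mean) summarizes the skewed length distribution
#' typical of striated myocytes.
#'
#' @param lines a `line_set`.
#' @param min_pixels minimum pixel count for a line to qualify (default 2).
#' @return scalar micrometres, or `NA` with a warning when no line
#'   qualifies.
#' @export
median_czl <- function(lines, min_pixels = 2) {
  tab <- line_lengths(lines)
  keep <- tab$pixel_count >= min_pixels
  if (!any(keep)) {
    warning("no lines with >= ", min_pixels, " pixels: median undefined")
    return(NA_real_)
  }
  stats::median(tab$length_um[keep])
}
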