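# Binary skeleton extraction: Zhang-Suen thinning, spur pruning,
# small-object removal. Thinning is hand-rolled because no installed
# package provides topology-preserving thinning.

# 8-connected component labels; 0 = background. Labels are assigned in
# order of each component's first (column-major) pixel, so the result is
# deterministic.
label_components <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  lab <- matrix(0L, nrow(mask), ncol(mask))
  n <- sum(mask)
  if (n == 0L) return(lab)
  vid <- matrix(0L, nrow(mask), ncol(mask))
  vid[mask] <- seq_len(n)
  edges <- integer(0)
  for (off in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    nb <- shift_mat(vid, off[1], off[2], pad = 0L)
    both <- mask & nb > 0L
    if (any(both)) edges <- c(edges, rbind(vid[both], nb[both]))
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges) > 0) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  # renumber by first occurrence
  comp <- match(comp, unique(comp))
  lab[mask] <- comp
  lab
}

# One pass of neighbor extraction: returns a list of 0/1 matrices P2..P9
# (clockwise from north) for the current mask.
zs_neighbors <- function(m) {
  list(
    p2 = shift_mat(m, -1L, 0L), p3 = shift_mat(m, -1L, 1L),
    p4 = shift_mat(m, 0L, 1L),  p5 = shift_mat(m, 1L, 1L),
    p6 = shift_mat(m, 1L, 0L),  p7 = shift_mat(m, 1L, -1L),
    p8 = shift_mat(m, 0L, -1L), p9 = shift_mat(m, -1L, -1L))
}

zs_transitions <- function(nb) {
  seq8 <- list(nb$p2, nb$p3, nb$p4, nb$p5, nb$p6, nb$p7, nb$p8, nb$p9, nb$p2)
  a <- 0
  for (k in 1:8) a <- a + (seq8[[k]] == 0) * (seq8[[k + 1]] == 1)
  a
}

# Zhang-Suen topology-preserving thinning to ~1-px width.
thin_mask <- function(mask) {
  m <- mask * 1
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      nb <- zs_neighbors(m)
      b <- nb$p2 + nb$p3 + nb$p4 + nb$p5 + nb$p6 + nb$p7 + nb$p8 + nb$p9
      a <- zs_transitions(nb)
      if (sub == 1) {
        cond <- m == 1 & b >= 2 & b <= 6 & a == 1 &
          (nb$p2 * nb$p4 * nb$p6 == 0) & (nb$p4 * nb$p6 * nb$p8 == 0)
      } else {
        cond <- m == 1 & b >= 2 & b <= 6 & a == 1 &
          (nb$p2 * nb$p4 * nb$p8 == 0) & (nb$p2 * nb$p6 * nb$p8 == 0)
      }
      if (any(cond)) {
        m[cond] <- 0
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1
}

# Remove residual 2x2 all-true blocks left by thinning, deleting only
# simple points (crossing number 1) so connectivity is preserved.
remove_square_blocks <- function(mask) {
  m <- mask
  repeat {
    blk <- m & shift_mat(m * 1, 0L, 1L) == 1 & shift_mat(m * 1, 1L, 0L) == 1 &
      shift_mat(m * 1, 1L, 1L) == 1
    idx <- which(blk, arr.ind = TRUE)
    if (nrow(idx) == 0L) break
    removed <- FALSE
    for (i in seq_len(nrow(idx))) {
      r <- idx[i, 1]; c <- idx[i, 2]
      for (pt in list(c(r, c), c(r, c + 1L), c(r + 1L, c), c(r + 1L, c + 1L))) {
        if (is_simple_point(m, pt[1], pt[2])) {
          m[pt[1], pt[2]] <- FALSE
          removed <- TRUE
          break
        }
      }
      if (removed) break
    }
    if (!removed) break  # degenerate; give up rather than loop forever
  }
  m
}

is_simple_point <- function(mask, r, c) {
  nr <- nrow(mask); nc <- ncol(mask)
  at <- function(rr, cc)
    if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) mask[rr, cc] else FALSE
  seq9 <- c(at(r - 1, c), at(r - 1, c + 1), at(r, c + 1), at(r + 1, c + 1),
            at(r + 1, c), at(r + 1, c - 1), at(r, c - 1), at(r - 1, c - 1))
  seq9 <- c(seq9, seq9[1])
  a <- sum(!seq9[-9] & seq9[-1])
  b <- sum(seq9[-9])
  a == 1 && b > 1
}

neighbor_count <- function(mask) {
  m <- mask * 1
  nb <- zs_neighbors(m)
  nb$p2 + nb$p3 + nb$p4 + nb$p5 + nb$p6 + nb$p7 + nb$p8 + nb$p9
}

# Remove spur branches shorter than min_spur_px: trace from each endpoint;
# if a branch point is reached within min_spur_px steps the traced pixels
# are deleted. Bare segments (endpoint-to-endpoint) are never pruned.
prune_spurs <- function(mask, min_spur_px) {
  if (min_spur_px <= 0) return(mask)
  m <- mask
  repeat {
    counts <- neighbor_count(m)
    endpoints <- which(m & counts == 1, arr.ind = TRUE)
    if (nrow(endpoints) == 0L) break
    changed <- FALSE
    offsets <- expand.grid(dr = -1:1, dc = -1:1)
    offsets <- offsets[!(offsets$dr == 0 & offsets$dc == 0), ]
    for (e in seq_len(nrow(endpoints))) {
      r <- endpoints[e, 1]; c <- endpoints[e, 2]
      if (!m[r, c] || neighbor_count_at(m, r, c) != 1) next
      path <- matrix(c(r, c), ncol = 2)
      prev <- c(NA_integer_, NA_integer_)
      cur <- c(r, c)
      is_spur <- FALSE
      # a spur is a dangling branch strictly shorter than min_spur_px
      # pixels terminating at a branch point
      while (nrow(path) < min_spur_px) {
        nbs <- find_true_neighbors(m, cur[1], cur[2], offsets)
        if (!any(is.na(prev)))
          nbs <- nbs[!(nbs[, 1] == prev[1] & nbs[, 2] == prev[2]), , drop = FALSE]
        if (nrow(nbs) == 0L) break            # bare segment end: keep
        nxt <- nbs[1, ]
        if (neighbor_count_at(m, nxt[1], nxt[2]) >= 3) {
          is_spur <- TRUE                     # reached a branch point
          break
        }
        prev <- cur
        cur <- nxt
        path <- rbind(path, cur)
      }
      if (is_spur) {
        m[path] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

neighbor_count_at <- function(mask, r, c) {
  nr <- nrow(mask); nc <- ncol(mask)
  rs <- max(1, r - 1):min(nr, r + 1)
  cs <- max(1, c - 1):min(nc, c + 1)
  sum(mask[rs, cs]) - mask[r, c]
}

find_true_neighbors <- function(mask, r, c, offsets) {
  rr <- r + offsets$dr; cc <- c + offsets$dc
  ok <- rr >= 1 & rr <= nrow(mask) & cc >= 1 & cc <= ncol(mask)
  rr <- rr[ok]; cc <- cc[ok]
  hit <- mask[cbind(rr, cc)]
  cbind(rr[hit], cc[hit])
}

#' Skeletonize a binary mask and trim it
#'
#' Thins the mask to one-pixel width with topology-preserving (Zhang-Suen)
#' thinning, removes residual 2x2 blocks, prunes spur branches shorter than
#' `min_spur_px`, and discards connected components smaller than
#' `min_object_px`.
#'
#' @param mask logical matrix.
#' @param min_spur_px spurs strictly shorter than this many pixels are
#'   removed (default 4).
#' @param min_object_px connected components with fewer pixels are removed
#'   (default 4).
#' @param resolution pixels per micrometre carried into the skeleton.
#' @return a [binary_skeleton()] with provenance `"raw_alpha_actinin"`.
#' @export
skeletonize_and_trim <- function(mask, min_spur_px = 4, min_object_px = 4,
                                 resolution = 6) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("`mask` must be a logical matrix")
  if (!any(mask)) {
    warning("empty mask: returning empty skeleton")
    return(binary_skeleton(mask, resolution, "raw_alpha_actinin"))
  }
  m <- thin_mask(mask)
  m <- remove_square_blocks(m)
  m <- prune_spurs(m, min_spur_px)
  # pruning can leave a redundant pixel where a spur met the line
  # diagonally; a final thinning pass cleans it without moving the line
  m <- thin_mask(m)
  if (min_object_px > 1 && any(m)) {
    lab <- label_components(m)
    sizes <- tabulate(lab[lab > 0])
    drop <- which(sizes < min_object_px)
    if (length(drop) > 0) m[lab %in% drop] <- FALSE
  }
  binary_skeleton(m, resolution, "raw_alpha_actinin")
}
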