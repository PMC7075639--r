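# Shared fixture builders and independent oracles used across test files.

# A vertical bright ridge of given width on a dark background.
ridge_image <- function(nr = 48, nc = 48, width = 3, value = 1) {
  m <- matrix(0, nr, nc)
  c0 <- floor(nc / 2)
  m[, c0:(c0 + width - 1)] <- value
  gray_image(m, resolution = 6)
}

# Parallel stripes at a given angle (degrees, y-up frame), rasterized from
# a sinusoidal profile so orientation is well-defined everywhere.
stripe_image <- function(angle_deg, nr = 64, nc = 64, period = 8) {
  a <- angle_deg * pi / 180
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  x <- cc; y <- -rr
  # intensity varies across the stripe direction
  s <- -x * sin(a) + y * cos(a)
  gray_image(0.5 + 0.5 * cos(2 * pi * s / period), resolution = 6)
}

# Brute-force reclassification oracle: recomputes the director per tile by
# direct summation and classifies each skeleton pixel independently.
brute_segment <- function(skeleton, skel_field, actin_field, grid_um,
                          resolution, gamma_threshold) {
  dims <- dim(skeleton$mask)
  grid_px <- max(1L, as.integer(round(grid_um * resolution)))
  if (grid_px > max(dims)) grid_px <- max(dims)
  zl <- matrix(FALSE, dims[1], dims[2])
  off <- matrix(FALSE, dims[1], dims[2])
  for (r in seq_len(dims[1])) {
    for (c in seq_len(dims[2])) {
      if (!skeleton$mask[r, c]) next
      if (!skel_field$valid[r, c]) next
      gi <- (r - 1) %/% grid_px
      gj <- (c - 1) %/% grid_px
      rs <- (gi * grid_px + 1):min((gi + 1) * grid_px, dims[1])
      cs <- (gj * grid_px + 1):min((gj + 1) * grid_px, dims[2])
      sxx <- 0; sxy <- 0; syy <- 0; n <- 0
      for (rr in rs) for (cc in cs) {
        if (!actin_field$valid[rr, cc]) next
        t <- actin_field$theta[rr, cc]
        sxx <- sxx + (2 * cos(t)^2 - 1)
        sxy <- sxy + 2 * cos(t) * sin(t)
        syy <- syy + (2 * sin(t)^2 - 1)
        n <- n + 1
      }
      if (n == 0) next
      txx <- sxx / n; txy <- sxy / n
      ev <- sqrt(txx^2 + txy^2)
      if (ev < 1e-9) next
      dir_th <- 0.5 * atan2(txy, txx)
      g <- abs(cos(dir_th - skel_field$theta[r, c]))
      if (g >= gamma_threshold) off[r, c] <- TRUE else zl[r, c] <- TRUE
    }
  }
  list(zline = zl, offtarget = off)
}

# Exhaustive mutual-link grouping oracle: naive per-pixel preference
# computation and connected components of the mutual-link graph.
brute_group <- function(skeleton, field) {
  dims <- dim(skeleton$mask)
  idx <- which(skeleton$mask, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  n <- nrow(idx)
  if (n == 0) return(list())
  id_of <- function(r, c) {
    w <- which(idx[, 1] == r & idx[, 2] == c)
    if (length(w) == 0) 0L else w
  }
  dr8 <- c(0, -1, -1, -1, 0, 1, 1, 1)
  dc8 <- c(1, 1, 0, -1, -1, -1, 0, 1)
  pref <- matrix(0L, n, 2)
  for (i in seq_len(n)) {
    th <- field$theta[idx[i, 1], idx[i, 2]]
    if (is.na(th)) next
    kex <- as.integer(floor(((th + pi / 2) %% (2 * pi)) / (pi / 4) + 0.5)) %% 8L
    kex <- c(kex, (kex + 4L) %% 8L)
    best <- c(-Inf, -Inf); best_st <- c(-Inf, -Inf)
    for (k in setdiff(0:7, kex)) {
      r <- idx[i, 1] + dr8[k + 1]; c <- idx[i, 2] + dc8[k + 1]
      if (r < 1 || r > dims[1] || c < 1 || c > dims[2]) next
      j <- id_of(r, c)
      if (j == 0L || !field$valid[r, c]) next
      sd <- cos(k * pi / 4 - th)
      side <- if (sd >= 0) 1L else 2L
      sc <- abs(cos(th - field$theta[r, c]))
      st <- abs(sd)
      take <- pref[i, side] == 0L || sc > best[side] + 1e-12 ||
        (abs(sc - best[side]) <= 1e-12 && st > best_st[side] + 1e-12) ||
        (abs(sc - best[side]) <= 1e-12 && abs(st - best_st[side]) <= 1e-12 &&
           j < pref[i, side])
      if (take) { pref[i, side] <- j; best[side] <- sc; best_st[side] <- st }
    }
  }
  edges <- matrix(integer(0), 0, 2)
  for (i in seq_len(n)) for (s in 1:2) {
    j <- pref[i, s]
    if (j > i && any(pref[j, ] == i)) edges <- rbind(edges, c(i, j))
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  split(seq_len(n), comp)
}

# Partition of pixel indices implied by a line_set, for comparison with
# the brute-force oracle (as sets of coordinate keys).
lineset_partition <- function(lines, dims) {
  lapply(lines$lines, function(l) sort((l$path[, 2] - 1) * dims[1] + l$path[, 1]))
}
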