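# Separable linear filtering with explicit boundary control.
#
# Filters are applied as banded-matrix products (A %*% M %*% t(B)), which
# keeps boundary handling exact and the whole operation vectorized. Two
# boundary policies are used in the package:
#   "replicate" - out-of-range taps accumulate on the nearest edge pixel
#                 (used for diffusion and Gaussian smoothing);
#   "truncate"  - out-of-range taps are dropped and the remaining weights
#                 renormalized (used for local means over a window).

band_matrix <- function(n, weights, boundary = c("replicate", "truncate")) {
  boundary <- match.arg(boundary)
  r <- (length(weights) - 1L) / 2L
  a <- matrix(0, n, n)
  idx <- seq_len(n)
  for (o in -r:r) {
    w <- weights[o + r + 1L]
    j <- idx + o
    if (boundary == "replicate") {
      j <- pmin(pmax(j, 1L), n)
      a[cbind(idx, j)] <- a[cbind(idx, j)] + w
    } else {
      ok <- j >= 1L & j <= n
      a[cbind(idx[ok], j[ok])] <- a[cbind(idx[ok], j[ok])] + w
    }
  }
  if (boundary == "truncate") a <- a / rowSums(a)
  a
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Gaussian blur of a plain matrix with replicate boundary.
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- gaussian_kernel_1d(sigma)
  a <- band_matrix(nrow(m), k, "replicate")
  b <- band_matrix(ncol(m), k, "replicate")
  a %*% m %*% t(b)
}

# Local mean over a square window, edge-truncated and renormalized.
box_mean <- function(m, window) {
  if (window %% 2 != 1 || window < 3)
    stop("window must be odd and >= 3")
  w <- rep(1, window)
  a <- band_matrix(nrow(m), w, "truncate")
  b <- band_matrix(ncol(m), w, "truncate")
  a %*% m %*% t(b)
}

# Box sum with replicate boundary (used for window-summed structure tensors).
box_sum_replicate <- function(m, window) {
  w <- rep(1, window)
  a <- band_matrix(nrow(m), w, "replicate")
  b <- band_matrix(ncol(m), w, "replicate")
  a %*% m %*% t(b)
}

# Central-difference derivatives with replicate boundary.
# d_col: derivative along columns (+x); d_row: derivative along rows (down).
d_col <- function(m) {
  nc <- ncol(m)
  left <- m[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  right <- m[, c(seq_len(nc)[-1L], nc), drop = FALSE]
  (right - left) / 2
}

d_row <- function(m) {
  nr <- nrow(m)
  up <- m[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  down <- m[c(seq_len(nr)[-1L], nr), , drop = FALSE]
  (down - up) / 2
}

# Shifted copy of a matrix: out[r, c] = m[r + dr, c + dc], padded with `pad`.
shift_mat <- function(m, dr, dc, pad = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(pad, nr, nc)
  rs <- max(1L, 1L - dr):min(nr, nr - dr)
  cs <- max(1L, 1L - dc):min(nc, nc - dc)
  if (length(rs) > 0 && length(cs) > 0)
    out[rs, cs] <- m[rs + dr, cs + dc]
  out
}
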