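# Parameter tuning against manually traced reference skeletons.

#' Tolerance-F1 similarity between two skeletons
#'
#' A pixel of one skeleton matches a pixel of the other when their
#' Chebyshev distance is at most `tol_px`; matches are one-to-one (maximum
#' bipartite matching, which makes the score symmetric) and
#' `S = 2 * matches / (|a| + |b|)`. Identical skeletons score 1; far-apart
#' skeletons score 0.
#'
#' @param a,b [binary_skeleton()] objects (or logical matrices) of the same
#'   shape.
#' @param tol_px match tolerance in pixels (default 1).
#' @return scalar in `[0, 1]`; two empty skeletons score 1 with a warning.
#' @export
skeleton_similarity <- function(a, b, tol_px = 1) {
  ma <- if (is_binary_skeleton(a)) a$mask else a
  mb <- if (is_binary_skeleton(b)) b$mask else b
  stopifnot(is.matrix(ma), is.matrix(mb), is.logical(ma), is.logical(mb))
  if (!identical(dim(ma), dim(mb))) stop("skeletons must have the same shape")
  na <- sum(ma); nb <- sum(mb)
  if (na == 0 && nb == 0) {
    warning("both skeletons empty: similarity defined as 1")
    return(1)
  }
  if (na == 0 || nb == 0) return(0)
  pa <- which(ma, arr.ind = TRUE)
  pb <- which(mb, arr.ind = TRUE)
  # index b pixels by coordinate for O(1) lookup
  key <- function(r, c) (r - 1) * ncol(ma) + c
  bid <- new.env(hash = TRUE)
  for (j in seq_len(nb))
    assign(as.character(key(pb[j, 1], pb[j, 2])), j, envir = bid)
  e_from <- integer(0); e_to <- integer(0)
  for (dr in -tol_px:tol_px) {
    for (dc in -tol_px:tol_px) {
      rr <- pa[, 1] + dr; cc <- pa[, 2] + dc
      ok <- rr >= 1 & rr <= nrow(ma) & cc >= 1 & cc <= ncol(ma)
      if (!any(ok)) next
      ks <- as.character(key(rr[ok], cc[ok]))
      hit <- vapply(ks, function(k) {
        v <- mget(k, envir = bid, ifnotfound = list(NA_integer_))[[1]]
        as.integer(v)
      }, integer(1))
      found <- !is.na(hit)
      e_from <- c(e_from, which(ok)[found])
      e_to <- c(e_to, hit[found])
    }
  }
  if (length(e_from) == 0L) return(0)
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, na), rep(TRUE, nb)),
    edges = as.vector(rbind(e_from, e_to + na)))
  m <- igraph::max_bipartite_match(g)
  2 * m$matching_size / (na + nb)
}

#' Parameter-selection error
#'
#' For a similarity matrix `S` (rows = images, columns = parameter sets),
#' the error of parameter set p is the mean squared shortfall from each
#' image's best similarity:
#' `E_p = (1/n) * sum_i (S[i, p] - max_p' S[i, p'])^2`.
#'
#' @param S numeric matrix of similarities in `[0, 1]`.
#' @return numeric vector `E`, one entry per parameter set; zero iff the
#'   set attains every image's maximum.
#' @export
parameter_error <- function(S) {
  if (!is.matrix(S) || nrow(S) < 1 || ncol(S) < 1)
    stop("S must be a matrix with at least one image and one parameter set")
  s_max <- apply(S, 1, max)
  colMeans((S - s_max)^2)
}

#' Grid search over preprocessing parameters
#'
#' Runs the alpha-actinin preprocessing chain for every row of
#' `parameter_grid`, scores the resulting skeletons against the reference
#' traces with [skeleton_similarity()], and returns the parameter set
#' minimizing [parameter_error()] (first row on ties, so the result is
#' deterministic for a fixed grid order).
#'
#' @param images list of [gray_image()] alpha-actinin micrographs.
#' @param reference_traces list of [binary_skeleton()] reference traces (or
#'   a list of lists for multiple tracers per image; similarities are then
#'   averaged at the S level).
#' @param parameter_grid data.frame whose columns override [zline_config()]
#'   fields (e.g. `diffusion_time`, `diffusion_rho`).
#' @param config base [zline_config()] supplying the non-searched values.
#' @param tol_px similarity tolerance.
#' @return list with `best` (named list of the winning parameters),
#'   `error` (vector E over the grid), and `similarity` (images x grid
#'   matrix).
#' @export
grid_search <- function(images, reference_traces, parameter_grid,
                        config = zline_config(), tol_px = 1) {
  if (!is.data.frame(parameter_grid) || nrow(parameter_grid) == 0)
    stop("`parameter_grid` must be a non-empty data.frame")
  if (length(images) != length(reference_traces))
    stop("one reference (or reference list) per image is required")
  n_img <- length(images)
  n_par <- nrow(parameter_grid)
  S <- matrix(NA_real_, n_img, n_par)
  for (p in seq_len(n_par)) {
    cfg <- config
    for (nm in names(parameter_grid))
      cfg[[nm]] <- parameter_grid[[nm]][p]
    for (i in seq_len(n_img)) {
      skel <- preprocess_actinin(images[[i]], cfg)$skeleton
      refs <- reference_traces[[i]]
      if (is_binary_skeleton(refs) || is.matrix(refs)) refs <- list(refs)
      sims <- vapply(refs, function(r)
        skeleton_similarity(skel, r, tol_px), numeric(1))
      S[i, p] <- mean(sims)
    }
  }
  E <- parameter_error(S)
  best_idx <- which.min(E)
  list(best = as.list(parameter_grid[best_idx, , drop = FALSE]),
       best_index = best_idx, error = E, similarity = S)
}
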