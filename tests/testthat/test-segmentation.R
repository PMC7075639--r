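# Actin-guided segmentation: director grids, gamma scores, off-target
# classification, z-line fraction.

test_that("director grid closed forms: aligned, cancelling, and tight angles", {
  th <- matrix(0, 30, 30)
  g <- compute_director_grid(orientation_field(th), grid_um = 5, resolution = 6)
  expect_true(all(g$populated))
  expect_equal(as.vector(g$director), rep(0, length(g$director)))
  expect_equal(as.vector(g$eigmax), rep(1, length(g$eigmax)))

  # half 0, half pi/2 in one tile: tensor cancels, director degenerate
  th2 <- matrix(0, 30, 30)
  th2[, 16:30] <- pi / 2
  g2 <- compute_director_grid(orientation_field(th2), grid_um = 5, resolution = 6)
  expect_true(all(abs(g2$eigmax) < 1e-12))
  expect_true(all(g2$degenerate))
  expect_true(all(is.na(g2$director)))

  # tight spread around pi/4
  set.seed(4)
  th3 <- matrix(pi / 4 + rnorm(900, 0, 0.01), 30, 30)
  g3 <- compute_director_grid(orientation_field(th3), grid_um = 5, resolution = 6)
  expect_lt(max(abs(g3$director - pi / 4)), 0.02)

  # oversized grid collapses to a single tile with warning
  expect_warning(
    g4 <- compute_director_grid(orientation_field(matrix(0, 20, 20)),
                                grid_um = 100, resolution = 6),
    "single")
  expect_equal(dim(g4$director), c(1L, 1L))
})

test_that("gamma score closed forms and nematic symmetry", {
  expect_equal(gamma_score(0, pi / 2), 0, tolerance = 1e-12)
  expect_equal(gamma_score(1.2, 1.2), 1)
  expect_equal(gamma_score(0, pi / 4), cos(pi / 4))
  # cos(pi/4) ~ 0.7071 >= 0.7, so a 45-degree pixel is off-target at default
  expect_gte(gamma_score(0, pi / 4), 0.7)
  # operand order and pi shifts are irrelevant
  expect_equal(gamma_score(0.3, 1.1), gamma_score(1.1, 0.3))
  expect_equal(gamma_score(0.3 + pi, 1.1), gamma_score(0.3, 1.1))
})

make_mixed_fixture <- function() {
  # 60 vertical (perpendicular to horizontal actin) + 40 horizontal pixels
  mask <- matrix(FALSE, 32, 64)
  th <- matrix(NA_real_, 32, 64)
  n_perp <- 0
  for (c0 in seq(3, 30, by = 3)) {     # vertical segments, 6 px each
    mask[5:10, c0] <- TRUE
    th[5:10, c0] <- pi / 2
    n_perp <- n_perp + 6
  }
  stopifnot(n_perp == 60)
  mask[20, 3:42] <- TRUE               # horizontal segment, 40 px
  th[20, 3:42] <- 0
  list(skeleton = binary_skeleton(mask), field = orientation_field(th))
}

test_that("segmentation separates perpendicular and parallel pixels with exact counts", {
  fx <- make_mixed_fixture()
  actin <- orientation_field(matrix(0, 32, 64))   # horizontal actin
  grid <- compute_director_grid(actin, 5, 6)
  seg <- segment_offtarget(fx$skeleton, fx$field, grid, 0.7)
  expect_equal(seg$n_z, 60L)
  expect_equal(seg$n_alpha - seg$n_z, 40L)
  expect_equal(zline_fraction(seg), 0.6)

  # all perpendicular kept; all parallel removed
  vert <- orientation_field(matrix(pi / 2, 32, 64))
  grid_v <- compute_director_grid(vert, 5, 6)
  seg_all <- segment_offtarget(fx$skeleton, fx$field, grid_v, 0.7)
  # actin vertical: vertical skeleton pixels now parallel -> off-target
  expect_equal(seg_all$n_z, 40L)
})

test_that("z-line fraction endpoints and undefined case", {
  fx <- make_mixed_fixture()
  actin <- orientation_field(matrix(0, 32, 64))
  grid <- compute_director_grid(actin, 5, 6)

  perp_field <- orientation_field(
    ifelse(fx$skeleton$mask, pi / 2, NA_real_))
  expect_equal(zline_fraction(
    segment_offtarget(fx$skeleton, perp_field, grid, 0.7)), 1)

  par_field <- orientation_field(ifelse(fx$skeleton$mask, 0, NA_real_))
  expect_equal(zline_fraction(
    segment_offtarget(fx$skeleton, par_field, grid, 0.7)), 0)

  empty <- binary_skeleton(matrix(FALSE, 32, 64))
  seg0 <- segment_offtarget(empty, perp_field, grid, 0.7)
  expect_warning(v <- zline_fraction(seg0), "undefined")
  expect_true(is.na(v))
})

test_that("boundary rule: gamma exactly at the threshold is off-target", {
  mask <- matrix(FALSE, 32, 32); mask[10:20, 16] <- TRUE
  th0 <- acos(0.7)                     # gamma against actin at 0 is exactly 0.7
  fld <- orientation_field(ifelse(mask, th0, NA_real_))
  grid <- compute_director_grid(orientation_field(matrix(0, 32, 32)), 5, 6)
  seg <- segment_offtarget(binary_skeleton(mask), fld, grid, 0.7)
  expect_equal(seg$n_z, 0L)
  expect_equal(seg$n_alpha, sum(mask))
})

test_that("lowering the gamma threshold never increases N_z", {
  set.seed(8)
  mask <- matrix(runif(48 * 48) < 0.15, 48, 48)
  fld <- orientation_field(ifelse(mask, runif(48 * 48, 0, pi), NA_real_))
  actin <- orientation_field(matrix(runif(48 * 48, 0, 0.3), 48, 48))
  grid <- compute_director_grid(actin, 5, 6)
  thresholds <- seq(0, 1, by = 0.1)
  nz <- vapply(thresholds, function(tt)
    segment_offtarget(binary_skeleton(mask), fld, grid, tt)$n_z, numeric(1))
  expect_true(all(diff(nz) >= 0))      # non-decreasing in the threshold
})

test_that("assigned pixels partition into z-line and off-target", {
  set.seed(9)
  mask <- matrix(runif(40 * 40) < 0.2, 40, 40)
  fld <- orientation_field(ifelse(mask & runif(1600) < 0.9,
                                  runif(1600, 0, pi), NA_real_))
  actin_th <- matrix(runif(1600, 0, pi), 40, 40)
  actin_valid <- matrix(runif(1600) < 0.8, 40, 40)
  actin <- orientation_field(ifelse(actin_valid, actin_th, NA_real_))
  grid <- compute_director_grid(actin, 5, 6)
  seg <- segment_offtarget(binary_skeleton(mask), fld, grid, 0.7)
  z <- seg$zline_skeleton$mask
  o <- seg$offtarget_mask
  u <- seg$unassigned_mask
  expect_false(any(z & o))
  expect_false(any(z & u))
  expect_false(any(o & u))
  expect_identical(z | o | u, mask)
  expect_equal(seg$n_z + sum(o), seg$n_alpha)
  expect_lte(seg$n_z, seg$n_alpha)
})

test_that("segmentation matches the brute-force per-pixel oracle on small images", {
  for (seed in c(3, 14)) {
    set.seed(seed)
    n <- 48
    mask <- matrix(runif(n * n) < 0.15, n, n)
    fld <- orientation_field(ifelse(mask, runif(n * n, 0, pi), NA_real_))
    actin_valid <- matrix(runif(n * n) < 0.7, n, n)
    actin <- orientation_field(
      ifelse(actin_valid, runif(n * n, 0, pi), NA_real_))
    grid <- compute_director_grid(actin, 5, 6)
    seg <- segment_offtarget(binary_skeleton(mask), fld, grid, 0.7)
    oracle <- brute_segment(binary_skeleton(mask), fld, actin, 5, 6, 0.7)
    expect_identical(seg$zline_skeleton$mask, oracle$zline)
    expect_identical(seg$offtarget_mask, oracle$offtarget)
  }
})

test_that("flipping all actin angles by pi leaves the segmentation unchanged", {
  fx <- make_mixed_fixture()
  th <- matrix(0.4, 32, 64)
  seg_a <- segment_offtarget(fx$skeleton, fx$field,
                             compute_director_grid(orientation_field(th), 5, 6), 0.7)
  seg_b <- segment_offtarget(fx$skeleton, fx$field,
                             compute_director_grid(orientation_field(th + pi), 5, 6), 0.7)
  expect_identical(seg_a$zline_skeleton$mask, seg_b$zline_skeleton$mask)
  expect_identical(seg_a$offtarget_mask, seg_b$offtarget_mask)
})

test_that("segmentation is idempotent on its own z-line output", {
  fx <- make_mixed_fixture()
  actin <- orientation_field(matrix(0, 32, 64))
  grid <- compute_director_grid(actin, 5, 6)
  seg1 <- segment_offtarget(fx$skeleton, fx$field, grid, 0.7)
  seg2 <- segment_offtarget(
    binary_skeleton(seg1$zline_skeleton$mask), fx$field, grid, 0.7)
  expect_identical(seg2$zline_skeleton$mask, seg1$zline_skeleton$mask)
  expect_equal(seg2$n_z, seg1$n_z)
})
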