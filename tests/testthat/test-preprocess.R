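# Preprocessing: diffusion, top-hat, background removal, thresholding,
# thinning, orientation estimation.

test_that("diffusion of a constant image is the constant, and time 0 is identity", {
  img <- gray_image(matrix(0.7, 32, 32))
  out <- diffuse(img, diffusion_params(time = 2))
  expect_equal(out$pixels, img$pixels)

  noisy <- gray_image(matrix(runif(32 * 32), 32, 32))
  expect_identical(diffuse(noisy, diffusion_params(time = 0))$pixels,
                   noisy$pixels)
})

test_that("diffusion rejects invalid inputs and unstable time steps", {
  expect_error(diffusion_params(dt = 0.5), "stable")
  expect_error(diffusion_params(time = -1))
  bad <- matrix(1, 20, 20); bad[3, 3] <- NaN
  expect_error(gray_image(bad), "non-finite")
})

test_that("diffusion is anisotropic: less cross-ridge blurring than the isotropic oracle", {
  img <- ridge_image(48, 48, width = 3)
  tt <- 3
  ced <- diffuse(img, diffusion_params(time = tt, rho = 3))
  iso <- zlinekit:::isotropic_diffuse(img, time = tt)
  # cross-ridge profile: column means; the ridge peak must survive better
  # under coherence-enhancing diffusion than under isotropic diffusion
  prof_ced <- colMeans(ced$pixels[10:38, ])
  prof_iso <- colMeans(iso$pixels[10:38, ])
  expect_gt(max(prof_ced), max(prof_iso))
  # and along-ridge variance must not grow
  mid <- floor(ncol(img$pixels) / 2)
  expect_lte(stats::var(ced$pixels[, mid]), stats::var(img$pixels[, mid]) + 1e-9)
})

test_that("white top-hat removes flat and ramp backgrounds, keeps thin ridges", {
  flat <- gray_image(matrix(0.4, 32, 32))
  expect_equal(tophat_enhance(flat, 3)$pixels, matrix(0, 32, 32))

  imp <- matrix(0, 32, 32); imp[16, 16] <- 10
  out <- tophat_enhance(gray_image(imp), 3)$pixels
  expect_equal(out[16, 16], 10)
  expect_equal(sum(out) - out[16, 16], 0)

  # ramp + thin ridge: ramp suppressed, ridge preserved within tolerance
  ramp <- matrix(rep(seq(0, 0.5, length.out = 64), each = 64), 64, 64)
  ridge <- matrix(0, 64, 64); ridge[, 31:33] <- 1
  out2 <- tophat_enhance(gray_image(ramp + ridge), 10)$pixels
  expect_gt(mean(out2[, 32]), 0.9)
  expect_lt(mean(out2[, c(1:20, 44:64)]), 0.05)

  expect_error(tophat_enhance(flat, 40), "larger")
})

test_that("background removal flattens smooth surfaces, preserves striations", {
  zero <- gray_image(matrix(0, 64, 64))
  expect_warning(out <- remove_background(zero, 16), "degenerate")
  expect_equal(out$pixels, matrix(0, 64, 64))

  plane <- outer(seq(0.2, 0.6, length.out = 64),
                 seq(0, 0.4, length.out = 64), `+`)
  resid <- remove_background(gray_image(plane), 16)$pixels
  expect_lt(max(resid), 0.1 * diff(range(plane)))

  stri <- matrix(0, 64, 64)
  stri[, seq(6, 60, by = 12)] <- 1
  both <- remove_background(gray_image(plane + stri), 16)$pixels
  peaks <- both[, seq(6, 60, by = 12)]
  raw_peaks <- (plane + stri)[, seq(6, 60, by = 12)] - plane[, seq(6, 60, by = 12)]
  expect_lt(max(abs(peaks - raw_peaks)) / max(raw_peaks), 0.10)
})

test_that("adaptive threshold matches a hand-computed local-mean oracle", {
  const <- gray_image(matrix(0.3, 16, 16))
  expect_false(any(binarize_adaptive(const, 3, offset = 0.01)))

  # checkerboard: compare against direct double-loop local means
  board <- matrix(0, 16, 16)
  board[(row(board) + col(board)) %% 2 == 0] <- 100
  got <- binarize_adaptive(gray_image(board), 3, offset = 0)
  want <- matrix(NA, 16, 16)
  for (r in 1:16) for (c in 1:16) {
    rs <- max(1, r - 1):min(16, r + 1)
    cs <- max(1, c - 1):min(16, c + 1)
    want[r, c] <- board[r, c] > mean(board[rs, cs])
  }
  expect_equal(got, want)

  line <- matrix(0, 20, 20); line[, 10] <- 1
  got2 <- binarize_adaptive(gray_image(line), 5, offset = 0.05)
  expect_true(all(got2[, 10]))
  expect_false(any(got2[, -10]))
})

test_that("thinning reduces a wide bar to a one-pixel line of similar length", {
  m <- matrix(FALSE, 30, 20)
  m[5:24, 9:11] <- TRUE
  sk <- skeletonize_and_trim(m, min_spur_px = 0, min_object_px = 0)
  expect_true(all(which(sk$mask, arr.ind = TRUE)[, 2] == 10))
  # thinning erodes up to half the bar width at each end
  expect_gte(sum(sk$mask), 16)
  expect_lte(sum(sk$mask), 22)
  # 1-px wide: no 2x2 all-true block
  blocks <- sk$mask[-nrow(sk$mask), -ncol(sk$mask)] &
    sk$mask[-1, -ncol(sk$mask)] & sk$mask[-nrow(sk$mask), -1] & sk$mask[-1, -1]
  expect_false(any(blocks))
})

test_that("trimming removes small objects and short spurs but keeps the main line", {
  sq <- matrix(FALSE, 16, 16); sq[8:9, 8:9] <- TRUE
  expect_equal(sum(skeletonize_and_trim(sq, 4, 5)$mask), 0)

  m <- matrix(FALSE, 20, 20)
  m[5:15, 10] <- TRUE          # main vertical line
  m[10, 11:12] <- TRUE         # 2-px spur off its middle
  sk <- skeletonize_and_trim(m, min_spur_px = 4, min_object_px = 4)
  expect_true(all(sk$mask[5:15, 10]))
  expect_false(any(sk$mask[, 11:12]))

  expect_warning(empty <- skeletonize_and_trim(matrix(FALSE, 8, 8), 4, 4),
                 "empty")
  expect_equal(sum(empty$mask), 0)
})

test_that("orientation estimation recovers stripe angles including 45 degrees", {
  f_v <- estimate_orientation(stripe_image(90))
  expect_lt(max(abs(f_v$theta[f_v$valid] - pi / 2)), 0.05)

  f_h <- estimate_orientation(stripe_image(0))
  th <- f_h$theta[f_h$valid]
  th <- pmin(th, pi - th)      # distance to 0 under nematic wrap
  expect_lt(max(th), 0.05)

  f_45 <- estimate_orientation(stripe_image(45))
  inner <- f_45$valid
  inner[c(1:8, 57:64), ] <- FALSE
  inner[, c(1:8, 57:64)] <- FALSE
  expect_lt(max(abs(f_45$theta[inner] - pi / 4)), 0.05)
})

test_that("flat windows are invalid, never NaN", {
  f <- estimate_orientation(gray_image(matrix(0.5, 24, 24)))
  expect_false(any(f$valid))
  expect_true(all(is.na(f$theta)))
})

test_that("rotating the input by 90 degrees rotates skeleton and orientations", {
  ph <- make_tissue_phantom(phantom_spec(size = 96, seed = 7))
  img <- ph$actinin
  cfg <- zline_config()
  a <- preprocess_actinin(img, cfg)
  # rotate raster 90 deg counter-clockwise: new[r, c] = old[c, N - r + 1]
  rot <- gray_image(t(img$pixels)[ncol(img$pixels):1, ], img$resolution,
                    img$channel)
  b <- preprocess_actinin(rot, cfg)
  rot_mask <- t(a$skeleton$mask)[ncol(a$skeleton$mask):1, ]
  # thinning picks a side on even-width ridges, so equivariance holds up
  # to one pixel of lateral ambiguity: compare with 1-px-tolerance F1
  sim <- skeleton_similarity(binary_skeleton(b$skeleton$mask),
                             binary_skeleton(rot_mask), tol_px = 1)
  expect_gte(sim, 0.95)
  # orientations rotate by pi/2 (nematic)
  ta <- t(a$field$theta)[ncol(a$field$theta):1, ]
  keep <- !is.na(ta) & b$field$valid
  dth <- abs(canonical_angle(b$field$theta[keep] - ta[keep] - pi / 2))
  dth <- pmin(dth, pi - dth)
  expect_lt(stats::median(dth), 1e-6)
})

test_that("the preprocessing pipeline is deterministic", {
  ph <- make_tissue_phantom(phantom_spec(size = 96, seed = 21))
  a <- preprocess_actinin(ph$actinin)
  b <- preprocess_actinin(ph$actinin)
  expect_identical(a$skeleton$mask, b$skeleton$mask)
  expect_identical(a$field$theta, b$field$theta)
})
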