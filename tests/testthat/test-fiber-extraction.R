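test_that("background subtraction is exact on constants, spikes and ramps", {
  expect_error(subtract_background(array(1, c(4, 4, 2))), "2D")

  const <- matrix(2.5, 40, 40)
  expect_equal(subtract_background(const), matrix(0, 40, 40),
               tolerance = 1e-12)

  # single bright pixel: output there is value - value / disc area
  img <- matrix(0, 61, 61); img[31, 31] <- 7
  out <- subtract_background(img, 10)
  area <- sum(outer(-10:10, -10:10, function(a, b) a^2 + b^2 <= 100))
  expect_equal(out[31, 31], 7 - 7 / area, tolerance = 1e-12)

  # affine ramp: disc mean preserves affine functions away from borders
  ramp <- outer(1:50, 1:50, function(i, j) 0.3 * i + 0.1 * j)
  outr <- subtract_background(ramp, 10)
  expect_lt(max(abs(outr[12:39, 12:39])), 1e-9)
})

test_that("disc local statistics match the brute-force double loop exactly", {
  set.seed(42)
  img <- matrix(runif(64 * 64), 64, 64)
  r <- 5
  fast_mean <- ecmorient:::local_mean(img, r)
  expect_equal(fast_mean, brute_disc_mean(img, r), tolerance = 1e-12)

  bg <- subtract_background(img, 10)
  expect_equal(bg, img - brute_disc_mean(img, 10), tolerance = 1e-12)

  mask <- rollingball_mask(img)
  expect_identical(unname(mask), unname(brute_rollingball(img, 5, 0.5)))
})

test_that("rolling-ball mask is empty on constants and flags a bright line", {
  expect_false(any(rollingball_mask(matrix(1, 32, 32))))

  img <- matrix(0, 64, 64)
  img[20:45, 32] <- 1
  mask <- rollingball_mask(img)
  expect_true(all(mask[25:40, 32]))
  expect_false(any(mask[1:10, 1:10]))
})

test_that("binary cleanup removes isolated pixels and bridges 1-px gaps", {
  m <- matrix(FALSE, 32, 32); m[16, 16] <- TRUE
  expect_false(any(clean_binary(m)))

  rect <- matrix(FALSE, 40, 40); rect[10:14, 5:34] <- TRUE
  expect_identical(clean_binary(rect), rect)

  broken <- matrix(FALSE, 40, 40)
  broken[5:18, 20] <- TRUE; broken[20:35, 20] <- TRUE  # gap at x = 19
  cleaned <- clean_binary(broken)
  expect_true(cleaned[19, 20])

  # oracle: explicit 3x3 dilation then erosion (background outside image)
  shift_or <- function(m, op) {
    nx <- nrow(m); ny <- ncol(m)
    p <- matrix(FALSE, nx + 2, ny + 2); p[2:(nx + 1), 2:(ny + 1)] <- m
    acc <- NULL
    for (dx in -1:1) for (dy in -1:1) {
      s <- p[(2 + dx):(nx + 1 + dx), (2 + dy):(ny + 1 + dy)]
      acc <- if (is.null(acc)) s else op(acc, s)
    }
    acc
  }
  oracle <- shift_or(shift_or(broken, `|`), `&`)
  expect_identical(cleaned[2:39, 2:39], oracle[2:39, 2:39])
})

test_that("component gating follows the >20 px and eccentricity >= 0.9 contracts", {
  # 1x25 horizontal line: one fiber, angle ~0, eccentricity ~1
  line <- matrix(FALSE, 60, 60); line[10:34, 30] <- TRUE
  f <- label_fibers(line)
  expect_identical(nrow(f), 1L)
  expect_identical(f$pixel_count, 25L)
  expect_lt(min(f$angle_deg, 180 - f$angle_deg), 1e-9)
  expect_gte(f$eccentricity, 0.999)

  # 4x4 square: 16 px, too small
  sq <- matrix(FALSE, 30, 30); sq[10:13, 10:13] <- TRUE
  expect_identical(nrow(label_fibers(sq)), 0L)

  # filled disk radius 5: big enough but isotropic
  dk <- disk_mask(40, c(20, 20), 5)
  expect_gt(sum(dk), 20)
  expect_identical(nrow(label_fibers(dk)), 0L)

  # exactly 20 px is rejected (strict >), 21 accepted
  l20 <- matrix(FALSE, 40, 40); l20[10:29, 5] <- TRUE
  expect_identical(nrow(label_fibers(l20)), 0L)
  l21 <- matrix(FALSE, 40, 40); l21[10:30, 5] <- TRUE
  expect_identical(nrow(label_fibers(l21)), 1L)
})

test_that("labeling uses 8-connectivity", {
  m <- matrix(FALSE, 40, 40)
  for (i in 0:24) m[8 + i, 8 + i] <- TRUE  # diagonal line, 25 px
  f <- label_fibers(m)
  expect_identical(nrow(f), 1L)
  expect_identical(f$pixel_count, 25L)
  expect_equal(f$angle_deg, 45, tolerance = 1e-9)
})

test_that("recovered angles track rendered fiber angles within 5 degrees", {
  for (ang in seq(0, 170, by = 10)) {
    sc <- render_single_fiber(ang, length_px = 32)
    fib <- extract_fibers(sc$image)
    expect_identical(nrow(fib), 1L)
    err <- abs(fib$angle_deg - ang) %% 180
    expect_lt(min(err, 180 - err), 5)
  }
})

test_that("extraction is rotation-consistent: rotating the image rotates angles", {
  p <- fiber_field_params(n_fibers = 25, image_size_px = c(300, 300),
                          pixel_size_um = 1, tumor_center_px = c(150, 150),
                          tumor_radius_um = 10, radial_bias_w0 = 0,
                          background_noise_sigma = 0, seed = 31)
  f <- generate_fiber_field(p)
  img <- render_reflection_image(f, p)
  fib <- extract_fibers(img)
  # rotate 90 deg: (x, y) -> (y, nx - 1 - x)
  rot <- t(img)[, nrow(img):1]
  fib_r <- extract_fibers(rot)
  expect_identical(nrow(fib_r), nrow(fib))
  a <- sort(fib$angle_deg)
  b <- sort((fib_r$angle_deg + 90) %% 180)
  d <- abs(a - b)
  expect_lt(max(pmin(d, 180 - d)), 2)
})

test_that("every extracted fiber satisfies the gating invariants", {
  p <- fiber_field_params(n_fibers = 400, image_size_px = c(512, 512),
                          pixel_size_um = 1, tumor_radius_um = 30,
                          radial_bias_w0 = 0.5, decay_length_um = 200,
                          seed = 17)
  fib <- extract_fibers(render_reflection_image(generate_fiber_field(p), p))
  expect_gt(nrow(fib), 0)
  expect_true(all(fib$pixel_count > 20))
  expect_true(all(fib$eccentricity >= 0.9))
  expect_true(all(fib$angle_deg >= 0 & fib$angle_deg < 180))
})
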