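fiber_row <- function(x, y, angle) {
  data.frame(centroid_x_px = x, centroid_y_px = y, angle_deg = angle)
}

test_that("orientation parameter hits its analytic anchor values", {
  ctr <- c(0, 0)
  expect_equal(fiber_orientation_parameter(fiber_row(300, 0, 0), ctr), 1)
  expect_equal(fiber_orientation_parameter(fiber_row(300, 0, 90), ctr), 0,
               tolerance = 1e-12)
  expect_equal(fiber_orientation_parameter(fiber_row(300, 0, 45), ctr), 0.5,
               tolerance = 1e-12)
  # radial direction at arbitrary position
  expect_equal(fiber_orientation_parameter(fiber_row(100, 100, 45), ctr), 1,
               tolerance = 1e-12)
  expect_error(fiber_orientation_parameter(fiber_row(0, 0, 10), ctr),
               "coincides")
})

test_that("orientation parameter is invariant to scene rotation and axis flip", {
  set.seed(8)
  n <- 200
  x <- runif(n, -400, 400); y <- runif(n, -400, 400)
  a <- runif(n, 0, 180)
  base <- fiber_orientation_parameter(fiber_row(x, y, a), c(0, 0))
  for (rot in c(30, 90, 135)) {
    th <- rot * pi / 180
    xr <- x * cos(th) - y * sin(th)
    yr <- x * sin(th) + y * cos(th)
    ar <- (a + rot) %% 180
    rotated <- fiber_orientation_parameter(fiber_row(xr, yr, ar), c(0, 0))
    expect_equal(rotated, base, tolerance = 1e-9)
  }
  flipped <- fiber_orientation_parameter(fiber_row(x, y, (a + 180) %% 180),
                                         c(0, 0))
  expect_equal(flipped, base, tolerance = 1e-12)
})

test_that("mean orientation parameter of uniform angles converges to 0.5", {
  set.seed(123)
  n <- 1e5
  r <- runif(n, 200, 3000)
  th <- runif(n, 0, 2 * pi)
  f <- fiber_row(r * cos(th), r * sin(th), runif(n, 0, 180))
  expect_lt(abs(mean(fiber_orientation_parameter(f, c(0, 0))) - 0.5), 0.005)
})

test_that("distance to edge is centroid distance minus radius", {
  f <- fiber_row(200, 0, 0)
  expect_equal(fiber_distance_to_edge(f, c(0, 0), 116, 1), 84)
  expect_equal(fiber_distance_to_edge(fiber_row(116, 0, 0), c(0, 0), 116, 1), 0)
  expect_lt(fiber_distance_to_edge(fiber_row(50, 0, 0), c(0, 0), 116, 1), 0)
  # pixel size conversion
  expect_equal(fiber_distance_to_edge(f, c(0, 0), 100, 0.67), 34)
})

test_that("bin_profile reproduces hand-computed means on a 6-fiber toy set", {
  f <- rbind(fiber_row(50, 0, 0),     # bin 1, op 1
             fiber_row(60, 0, 90),    # bin 1, op 0
             fiber_row(100, 0, 45),   # bin 2, op 0.5
             fiber_row(120, 0, 30),   # bin 2, op cos^2 30 = 0.75
             fiber_row(0, 150, 90),   # bin 3, op 1 (radial = 90 deg)
             fiber_row(0, 160, 0))    # bin 3, op 0
  prof <- bin_profile(f, c(0, 0), 0, 1)
  expect_identical(prof$n_fibers, c(2L, 2L, 2L))
  expect_equal(prof$mean_cos2, c(0.5, 0.625, 0.5), tolerance = 1e-12)
  expect_equal(prof$sd_cos2[1], sd(c(1, 0)), tolerance = 1e-12)
  expect_equal(prof$bin_lo_um, c(0, 67, 134))

  # fibers inside the spheroid are excluded; all-inside errors out
  f2 <- rbind(f, fiber_row(10, 0, 0))
  expect_identical(bin_profile(f2, c(0, 0), 20, 1)$n_fibers[1],
                   bin_profile(f, c(0, 0), 20, 1)$n_fibers[1])
  expect_error(bin_profile(fiber_row(10, 0, 0), c(0, 0), 50, 1), "empty")
})

test_that("exponential fit recovers its own model exactly and handles plateaus", {
  mid <- seq(33.5, 3000, by = 67)
  prof <- make_profile(mid, 0.5 + 0.4 * exp(-mid / 500))
  fit <- fit_exponential(prof)
  expect_true(fit$converged)
  expect_equal(fit$Y0, 0.9, tolerance = 1e-6)
  expect_equal(fit$L0, 500, tolerance = 1e-3)
  expect_equal(integrated_orientation(fit), 200, tolerance = 1e-3)

  flat <- make_profile(mid, rep(0.5, length(mid)))
  ffit <- fit_exponential(flat)
  expect_true(ffit$converged)
  expect_equal(ffit$Y0, 0.5, tolerance = 1e-6)
  expect_equal(integrated_orientation(ffit), 0, tolerance = 1e-6)

  short <- make_profile(c(120.5, 187.5), c(0.7, 0.6))
  sfit <- fit_exponential(short)
  expect_false(sfit$converged)
  expect_match(sfit$reason, "3 usable bins")
})

test_that("simulated biased fields recover Y0 and L0 within 10% over seeds", {
  res <- do.call(rbind, lapply(1:6, function(s)
    run_recovery_scene(0.8, 500, seed = 100 + s, route = "truth")))
  expect_true(all(res$converged))
  expect_lt(abs(median(res$Y0) - 0.9) / 0.9, 0.10)
  expect_lt(abs(median(res$L0) - 500) / 500, 0.10)
})

test_that("integrated orientation equals the closed form and the quadrature", {
  mid <- seq(33.5, 3000, by = 67)
  fit <- fit_exponential(make_profile(mid, 0.5 + 0.5 * exp(-mid / 100)))
  expect_equal(integrated_orientation(fit), (fit$Y0 - 0.5) * fit$L0)
  quad <- integrate(function(x) (fit$Y0 - 0.5) * exp(-x / fit$L0), 0, Inf,
                    rel.tol = 1e-10)$value
  expect_equal(integrated_orientation(fit), quad, tolerance = 1e-6)
  expect_equal((1.0 - 0.5) * 100, 50)
})

test_that("orientation extent is 0 for flat profiles and full-range when noiseless", {
  mid <- seq(33.5, 3000, by = 67)
  set.seed(2)
  flat <- make_profile(mid, 0.5 + rnorm(length(mid), 0, 0.01))
  ffit <- fit_exponential(flat)
  expect_identical(orientation_extent(flat, ffit), 0)

  strong <- make_profile(mid, 0.5 + 0.45 * exp(-mid / 800))
  sfit <- fit_exponential(strong)
  expect_gte(orientation_extent(strong, sfit), max(strong$bin_hi_um))
})

test_that("orientation extent grows with the radial bias strength", {
  extents <- vapply(c(0.25, 0.5, 0.75), function(w0) {
    p <- fiber_field_params(image_size_px = c(4500, 4500),
                            pixel_size_um = 1, tumor_radius_um = 100,
                            n_fibers = 20000, radial_bias_w0 = w0,
                            decay_length_um = 500, seed = 41)
    f <- generate_fiber_field(p)
    prof <- bin_profile(f, p$tumor_center_px, 100, 1)
    fit <- fit_exponential(prof, weights = "inverse_se")
    orientation_extent(prof, fit)
  }, numeric(1))
  expect_true(all(diff(extents) > 0))
})

test_that("oriented/random classification thresholds at mean + 1 sd", {
  ref <- c(0.52, 0.55, 0.48, 0.61, 0.50)  # toy reference set
  thr <- mean(ref) + sd(ref)
  expect_identical(as.character(classify_oriented(mean(ref), ref)), "random")
  expect_identical(as.character(classify_oriented(mean(ref) + 2 * sd(ref), ref)),
                   "oriented")
  expect_equal(attr(classify_oriented(0.9, ref), "threshold"), thr)
  expect_error(classify_oriented(0.6, c(0.5)), "at least 2")
  expect_error(classify_oriented(0.6, c(0.5, 0.5)), "degenerate")
})

test_that("group comparisons match brute-force oracles", {
  a <- c(1, 2, 3, 4)
  expect_equal(compare_groups(a, a, "distribution")$p_value, 1)

  x <- c(1.2, 3.4, 2.2, 5.0); y <- c(0.8, 2.9, 4.1, 1.1)
  res <- compare_groups(x, y, "distribution")
  expect_equal(res$statistic, brute_U(x, y))
  expect_equal(res$p_value, brute_U_pvalue(x, y), tolerance = 1e-12)

  # t statistic by hand (pooled-variance unpaired t)
  g1 <- c(2.1, 2.5, 1.9, 2.8); g2 <- c(3.0, 3.4, 2.9, 3.6)
  sp2 <- (3 * var(g1) + 3 * var(g2)) / 6
  t_hand <- (mean(g1) - mean(g2)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  rest <- compare_groups(g1, g2, "integrated")
  expect_equal(rest$statistic, t_hand, tolerance = 1e-12)
  expect_error(compare_groups(1, c(1, 2), "distribution"), "at least 2")
})

test_that("score correlation returns Pearson r and the linear fit", {
  set.seed(5)
  x <- runif(20); y <- 0.6 * x - 0.1 + rnorm(20, 0, 0.02)
  sc <- score_correlation(x, y)
  expect_equal(sc$pcc, cor(x, y))
  expect_equal(sc$slope, unname(coef(lm(y ~ x))[2]))
  expect_equal(sc$r_squared, cor(x, y)^2, tolerance = 1e-12)
})
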