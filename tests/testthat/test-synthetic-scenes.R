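test_that("fiber field parameter validation rejects invalid bias and decay", {
  expect_error(fiber_field_params(radial_bias_w0 = -0.1), "radial_bias_w0")
  expect_error(fiber_field_params(radial_bias_w0 = 1.2), "radial_bias_w0")
  expect_error(fiber_field_params(decay_length_um = 0), "decay_length_um")
  expect_error(fiber_field_params(decay_length_um = -5), "decay_length_um")
  # a tumor disk swallowing the whole image leaves nowhere to put fibers
  p <- fiber_field_params(n_fibers = 10, image_size_px = c(64, 64),
                          pixel_size_um = 1, tumor_radius_um = 500)
  expect_error(generate_fiber_field(p), "covers the entire image")
})

test_that("same seed gives bit-identical fields and images, different seeds differ", {
  p <- fiber_field_params(n_fibers = 200, image_size_px = c(256, 256),
                          tumor_radius_um = 20, seed = 11)
  f1 <- generate_fiber_field(p)
  f2 <- generate_fiber_field(p)
  expect_identical(f1, f2)
  expect_identical(render_reflection_image(f1, p),
                   render_reflection_image(f2, p))
  p2 <- fiber_field_params(n_fibers = 200, image_size_px = c(256, 256),
                           tumor_radius_um = 20, seed = 12)
  expect_false(identical(generate_fiber_field(p2), f1))
})

test_that("fiber centroids avoid the tumor disk and angles live in [0, 180)", {
  p <- fiber_field_params(n_fibers = 2000, image_size_px = c(512, 512),
                          pixel_size_um = 1, tumor_radius_um = 80, seed = 3)
  f <- generate_fiber_field(p)
  d_px <- sqrt((f$centroid_x_px - p$tumor_center_px[1])^2 +
                 (f$centroid_y_px - p$tumor_center_px[2])^2)
  expect_true(all(d_px > 80))
  expect_true(all(f$angle_deg >= 0 & f$angle_deg < 180))
  expect_true(all(f$distance_um >= 0))
})

test_that("unbiased field (w0 = 0) has mean orientation parameter 0.5 per bin", {
  p <- fiber_field_params(n_fibers = 50000, image_size_px = c(2000, 2000),
                          pixel_size_um = 1, tumor_radius_um = 100,
                          radial_bias_w0 = 0, seed = 5)
  f <- generate_fiber_field(p)
  prof <- bin_profile(f, p$tumor_center_px, p$tumor_radius_um,
                      p$pixel_size_um)
  ok <- prof$n_fibers >= 200
  se <- sqrt(1 / 12) / sqrt(prof$n_fibers[ok])  # var(cos^2) = 1/8... bounded by 1/12? use empirical sd
  se <- prof$sd_cos2[ok] / sqrt(prof$n_fibers[ok])
  expect_true(all(abs(prof$mean_cos2[ok] - 0.5) < 3.5 * se))
})

test_that("fully biased field (w0 = 1, huge decay, no wobble) is exactly radial", {
  p <- fiber_field_params(n_fibers = 1000, image_size_px = c(800, 800),
                          pixel_size_um = 1, tumor_radius_um = 50,
                          radial_bias_w0 = 1, decay_length_um = 1e9,
                          angular_noise_deg = 0, seed = 7)
  f <- generate_fiber_field(p)
  op <- fiber_orientation_parameter(f, p$tumor_center_px)
  expect_equal(op, rep(1, nrow(f)), tolerance = 1e-12)
})

test_that("binned mean cos2 of a biased field matches the closed form 0.5 + 0.5 w0 exp(-d/lambda)", {
  p <- fiber_field_params(n_fibers = 20000, image_size_px = c(4500, 4500),
                          pixel_size_um = 1, tumor_radius_um = 100,
                          radial_bias_w0 = 0.8, decay_length_um = 500,
                          seed = 13)
  f <- generate_fiber_field(p)
  # independent binning: straight tapply over hand-computed distances/cos2
  dx <- f$centroid_x_px - p$tumor_center_px[1]
  dy <- f$centroid_y_px - p$tumor_center_px[2]
  d <- sqrt(dx^2 + dy^2) - 100
  delta <- (atan2(dy, dx) * 180 / pi - f$angle_deg) %% 180
  delta <- pmin(delta, 180 - delta)
  cos2 <- cos(delta * pi / 180)^2
  bin <- floor(d / 67)
  for (b in 0:20) {
    sel <- bin == b
    if (sum(sel) < 100) next
    mid <- (b + 0.5) * 67
    expected <- 0.5 + 0.5 * 0.8 * exp(-mid / 500)
    se <- sd(cos2[sel]) / sqrt(sum(sel))
    # 3 MC standard errors plus the within-bin curvature of the exponential
    slack <- 3 * se + abs(expected - (0.5 + 0.4 * exp(-b * 67 / 500))) / 2
    expect_lt(abs(mean(cos2[sel]) - expected), max(slack, 0.02))
  }
  # package binning agrees with the independent one
  prof <- bin_profile(f, p$tumor_center_px, 100, 1)
  expect_equal(prof$mean_cos2[1], mean(cos2[bin == 0 & d >= 0]),
               tolerance = 1e-12)
})

test_that("rendering an empty fiber list gives a background-only image", {
  p <- fiber_field_params(n_fibers = 0, image_size_px = c(64, 64),
                          background_noise_sigma = 0, seed = 1)
  img <- render_reflection_image(generate_fiber_field(p), p)
  expect_identical(dim(img), c(64L, 64L))
  expect_true(all(img == 0))
})

test_that("a rendered single fiber is recovered with the right angle", {
  sc <- render_single_fiber(0, length_px = 30)
  fib <- extract_fibers(sc$image)
  expect_identical(nrow(fib), 1L)
  expect_lt(min(fib$angle_deg, 180 - fib$angle_deg), 5)
})

test_that("spheroid phantom honours rim width and is reproducible", {
  ph0 <- generate_spheroid_phantom(c(127, 127), 40, 0, c(256, 256), seed = 2)
  expect_identical(ph0$mask, disk_mask(256, c(127, 127), 40))
  ph1 <- generate_spheroid_phantom(c(127, 127), 40, 20, c(256, 256), seed = 2)
  expect_identical(ph1$mask, disk_mask(256, c(127, 127), 60))
  ph2 <- generate_spheroid_phantom(c(127, 127), 40, 20, c(256, 256), seed = 2)
  expect_identical(ph1$image, ph2$image)
  expect_true(all(ph1$image >= 0 & ph1$image <= 1))
})

test_that("nuclei stack generator returns the true count and respects separation", {
  nz <- generate_nuclei_stack(30, c(256, 256), 5, min_separation_px = 14,
                              seed = 21)
  expect_identical(nz$n_true, 30L)
  expect_identical(dim(nz$stack), c(256L, 256L, 5L))
  d <- as.matrix(dist(nz$centers_px)); diag(d) <- Inf
  expect_gte(min(d), 14)
})

test_that("endothelial mask generator controls angle and elongation", {
  expect_error(generate_endothelial_mask(30, 0.8), "elongation")
  m1 <- generate_endothelial_mask(0, 1)
  expect_equal(elongation(m1), 1, tolerance = 0.01)
  m2 <- generate_endothelial_mask(30, 2)
  ax <- mask_principal_axes(m2)
  expect_equal(ax$major_angle_deg, 30, tolerance = 1)
  expect_equal(elongation(m2), 2, tolerance = 0.04)
  # second-moment oracle: analytic ellipse moments give angle 30 exactly
  m3 <- generate_endothelial_mask(90, 3)
  ax3 <- mask_principal_axes(m3)
  expect_equal(ax3$major_angle_deg, 90, tolerance = 1)
})

test_that("fiber scenes round-trip through TIFF + CSV + JSON sidecar", {
  dir <- withr::local_tempdir()
  p <- fiber_field_params(n_fibers = 50, image_size_px = c(128, 128),
                          tumor_radius_um = 15, seed = 4)
  paths <- write_fiber_scene(dir, p)
  expect_true(all(file.exists(paths)))
  tab <- read.csv(paths[["fibers"]])
  expect_identical(nrow(tab), 50L)
  meta <- jsonlite::read_json(paths[["params"]], simplifyVector = TRUE)
  expect_identical(meta$seed, 4L)
  img <- EBImage::readImage(paths[["image"]])
  expect_identical(dim(img)[1:2], c(128L, 128L))
})
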