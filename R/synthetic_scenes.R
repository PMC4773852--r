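# Ground-truthed synthetic scenes: fiber fields with a radial orientation
# bias decaying exponentially with distance from the tumor edge, rendered
# reflection images, DIC-like spheroid phantoms, nuclei z-stacks, and
# elliptical endothelial masks.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Parameters of a synthetic collagen fiber field
#'
#' Bundles the geometry and statistics of a synthetic fiber scene.  The
#' generative law is a mixture: a fiber centred at distance `d` (micrometres)
#' from the tumor spheroid edge is exactly radial (plus optional angular
#' wobble) with probability `radial_bias_w0 * exp(-d / decay_length_um)` and
#' uniformly oriented otherwise, so that with zero wobble the expected
#' orientation parameter is `0.5 + 0.5 * w0 * exp(-d / lambda)` — the same
#' plateau-at-0.5 exponential form the analysis fits.
#'
#' @param image_size_px integer pair, image width and height in pixels.
#' @param pixel_size_um physical pixel size, micrometres per pixel.  The
#'   default 0.67 makes a 100-pixel distance bin equal 67 micrometres.
#' @param tumor_center_px tumor spheroid centre, 0-based pixel coordinates.
#'   May lie on the image border (e.g. a corner) to widen the distance range.
#' @param tumor_radius_um tumor spheroid radius in micrometres; fibers are
#'   never placed inside the spheroid disk.
#' @param n_fibers number of fibers to draw.
#' @param fiber_length_px_mean,fiber_length_px_sd mean and spread of fiber
#'   segment length in pixels (Gaussian, truncated below at 5 px).
#' @param radial_bias_w0 mixture weight of the radial component at the
#'   spheroid edge, in `[0, 1]`.
#' @param decay_length_um decay length of the radial bias, micrometres (> 0).
#' @param angular_noise_deg standard deviation of Gaussian wobble added to
#'   the radial direction of biased fibers, degrees.
#' @param background_noise_sigma standard deviation of additive Gaussian
#'   intensity noise in the rendered image.
#' @param render_blur_sigma optional Gaussian blur of the rendered image
#'   (pixels; 0 disables — segments are already anti-aliased).
#' @param seed integer seed of the scene's pseudo-random stream.
#' @return An object of class `fiber_field_params`.
#' @export
fiber_field_params <- function(image_size_px = c(2048, 2048),
                               pixel_size_um = 0.67,
                               tumor_center_px = (image_size_px - 1) / 2,
                               tumor_radius_um = 116,
                               n_fibers = 5000,
                               fiber_length_px_mean = 30,
                               fiber_length_px_sd = 5,
                               radial_bias_w0 = 0.5,
                               decay_length_um = 500,
                               angular_noise_deg = 0,
                               background_noise_sigma = 0.02,
                               render_blur_sigma = 0,
                               seed = 1L) {
  stopifnot(length(image_size_px) == 2, all(image_size_px >= 8))
  check_scalar(pixel_size_um, "pixel_size_um", 0, strict_lower = TRUE)
  check_scalar(tumor_radius_um, "tumor_radius_um", 0)
  check_scalar(n_fibers, "n_fibers", 0)
  check_scalar(radial_bias_w0, "radial_bias_w0", 0, 1)
  check_scalar(decay_length_um, "decay_length_um", 0, strict_lower = TRUE)
  check_scalar(angular_noise_deg, "angular_noise_deg", 0)
  check_scalar(background_noise_sigma, "background_noise_sigma", 0)
  p <- list(image_size_px = as.integer(image_size_px),
            pixel_size_um = pixel_size_um,
            tumor_center_px = as.numeric(tumor_center_px),
            tumor_radius_um = tumor_radius_um,
            n_fibers = as.integer(n_fibers),
            fiber_length_px_mean = fiber_length_px_mean,
            fiber_length_px_sd = fiber_length_px_sd,
            radial_bias_w0 = radial_bias_w0,
            decay_length_um = decay_length_um,
            angular_noise_deg = angular_noise_deg,
            background_noise_sigma = background_noise_sigma,
            render_blur_sigma = render_blur_sigma,
            seed = as.integer(seed))
  class(p) <- "fiber_field_params"
  p
}

#' Generate a ground-truth fiber field
#'
#' Draws fiber centroids uniformly over the image excluding the tumor disk
#' and assigns each fiber an orientation by the mixture law described in
#' [fiber_field_params()].  Deterministic given `params$seed`.
#'
#' @param params a [fiber_field_params()] object.
#' @return A data frame with one row per fiber: `centroid_x_px`,
#'   `centroid_y_px`, `angle_deg` (axis orientation in `[0, 180)`),
#'   `length_px`, `distance_um` (centroid distance to the tumor edge) and
#'   `is_radial` (mixture component indicator, for diagnostics).
#' @export
generate_fiber_field <- function(params) {
  stopifnot(inherits(params, "fiber_field_params"))
  p <- params
  n <- p$n_fibers
  if (n == 0)
    return(data.frame(centroid_x_px = numeric(0), centroid_y_px = numeric(0),
                      angle_deg = numeric(0), length_px = numeric(0),
                      distance_um = numeric(0), is_radial = logical(0)))
  nx <- p$image_size_px[1]; ny <- p$image_size_px[2]
  r_px <- p$tumor_radius_um / p$pixel_size_um
  cx <- p$tumor_center_px[1]; cy <- p$tumor_center_px[2]

  # the free area must exist: reject scenes whose tumor disk swallows the
  # whole image (otherwise rejection sampling cannot terminate)
  corners <- rbind(c(0, 0), c(nx - 1, 0), c(0, ny - 1), c(nx - 1, ny - 1))
  if (all((corners[, 1] - cx)^2 + (corners[, 2] - cy)^2 <= r_px^2))
    stop("tumor disk covers the entire image: no room for fibers")

  with_seed(p$seed, {
    xs <- numeric(0); ys <- numeric(0)
    attempts <- 0
    while (length(xs) < n) {
      m <- max(2L * (n - length(xs)), 128L)
      x <- runif(m, 0, nx - 1); y <- runif(m, 0, ny - 1)
      keep <- (x - cx)^2 + (y - cy)^2 > r_px^2
      xs <- c(xs, x[keep]); ys <- c(ys, y[keep])
      attempts <- attempts + m
      if (attempts > 1000 * n + 1e6)
        stop("tumor disk leaves too little free area to place fibers")
    }
    xs <- xs[seq_len(n)]; ys <- ys[seq_len(n)]

    d_um <- pmax(sqrt((xs - cx)^2 + (ys - cy)^2) * p$pixel_size_um -
                   p$tumor_radius_um, 0)
    radial_angle <- wrap_axial(atan2(ys - cy, xs - cx) * 180 / pi)
    p_radial <- p$radial_bias_w0 * exp(-d_um / p$decay_length_um)
    is_radial <- runif(n) < p_radial
    angle <- wrap_axial(runif(n, 0, 180))
    wobble <- if (p$angular_noise_deg > 0) rnorm(n, 0, p$angular_noise_deg)
              else 0
    angle[is_radial] <- wrap_axial(radial_angle + wobble)[is_radial]
    len <- pmax(rnorm(n, p$fiber_length_px_mean, p$fiber_length_px_sd), 5)
    data.frame(centroid_x_px = xs, centroid_y_px = ys, angle_deg = angle,
               length_px = len, distance_um = d_um, is_radial = is_radial)
  })
}

#' Render a reflection-microscopy-like image from a fiber field
#'
#' Draws each fiber as an anti-aliased bright line segment on a dark
#' background, optionally blurs, adds Gaussian noise and rescales to
#' `[0, 1]`.  Segments falling partly outside the image are clipped.
#'
#' @param fibers data frame from [generate_fiber_field()] (or any table with
#'   `centroid_x_px`, `centroid_y_px`, `angle_deg`, `length_px`).
#' @param params a [fiber_field_params()] object (image geometry, noise and
#'   seed).
#' @param thickness_px rendered fiber thickness in pixels.
#' @return Numeric matrix in `[0, 1]`, `[x, y]` layout.
#' @export
render_reflection_image <- function(fibers, params, thickness_px = 1) {
  stopifnot(inherits(params, "fiber_field_params"))
  nx <- params$image_size_px[1]; ny <- params$image_size_px[2]
  n <- nrow(fibers)
  img <- with_seed(params$seed + 1L, {
    if (n > 0) {
      th <- fibers$angle_deg * pi / 180
      hx <- cos(th) * fibers$length_px / 2
      hy <- sin(th) * fibers$length_px / 2
      amp <- runif(n, 0.75, 1)
      img <- cpp_draw_segments(nx, ny,
                               fibers$centroid_x_px - hx, fibers$centroid_y_px - hy,
                               fibers$centroid_x_px + hx, fibers$centroid_y_px + hy,
                               amp, thickness_px / 2)
      img[img > 1] <- 1
    } else {
      img <- matrix(0, nx, ny)
    }
    if (params$render_blur_sigma > 0)
      img <- EBImage::imageData(EBImage::gblur(img, params$render_blur_sigma))
    if (params$background_noise_sigma > 0)
      img <- img + rnorm(length(img), 0, params$background_noise_sigma)
    img
  })
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

#' Generate a DIC-like tumor spheroid phantom
#'
#' Builds a grayscale image with a dark spheroid core, a textured annulus
#' emulating migrating cells, and a smooth uneven background illumination,
#' together with the true combined (core + rim) mask.
#'
#' @param center_px spheroid centre, 0-based pixel coordinates.
#' @param core_radius_px core radius in pixels (> 0).
#' @param rim_width_px width of the textured migration rim in pixels (>= 0).
#' @param image_size_px integer pair, image size.
#' @param seed integer seed.
#' @return List with `image` (matrix in `[0, 1]`), `mask` (logical matrix,
#'   the true core + rim disk), `center_px`, `core_radius_px`,
#'   `rim_width_px`, `true_radius_px`.
#' @export
generate_spheroid_phantom <- function(center_px, core_radius_px,
                                      rim_width_px = 30,
                                      image_size_px = c(512, 512),
                                      seed = 1L) {
  check_scalar(core_radius_px, "core_radius_px", 0, strict_lower = TRUE)
  check_scalar(rim_width_px, "rim_width_px", 0)
  nx <- image_size_px[1]; ny <- image_size_px[2]
  xs <- matrix(0:(nx - 1), nx, ny)
  ys <- matrix(0:(ny - 1), nx, ny, byrow = TRUE)
  r <- sqrt((xs - center_px[1])^2 + (ys - center_px[2])^2)
  with_seed(seed, {
    # smooth illumination: gentle planar + quadratic field
    cf <- runif(5, -1, 1)
    gx <- (xs / nx - 0.5); gy <- (ys / ny - 0.5)
    illum <- 0.55 + 0.08 * (cf[1] * gx + cf[2] * gy + cf[3] * gx * gy +
                              cf[4] * gx^2 + cf[5] * gy^2)
    img <- illum + rnorm(nx * ny, 0, 0.01)
    core <- r <= core_radius_px
    img[core] <- 0.12 + 0.02 * runif(sum(core))
    rim <- r > core_radius_px & r <= core_radius_px + rim_width_px
    if (any(rim)) {
      # cell-scale granular texture: blob-sized (~5 px) dark/bright patches,
      # as migrating cells appear in DIC, not per-pixel white noise
      gran <- EBImage::imageData(
        EBImage::gblur(matrix(runif(nx * ny, -1, 1), nx, ny), 2.5))
      gran <- gran / sd(gran)
      img[rim] <- illum[rim] - 0.06 + 0.18 * gran[rim]
    }
    img[img < 0] <- 0; img[img > 1] <- 1
    list(image = img, mask = r <= core_radius_px + rim_width_px,
         center_px = as.numeric(center_px),
         core_radius_px = core_radius_px, rim_width_px = rim_width_px,
         true_radius_px = core_radius_px + rim_width_px)
  })
}

#' Generate a synthetic nuclei z-stack
#'
#' Places Gaussian-blob nuclei at random positions with a minimum centre
#' separation, spreading each blob's intensity over neighbouring z-planes.
#'
#' @param n_nuclei number of nuclei (>= 0).
#' @param image_size_px integer pair, plane size.
#' @param z_planes number of planes in the stack.
#' @param min_separation_px minimum centre-to-centre distance in pixels.
#' @param sigma_px in-plane Gaussian radius of a nucleus, pixels.
#' @param centers_px optional n x 2 matrix of explicit centres (overrides
#'   random placement; used e.g. to build touching pairs).
#' @param seed integer seed.
#' @return List with `stack` (array `[x, y, z]`), `n_true`, `centers_px`,
#'   `sigma_px`.
#' @export
generate_nuclei_stack <- function(n_nuclei, image_size_px = c(256, 256),
                                  z_planes = 5, min_separation_px = 12,
                                  sigma_px = 2.5, centers_px = NULL,
                                  seed = 1L) {
  check_scalar(n_nuclei, "n_nuclei", 0)
  nx <- image_size_px[1]; ny <- image_size_px[2]
  with_seed(seed, {
    if (is.null(centers_px)) {
      pts <- matrix(numeric(0), 0, 2)
      margin <- 4 * sigma_px
      tries <- 0
      while (nrow(pts) < n_nuclei && tries < 20000) {
        cand <- c(runif(1, margin, nx - 1 - margin),
                  runif(1, margin, ny - 1 - margin))
        if (nrow(pts) == 0 ||
            min(sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2)) >=
              min_separation_px)
          pts <- rbind(pts, cand)
        tries <- tries + 1
      }
      if (nrow(pts) < n_nuclei)
        stop("could not place nuclei at the requested separation")
    } else {
      pts <- as.matrix(centers_px)
      stopifnot(ncol(pts) == 2)
    }
    n <- nrow(pts)
    stack <- array(0, dim = c(nx, ny, z_planes))
    if (n > 0) {
      zc <- sample.int(z_planes, n, replace = TRUE)
      xs <- matrix(0:(nx - 1), nx, ny)
      ys <- matrix(0:(ny - 1), nx, ny, byrow = TRUE)
      for (i in seq_len(n)) {
        blob <- exp(-((xs - pts[i, 1])^2 + (ys - pts[i, 2])^2) /
                      (2 * sigma_px^2))
        for (z in seq_len(z_planes)) {
          wz <- exp(-(z - zc[i])^2 / 2)
          if (wz > 1e-3) stack[, , z] <- stack[, , z] + wz * blob
        }
      }
    }
    stack <- stack + array(abs(rnorm(length(stack), 0, 0.01)), dim(stack))
    list(stack = stack, n_true = n, centers_px = pts, sigma_px = sigma_px)
  })
}

#' Generate an elliptical endothelial spheroid mask
#'
#' Filled ellipse with the major axis at a controlled angle and a controlled
#' major/minor axis ratio, used as ground truth for the endothelial scoring
#' functions.
#'
#' @param angle_deg major-axis orientation, degrees in `[0, 180)`.
#' @param elongation major/minor axis ratio (>= 1).
#' @param image_size_px integer pair, mask image size.
#' @param semi_minor_px semi-minor axis length in pixels.
#' @param center_px ellipse centre (defaults to the image centre).
#' @return Logical matrix, `[x, y]` layout.
#' @export
generate_endothelial_mask <- function(angle_deg, elongation,
                                      image_size_px = c(201, 201),
                                      semi_minor_px = 20,
                                      center_px = (image_size_px - 1) / 2) {
  check_scalar(elongation, "elongation", 1)
  check_scalar(semi_minor_px, "semi_minor_px", 0, strict_lower = TRUE)
  nx <- image_size_px[1]; ny <- image_size_px[2]
  a <- elongation * semi_minor_px; b <- semi_minor_px
  th <- angle_deg * pi / 180
  xs <- matrix(0:(nx - 1), nx, ny) - center_px[1]
  ys <- matrix(0:(ny - 1), nx, ny, byrow = TRUE) - center_px[2]
  u <- xs * cos(th) + ys * sin(th)
  v <- -xs * sin(th) + ys * cos(th)
  (u / a)^2 + (v / b)^2 <= 1
}

#' Write a synthetic fiber scene to disk
#'
#' Writes the rendered reflection image as TIFF, the ground-truth fiber
#' table as CSV and the scene parameters as a JSON sidecar.
#'
#' @param dir output directory (created if needed).
#' @param params a [fiber_field_params()] object.
#' @param fibers,image optional precomputed field/rendering (generated from
#'   `params` if omitted).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_fiber_scene <- function(dir, params, fibers = NULL, image = NULL) {
  stopifnot(inherits(params, "fiber_field_params"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(fibers)) fibers <- generate_fiber_field(params)
  if (is.null(image)) image <- render_reflection_image(fibers, params)
  paths <- c(image = file.path(dir, "reflection.tif"),
             fibers = file.path(dir, "fibers_truth.csv"),
             params = file.path(dir, "scene_params.json"))
  EBImage::writeImage(EBImage::Image(image), paths[["image"]], type = "tiff",
                      bits.per.sample = 16L)
  write.csv(fibers[, c("centroid_x_px", "centroid_y_px", "angle_deg",
                       "length_px")],
            paths[["fibers"]], row.names = FALSE)
  jsonlite::write_json(unclass(params), paths[["params"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
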