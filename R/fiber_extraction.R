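# Fibrillar structure detection in reflection-microscopy images: background
# subtraction, squared-intensity local thresholding ("rolling ball"), binary
# cleanup, and component labeling with size/eccentricity gating.

#' Fiber extraction parameters
#'
#' @param background_radius_px radius of the circular averaging filter used
#'   to estimate the background (default 10 px).
#' @param local_window_px radius of the local neighbourhood over which the
#'   squared-intensity mean and standard deviation are computed (default 5
#'   px).
#' @param local_threshold_sd number of local standard deviations above the
#'   local mean squared intensity at which a pixel is assigned to a fiber
#'   (default 0.5; strict inequality).
#' @param min_pixels minimum component size; components must exceed this
#'   strictly (default 20).
#' @param min_eccentricity minimum equivalent-ellipse eccentricity,
#'   inclusive (default 0.9).
#' @param window_shape `"disc"` (circular neighbourhood, default) or
#'   `"square"` for the local statistics window.
#' @param sd_normalization `"population"` (divide by n, default) or
#'   `"sample"` (divide by n - 1) for the local standard deviation.
#' @return An object of class `extraction_params`.
#' @export
extraction_params <- function(background_radius_px = 10,
                              local_window_px = 5,
                              local_threshold_sd = 0.5,
                              min_pixels = 20,
                              min_eccentricity = 0.9,
                              window_shape = c("disc", "square"),
                              sd_normalization = c("population", "sample")) {
  check_scalar(background_radius_px, "background_radius_px", 0,
               strict_lower = TRUE)
  check_scalar(local_window_px, "local_window_px", 0, strict_lower = TRUE)
  check_scalar(local_threshold_sd, "local_threshold_sd", 0)
  check_scalar(min_pixels, "min_pixels", 0, strict_lower = TRUE)
  check_scalar(min_eccentricity, "min_eccentricity", 0, 1)
  p <- list(background_radius_px = as.integer(background_radius_px),
            local_window_px = as.integer(local_window_px),
            local_threshold_sd = local_threshold_sd,
            min_pixels = min_pixels,
            min_eccentricity = min_eccentricity,
            window_shape = match.arg(window_shape),
            sd_normalization = match.arg(sd_normalization))
  class(p) <- "extraction_params"
  p
}

# Local mean over the configured neighbourhood, reflective padding.
local_mean <- function(image, radius, shape = "disc") {
  if (shape == "disc") {
    cpp_disc_local_sum(image, radius) / cpp_disc_area(radius)
  } else {
    k <- matrix(1, 2 * radius + 1, 2 * radius + 1)
    EBImage::imageData(EBImage::filter2(image, k / sum(k),
                                        boundary = "replicate"))
  }
}

#' Subtract the locally averaged background from an image
#'
#' Estimates the background as a circular averaging filter of the original
#' image (radius `radius_px`) and subtracts it.  The result may be negative.
#'
#' @param image 2D grayscale matrix (`[x, y]` layout).
#' @param radius_px averaging-disk radius, pixels.
#' @return Matrix of the same size.
#' @export
subtract_background <- function(image, radius_px = 10) {
  image <- as_image_matrix(image)
  image - local_mean(image, as.integer(radius_px), "disc")
}

#' Rolling-ball squared-intensity local threshold
#'
#' Multiplies the signal by itself and flags pixels whose squared intensity
#' strictly exceeds the local mean squared intensity plus
#' `local_threshold_sd` local standard deviations, computed over a
#' neighbourhood of radius `local_window_px` around each pixel.
#'
#' @param image background-subtracted grayscale matrix.
#' @param params an [extraction_params()] object.
#' @return Logical matrix (foreground = fiber candidate).
#' @export
rollingball_mask <- function(image, params = extraction_params()) {
  image <- as_image_matrix(image)
  sq <- image * image
  r <- params$local_window_px
  m <- local_mean(sq, r, params$window_shape)
  m2 <- local_mean(sq * sq, r, params$window_shape)
  v <- pmax(m2 - m * m, 0)
  if (params$sd_normalization == "sample") {
    n <- if (params$window_shape == "disc") cpp_disc_area(r) else
      (2 * r + 1)^2
    v <- v * n / (n - 1)
  }
  sq > m + params$local_threshold_sd * sqrt(v)
}

#' Remove isolated pixels and close small gaps in a binary mask
#'
#' Deletes foreground pixels with no 8-connected foreground neighbour, then
#' applies a morphological closing with a 3x3 square structuring element.
#'
#' @param mask logical matrix.
#' @return Logical matrix.
#' @export
clean_binary <- function(mask) {
  m <- as_binary_matrix(mask)
  nx <- nrow(m); ny <- ncol(m)
  # 8-neighbour foreground count via shifted sums (zero padding: neighbours
  # outside the image do not exist)
  p <- matrix(0, nx + 2, ny + 2)
  p[2:(nx + 1), 2:(ny + 1)] <- m
  nb <- matrix(0, nx, ny)
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    nb <- nb + p[(2 + dx):(nx + 1 + dx), (2 + dy):(ny + 1 + dy)]
  }
  m[nb == 0] <- FALSE
  closed <- EBImage::closing(EBImage::Image(m * 1),
                             EBImage::makeBrush(3, "box"))
  EBImage::imageData(closed) > 0
}

# Per-component second-moment summaries for a label matrix.
label_moments <- function(labels) {
  idx <- which(labels > 0)
  if (length(idx) == 0)
    return(data.frame(label = integer(0), n = integer(0),
                      cx = numeric(0), cy = numeric(0),
                      mu20 = numeric(0), mu02 = numeric(0),
                      mu11 = numeric(0)))
  nx <- nrow(labels)
  lab <- labels[idx]
  xs <- (idx - 1) %% nx
  ys <- (idx - 1) %/% nx
  s <- rowsum(cbind(1, xs, ys, xs * xs, ys * ys, xs * ys), lab)
  n <- s[, 1]
  cx <- s[, 2] / n; cy <- s[, 3] / n
  data.frame(label = as.integer(rownames(s)), n = as.integer(n),
             cx = cx, cy = cy,
             mu20 = s[, 4] / n - cx^2,
             mu02 = s[, 5] / n - cy^2,
             mu11 = s[, 6] / n - cx * cy)
}

moments_to_shape <- function(mom) {
  tr <- mom$mu20 + mom$mu02
  gap <- sqrt(((mom$mu20 - mom$mu02) / 2)^2 + mom$mu11^2)
  l1 <- tr / 2 + gap
  l2 <- pmax(tr / 2 - gap, 0)
  angle <- wrap_axial(0.5 * atan2(2 * mom$mu11, mom$mu20 - mom$mu02) *
                        180 / pi)
  angle[gap < .Machine$double.eps] <- 0
  ecc <- ifelse(l1 <= 0, 0, sqrt(pmax(0, 1 - l2 / l1)))
  data.frame(angle_deg = angle, eccentricity = ecc,
             lambda1 = l1, lambda2 = l2)
}

#' Label fiber components in a cleaned binary mask
#'
#' Finds 8-connected components and keeps those with strictly more than
#' `min_pixels` pixels and equivalent-ellipse eccentricity of at least
#' `min_eccentricity`.
#'
#' @param mask cleaned logical matrix.
#' @param params an [extraction_params()] object.
#' @return A `fiber_table` data frame: `centroid_x_px`, `centroid_y_px`,
#'   `angle_deg` in `[0, 180)`, `pixel_count`, `eccentricity`.  Empty mask
#'   gives an empty table.
#' @export
label_fibers <- function(mask, params = extraction_params()) {
  m <- as_binary_matrix(mask)
  labels <- cpp_label8(m)
  mom <- label_moments(labels)
  shape <- moments_to_shape(mom)
  keep <- mom$n > params$min_pixels &
    shape$eccentricity >= params$min_eccentricity
  out <- data.frame(centroid_x_px = mom$cx[keep],
                    centroid_y_px = mom$cy[keep],
                    angle_deg = shape$angle_deg[keep],
                    pixel_count = mom$n[keep],
                    eccentricity = shape$eccentricity[keep])
  stopifnot(all(out$pixel_count > params$min_pixels),
            all(out$eccentricity >= params$min_eccentricity),
            all(out$angle_deg >= 0 & out$angle_deg < 180))
  class(out) <- c("fiber_table", "data.frame")
  out
}

#' Extract fibers from a reflection image
#'
#' Full chain: background subtraction, squared-intensity local thresholding,
#' binary cleanup, component labeling and size/eccentricity gating.
#'
#' @param image grayscale reflection image (`[x, y]` matrix or EBImage
#'   `Image`).
#' @param params an [extraction_params()] object.
#' @return A `fiber_table` data frame (see [label_fibers()]).
#' @export
extract_fibers <- function(image, params = extraction_params()) {
  bg <- subtract_background(image, params$background_radius_px)
  mask <- rollingball_mask(bg, params)
  label_fibers(clean_binary(mask), params)
}
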