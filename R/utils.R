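# Internal helpers shared across modules.

# Coerce an image-like object (matrix or single-frame EBImage Image) to a
# plain numeric matrix in [x, y] layout.
as_image_matrix <- function(image, arg = "image") {
  if (inherits(image, "Image")) image <- EBImage::imageData(image)
  if (is.array(image) && length(dim(image)) > 2) {
    if (all(dim(image)[-(1:2)] == 1)) {
      dim(image) <- dim(image)[1:2]
    } else {
      stop(sprintf("`%s` must be a single 2D grayscale plane", arg))
    }
  }
  if (!is.matrix(image) || !is.numeric(image))
    stop(sprintf("`%s` must be a 2D numeric matrix", arg))
  if (!all(is.finite(image)))
    stop(sprintf("`%s` contains non-finite values", arg))
  image
}

as_binary_matrix <- function(mask, arg = "mask") {
  if (inherits(mask, "Image")) mask <- EBImage::imageData(mask)
  if (is.logical(mask)) {
    stopifnot(is.matrix(mask))
    return(mask)
  }
  mask <- as_image_matrix(mask, arg)
  mask > 0
}

# Wrap an axial (headless) angle into [0, 180).
wrap_axial <- function(angle_deg) {
  a <- angle_deg %% 180
  a[a < 0] <- a[a < 0] + 180
  a
}

# Acute angle in [0, 90] between two axial directions given in degrees.
acute_axial_diff <- function(a_deg, b_deg) {
  d <- abs(a_deg - b_deg) %% 180
  pmin(d, 180 - d)
}

# Second-moment summary of a pixel set given 0-based centre coordinates.
# Returns centroid, central second moments, principal angle (deg in
# [0, 180)), equivalent-ellipse axis lengths and eccentricity, following
# regionprops semantics (major_axis = 4 * sqrt(largest eigenvalue)).
pixel_moments <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 1)
  cx <- mean(x); cy <- mean(y)
  dx <- x - cx; dy <- y - cy
  mu20 <- mean(dx * dx)
  mu02 <- mean(dy * dy)
  mu11 <- mean(dx * dy)
  tr <- mu20 + mu02
  det_gap <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- tr / 2 + det_gap
  l2 <- tr / 2 - det_gap
  l2 <- max(l2, 0)
  angle <- if (det_gap < .Machine$double.eps) 0 else
    wrap_axial(0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi)
  ecc <- if (l1 <= 0) 0 else sqrt(max(0, 1 - l2 / l1))
  list(centroid = c(cx, cy), n = n,
       mu20 = mu20, mu02 = mu02, mu11 = mu11,
       lambda1 = l1, lambda2 = l2,
       major_axis = 4 * sqrt(l1), minor_axis = 4 * sqrt(l2),
       angle_deg = angle, eccentricity = ecc)
}

# Moments for a binary mask (0-based pixel-centre coordinates).
mask_moments <- function(mask) {
  m <- as_binary_matrix(mask)
  idx <- which(m)
  if (length(idx) == 0) stop("mask is empty")
  nx <- nrow(m)
  xs <- (idx - 1) %% nx
  ys <- (idx - 1) %/% nx
  pixel_moments(xs, ys)
}

check_scalar <- function(x, arg, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", arg))
  if (strict_lower && x <= lower)
    stop(sprintf("`%s` must be > %g", arg, lower))
  if (!strict_lower && x < lower)
    stop(sprintf("`%s` must be >= %g", arg, lower))
  if (x > upper)
    stop(sprintf("`%s` must be <= %g", arg, upper))
  invisible(x)
}
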