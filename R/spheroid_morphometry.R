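# Tumor spheroid segmentation from DIC-like images (illumination
# normalization, dark-core thresholding, Canny rim masking), morphometrics,
# and nuclei counting from z-stacks.

#' Normalize a DIC image to its background illumination
#'
#' Runs a large median filter over the image to estimate the smooth
#' background illumination and divides the original by it.  The result is
#' close to 1 in background areas regardless of uneven illumination.
#'
#' @param image 2D grayscale matrix with values in `[0, 1]` (rescaled if
#'   outside).
#' @param median_radius_px median filter radius, pixels.  Must exceed the
#'   spheroid radius so that the spheroid itself is not absorbed into the
#'   background estimate; the default 200 covers spheroids up to ~180 px.
#' @param downsample integer factor; radii above 20 px are computed on a
#'   downsampled copy and upsampled back (the background is smooth by
#'   construction), keeping the large-kernel median cheap.
#' @return Numeric matrix, finite everywhere.
#' @export
normalize_dic <- function(image, median_radius_px = 200, downsample = 8) {
  image <- as_image_matrix(image)
  if (all(image == 0)) stop("all-zero image cannot be normalized")
  rng <- range(image)
  scaled <- if (rng[1] < 0 || rng[2] > 1)
    (image - rng[1]) / (rng[2] - rng[1]) else image
  # cap at a quarter of the image's smaller dimension: the median of a
  # near-window-sized field is dominated by boundary truncation bias
  r <- min(as.integer(median_radius_px), min(dim(scaled)) %/% 4L)
  if (r > 20 && downsample > 1) {
    small <- EBImage::resize(EBImage::Image(scaled),
                             w = max(8, nrow(scaled) %/% downsample))
    rs <- max(1L, as.integer(round(r / downsample)))
    rs <- min(rs, (min(dim(small)) - 1L) %/% 2L)
    bg_small <- EBImage::medianFilter(small, rs)
    bg <- EBImage::imageData(EBImage::resize(bg_small, w = nrow(scaled),
                                             h = ncol(scaled)))
  } else {
    r <- min(r, (min(dim(scaled)) - 1L) %/% 2L)
    bg <- EBImage::imageData(
      EBImage::medianFilter(EBImage::Image(scaled), r))
  }
  eps <- max(1e-6, 1e-3 * max(bg))
  out <- scaled / pmax(bg, eps)
  stopifnot(all(is.finite(out)))
  out
}

#' Segment the dark spheroid core
#'
#' Blurs the normalized image and thresholds for signal lower than two
#' standard deviations below the image mean, keeping only the central
#' binary component (the one whose centroid is nearest the image centre).
#'
#' @param normalized output of [normalize_dic()].
#' @param blur_sigma Gaussian blur sigma, pixels.
#' @param threshold_sd number of standard deviations below the mean.
#' @return Logical core mask.
#' @export
segment_core <- function(normalized, blur_sigma = 4, threshold_sd = 2) {
  img <- as_image_matrix(normalized, "normalized")
  g <- EBImage::imageData(EBImage::gblur(img, blur_sigma))
  thr <- mean(g) - threshold_sd * sd(g)
  mask <- g < thr
  if (!any(mask)) stop("empty core: no pixels below the threshold")
  labels <- cpp_label8(mask)
  mom <- label_moments(labels)
  ctr <- (dim(img) - 1) / 2
  d2 <- (mom$cx - ctr[1])^2 + (mom$cy - ctr[2])^2
  labels == mom$label[which.min(d2)]
}

# Canny edge detection: Gaussian blur, Sobel gradients, non-maximum
# suppression, hysteresis thresholding.  Thresholds default to quantiles of
# the gradient magnitude.
canny_edges <- function(image, sigma = 2, low = NULL, high = NULL) {
  img <- as_image_matrix(image)
  g <- EBImage::imageData(EBImage::gblur(img, sigma))
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gx <- EBImage::imageData(EBImage::filter2(g, kx, boundary = "replicate"))
  gy <- EBImage::imageData(EBImage::filter2(g, t(kx), boundary = "replicate"))
  mag <- sqrt(gx^2 + gy^2)
  if (is.null(high)) {
    # Otsu split of the gradient-magnitude histogram separates the noise
    # floor from genuine edges even when edges are sparse
    mx <- max(mag)
    high <- if (mx == 0) Inf else
      mx * EBImage::otsu(EBImage::Image(mag / mx), range = c(0, 1))
  }
  if (is.null(low)) low <- 0.4 * high
  # quantize gradient direction into 4 sectors and suppress non-maxima
  ang <- (atan2(gy, gx) * 180 / pi) %% 180
  sector <- (floor((ang + 22.5) / 45) %% 4) + 1  # 1: 0deg, 2: 45, 3: 90, 4: 135
  nx <- nrow(mag); ny <- ncol(mag)
  p <- matrix(0, nx + 2, ny + 2)
  p[2:(nx + 1), 2:(ny + 1)] <- mag
  shift <- function(dx, dy) p[(2 + dx):(nx + 1 + dx), (2 + dy):(ny + 1 + dy)]
  offs <- list(c(1, 0), c(1, 1), c(0, 1), c(-1, 1))
  keep <- matrix(FALSE, nx, ny)
  for (s in 1:4) {
    o <- offs[[s]]
    sel <- sector == s
    keep[sel] <- mag[sel] >= shift(o[1], o[2])[sel] &
      mag[sel] >= shift(-o[1], -o[2])[sel]
  }
  strong <- keep & mag >= high
  weak <- keep & mag >= low
  if (!any(weak)) return(weak)
  labels <- cpp_label8(weak)
  good <- unique(labels[strong])
  good <- good[good > 0]
  matrix(labels %in% good, nx, ny)
}

#' Spheroid mask morphometrics
#'
#' Wraps a binary mask with its morphometrics: centroid, equivalent-circle
#' radius (`pixel_size * sqrt(area / pi)`), principal axis lengths and
#' major-axis angle from central second moments.
#'
#' @param mask logical matrix.
#' @param pixel_size_um physical pixel size, micrometres per pixel.
#' @return An object of class `spheroid_mask`.
#' @export
spheroid_mask <- function(mask, pixel_size_um = 0.67) {
  m <- as_binary_matrix(mask)
  mom <- mask_moments(m)
  area <- mom$n
  out <- list(mask = m,
              center_px = mom$centroid,
              area_px = area,
              radius_px = sqrt(area / pi),
              radius_um = pixel_size_um * sqrt(area / pi),
              major_axis_px = mom$major_axis,
              minor_axis_px = mom$minor_axis,
              major_angle_deg = mom$angle_deg,
              pixel_size_um = pixel_size_um)
  stopifnot(out$major_axis_px >= out$minor_axis_px)
  class(out) <- "spheroid_mask"
  out
}

#' @export
print.spheroid_mask <- function(x, ...) {
  cat(sprintf(
    "Spheroid mask: area %d px, radius %.1f um, center (%.1f, %.1f) px\n",
    x$area_px, x$radius_um, x$center_px[1], x$center_px[2]))
  invisible(x)
}

#' Segment the full spheroid (core plus migration zone)
#'
#' Applies Canny edge detection to the normalized image to mask the
#' spheroid's textured outer rim, dilates the edge map to cover the area of
#' cell migration, unites it with the core mask, fills holes, and keeps the
#' connected component containing the core.
#'
#' @param normalized output of [normalize_dic()].
#' @param core_mask logical mask from [segment_core()].
#' @param dilation_radius_px dilation radius applied to the edge map.
#' @param pixel_size_um physical pixel size, micrometres per pixel.
#' @param canny_sigma,canny_low,canny_high Canny blur sigma and hysteresis
#'   thresholds (`NULL` = automatic, from gradient-magnitude quantiles).
#' @return A [spheroid_mask()] object.
#' @export
segment_full_spheroid <- function(normalized, core_mask,
                                  dilation_radius_px = 15,
                                  pixel_size_um = 0.67,
                                  canny_sigma = 2, canny_low = NULL,
                                  canny_high = NULL) {
  core <- as_binary_matrix(core_mask, "core_mask")
  if (!any(core)) stop("empty core mask")
  edges <- canny_edges(normalized, canny_sigma, canny_low, canny_high)
  dilated <- edges
  brush <- NULL
  if (dilation_radius_px > 0 && any(edges)) {
    brush <- EBImage::makeBrush(2 * as.integer(dilation_radius_px) + 1, "disc")
    dilated <- EBImage::imageData(
      EBImage::dilate(EBImage::Image(edges * 1), brush)) > 0
  }
  combined <- dilated | core
  filled <- EBImage::imageData(
    EBImage::fillHull(EBImage::Image(combined * 1))) > 0
  # erode back by the dilation radius (dilate + fill + erode = close the
  # rim without advancing the outer boundary), then re-add the core
  if (!is.null(brush))
    filled <- (EBImage::imageData(
      EBImage::erode(EBImage::Image(filled * 1), brush)) > 0) | core
  # keep the component the core belongs to; stray background edges are
  # disconnected blobs and must not inflate the morphometrics
  labels <- cpp_label8(filled)
  core_labels <- unique(labels[core])
  core_labels <- core_labels[core_labels > 0]
  main_label <- core_labels[which.max(tabulate(labels)[core_labels])]
  spheroid_mask(labels == main_label, pixel_size_um)
}

#' Spheroid expansion ratio
#'
#' Radius at the later time point divided by the radius directly after
#' injection.
#'
#' @param mask_t48,mask_t0 [spheroid_mask()] objects (later / initial).
#' @return Ratio of equivalent-circle radii.
#' @export
expansion_ratio <- function(mask_t48, mask_t0) {
  stopifnot(inherits(mask_t48, "spheroid_mask"),
            inherits(mask_t0, "spheroid_mask"))
  if (mask_t0$radius_um <= 0) stop("zero initial radius")
  mask_t48$radius_um / mask_t0$radius_um
}

#' Count nuclei in a fluorescence z-stack
#'
#' Sums the stack over z, applies a Gaussian low-pass filter, thresholds at
#' two standard deviations above the mean, splits touching objects by
#' watershed on the distance transform, and counts the resulting objects.
#'
#' @param zstack 3D array `[x, y, z]` (a single plane matrix is accepted).
#' @param blur_sigma Gaussian blur sigma, pixels.
#' @param threshold_sd number of standard deviations above the mean.
#' @param min_area_px objects smaller than this are discarded as noise.
#' @param min_peak_mad objects whose peak blurred intensity does not reach
#'   this many median absolute deviations above the image median are
#'   discarded: the maximum of pure noise over a whole image stays below
#'   ~4-5 robust SDs, while genuine nuclei tower far above the
#'   background-dominated MAD.
#' @param watershed_tolerance minimum height difference between two
#'   distance-map maxima for them to count as separate nuclei.
#' @return Integer nucleus count, with the label matrix attached as
#'   attribute `labels`.
#' @export
count_nuclei <- function(zstack, blur_sigma = 2, threshold_sd = 2,
                         min_area_px = 20, min_peak_mad = 8,
                         watershed_tolerance = 0.3) {
  if (is.matrix(zstack)) zstack <- array(zstack, dim = c(dim(zstack), 1))
  stopifnot(is.array(zstack), length(dim(zstack)) == 3, dim(zstack)[3] >= 1)
  proj <- apply(zstack, c(1, 2), sum)
  g <- EBImage::imageData(EBImage::gblur(proj, blur_sigma))
  s <- sd(g)
  none <- structure(0L, labels = matrix(0L, nrow(g), ncol(g)))
  if (s == 0) return(none)
  mask <- g > mean(g) + threshold_sd * s
  if (!any(mask)) return(none)
  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  ws <- EBImage::imageData(
    EBImage::watershed(dm, tolerance = watershed_tolerance, ext = 1))
  counts <- tabulate(ws[ws > 0])
  peaks <- vapply(seq_along(counts),
                  function(l) if (counts[l] > 0) max(g[ws == l]) else 0,
                  numeric(1))
  peak_floor <- stats::median(g) + min_peak_mad * max(stats::mad(g), 1e-12)
  good <- which(counts >= min_area_px & peaks >= peak_floor)
  labels <- matrix(match(ws, good, nomatch = 0L), nrow(ws), ncol(ws))
  structure(length(good), labels = labels)
}
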