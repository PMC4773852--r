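# Endothelial (HMEC-1) spheroid scoring: principal axes of the injection
# mask, direction toward the tumor, elongation, and their product.

#' Principal axes of a binary mask
#'
#' Equivalent-ellipse axis lengths and major-axis angle from the central
#' second moments of the mask's pixel set.
#'
#' @param mask logical matrix with at least 2 foreground pixels.
#' @return List with `major_axis_px`, `minor_axis_px`, `major_angle_deg`
#'   (degrees in `[0, 180)`), `centroid_px`, and the moment eigenvalues
#'   `lambda1`, `lambda2`.
#' @export
mask_principal_axes <- function(mask) {
  m <- as_binary_matrix(mask)
  if (sum(m) < 2) stop("mask must contain at least 2 pixels")
  mom <- mask_moments(m)
  list(major_axis_px = mom$major_axis,
       minor_axis_px = mom$minor_axis,
       major_angle_deg = mom$angle_deg,
       centroid_px = mom$centroid,
       lambda1 = mom$lambda1, lambda2 = mom$lambda2)
}

#' Direction of an endothelial spheroid toward the tumor
#'
#' Takes the acute angle (0 to 90 degrees) between the mask's long axis and
#' the vector from the mask centroid to the tumor spheroid centre, subtracts
#' it from 90 and divides by 90, so a spheroid pointing at the tumor scores
#' 1 and one pointing perpendicularly scores 0.
#'
#' @param mask logical matrix (endothelial spheroid injection mask).
#' @param tumor_center_px tumor spheroid centre, 0-based pixel coordinates.
#' @param isotropy_tol relative eigenvalue gap below which the long axis is
#'   considered undefined.
#' @return Direction in `[0, 1]`, with attributes `angle_to_tumor_deg` and
#'   `low_confidence` (`TRUE` for near-circular masks, elongation < 1.05).
#'   An isotropic mask (axis undefined within tolerance) returns `NA` with
#'   attribute `indeterminate = TRUE`.
#' @export
direction_parameter <- function(mask, tumor_center_px, isotropy_tol = 1e-9) {
  ax <- mask_principal_axes(mask)
  dx <- tumor_center_px[1] - ax$centroid_px[1]
  dy <- tumor_center_px[2] - ax$centroid_px[2]
  if (dx == 0 && dy == 0)
    stop("mask centroid coincides with the tumor center")
  if (ax$lambda1 <= 0 ||
      (ax$lambda1 - ax$lambda2) / ax$lambda1 < isotropy_tol)
    return(structure(NA_real_, indeterminate = TRUE))
  radial <- wrap_axial(atan2(dy, dx) * 180 / pi)
  ang <- acute_axial_diff(ax$major_angle_deg, radial)
  elong <- ax$major_axis_px / max(ax$minor_axis_px, .Machine$double.eps)
  structure((90 - ang) / 90,
            angle_to_tumor_deg = ang,
            low_confidence = elong < 1.05)
}

#' Elongation of a mask
#'
#' Equivalent-ellipse major axis length divided by minor axis length.
#'
#' @param mask logical matrix.
#' @return Elongation ratio (>= 1).
#' @export
elongation <- function(mask) {
  ax <- mask_principal_axes(mask)
  if (ax$minor_axis_px == 0) stop("zero minor axis: elongation undefined")
  ax$major_axis_px / ax$minor_axis_px
}

#' Score an endothelial spheroid mask
#'
#' Computes direction toward the tumor, elongation, and the orientation
#' score (their product) for one endothelial spheroid mask.
#'
#' @inheritParams direction_parameter
#' @param pixel_size_um physical pixel size, micrometres per pixel (for the
#'   centroid-to-tumor distance).
#' @return An `endothelial_score` list: `direction`, `elongation`,
#'   `orientation`, `angle_to_tumor_deg`, `distance_to_tumor_um`,
#'   `low_confidence`.
#' @export
endothelial_score <- function(mask, tumor_center_px, pixel_size_um = 0.67) {
  ax <- mask_principal_axes(mask)
  dir <- direction_parameter(mask, tumor_center_px)
  if (isTRUE(attr(dir, "indeterminate")))
    stop("isotropic mask: direction indeterminate")
  el <- elongation(mask)
  d_um <- sqrt(sum((tumor_center_px - ax$centroid_px)^2)) * pixel_size_um
  out <- list(direction = as.numeric(dir),
              elongation = el,
              orientation = as.numeric(dir) * el,
              angle_to_tumor_deg = attr(dir, "angle_to_tumor_deg"),
              distance_to_tumor_um = d_um,
              low_confidence = isTRUE(attr(dir, "low_confidence")))
  stopifnot(out$direction >= 0, out$direction <= 1, out$elongation >= 1,
            out$orientation >= 0, out$orientation <= out$elongation)
  class(out) <- "endothelial_score"
  out
}

#' Orientation score of an endothelial spheroid
#'
#' Product of the direction parameter and the elongation.
#'
#' @param score an [endothelial_score()] object.
#' @return Numeric orientation score in `[0, elongation]`.
#' @export
orientation_score <- function(score) {
  stopifnot(inherits(score, "endothelial_score"))
  score$direction * score$elongation
}

#' @export
print.endothelial_score <- function(x, ...) {
  cat(sprintf(
    "Endothelial score: direction %.3f, elongation %.3f, orientation %.3f%s\n",
    x$direction, x$elongation, x$orientation,
    if (x$low_confidence) " (low confidence: near-circular)" else ""))
  invisible(x)
}
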