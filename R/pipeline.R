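# Per-well orchestration: configuration, end-to-end analysis with
# per-stage error capture, tabular outputs, and the region-comparison
# branch used for severed/control gel areas.

#' Per-well analysis configuration
#'
#' Collects images, geometry and parameters for one well.  Image arguments
#' accept either file paths (TIFF, read via EBImage) or in-memory matrices.
#'
#' @param reflection_image reflection-channel image (collagen), or `NULL`.
#' @param dic_t0_image,dic_t48_image DIC-like images directly after
#'   injection and at the analysis time point, or `NULL`.
#' @param nuclei_stack 3D array or path to a multi-plane TIFF, or `NULL`.
#' @param pixel_size_um physical pixel size, micrometres per pixel.
#' @param tumor_center_px optional manual tumor centre override (0-based
#'   pixels); defaults to the segmented spheroid centroid.
#' @param tumor_radius_um optional manual tumor radius override.
#' @param injections list of endothelial injections, each a list with
#'   `mask` (matrix or path) and optionally `id`.
#' @param reference_orientation_values optional reference collagen
#'   orientation values for the oriented/random classification.
#' @param bin_width_um,fit_window_min_um profile and fit settings.
#' @param extraction an [extraction_params()] object.
#' @param segmentation named list of [segment_core()] /
#'   [segment_full_spheroid()] / [count_nuclei()] settings.
#' @param seed integer seed echoed into the report.
#' @return An object of class `well_config`.
#' @export
well_config <- function(reflection_image = NULL, dic_t0_image = NULL,
                        dic_t48_image = NULL, nuclei_stack = NULL,
                        pixel_size_um = 0.67, tumor_center_px = NULL,
                        tumor_radius_um = NULL, injections = list(),
                        reference_orientation_values = NULL,
                        bin_width_um = 67, fit_window_min_um = 100,
                        extraction = extraction_params(),
                        segmentation = list(), seed = 1L) {
  check_scalar(pixel_size_um, "pixel_size_um", 0, strict_lower = TRUE)
  seg_defaults <- list(median_radius_px = 200, blur_sigma = 4,
                       dilation_radius_px = 15, canny_sigma = 2,
                       nuclei_blur_sigma = 2, nuclei_min_area_px = 20)
  seg <- utils::modifyList(seg_defaults, segmentation)
  cfg <- list(reflection_image = reflection_image,
              dic_t0_image = dic_t0_image,
              dic_t48_image = dic_t48_image,
              nuclei_stack = nuclei_stack,
              pixel_size_um = pixel_size_um,
              tumor_center_px = tumor_center_px,
              tumor_radius_um = tumor_radius_um,
              injections = injections,
              reference_orientation_values = reference_orientation_values,
              bin_width_um = bin_width_um,
              fit_window_min_um = fit_window_min_um,
              extraction = extraction,
              segmentation = seg,
              seed = as.integer(seed))
  class(cfg) <- "well_config"
  cfg
}

#' Read a well configuration from YAML or JSON
#'
#' @param path configuration file (`.yaml`/`.yml` or `.json`).  Relative
#'   image paths are resolved against the file's directory.
#' @return A [well_config()] object.
#' @export
read_well_config <- function(path) {
  stopifnot(file.exists(path))
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(normalizePath(path))
  fix_path <- function(p) {
    if (is.null(p) || is.matrix(p)) return(p)
    if (file.exists(p)) p else file.path(base, p)
  }
  for (nm in c("reflection_image", "dic_t0_image", "dic_t48_image",
               "nuclei_stack"))
    raw[[nm]] <- fix_path(raw[[nm]])
  if (!is.null(raw$injections))
    raw$injections <- lapply(raw$injections, function(inj) {
      inj$mask <- fix_path(inj$mask); inj
    })
  if (!is.null(raw$extraction))
    raw$extraction <- do.call(extraction_params, raw$extraction)
  do.call(well_config, raw[!vapply(raw, is.null, logical(1))])
}

load_image <- function(x) {
  if (is.character(x)) {
    img <- EBImage::readImage(x)
    d <- dim(img)
    if (length(d) == 3 && d[3] > 1) return(EBImage::imageData(img))
    return(as_image_matrix(img))
  }
  if (is.array(x) && length(dim(x)) == 3) return(x)
  as_image_matrix(x)
}

run_stage <- function(state, name, expr) {
  tryCatch(expr, error = function(e) {
    state$errors[[name]] <- conditionMessage(e)
    NULL
  })
}

#' Run the full per-well analysis
#'
#' Executes, for whatever inputs the configuration provides: spheroid
#' segmentation and morphometry (t0/t48, expansion ratio), nuclei
#' counting, fiber extraction, the orientation profile with exponential
#' fit, integrated orientation and orientation extent, and per-injection
#' endothelial scoring with the local collagen orientation.  Stage
#' failures are captured per stage and a partial report is emitted.
#'
#' @param config a [well_config()] object.
#' @param out_dir optional output directory for CSV tables and a JSON
#'   summary.
#' @return A `well_report` list; `$errors` names any failed stages.
#' @export
run_well <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "well_config"))
  seg <- config$segmentation
  state <- new.env(parent = emptyenv())
  state$errors <- list()
  report <- list(parameters = list(
    pixel_size_um = config$pixel_size_um,
    bin_width_um = config$bin_width_um,
    fit_window_min_um = config$fit_window_min_um,
    extraction = unclass(config$extraction),
    segmentation = seg,
    seed = config$seed))

  segment_one <- function(img) {
    norm <- normalize_dic(img, seg$median_radius_px)
    core <- segment_core(norm, seg$blur_sigma)
    segment_full_spheroid(norm, core, seg$dilation_radius_px,
                          config$pixel_size_um, seg$canny_sigma)
  }
  mask_t0 <- if (!is.null(config$dic_t0_image))
    run_stage(state, "morphometry_t0",
              segment_one(load_image(config$dic_t0_image)))
  mask_t48 <- if (!is.null(config$dic_t48_image))
    run_stage(state, "morphometry_t48",
              segment_one(load_image(config$dic_t48_image)))
  if (!is.null(mask_t0))
    report$tumor_radius_t0_um <- mask_t0$radius_um
  if (!is.null(mask_t48))
    report$tumor_radius_t48_um <- mask_t48$radius_um
  if (!is.null(mask_t0) && !is.null(mask_t48))
    report$expansion_ratio <- run_stage(state, "expansion_ratio",
                                        expansion_ratio(mask_t48, mask_t0))

  tumor_center <- config$tumor_center_px
  if (is.null(tumor_center) && !is.null(mask_t48))
    tumor_center <- mask_t48$center_px
  tumor_radius <- config$tumor_radius_um
  if (is.null(tumor_radius) && !is.null(mask_t48))
    tumor_radius <- mask_t48$radius_um
  report$tumor_center_px <- tumor_center
  report$tumor_radius_um <- tumor_radius

  if (!is.null(config$nuclei_stack))
    report$nuclei_count <- run_stage(state, "nuclei", {
      cnt <- count_nuclei(load_image(config$nuclei_stack),
                          seg$nuclei_blur_sigma,
                          min_area_px = seg$nuclei_min_area_px)
      as.integer(cnt)
    })

  fibers <- NULL
  if (!is.null(config$reflection_image))
    fibers <- run_stage(state, "fiber_extraction",
                        extract_fibers(load_image(config$reflection_image),
                                       config$extraction))
  report$n_fibers <- if (!is.null(fibers)) nrow(fibers) else NA_integer_
  report$fibers <- fibers

  if (!is.null(fibers) && nrow(fibers) > 0 && !is.null(tumor_center) &&
      !is.null(tumor_radius)) {
    profile <- run_stage(state, "orientation_profile",
                         bin_profile(fibers, tumor_center, tumor_radius,
                                     config$pixel_size_um,
                                     config$bin_width_um))
    report$profile <- profile
    if (!is.null(profile)) {
      fit <- fit_exponential(profile, config$fit_window_min_um)
      report$fit <- fit
      if (fit$converged) {
        report$integrated_orientation_um <- integrated_orientation(fit)
        report$orientation_extent_um <-
          run_stage(state, "orientation_extent",
                    orientation_extent(profile, fit))
      } else {
        errors$exponential_fit <- fit$reason
      }
    }
  }

  if (length(config$injections) > 0 && !is.null(tumor_center)) {
    report$injections <- run_stage(state, "injections", {
      rows <- lapply(seq_along(config$injections), function(i) {
        inj <- config$injections[[i]]
        mask <- as_binary_matrix(load_image(inj$mask), "injection mask")
        sc <- endothelial_score(mask, tumor_center, config$pixel_size_um)
        coll <- NA_real_
        if (!is.null(report$profile) && !is.null(tumor_radius)) {
          d <- sc$distance_to_tumor_um - tumor_radius
          row <- which(report$profile$bin_lo_um <= d &
                         d < report$profile$bin_hi_um)
          if (length(row) == 1) coll <- report$profile$mean_cos2[row]
        }
        cls <- NA_character_
        if (!is.na(coll) && !is.null(config$reference_orientation_values))
          cls <- as.character(
            classify_oriented(coll, config$reference_orientation_values))
        data.frame(id = if (!is.null(inj$id)) inj$id else i,
                   direction = sc$direction, elongation = sc$elongation,
                   orientation = sc$orientation,
                   angle_to_tumor_deg = sc$angle_to_tumor_deg,
                   distance_to_tumor_um = sc$distance_to_tumor_um,
                   collagen_orientation = coll,
                   collagen_class = cls,
                   low_confidence = sc$low_confidence)
      })
      do.call(rbind, rows)
    })
  }

  report$errors <- state$errors
  class(report) <- "well_report"
  if (!is.null(out_dir)) write_well_report(report, out_dir)
  report
}

#' Write a well report to disk
#'
#' One CSV per table (fibers, profile bins, injections) plus a JSON
#' summary of the scalar results and the parameters actually used.
#'
#' @param report a `well_report` from [run_well()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_well_report <- function(report, out_dir) {
  stopifnot(inherits(report, "well_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  if (!is.null(report$fibers)) {
    f <- file.path(out_dir, "fibers.csv")
    write.csv(report$fibers, f, row.names = FALSE)
    written <- c(written, f)
  }
  if (!is.null(report$profile)) {
    f <- file.path(out_dir, "profile_bins.csv")
    write.csv(as.data.frame(report$profile), f, row.names = FALSE)
    written <- c(written, f)
  }
  if (!is.null(report$injections)) {
    f <- file.path(out_dir, "injections.csv")
    write.csv(report$injections, f, row.names = FALSE)
    written <- c(written, f)
  }
  summary <- report[setdiff(names(report),
                            c("fibers", "profile", "injections"))]
  if (!is.null(summary$fit))
    summary$fit <- summary$fit[c("Y0", "L0", "integrated_orientation",
                                 "ci95_Y0", "ci95_L0", "converged")]
  f <- file.path(out_dir, "report.json")
  jsonlite::write_json(summary, f, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(c(written, f))
}

# Select fibers falling in a region: a pixel-coordinate rectangle
# (list(type = "rect", x_min, x_max, y_min, y_max)) or an annular sector
# around the tumor (list(type = "sector", r_min_um, r_max_um,
# angle_min_deg, angle_max_deg)).
region_select <- function(fibers, region, tumor_center_px, tumor_radius_um,
                          pixel_size_um) {
  if (region$type == "rect") {
    fibers$centroid_x_px >= region$x_min &
      fibers$centroid_x_px <= region$x_max &
      fibers$centroid_y_px >= region$y_min &
      fibers$centroid_y_px <= region$y_max
  } else if (region$type == "sector") {
    d <- fiber_distance_to_edge(fibers, tumor_center_px, tumor_radius_um,
                                pixel_size_um)
    ang <- (atan2(fibers$centroid_y_px - tumor_center_px[2],
                  fibers$centroid_x_px - tumor_center_px[1]) * 180 / pi) %% 360
    d >= region$r_min_um & d < region$r_max_um &
      ang >= region$angle_min_deg & ang < region$angle_max_deg
  } else stop("unknown region type: ", region$type)
}

#' Compare collagen orientation between two regions of a well
#'
#' Rank-sum comparison of the per-fiber orientation-parameter
#' distributions of two regions (e.g. a laser-disconnected area versus a
#' control area), with per-region profiles, exponential fits and
#' integrated orientation where enough bins exist.
#'
#' @param report a `well_report` containing fibers and tumor geometry.
#' @param region_a,region_b region specifications (see Details in
#'   [run_well()]; rectangles in pixels or annular sectors around the
#'   tumor).
#' @return List with the per-region summary table (`regions`), the
#'   rank-sum result (`distribution_test`), and per-region fits (`fits`).
#' @export
compare_regions <- function(report, region_a, region_b) {
  stopifnot(inherits(report, "well_report"))
  fibers <- report$fibers
  if (is.null(fibers) || nrow(fibers) == 0) stop("report contains no fibers")
  ctr <- report$tumor_center_px
  rad <- report$tumor_radius_um
  px <- report$parameters$pixel_size_um
  sel_a <- region_select(fibers, region_a, ctr, rad, px)
  sel_b <- region_select(fibers, region_b, ctr, rad, px)
  if (!any(sel_a)) stop("region_a contains no fibers")
  if (!any(sel_b)) stop("region_b contains no fibers")
  op_a <- fiber_orientation_parameter(fibers[sel_a, ], ctr)
  op_b <- fiber_orientation_parameter(fibers[sel_b, ], ctr)
  test <- compare_groups(op_a, op_b, mode = "distribution")
  fit_one <- function(sel) {
    tryCatch({
      prof <- bin_profile(fibers[sel, ], ctr, rad, px,
                          report$parameters$bin_width_um)
      fit_exponential(prof, report$parameters$fit_window_min_um)
    }, error = function(e) NULL)
  }
  fits <- list(a = fit_one(sel_a), b = fit_one(sel_b))
  io <- function(f) if (!is.null(f) && f$converged)
    integrated_orientation(f) else NA_real_
  regions <- data.frame(region = c("a", "b"),
                        n_fibers = c(sum(sel_a), sum(sel_b)),
                        mean_cos2 = c(mean(op_a), mean(op_b)),
                        sd_cos2 = c(sd(op_a), sd(op_b)),
                        integrated_orientation_um = c(io(fits$a), io(fits$b)))
  list(regions = regions, distribution_test = test, fits = fits)
}
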