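# Radial orientation statistic and its distance profile: per-fiber cos^2
# orientation parameter, distance binning from the tumor edge, the
# plateau-at-0.5 exponential fit, integrated orientation, orientation
# extent, oriented/random classification and group comparisons.

#' Per-fiber radial orientation parameter
#'
#' Computes `cos^2` of the acute angle between the radial vector (tumor
#' centre to fiber centroid) and the fiber axis.  1 means the fiber points
#' radially at the tumor, 0 means tangential, and uniformly random
#' orientations average 0.5.  Invariant to 180-degree fiber-axis flips.
#'
#' @param fibers a `fiber_table` data frame (columns `centroid_x_px`,
#'   `centroid_y_px`, `angle_deg`), e.g. from [extract_fibers()] or
#'   [generate_fiber_field()] (ground-truth columns are accepted).
#' @param tumor_center_px tumor spheroid centre, 0-based pixel coordinates.
#' @return Numeric vector in `[0, 1]`, one value per fiber.
#' @export
fiber_orientation_parameter <- function(fibers, tumor_center_px) {
  f <- normalize_fiber_table(fibers)
  dx <- f$centroid_x_px - tumor_center_px[1]
  dy <- f$centroid_y_px - tumor_center_px[2]
  if (any(dx == 0 & dy == 0))
    stop("fiber centroid coincides with the tumor center: radial direction undefined")
  radial <- wrap_axial(atan2(dy, dx) * 180 / pi)
  delta <- acute_axial_diff(radial, f$angle_deg)
  cos(delta * pi / 180)^2
}

# Accept a fiber table under either the detection or ground-truth schema.
normalize_fiber_table <- function(fibers) {
  need <- c("centroid_x_px", "centroid_y_px", "angle_deg")
  if (!all(need %in% names(fibers)))
    stop("fiber table must have columns centroid_x_px, centroid_y_px, angle_deg")
  fibers
}

#' Fiber distance to the tumor spheroid edge
#'
#' Euclidean distance from each fiber centroid to the tumor centre,
#' converted to micrometres, minus the tumor spheroid radius.  Negative for
#' fibers inside the spheroid mask (such fibers are excluded from
#' profiles).
#'
#' @inheritParams fiber_orientation_parameter
#' @param tumor_radius_um tumor spheroid radius, micrometres (>= 0).
#' @param pixel_size_um physical pixel size, micrometres per pixel.
#' @return Numeric vector of distances in micrometres (may be negative).
#' @export
fiber_distance_to_edge <- function(fibers, tumor_center_px, tumor_radius_um,
                                   pixel_size_um) {
  check_scalar(tumor_radius_um, "tumor_radius_um", 0)
  check_scalar(pixel_size_um, "pixel_size_um", 0, strict_lower = TRUE)
  f <- normalize_fiber_table(fibers)
  d_px <- sqrt((f$centroid_x_px - tumor_center_px[1])^2 +
                 (f$centroid_y_px - tumor_center_px[2])^2)
  d_px * pixel_size_um - tumor_radius_um
}

#' Distance-binned orientation profile
#'
#' Bins the per-fiber orientation parameter by distance from the tumor
#' spheroid edge in half-open bins `[lo, hi)` of width `bin_width_um`
#' anchored at the edge (distance 0).  Fibers with negative distance
#' (inside the spheroid) are excluded.
#'
#' @inheritParams fiber_distance_to_edge
#' @param bin_width_um bin width in micrometres; the default 67 corresponds
#'   to 100 pixels at 0.67 micrometre pixels.
#' @return An `orientation_profile` data frame with one row per bin:
#'   `bin_lo_um`, `bin_hi_um`, `bin_mid_um`, `mean_cos2`, `sd_cos2`,
#'   `n_fibers`.  Empty bins carry `NA` for mean and sd.
#' @export
bin_profile <- function(fibers, tumor_center_px, tumor_radius_um,
                        pixel_size_um, bin_width_um = 67) {
  check_scalar(bin_width_um, "bin_width_um", 0, strict_lower = TRUE)
  op <- fiber_orientation_parameter(fibers, tumor_center_px)
  d <- fiber_distance_to_edge(fibers, tumor_center_px, tumor_radius_um,
                              pixel_size_um)
  keep <- d >= 0
  if (!any(keep))
    stop("no fibers outside the tumor spheroid: empty profile")
  op <- op[keep]; d <- d[keep]
  n_bins <- floor(max(d) / bin_width_um) + 1
  edges <- seq(0, by = bin_width_um, length.out = n_bins + 1)
  bin <- findInterval(d, edges, rightmost.closed = FALSE)
  mean_cos2 <- rep(NA_real_, n_bins)
  sd_cos2 <- rep(NA_real_, n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  present <- sort(unique(bin))
  mean_cos2[present] <- vapply(split(op, bin), mean, numeric(1))
  sd_cos2[present] <- vapply(split(op, bin), sd, numeric(1))
  out <- data.frame(bin_lo_um = edges[-(n_bins + 1)],
                    bin_hi_um = edges[-1],
                    bin_mid_um = (edges[-1] + edges[-(n_bins + 1)]) / 2,
                    mean_cos2 = mean_cos2,
                    sd_cos2 = sd_cos2,
                    n_fibers = counts)
  stopifnot(all(is.na(out$mean_cos2) |
                  (out$mean_cos2 >= 0 & out$mean_cos2 <= 1)))
  attr(out, "bin_width_um") <- bin_width_um
  attr(out, "tumor_center_px") <- tumor_center_px
  attr(out, "tumor_radius_um") <- tumor_radius_um
  attr(out, "pixel_size_um") <- pixel_size_um
  class(out) <- c("orientation_profile", "data.frame")
  out
}

#' Fit the plateau-at-0.5 exponential to an orientation profile
#'
#' Least-squares fit of `y(x) = 0.5 + (Y0 - 0.5) * exp(-x / L0)` to the
#' per-bin mean orientation parameter against bin-midpoint distance, using
#' only bins beyond `fit_window_min_um`.  `Y0` is the extrapolated
#' orientation at the spheroid edge and `L0` the decay length in
#' micrometres; the curve plateaus at the random baseline 0.5.
#'
#' @param profile an [bin_profile()] result.
#' @param fit_window_min_um only bins with midpoint distance strictly
#'   greater than this are fitted (default 100 micrometres).
#' @param weights `"none"` (default; unweighted bin means) or
#'   `"inverse_se"` (weights proportional to `n / sd^2`).
#' @return An `exponential_fit` object: `Y0`, `L0`,
#'   `integrated_orientation = (Y0 - 0.5) * L0`, 95% confidence half-widths
#'   `ci95_Y0`, `ci95_L0`, the parameter covariance, residual degrees of
#'   freedom and the fitted data.  If the fit cannot be performed,
#'   `converged` is `FALSE` and a `reason` is given.
#' @export
fit_exponential <- function(profile, fit_window_min_um = 100,
                            weights = c("none", "inverse_se")) {
  weights <- match.arg(weights)
  use <- !is.na(profile$mean_cos2) & profile$bin_mid_um > fit_window_min_um
  x <- profile$bin_mid_um[use]
  y <- profile$mean_cos2[use]
  fail <- function(reason) {
    structure(list(Y0 = NA_real_, L0 = NA_real_,
                   integrated_orientation = NA_real_,
                   ci95_Y0 = NA_real_, ci95_L0 = NA_real_,
                   vcov = matrix(NA_real_, 2, 2), df = NA_integer_,
                   converged = FALSE, reason = reason,
                   fit_window_min_um = fit_window_min_um,
                   data = data.frame(x = x, y = y)),
              class = "exponential_fit")
  }
  if (length(x) < 3) return(fail("fewer than 3 usable bins"))
  w <- if (weights == "inverse_se") {
    s <- profile$sd_cos2[use]
    n <- profile$n_fibers[use]
    wi <- n / pmax(s, 1e-6)^2
    wi / mean(wi)
  } else rep(1, length(x))
  max_x <- max(x)
  # initialize by profiling L0 on a log grid: for fixed L0 the amplitude
  # A = Y0 - 0.5 has a closed-form weighted least-squares solution
  grid <- exp(seq(log(20), log(10 * max_x), length.out = 60))
  prof_A <- vapply(grid, function(l0) {
    e <- exp(-x / l0)
    a <- sum(w * e * (y - 0.5)) / sum(w * e * e)
    min(max(a, -0.5), 0.5)
  }, numeric(1))
  sse <- vapply(seq_along(grid), function(i) {
    r <- y - 0.5 - prof_A[i] * exp(-x / grid[i])
    sum(w * r * r)
  }, numeric(1))
  best <- which.min(sse)
  start <- list(Y0 = min(max(0.5 + prof_A[best], 0), 1), L0 = grid[best])
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ 0.5 + (Y0 - 0.5) * exp(-x / L0),
                      data = data.frame(x = x, y = y),
                      start = start, weights = w,
                      lower = c(Y0 = 0, L0 = 1e-6),
                      upper = c(Y0 = 1, L0 = 10 * max_x),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  df <- length(x) - 2L
  if (!is.null(fit)) {
    est <- coef(fit)
    V <- tryCatch(vcov(fit), error = function(e) matrix(0, 2, 2))
  } else {
    # degenerate problems (e.g. perfectly flat profiles) have a singular
    # gradient; report the profiled-grid solution with a Gauss-Newton
    # covariance from the analytic Jacobian
    est <- c(Y0 = start$Y0, L0 = start$L0)
    e <- exp(-x / est["L0"])
    J <- cbind(e, (est["Y0"] - 0.5) * e * x / est["L0"]^2)
    s2 <- sse[best] / max(df, 1)
    JtJ <- crossprod(J * sqrt(w))
    V <- tryCatch(s2 * solve(JtJ), error = function(e2) {
      sv <- svd(JtJ)
      pos <- sv$d > max(sv$d) * 1e-10
      s2 * sv$v[, pos, drop = FALSE] %*%
        diag(1 / sv$d[pos], sum(pos)) %*% t(sv$u[, pos, drop = FALSE])
    })
  }
  V[!is.finite(V)] <- 0
  tq <- qt(0.975, df)
  structure(list(Y0 = unname(est["Y0"]), L0 = unname(est["L0"]),
                 integrated_orientation =
                   unname((est["Y0"] - 0.5) * est["L0"]),
                 ci95_Y0 = tq * sqrt(V[1, 1]),
                 ci95_L0 = tq * sqrt(V[2, 2]),
                 vcov = V, df = df, converged = TRUE, reason = NULL,
                 fit_window_min_um = fit_window_min_um,
                 data = data.frame(x = x, y = y, w = w)),
            class = "exponential_fit")
}

#' @export
print.exponential_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Exponential orientation fit: FAILED (", x$reason, ")\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf(
    "Exponential orientation fit: y = 0.5 + (Y0 - 0.5) exp(-x / L0)\n  Y0 = %.4f (+/- %.4f)\n  L0 = %.1f um (+/- %.1f)\n  integrated orientation = %.1f um\n",
    x$Y0, x$ci95_Y0, x$L0, x$ci95_L0, x$integrated_orientation))
  invisible(x)
}

#' Integrated orientation
#'
#' Area between the fitted orientation curve and the random baseline 0.5
#' over distances from 0 to infinity, which for the plateau-at-0.5
#' exponential equals `(Y0 - 0.5) * L0` (micrometres).
#'
#' @param fit an [fit_exponential()] result with `converged = TRUE`.
#' @return Integrated orientation in micrometres.
#' @export
integrated_orientation <- function(fit) {
  stopifnot(inherits(fit, "exponential_fit"))
  if (!fit$converged) stop("fit did not converge: ", fit$reason)
  (fit$Y0 - 0.5) * fit$L0
}

# Fitted curve and delta-method standard error at distances x.
fit_curve_band <- function(fit, x) {
  e <- exp(-x / fit$L0)
  yhat <- 0.5 + (fit$Y0 - 0.5) * e
  g1 <- e
  g2 <- (fit$Y0 - 0.5) * e * x / fit$L0^2
  V <- fit$vcov
  se <- sqrt(pmax(g1^2 * V[1, 1] + 2 * g1 * g2 * V[1, 2] +
                    g2^2 * V[2, 2], 0))
  tq <- qt(0.975, max(fit$df, 1))
  data.frame(x = x, y = yhat, lower = yhat - tq * se, upper = yhat + tq * se)
}

#' Orientation extent
#'
#' Largest distance at which the lower 95% confidence bound of the fitted
#' orientation curve still exceeds the random baseline 0.5, i.e. the range
#' over which collagen orientation is significantly different from random.
#'
#' @param profile the fitted [bin_profile()] result (sets the evaluation
#'   range: up to the last populated bin edge).
#' @param fit an [fit_exponential()] result.
#' @param step_um evaluation grid step in micrometres.
#' @return Distance in micrometres; 0 if the bound never exceeds 0.5.
#' @export
orientation_extent <- function(profile, fit, step_um = 1) {
  stopifnot(inherits(fit, "exponential_fit"))
  if (!fit$converged) stop("fit did not converge: ", fit$reason)
  xmax <- max(profile$bin_hi_um[profile$n_fibers > 0])
  grid <- seq(0, xmax, by = step_um)
  band <- fit_curve_band(fit, grid)
  above <- band$lower > 0.5
  if (!any(above)) return(0)
  max(grid[above])
}

#' Classify a collagen orientation value as oriented or random
#'
#' A value is called "oriented" when it exceeds the mean of a reference set
#' (typically control wells) by more than one standard deviation.
#'
#' @param value the orientation value to classify (e.g. the mean
#'   orientation parameter at an injection site).
#' @param reference_values numeric vector (length >= 2, non-degenerate) of
#'   reference orientation values.
#' @return `"oriented"` or `"random"`, with the threshold attached as
#'   attribute `threshold`.
#' @export
classify_oriented <- function(value, reference_values) {
  if (length(reference_values) < 2 || !all(is.finite(reference_values)))
    stop("need at least 2 finite reference values")
  s <- sd(reference_values)
  if (s == 0) stop("degenerate reference set: zero variance")
  thr <- mean(reference_values) + s
  structure(if (value > thr) "oriented" else "random", threshold = thr)
}

#' Compare two groups of orientation measurements
#'
#' Mann-Whitney U (Wilcoxon rank-sum) test for distribution-level data,
#' two-sided unpaired Student's t-test for integrated-orientation values.
#'
#' @param sample_a,sample_b numeric vectors (length >= 2 each).
#' @param mode `"distribution"` (rank-sum) or `"integrated"` (t-test).
#' @return List with `statistic`, `p_value`, `method`, `mode`.
#' @export
compare_groups <- function(sample_a, sample_b,
                           mode = c("distribution", "integrated")) {
  mode <- match.arg(mode)
  if (length(sample_a) < 2 || length(sample_b) < 2)
    stop("need at least 2 observations per group")
  if (mode == "distribution") {
    ht <- suppressWarnings(wilcox.test(sample_a, sample_b))
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         method = "Mann-Whitney U", mode = mode)
  } else {
    ht <- t.test(sample_a, sample_b, var.equal = TRUE)
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         method = "unpaired t-test", mode = mode)
  }
}

#' Pearson correlation and linear fit between collagen orientation and an
#' endothelial score
#'
#' @param collagen numeric vector, collagen orientation at injection sites.
#' @param score numeric vector, matched endothelial scores.
#' @return List with `pcc`, `p_value`, `slope`, `intercept`, `r_squared`.
#' @export
score_correlation <- function(collagen, score) {
  stopifnot(length(collagen) == length(score), length(collagen) >= 3)
  ct <- stats::cor.test(collagen, score, method = "pearson")
  lf <- stats::lm(score ~ collagen)
  list(pcc = unname(ct$estimate), p_value = ct$p.value,
       slope = unname(coef(lf)[2]), intercept = unname(coef(lf)[1]),
       r_squared = summary(lf)$r.squared)
}
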