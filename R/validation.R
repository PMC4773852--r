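# Parameter-recovery harness: generate a biased fiber field, optionally
# render and re-extract it, and compare the fitted (Y0, L0) against the
# generative ground truth Y0 = 0.5 + 0.5 * w0, L0 = lambda.

# Pixel size used for recovery scenes: scales with the decay length probed
# (lambda / 500 um per px, clamped to [0.45, 1.4]) so that a 4500 px field
# of view spans 3-5 decay lengths while fiber area coverage stays ~6%.
recovery_pixel_size <- function(decay_length_um) {
  min(1.4, max(0.45, decay_length_um / 500))
}

#' Run one parameter-recovery scene
#'
#' Generates a fiber field whose radial bias decays with distance from the
#' tumor edge (`E[cos^2](d) = 0.5 + 0.5 * w0 * exp(-d / lambda)`), runs it
#' through the analysis (optionally via the rendered image and the full
#' extraction chain), and returns the fitted parameters next to the ground
#' truth `Y0 = 0.5 + 0.5 * w0`, `L0 = lambda`.
#'
#' @param w0 radial mixture weight at the spheroid edge, in `[0, 1]`.
#' @param decay_length_um decay length lambda, micrometres.
#' @param seed scene seed.
#' @param n_fibers fibers per scene.
#' @param route `"render"` (render the reflection image and re-extract
#'   fibers — the full chain) or `"truth"` (bin the ground-truth fibers
#'   directly).
#' @param weights fit weighting passed to [fit_exponential()]; the
#'   inverse-standard-error default downweights sparse far-field bins.
#' @param image_size_px scene size in pixels.
#' @return One-row data frame: `w0`, `decay_length_um`, `seed`, `Y0_true`,
#'   `L0_true`, `Y0`, `L0`, `n_detected`, `converged`.
#' @export
run_recovery_scene <- function(w0, decay_length_um, seed,
                               n_fibers = 20000,
                               route = c("render", "truth"),
                               weights = "inverse_se",
                               image_size_px = c(4500, 4500)) {
  route <- match.arg(route)
  p <- fiber_field_params(image_size_px = image_size_px,
                          pixel_size_um = recovery_pixel_size(decay_length_um),
                          tumor_radius_um = 100,
                          n_fibers = n_fibers,
                          fiber_length_px_mean = 25, fiber_length_px_sd = 4,
                          radial_bias_w0 = w0,
                          decay_length_um = decay_length_um,
                          background_noise_sigma = 0.02,
                          seed = seed)
  field <- generate_fiber_field(p)
  fibers <- if (route == "render") {
    extract_fibers(render_reflection_image(field, p))
  } else field
  prof <- bin_profile(fibers, p$tumor_center_px, p$tumor_radius_um,
                      p$pixel_size_um)
  fit <- fit_exponential(prof, weights = weights)
  data.frame(w0 = w0, decay_length_um = decay_length_um, seed = seed,
             Y0_true = 0.5 + 0.5 * w0, L0_true = decay_length_um,
             Y0 = fit$Y0, L0 = fit$L0,
             n_detected = nrow(fibers), converged = fit$converged)
}

#' Parameter-recovery experiment over a (w0, lambda) grid
#'
#' Runs [run_recovery_scene()] for every requested scene, assigning seeds
#' round-robin over the grid cells, and appends relative recovery errors.
#'
#' @param w0_grid,lambda_grid grids of mixture weights and decay lengths.
#' @param seeds integer vector of scene seeds; seed `i` runs in grid cell
#'   `(i - 1) %% (length(w0_grid) * length(lambda_grid)) + 1`.
#' @inheritParams run_recovery_scene
#' @return Data frame with one row per scene, including `rel_err_Y0` and
#'   `rel_err_L0`.
#' @export
recovery_grid <- function(w0_grid = c(0.2, 0.5, 0.8),
                          lambda_grid = c(200, 500, 1000),
                          seeds = 1:20, n_fibers = 20000,
                          route = c("render", "truth")) {
  route <- match.arg(route)
  cells <- expand.grid(w0 = w0_grid, lambda = lambda_grid)
  rows <- lapply(seq_along(seeds), function(i) {
    cell <- cells[(i - 1) %% nrow(cells) + 1, ]
    run_recovery_scene(cell$w0, cell$lambda, seeds[i], n_fibers,
                       route = route)
  })
  out <- do.call(rbind, rows)
  out$rel_err_Y0 <- (out$Y0 - out$Y0_true) / out$Y0_true
  out$rel_err_L0 <- (out$L0 - out$L0_true) / out$L0_true
  out
}
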