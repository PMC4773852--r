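# Brute-force oracles and small fixture builders, independent of the
# package's vectorized/compiled implementations.

# symmetric (edge-repeating) reflective index, 1-based
refl_idx <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

# double-loop local disc mean with reflective padding
brute_disc_mean <- function(image, r) {
  nx <- nrow(image); ny <- ncol(image)
  out <- matrix(0, nx, ny)
  offs <- expand.grid(dx = -r:r, dy = -r:r)
  offs <- offs[offs$dx^2 + offs$dy^2 <= r^2, ]
  for (x in 1:nx) for (y in 1:ny) {
    acc <- 0
    for (k in seq_len(nrow(offs))) {
      acc <- acc + image[refl_idx(x + offs$dx[k], nx),
                         refl_idx(y + offs$dy[k], ny)]
    }
    out[x, y] <- acc / nrow(offs)
  }
  out
}

# per-pixel rolling-ball mask: squared intensity > local mean + k * local
# population sd of squared intensity over the disc neighbourhood
brute_rollingball <- function(image, r = 5, k = 0.5) {
  sq <- image^2
  nx <- nrow(sq); ny <- ncol(sq)
  out <- matrix(FALSE, nx, ny)
  offs <- expand.grid(dx = -r:r, dy = -r:r)
  offs <- offs[offs$dx^2 + offs$dy^2 <= r^2, ]
  for (x in 1:nx) for (y in 1:ny) {
    vals <- numeric(nrow(offs))
    for (kk in seq_len(nrow(offs)))
      vals[kk] <- sq[refl_idx(x + offs$dx[kk], nx),
                     refl_idx(y + offs$dy[kk], ny)]
    m <- mean(vals)
    s <- sqrt(mean((vals - m)^2))
    out[x, y] <- sq[x, y] > m + k * s
  }
  out
}

# Mann-Whitney U by pair counting, and exact two-sided p by exhaustive
# enumeration of group labelings
brute_U <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

brute_U_pvalue <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  obs <- brute_U(x, y)
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, function(idx)
    brute_U(pooled[idx], pooled[-idx]))
  mu <- n1 * (length(pooled) - n1) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

# render one fiber and return the rendered image plus its params
render_single_fiber <- function(angle_deg, length_px = 30, size = 96,
                                noise = 0) {
  p <- fiber_field_params(image_size_px = c(size, size), pixel_size_um = 1,
                          tumor_center_px = c(0, 0), tumor_radius_um = 0,
                          n_fibers = 1, background_noise_sigma = noise,
                          seed = 1)
  fib <- data.frame(centroid_x_px = (size - 1) / 2,
                    centroid_y_px = (size - 1) / 2,
                    angle_deg = angle_deg, length_px = length_px)
  list(image = render_reflection_image(fib, p), params = p, fibers = fib)
}

# orientation profile object built directly from bin data
make_profile <- function(mid, mean_cos2, n = 500, sd = 0.35) {
  half <- (mid[2] - mid[1]) / 2
  out <- data.frame(bin_lo_um = mid - half, bin_hi_um = mid + half,
                    bin_mid_um = mid, mean_cos2 = mean_cos2,
                    sd_cos2 = sd, n_fibers = n)
  class(out) <- c("orientation_profile", "data.frame")
  out
}

# true disk mask
disk_mask <- function(size, center, radius) {
  xs <- matrix(0:(size - 1), size, size)
  ys <- t(xs)
  sqrt((xs - center[1])^2 + (ys - center[2])^2) <= radius
}
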