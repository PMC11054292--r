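# Shared desk-scale objects: a miniature z range keeps the calibration
# library small (8 positions x 2 classes) so most tests run in milliseconds.
mini_optical <- function(seed = 7L, noise_sd = 0.02) {
  optical_config(z_min = -2, z_max = 2, z_step = 0.5, noise_sd = noise_sd,
                 seed = seed)
}

mini_classes <- default_bead_classes()

mini_library <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_calibration_library(mini_classes,
                                                            mini_optical())
    cache
  }
})

# An isotropic Gaussian spot on an arbitrary grid, for localization tests.
gaussian_spot <- function(n, cx, cy, sigma = 3, amp = 0.8, bg = 0.1) {
  xy <- seq_len(n) - 1
  r2 <- outer((xy - cy)^2, (xy - cx)^2, "+")
  bg + amp * exp(-r2 / (2 * sigma^2))
}

# Brute-force oracle for the radial-symmetry objective: evaluate the exact
# weighted sum of squared line distances on a 0.01-px grid (via the
# quadratic sufficient statistics) and return the grid argmin.
grid_search_center <- function(pixels, window = 1.5, step = 0.01) {
  H <- nrow(pixels); W <- ncol(pixels)
  a <- pixels[-H, -W]; b <- pixels[-H, -1]
  c_ <- pixels[-1, -W]; d <- pixels[-1, -1]
  gx <- defocustrack:::boxcar3((b + d - a - c_) / 2)
  gy <- defocustrack:::boxcar3((c_ + d - a - b) / 2)
  mag2 <- gx^2 + gy^2
  xm <- matrix(seq_len(W - 1) - 0.5, H - 1, W - 1, byrow = TRUE)
  ym <- matrix(seq_len(H - 1) - 0.5, H - 1, W - 1)
  x0 <- sum(xm * mag2) / sum(mag2); y0 <- sum(ym * mag2) / sum(mag2)
  wgt <- mag2 / pmax(sqrt((xm - x0)^2 + (ym - y0)^2), 0.5)
  co <- defocustrack:::radial_objective_coeffs(gx, gy, xm, ym, wgt)
  # objective(xc, yc) = Saa xc^2 + 2 Sab xc yc + Sbb yc^2
  #                     - 2 Sac xc - 2 Sbc yc + Scc
  xs <- seq(x0 - window, x0 + window, by = step)
  ys <- seq(y0 - window, y0 + window, by = step)
  obj <- outer(ys, xs, function(yc, xc)
    co$Saa * xc^2 + 2 * co$Sab * xc * yc + co$Sbb * yc^2 -
      2 * co$Sac * xc - 2 * co$Sbc * yc + co$Scc)
  k <- arrayInd(which.min(obj), dim(obj))
  c(x = xs[k[2]], y = ys[k[1]])
}

# Brute-force assignment oracle: minimal-total-cost one-to-one matching by
# exhaustive permutation (n <= 6).
brute_force_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m, n <= 6)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- NULL; best_cost <- Inf
  for (p in perms(seq_len(m))) {
    sel <- p[seq_len(n)]
    tc <- sum(cost[cbind(seq_len(n), sel)])
    if (tc < best_cost) { best_cost <- tc; best <- sel }
  }
  list(assignment = best, cost = best_cost)
}

# Random well-separated annotation sets for codec round-trip tests.
random_annotations <- function(n, image_size, classes, z_grid,
                               min_sep = 80) {
  pts <- matrix(numeric(0), 0, 2)
  while (nrow(pts) < n) {
    cand <- runif(2, 40, image_size - 41)
    if (nrow(pts) == 0 ||
        min(sqrt(colSums((t(pts) - cand)^2))) >= min_sep)
      pts <- rbind(pts, cand)
  }
  data.frame(particle_id = seq_len(n),
             class = sample(names(classes), n, replace = TRUE),
             x_px = pts[, 1], y_px = pts[, 2],
             z_um = sample(z_grid, n, replace = TRUE))
}
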