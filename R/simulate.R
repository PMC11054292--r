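#' Render a single-bead defocus pattern
#'
#' Parametric model of the ringed diffraction pattern a bead produces under
#' wide-field illumination at signed defocus `z`:
#'
#' \deqn{I(r, z) = B + A(z)\, e^{-r^2 / 2 w(|z|)^2}
#'       \left[1 + m(z) \cos(2\pi f(|z|)\, r)\right]}
#'
#' with envelope width \eqn{w} and ring frequency \eqn{f} affine in `|z|`,
#' amplitude \eqn{A(z) = A_0 w(0)/w(|z|)} (energy spreads as the pattern
#' defocuses), and modulation depth \eqn{m(z) = m_0 \tanh(z / z_0)} odd in
#' `z`.  The odd contrast term flips the ring polarity across the focal
#' plane, which is what makes above-focus and below-focus patterns
#' distinguishable under wide-field illumination.  At `z = 0` the pattern is
#' a plain Gaussian spot, the most compact the class produces.
#'
#' Coordinates are 0-based with pixel centers at integers; the default
#' pattern center is the geometric patch center `(P - 1)/2`.
#'
#' @param bead a [bead_class()].
#' @param z signed defocus in micrometres; must lie in
#'   `[config$z_min, config$z_max]`.
#' @param config an [optical_config()].
#' @param center optional length-2 numeric `(x, y)` sub-pixel pattern center
#'   within the patch; defaults to the geometric center.
#' @param noise_sd additive Gaussian noise sd (fraction of dynamic range);
#'   default 0 renders the noise-free component.  Noise draws come from the
#'   current RNG state.
#' @return A `feature_patch`: list with `pixels` (patch matrix in `[0, 1]`,
#'   rows = y), `z`, `class` (label), and `center` (`c(x, y)`).
#' @export
simulate_bead_pattern <- function(bead, z, config, center = NULL,
                                  noise_sd = 0) {
  stopifnot(inherits(bead, "bead_class"), inherits(config, "optical_config"))
  if (z < config$z_min - 1e-9 || z > config$z_max + 1e-9)
    stop(sprintf("z = %g um outside calibrated range [%g, %g]",
                 z, config$z_min, config$z_max))
  P <- bead$patch_size_px
  if (is.null(center)) center <- c((P - 1) / 2, (P - 1) / 2)
  stopifnot(length(center) == 2, all(center > 0), all(center < P - 1))
  p <- bead$pattern
  w <- pattern_width_px(bead, z)
  f <- p$freq0 + p$freq_slope * abs(z)
  m <- p$contrast * tanh(z / p$contrast_zscale)
  amp <- p$amp * p$width0 / w

  xy <- seq_len(P) - 1
  r <- sqrt(outer((xy - center[2])^2, (xy - center[1])^2, "+"))  # rows = y
  img <- p$background +
    amp * exp(-r^2 / (2 * w^2)) * (1 + m * cos(2 * pi * f * r))
  if (noise_sd > 0)
    img <- img + matrix(rnorm(P * P, sd = noise_sd), P, P)
  img <- pmin(pmax(img, 0), 1)
  structure(list(pixels = img, z = z, class = bead$label, center = center),
            class = "feature_patch")
}

#' Build a calibration library of feature patches
#'
#' One noise-free feature patch is rendered per (bead class, z-grid
#' position), emulating a piezo z-scan of immobilized beads.  Each patch's
#' true pattern center is jittered sub-pixel (uniform in +/- 0.5 px, from a
#' per-patch RNG substream of `config$seed`) so that the library spans the
#' sub-pixel phase space, and the stored `center` field is *measured* from
#' the rendered pattern with [radial_symmetry_center()], as one would
#' calibrate real crops.  With the default two classes and the default
#' 400-position grid the library holds 800 patches.
#'
#' @param classes non-empty named list of [bead_class()] objects.
#' @param config an [optical_config()].
#' @param jitter logical; set `FALSE` to pin every pattern at the geometric
#'   patch center.
#' @return A `calibration_library`: list with `patches` (list indexed
#'   `[[class]][[k]]` of `feature_patch`), `z_grid`, `classes`, `config`.
#' @export
build_calibration_library <- function(classes, config, jitter = TRUE) {
  stopifnot(inherits(config, "optical_config"))
  if (length(classes) == 0) stop("`classes` must be a non-empty list")
  stopifnot(all(vapply(classes, inherits, TRUE, "bead_class")))
  labels <- vapply(classes, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("duplicate bead class labels")
  names(classes) <- labels
  z_grid <- make_z_grid(config$z_min, config$z_max, config$z_step)
  patches <- lapply(classes, function(bead) {
    P <- bead$patch_size_px
    nominal <- (P - 1) / 2
    lapply(seq_along(z_grid), function(k) {
      ctr <- if (jitter) {
        s <- substream_seed(config$seed, sprintf("calib/%s/%d", bead$label, k))
        nominal + with_seed(s, runif(2, -0.5, 0.5))
      } else c(nominal, nominal)
      patch <- simulate_bead_pattern(bead, z_grid[k], config, center = ctr)
      patch$center <- radial_symmetry_center(patch$pixels)
      patch
    })
  })
  structure(list(patches = patches, z_grid = z_grid, classes = classes,
                 config = config),
            class = "calibration_library")
}

#' @export
print.calibration_library <- function(x, ...) {
  cat(sprintf("<calibration_library> %d classes x %d z positions = %d patches\n",
              length(x$classes), length(x$z_grid), library_size(x)))
  invisible(x)
}

#' Number of patches in a calibration library
#' @param library a `calibration_library`.
#' @return Integer patch count (classes x z positions).
#' @export
library_size <- function(library) {
  sum(vapply(library$patches, length, 0L))
}

#' Sub-pixel center by radial symmetry of intensity gradients
#'
#' Locates the center of a radially symmetric spot as the point minimizing
#' the weighted sum of squared perpendicular distances to the lines through
#' each inter-pixel midpoint along the local intensity gradient (for a
#' radially symmetric pattern every gradient line passes through the
#' center).  Gradients are computed on the 2x2 inter-pixel midpoint grid,
#' smoothed with a 3x3 boxcar; weights are the smoothed squared gradient
#' magnitude divided by the midpoint's distance to a rough
#' magnitude-weighted centroid.  The weighted least-squares solution is
#' closed-form.
#'
#' @param pixels numeric matrix (rows = y), at least 5x5.
#' @return `c(x, y)` sub-pixel center, 0-based pixel-center coordinates.
#' @export
radial_symmetry_center <- function(pixels) {
  stopifnot(is.matrix(pixels), nrow(pixels) >= 5, ncol(pixels) >= 5,
            all(is.finite(pixels)))
  H <- nrow(pixels); W <- ncol(pixels)
  # 2x2 gradient at midpoints (i + 0.5, j + 0.5), 0-based
  a <- pixels[-H, -W]; b <- pixels[-H, -1]   # (i,j), (i,j+1)
  c_ <- pixels[-1, -W]; d <- pixels[-1, -1]  # (i+1,j), (i+1,j+1)
  gx <- (b + d - a - c_) / 2
  gy <- (c_ + d - a - b) / 2
  gx <- boxcar3(gx); gy <- boxcar3(gy)
  mag2 <- gx^2 + gy^2
  if (max(mag2) <= 0)
    stop("degenerate input: image has no intensity gradients")
  xm <- matrix(seq_len(W - 1) - 0.5, H - 1, W - 1, byrow = TRUE)
  ym <- matrix(seq_len(H - 1) - 0.5, H - 1, W - 1)
  # rough centroid of gradient magnitude, for distance weighting
  x0 <- sum(xm * mag2) / sum(mag2)
  y0 <- sum(ym * mag2) / sum(mag2)
  dist0 <- sqrt((xm - x0)^2 + (ym - y0)^2)
  wgt <- mag2 / pmax(dist0, 0.5)
  co <- radial_objective_coeffs(gx, gy, xm, ym, wgt)
  denom <- co$Saa * co$Sbb - co$Sab^2
  if (abs(denom) < 1e-12 * max(co$Saa, co$Sbb, 1e-300))
    stop("degenerate input: gradient directions do not intersect")
  xc <- (co$Sac * co$Sbb - co$Sbc * co$Sab) / denom
  yc <- (co$Sbc * co$Saa - co$Sac * co$Sab) / denom
  if (xc < 0 || xc > W - 1 || yc < 0 || yc > H - 1)
    stop("radial symmetry center fell outside the grid")
  c(x = xc, y = yc)
}

# Sufficient statistics of the radial-symmetry objective
#   sum_k W_k (a_k x + b_k y - c_k)^2,  a = gy, b = -gx, c = gy*xm - gx*ym,
# with W_k = wgt_k / (gx^2 + gy^2).  Shared by the solver above and by the
# brute-force grid-search oracle in the tests.
radial_objective_coeffs <- function(gx, gy, xm, ym, wgt) {
  mag2 <- gx^2 + gy^2
  Wk <- ifelse(mag2 > 0, wgt / mag2, 0)
  a <- gy; b <- -gx; cc <- gy * xm - gx * ym
  list(Saa = sum(Wk * a * a), Sbb = sum(Wk * b * b), Sab = sum(Wk * a * b),
       Sac = sum(Wk * a * cc), Sbc = sum(Wk * b * cc), Scc = sum(Wk * cc * cc))
}

# 3x3 boxcar smoothing with edge replication.
boxcar3 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  pad <- m[c(1, seq_len(H), H), c(1, seq_len(W), W)]
  out <- matrix(0, H, W)
  for (di in 0:2) for (dj in 0:2)
    out <- out + pad[di + seq_len(H), dj + seq_len(W)]
  out / 9
}

#' Normalized cross-correlation of two equal-size patches
#' @param a,b numeric matrices of identical dimension.
#' @return Pearson correlation of the flattened intensities.
#' @export
patch_ncc <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  stats::cor(as.vector(a), as.vector(b))
}

#' Radial second moment of a background-subtracted pattern
#'
#' Intensity-weighted mean squared radius about the pattern center, a scalar
#' summary of pattern spread that grows monotonically with |z| for the
#' parametric defocus model.
#'
#' @param pixels patch matrix.
#' @param center `c(x, y)` center; defaults to the geometric patch center.
#' @param background baseline intensity subtracted before weighting
#'   (negative residuals are clipped to zero).
#' @return Mean squared radius in px^2.
#' @export
radial_second_moment <- function(pixels, center = NULL, background = 0) {
  H <- nrow(pixels); W <- ncol(pixels)
  if (is.null(center)) center <- c((W - 1) / 2, (H - 1) / 2)
  wts <- pmax(pixels - background, 0)
  x <- matrix(seq_len(W) - 1, H, W, byrow = TRUE)
  y <- matrix(seq_len(H) - 1, H, W)
  r2 <- (x - center[1])^2 + (y - center[2])^2
  sum(wts * r2) / sum(wts)
}

#' Write a calibration library to disk
#'
#' Persists one 16-bit grayscale TIFF per patch plus an `index.csv` with
#' columns `class,z_um,patch_file,center_x_px,center_y_px`.
#'
#' @param library a `calibration_library`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_calibration_library <- function(library, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (lab in names(library$patches)) {
    for (k in seq_along(library$patches[[lab]])) {
      patch <- library$patches[[lab]][[k]]
      file <- sprintf("%s_%04d.tiff", lab, k)
      write_gray_image(patch$pixels, file.path(dir, file),
                       bit_depth = library$config$bit_depth)
      rows[[length(rows) + 1]] <- data.frame(
        class = lab, z_um = patch$z, patch_file = file,
        center_x_px = patch$center[1], center_y_px = patch$center[2])
    }
  }
  idx <- do.call(rbind, rows)
  write.csv(idx, file.path(dir, "index.csv"), row.names = FALSE)
  saveRDS(list(z_grid = library$z_grid, classes = library$classes,
               config = library$config),
          file.path(dir, "library_meta.rds"))
  invisible(dir)
}

#' Read a calibration library written by [write_calibration_library()]
#' @param dir directory containing `index.csv` and the patch TIFFs.
#' @return A `calibration_library`.
#' @export
read_calibration_library <- function(dir) {
  idx <- read.csv(file.path(dir, "index.csv"), stringsAsFactors = FALSE)
  meta <- readRDS(file.path(dir, "library_meta.rds"))
  patches <- lapply(split(idx, idx$class), function(rows) {
    rows <- rows[order(rows$z_um), ]
    lapply(seq_len(nrow(rows)), function(i) {
      structure(list(
        pixels = read_gray_image(file.path(dir, rows$patch_file[i])),
        z = rows$z_um[i], class = rows$class[i],
        center = c(x = rows$center_x_px[i], y = rows$center_y_px[i])),
        class = "feature_patch")
    })
  })
  patches <- patches[names(meta$classes)]
  structure(list(patches = patches, z_grid = meta$z_grid,
                 classes = meta$classes, config = meta$config),
            class = "calibration_library")
}
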