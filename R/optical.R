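#' Optical configuration for simulation and encoding
#'
#' Bundles the acquisition geometry used throughout the package: the camera
#' pixel scale, the signed axial (z) calibration range and step, the additive
#' noise level, and the root RNG seed.  The defaults correspond to the
#' wide-field bead-tracking geometry the package targets: 23.3 nm per pixel
#' and a piezo z-scan from 10 um below to 10 um above the focal plane in
#' 50 nm steps.
#'
#' @param pixel_scale_um physical size of one camera pixel, in micrometres.
#' @param z_min,z_max signed axial range in micrometres (negative = below
#'   focus).
#' @param z_step axial calibration increment in micrometres.
#' @param noise_sd standard deviation of additive Gaussian noise, as a
#'   fraction of the intensity dynamic range `[0, 1]`.
#' @param bit_depth camera bit depth used when patches/scenes are written to
#'   disk (images are held in `[0, 1]` doubles in memory).
#' @param seed integer root RNG seed; all stochastic operations derive named
#'   substreams from it via [substream_seed()].
#' @return An object of class `optical_config`.
#' @export
optical_config <- function(pixel_scale_um = 0.0233,
                           z_min = -10, z_max = 10, z_step = 0.05,
                           noise_sd = 0.02, bit_depth = 16L, seed = 1L) {
  stopifnot(pixel_scale_um > 0, noise_sd >= 0, bit_depth %in% c(8L, 16L))
  if (!(z_min < z_max)) stop("optical.z_min must be smaller than optical.z_max")
  if (!(z_step > 0)) stop("optical.z_step must be positive, got ", z_step)
  cfg <- structure(list(
    pixel_scale_um = pixel_scale_um, z_min = z_min, z_max = z_max,
    z_step = z_step, noise_sd = noise_sd, bit_depth = as.integer(bit_depth),
    seed = as.integer(seed)
  ), class = "optical_config")
  make_z_grid(z_min, z_max, z_step)  # validates divisibility
  cfg
}

#' @export
print.optical_config <- function(x, ...) {
  cat(sprintf(
    "<optical_config> %.4g um/px, z in [%g, %g] um step %g um (%d positions), noise sd %g, seed %d\n",
    x$pixel_scale_um, x$z_min, x$z_max, x$z_step,
    length(make_z_grid(x$z_min, x$z_max, x$z_step)), x$noise_sd, x$seed))
  invisible(x)
}

#' Axial calibration grid
#'
#' Divides the signed defocus range into uniform segments and returns the
#' segment-start positions: `z_min + k * z_step` for
#' `k = 0, ..., (z_max - z_min)/z_step - 1`.  The upper endpoint is excluded,
#' so the default 20 um range at a 50 nm step yields exactly 400 positions.
#'
#' @param z_min,z_max signed axial range in micrometres.
#' @param z_step axial increment in micrometres; the range must be an integer
#'   multiple of it.
#' @return Numeric vector of strictly increasing z positions (um).
#' @export
make_z_grid <- function(z_min, z_max, z_step) {
  stopifnot(z_min < z_max, z_step > 0)
  n <- round((z_max - z_min) / z_step)
  rem <- abs(n * z_step - (z_max - z_min))
  if (rem > 1e-9) {
    stop(sprintf(
      "z range [%g, %g] is not an integer multiple of z_step = %g (remainder %.3g um)",
      z_min, z_max, z_step, rem))
  }
  z_min + (seq_len(n) - 1) * z_step
}

#' Bead size class
#'
#' Describes one particle size class: its physical radius, the patch size its
#' defocus pattern is rendered into, and the parameters of the parametric
#' defocus-ring model (see [simulate_bead_pattern()]).
#'
#' @param label class label, conventionally `"small"` or `"big"`.
#' @param radius_um bead radius in micrometres.
#' @param patch_size_px edge length (pixels) of the square feature patch.
#' @param pattern named list of pattern-model parameters: `amp` (peak
#'   amplitude at focus), `background` (baseline intensity), `width0` /
#'   `width_slope` (Gaussian envelope width in px at focus and its growth per
#'   um of defocus), `freq0` / `freq_slope` (ring frequency in cycles/px and
#'   its change per um), `contrast` (maximal ring modulation depth) and
#'   `contrast_zscale` (um scale of the odd-in-z contrast term that makes
#'   above-focus and below-focus patterns distinguishable).
#' @return An object of class `bead_class`.
#' @export
bead_class <- function(label, radius_um, patch_size_px, pattern = list()) {
  stopifnot(is.character(label), length(label) == 1, radius_um > 0,
            patch_size_px >= 8)
  defaults <- list(amp = 0.6, background = 0.15, width0 = 3, width_slope = 2.2,
                   freq0 = 0.12, freq_slope = 0.01, contrast = 0.5,
                   contrast_zscale = 2)
  unknown <- setdiff(names(pattern), names(defaults))
  if (length(unknown))
    stop("unknown pattern parameter(s): ", paste(unknown, collapse = ", "))
  structure(list(label = label, radius_um = radius_um,
                 patch_size_px = as.integer(patch_size_px),
                 pattern = modifyList(defaults, pattern)),
            class = "bead_class")
}

#' Default bead classes
#'
#' The two polystyrene bead classes the system is calibrated for: radii 1 um
#' ("small") and 2 um ("big").  The big bead gets a larger patch and a wider,
#' coarser ring pattern so its defocus halo at |z| = 10 um still fits inside
#' the patch.
#'
#' @return Named list of two [bead_class()] objects (`small`, `big`).
#' @export
default_bead_classes <- function() {
  list(
    small = bead_class("small", radius_um = 1, patch_size_px = 64,
                       pattern = list(amp = 0.6, width0 = 3, width_slope = 2.2,
                                      freq0 = 0.12, freq_slope = 0.010)),
    big = bead_class("big", radius_um = 2, patch_size_px = 96,
                     pattern = list(amp = 0.7, width0 = 5, width_slope = 3.0,
                                    freq0 = 0.08, freq_slope = 0.008))
  )
}

# Envelope width (px) of a class's pattern at signed defocus z (um).
pattern_width_px <- function(bead, z) {
  bead$pattern$width0 + bead$pattern$width_slope * abs(z)
}

# Effective footprint radius (px) of the rendered pattern: the envelope is
# negligible beyond ~2.5 widths, clipped to the patch half-size.
pattern_footprint_px <- function(bead, z) {
  min(bead$patch_size_px / 2, 2.5 * pattern_width_px(bead, z))
}
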