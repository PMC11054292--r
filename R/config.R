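#' Default run configuration
#'
#' The full nested configuration tree used by the command-line interface
#' and [make_fixture()]: optics, bead classes, scene composition, network,
#' training, evaluation and tracking sections, plus the root seed.  Any
#' subset may be overridden from a YAML file via [load_config()]; unknown
#' keys are rejected.
#'
#' @return Nested list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    seed = 1L,
    optical = list(pixel_scale_um = 0.0233, z_min = -10, z_max = 10,
                   z_step = 0.05, noise_sd = 0.02, bit_depth = 16L),
    beads = lapply(default_bead_classes(), function(b)
      list(radius_um = b$radius_um, patch_size_px = b$patch_size_px,
           pattern = b$pattern)),
    compose = list(size_min = 950L, size_max = 1050L,
                   n_particles_min = 3L, n_particles_max = 8L,
                   background_level = 0.15,
                   split_train = 0.7, split_eval = 0.3),
    net = list(backbone = "tiny", input_size = 256L),
    train = list(epochs = 60L, batch_size = 4L, lr = 1e-3,
                 flip_augment = TRUE),
    eval = list(gate_um = 2, score_threshold = 0.3, top_k = 100L),
    track = list(max_disp_px = 10, max_misses = 3L, global = FALSE,
                 frame_interval_s = 0.1)
  ), class = "run_config")
}

#' Load and validate a run configuration from YAML
#'
#' Reads a (possibly partial) YAML document, fills in defaults from
#' [default_run_config()], and validates: unknown keys, type mismatches
#' and constraint violations are each reported with the full key path
#' (e.g. `optical.z_step`).  A loaded configuration re-serializes with
#' [dump_config()] to an equivalent document.
#'
#' @param path YAML file path.
#' @return A validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(default_run_config(), user, "")
  validate_config(cfg)
  cfg
}

merge_config <- function(template, user, path) {
  if (!is.list(user)) {
    stop(sprintf("config entry '%s' must be a section, got a scalar",
                 sub("^\\.", "", path)))
  }
  unknown <- setdiff(names(user), names(template))
  if (length(unknown))
    stop(sprintf("unknown config key '%s'",
                 sub("^\\.", "", paste0(path, ".", unknown[1]))))
  for (nm in names(user)) {
    here <- paste0(path, ".", nm)
    if (is.list(template[[nm]])) {
      template[[nm]] <- merge_config(template[[nm]], user[[nm]], here)
    } else {
      v <- user[[nm]]
      if (!is.null(template[[nm]])) {
        want_num <- is.numeric(template[[nm]])
        want_chr <- is.character(template[[nm]])
        want_lgl <- is.logical(template[[nm]])
        ok <- (want_num && is.numeric(v)) || (want_chr && is.character(v)) ||
          (want_lgl && is.logical(v))
        if (!ok)
          stop(sprintf("config key '%s' has wrong type (expected %s)",
                       sub("^\\.", "", here),
                       if (want_num) "number" else if (want_chr) "string"
                       else "logical"))
      }
      template[[nm]] <- v
    }
  }
  template
}

validate_config <- function(cfg) {
  fail <- function(key, msg) stop(sprintf("invalid config: %s %s", key, msg))
  o <- cfg$optical
  if (o$z_step <= 0) fail("optical.z_step", "must be positive")
  if (o$z_min >= o$z_max) fail("optical.z_min", "must be below optical.z_max")
  if (o$pixel_scale_um <= 0) fail("optical.pixel_scale_um", "must be positive")
  if (o$noise_sd < 0) fail("optical.noise_sd", "must be non-negative")
  tryCatch(make_z_grid(o$z_min, o$z_max, o$z_step),
           error = function(e) fail("optical.z_step", conditionMessage(e)))
  for (nm in names(cfg$beads))
    if (cfg$beads[[nm]]$radius_um <= 0)
      fail(paste0("beads.", nm, ".radius_um"), "must be positive")
  if (cfg$compose$size_min > cfg$compose$size_max)
    fail("compose.size_min", "must not exceed compose.size_max")
  sf <- cfg$compose$split_train + cfg$compose$split_eval
  if (abs(sf - 1) > 1e-9) fail("compose.split_train", "splits must sum to 1")
  if (cfg$net$input_size %% 32 != 0)
    fail("net.input_size", "must be divisible by 32")
  if (cfg$train$epochs < 1) fail("train.epochs", "must be >= 1")
  if (cfg$track$max_disp_px <= 0) fail("track.max_disp_px", "must be positive")
  invisible(cfg)
}

#' @rdname load_config
#' @param config a `run_config`.
#' @export
dump_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 12)
  invisible(path)
}

#' Build the package objects described by a run configuration
#' @param config a `run_config`.
#' @return List with `optical` ([optical_config()]) and `classes`
#'   (named [bead_class()] list).
#' @export
config_objects <- function(config) {
  optical <- optical_config(
    pixel_scale_um = config$optical$pixel_scale_um,
    z_min = config$optical$z_min, z_max = config$optical$z_max,
    z_step = config$optical$z_step, noise_sd = config$optical$noise_sd,
    bit_depth = config$optical$bit_depth, seed = config$seed)
  classes <- lapply(names(config$beads), function(nm)
    bead_class(nm, config$beads[[nm]]$radius_um,
               config$beads[[nm]]$patch_size_px, config$beads[[nm]]$pattern))
  names(classes) <- names(config$beads)
  list(optical = optical, classes = classes)
}
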