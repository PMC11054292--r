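# Desk-scale fixture settings shared by the test suite and examples:
# a miniature z range so fixture generation stays in seconds.
fixture_optical <- function(seed = 7L) {
  optical_config(z_min = -2, z_max = 2, z_step = 0.5, noise_sd = 0.02,
                 seed = seed)
}

#' Generate a small deterministic on-disk fixture
#'
#' Reproducible desk-scale inputs binding the modules together:
#' \describe{
#'   \item{`calib`}{a 2-class mini calibration library (z in `[-2, 2]` um,
#'     0.5 um step: 8 positions x 2 classes = 16 patches) written as
#'     TIFF + index CSV.}
#'   \item{`dataset`}{a 12-scene composed dataset (256 px scenes, 1-4
#'     particles) with train/eval splits, annotation CSVs and manifest.}
#'   \item{`video`}{a 30-frame stepped-z video of one bead per class (6
#'     stage levels x 5 frames), with per-frame truth CSV and a stage
#'     profile YAML.}
#'   \item{`ideal_maps`}{one composed scene plus its exactly-encoded
#'     target maps (RDS), for codec experiments.}
#' }
#'
#' @param kind one of `"calib"`, `"dataset"`, `"video"`, `"ideal_maps"`.
#' @param seed integer seed; identical seeds give byte-identical fixtures.
#' @param dir output directory.
#' @return `dir`, invisibly (with fixture-specific files inside).
#' @export
make_fixture <- function(kind = c("calib", "dataset", "video", "ideal_maps"),
                         seed = 7L, dir = tempfile("fixture_")) {
  kind <- match.arg(kind)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  optical <- fixture_optical(seed)
  classes <- default_bead_classes()
  lib <- build_calibration_library(classes, optical)
  switch(kind,
    calib = write_calibration_library(lib, dir),
    dataset = build_dataset(lib, n_images = 12, out_dir = dir,
                            size_range = c(256, 256),
                            n_particles_range = c(1, 4),
                            split_fractions = c(train = 0.75, eval = 0.25),
                            seed = seed),
    video = {
      prof <- stage_profile(c(-2, -1, -0.5, 0, 0.5, 1), frames_per_level = 5)
      render_stepped_video(lib, prof, dir, seed = seed)
    },
    ideal_maps = {
      scene <- compose_scene(lib, n_particles = 3, image_size = 256,
                             seed = substream_seed(seed, "ideal-scene"))
      write_gray_image(scene$pixels, file.path(dir, "scene.tiff"))
      write.csv(scene$annotations, file.path(dir, "scene_annotations.csv"),
                row.names = FALSE)
      maps <- encode_targets(scene$annotations, 256, 4L, classes, optical)
      saveRDS(maps, file.path(dir, "ideal_maps.rds"))
      dir
    })
  invisible(dir)
}

#' Render a stepped-z validation video
#'
#' One immobilized bead per class is rendered at a fixed xy position while
#' the commanded stage offset steps through a [stage_profile()]; each
#' bead's z is its base z plus the level offset (snapped to the calibration
#' grid).  Writes `frames.tiff` (multi-page), `truth.csv` (per-frame
#' ground-truth positions) and `stage_profile.yaml`.
#'
#' @param library a `calibration_library`.
#' @param profile a [stage_profile()]; offsets must keep base + offset
#'   inside the calibrated z range.
#' @param dir output directory.
#' @param image_size frame edge length (px).
#' @param base_z_um base bead depth at zero offset.
#' @param jitter_px per-frame xy jitter sd emulating residual motion.
#' @param seed RNG seed.
#' @return `dir`, invisibly.
#' @export
render_stepped_video <- function(library, profile, dir, image_size = 256L,
                                 base_z_um = 0, jitter_px = 0.3, seed = 7L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  optical <- library$config
  labels <- names(library$patches)
  n_frames <- max(profile$frame_end)
  # fixed, well-separated anchor positions per class
  anchors <- with_seed(substream_seed(seed, "video-anchors"), {
    qs <- seq(0.3, 0.7, length.out = length(labels))
    lapply(seq_along(labels), function(i)
      c(x = image_size * qs[i],
        y = image_size * qs[length(labels) + 1 - i]) +
        runif(2, -8, 8))
  })
  z_grid <- library$z_grid
  frames <- vector("list", n_frames)
  truth <- list()
  for (f in seq_len(n_frames)) {
    lvl <- profile$level[profile$frame_start <= f & f <= profile$frame_end][1]
    img <- matrix(0.15, image_size, image_size)
    fs <- substream_seed(seed, sprintf("video-frame/%d", f))
    jit <- with_seed(fs, matrix(rnorm(2 * length(labels), sd = jitter_px), 2))
    for (i in seq_along(labels)) {
      lab <- labels[i]
      z_cmd <- base_z_um + profile$offset_um[lvl]
      k <- which.min(abs(z_grid - z_cmd))      # snap to calibration grid
      patch <- library$patches[[lab]][[k]]
      P <- nrow(patch$pixels)
      ctr <- c(anchors[[i]][1] + jit[1, i], anchors[[i]][2] + jit[2, i])
      tl <- round(ctr - patch$center)          # integer placement
      placed <- patch$center + tl
      rows <- tl[2] + seq_len(P); cols <- tl[1] + seq_len(P)
      stopifnot(all(rows >= 1), all(rows <= image_size),
                all(cols >= 1), all(cols <= image_size))
      img[rows, cols] <- img[rows, cols] +
        (patch$pixels - library$classes[[lab]]$pattern$background)
      truth[[length(truth) + 1]] <- data.frame(
        frame = f, class = lab, x_px = unname(placed[1]),
        y_px = unname(placed[2]), z_um = z_grid[k],
        commanded_offset_um = profile$offset_um[lvl], level = lvl)
    }
    noise <- with_seed(substream_seed(seed, sprintf("video-noise/%d", f)),
                       matrix(rnorm(image_size^2, sd = optical$noise_sd),
                              image_size, image_size))
    frames[[f]] <- pmin(pmax(img + noise, 0), 1)
  }
  write_video_tiff(frames, file.path(dir, "frames.tiff"),
                   bit_depth = optical$bit_depth)
  write.csv(do.call(rbind, truth), file.path(dir, "truth.csv"),
            row.names = FALSE)
  yaml::write_yaml(list(levels = lapply(seq_len(nrow(profile)), function(i)
    list(level = profile$level[i], frame_start = profile$frame_start[i],
         frame_end = profile$frame_end[i],
         offset_um = profile$offset_um[i]))),
    file.path(dir, "stage_profile.yaml"))
  invisible(dir)
}

#' Read a stage profile YAML written by [render_stepped_video()]
#' @param path `stage_profile.yaml` path.
#' @return A [stage_profile()] data.frame.
#' @export
read_stage_profile <- function(path) {
  lv <- yaml::read_yaml(path)$levels
  structure(data.frame(
    level = as.integer(vapply(lv, function(x) as.numeric(x$level), 0)),
    frame_start = as.integer(vapply(lv, function(x)
      as.numeric(x$frame_start), 0)),
    frame_end = as.integer(vapply(lv, function(x)
      as.numeric(x$frame_end), 0)),
    offset_um = vapply(lv, function(x) as.numeric(x$offset_um), 0)),
    class = c("stage_profile", "data.frame"))
}
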