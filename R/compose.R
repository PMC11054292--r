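#' Compose a multi-particle scene from calibration patches
#'
#' Draws `n_particles` patches uniformly over (class, z-grid index), places
#' them uniformly over admissible positions subject to a pairwise
#' center-distance constraint (rejection sampling with a bounded attempt
#' budget), and blends each patch onto the uniform background by adding its
#' background-subtracted intensity (no hard paste seams).  Additive Gaussian
#' noise is applied once to the finished scene and intensities are clipped
#' to `[0, 1]`.
#'
#' Annotations carry the placed sub-pixel center: the patch's calibrated
#' `center` field translated to image coordinates (0-based, x = column
#' rightward, y = row downward).
#'
#' @param library a `calibration_library`.
#' @param n_particles number of particles to place (may be 0).
#' @param image_size square image edge length in px; must be at least the
#'   largest patch size.
#' @param min_separation minimum pairwise center distance in px.  The
#'   default, `NULL`, uses 0.6 x the sum of the two patches' half-sizes;
#'   pass 0 to allow collisions.
#' @param background_level background intensity in `[0, 1]`.
#' @param noise_sd additive noise sd; defaults to the library config's.
#' @param seed integer seed making the scene reproducible in isolation.
#' @param max_attempts placement attempts per particle before the scene is
#'   declared over-crowded.
#' @return A `scene`: list with `pixels`, `annotations` (data.frame
#'   `particle_id,class,x_px,y_px,z_um,source_class,source_index`), `seed`,
#'   `background`, `image_size`.  On over-crowding an error of class
#'   `defocustrack_overcrowded` is signalled carrying the achieved count.
#' @export
compose_scene <- function(library, n_particles, image_size,
                          min_separation = NULL, background_level = 0.15,
                          noise_sd = NULL, seed = 1L, max_attempts = 200L) {
  stopifnot(inherits(library, "calibration_library"), n_particles >= 0)
  patch_sizes <- vapply(library$classes, `[[`, 0L, "patch_size_px")
  if (image_size < max(patch_sizes))
    stop("image_size must be at least the largest patch size (",
         max(patch_sizes), " px)")
  if (is.null(noise_sd)) noise_sd <- library$config$noise_sd
  labels <- names(library$patches)
  nz <- length(library$z_grid)

  with_seed(seed, {
    img <- matrix(background_level, image_size, image_size)
    ann <- list()
    centers <- matrix(numeric(0), 0, 2)
    half <- numeric(0)
    for (i in seq_len(n_particles)) {
      placed <- FALSE
      for (attempt in seq_len(max_attempts)) {
        lab <- labels[sample.int(length(labels), 1)]
        k <- sample.int(nz, 1)
        patch <- library$patches[[lab]][[k]]
        P <- nrow(patch$pixels)
        tl <- floor(runif(2, 0, image_size - P + 1))  # (x, y) top-left, 0-based
        ctr <- patch$center + tl                      # (x, y) in image coords
        sep_ok <- TRUE
        if (nrow(centers) > 0) {
          req <- if (is.null(min_separation))
            0.6 * (half + P / 2) else rep(min_separation, nrow(centers))
          d <- sqrt((centers[, 1] - ctr[1])^2 + (centers[, 2] - ctr[2])^2)
          sep_ok <- all(d >= req)
        }
        if (sep_ok) {
          rows <- tl[2] + seq_len(P); cols <- tl[1] + seq_len(P)
          img[rows, cols] <- img[rows, cols] +
            (patch$pixels - patch_background(library, lab))
          centers <- rbind(centers, ctr)
          half <- c(half, P / 2)
          ann[[i]] <- data.frame(
            particle_id = i, class = lab, x_px = unname(ctr[1]),
            y_px = unname(ctr[2]), z_um = patch$z,
            source_class = lab, source_index = k)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        cond <- structure(
          class = c("defocustrack_overcrowded", "error", "condition"),
          list(message = sprintf(
                 "could not place particle %d of %d within %d attempts (achieved %d)",
                 i, n_particles, max_attempts, i - 1L),
               call = sys.call(-1), achieved = i - 1L))
        stop(cond)
      }
    }
    if (noise_sd > 0)
      img <- img + matrix(rnorm(image_size^2, sd = noise_sd),
                          image_size, image_size)
    img <- pmin(pmax(img, 0), 1)
    annotations <- if (length(ann)) do.call(rbind, ann) else
      data.frame(particle_id = integer(), class = character(),
                 x_px = numeric(), y_px = numeric(), z_um = numeric(),
                 source_class = character(), source_index = integer())
    structure(list(pixels = img, annotations = annotations, seed = seed,
                   background = background_level, image_size = image_size),
              class = "scene")
  })
}

#' Floor-based split sizes
#'
#' Per-split image counts: `floor(n * fraction)` per split with the
#' remainder assigned to the first (training) split, so a 12,000-image
#' dataset at 0.7/0.3 yields 8400 training and 3600 evaluation images.
#'
#' @param n_images total image count.
#' @param split_fractions numeric fractions summing to 1; unnamed vectors
#'   get names train/eval/test in order.
#' @return Named integer vector of per-split counts.
#' @export
split_counts <- function(n_images, split_fractions) {
  if (abs(sum(split_fractions) - 1) > 1e-9)
    stop("split_fractions must sum to 1, got ", sum(split_fractions))
  if (is.null(names(split_fractions)))
    names(split_fractions) <- c("train", "eval", "test")[seq_along(split_fractions)]
  counts <- floor(n_images * split_fractions)
  counts[1] <- counts[1] + (n_images - sum(counts))  # remainder to train
  as.integer(counts) |> setNames(names(split_fractions))
}

patch_background <- function(library, label) {
  library$classes[[label]]$pattern$background
}

#' Build a dataset of composed scenes on disk
#'
#' Writes `n_images` scenes (16-bit TIFF) plus one annotation CSV per split
#' and a `manifest.yaml`.  Split counts are floor-based with the remainder
#' assigned to the first (training) split.  Scene seeds are substreams of
#' `seed`, so any single image can be regenerated in isolation.
#'
#' @param library a `calibration_library`.
#' @param n_images total number of scenes.
#' @param out_dir output directory.
#' @param size_range integer range of square image edge lengths in px;
#'   scenes sample uniformly from it (the network input pipeline rescales).
#' @param n_particles_range integer range of per-scene particle counts.
#' @param split_fractions named numeric vector summing to 1 (names become
#'   split names; defaults to train/eval/test in order).
#' @param min_separation,background_level,noise_sd passed to
#'   [compose_scene()].
#' @param seed root seed for the dataset.
#' @return The manifest (list), invisibly readable back with
#'   [read_manifest()].
#' @export
build_dataset <- function(library, n_images, out_dir,
                          size_range = c(950, 1050),
                          n_particles_range = c(3, 8),
                          split_fractions = c(train = 0.7, eval = 0.3),
                          min_separation = NULL, background_level = 0.15,
                          noise_sd = NULL, seed = 1L) {
  stopifnot(n_images >= 1)
  counts <- split_counts(n_images, split_fractions)
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)

  split_of <- rep(names(counts), counts)
  rows_by_split <- setNames(vector("list", length(counts)), names(counts))
  image_files <- character(n_images)
  for (i in seq_len(n_images)) {
    s <- substream_seed(seed, sprintf("scene/%d", i))
    size <- with_seed(substream_seed(seed, sprintf("scene-size/%d", i)), {
      np <- sample_int_range(n_particles_range[1], n_particles_range[2])
      sz <- sample_int_range(size_range[1], size_range[2])
      c(sz, np)
    })
    scene <- compose_scene(library, n_particles = size[2], image_size = size[1],
                           min_separation = min_separation,
                           background_level = background_level,
                           noise_sd = noise_sd, seed = s)
    file <- sprintf("img_%05d.tiff", i)
    write_gray_image(scene$pixels, file.path(out_dir, "images", file),
                     bit_depth = library$config$bit_depth)
    image_files[i] <- file
    ann <- scene$annotations
    if (nrow(ann)) {
      ann <- data.frame(image = file, particle_id = ann$particle_id,
                        class = ann$class, x_px = ann$x_px, y_px = ann$y_px,
                        z_um = ann$z_um)
      rows_by_split[[split_of[i]]] <-
        c(rows_by_split[[split_of[i]]], list(ann))
    }
  }
  splits <- list()
  for (sp in names(counts)) {
    ann <- if (length(rows_by_split[[sp]])) do.call(rbind, rows_by_split[[sp]])
           else data.frame(image = character(), particle_id = integer(),
                           class = character(), x_px = numeric(),
                           y_px = numeric(), z_um = numeric())
    csv <- sprintf("annotations_%s.csv", sp)
    write.csv(ann, file.path(out_dir, csv), row.names = FALSE)
    splits[[sp]] <- list(images = image_files[split_of == sp],
                         annotations_csv = csv, n_images = unname(counts[sp]))
  }
  manifest <- list(
    n_images = n_images, seed = seed,
    optical = unclass(library$config),
    bead_classes = lapply(library$classes, function(b)
      list(label = b$label, radius_um = b$radius_um,
           patch_size_px = b$patch_size_px, pattern = b$pattern)),
    compose = list(size_range = as.integer(size_range),
                   n_particles_range = as.integer(n_particles_range),
                   background_level = background_level),
    splits = splits)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  manifest$dir <- out_dir
  invisible(manifest)
}

#' Read and validate a dataset manifest
#'
#' Checks that the splits are disjoint, that every referenced image file
#' exists, and that each split's annotation CSV is readable.
#'
#' @param dir dataset directory containing `manifest.yaml`.
#' @return The manifest list, with `dir` attached.
#' @export
read_manifest <- function(dir) {
  path <- file.path(dir, "manifest.yaml")
  if (!file.exists(path)) stop("no manifest.yaml in ", dir)
  manifest <- yaml::read_yaml(path)
  all_imgs <- unlist(lapply(manifest$splits, `[[`, "images"))
  if (anyDuplicated(all_imgs)) stop("manifest splits are not disjoint")
  missing <- !file.exists(file.path(dir, "images", all_imgs))
  if (any(missing))
    stop("manifest references missing image files, e.g. ",
         all_imgs[which(missing)[1]])
  for (sp in names(manifest$splits)) {
    csv <- file.path(dir, manifest$splits[[sp]]$annotations_csv)
    if (!file.exists(csv)) stop("missing annotation CSV for split ", sp)
  }
  manifest$dir <- dir
  manifest
}

#' Load the images and annotations of one dataset split
#' @param manifest manifest from [read_manifest()] / [build_dataset()].
#' @param split split name, e.g. `"train"`.
#' @return List of per-image records: `image` (matrix), `annotations`
#'   (data.frame), `file`.
#' @export
load_split <- function(manifest, split) {
  sp <- manifest$splits[[split]]
  if (is.null(sp)) stop("no such split: ", split)
  ann <- read.csv(file.path(manifest$dir, sp$annotations_csv),
                  stringsAsFactors = FALSE)
  lapply(sp$images, function(f) {
    list(image = read_gray_image(file.path(manifest$dir, "images", f)),
         annotations = ann[ann$image == f, , drop = FALSE], file = f)
  })
}
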