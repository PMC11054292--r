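#' Normalize / de-normalize signed defocus
#'
#' Depth targets are stored as `z_norm = (z - z_min) / (z_max - z_min)`
#' in `[0, 1]`; the mapping is affine and exactly invertible.
#'
#' @param z,z_norm values to convert.
#' @param config an [optical_config()] (only `z_min`/`z_max` are used).
#' @return Converted numeric vector.
#' @export
z_normalize <- function(z, config) (z - config$z_min) / (config$z_max - config$z_min)

#' @rdname z_normalize
#' @export
z_denormalize <- function(z_norm, config)
  config$z_min + z_norm * (config$z_max - config$z_min)

# Size-adaptive Gaussian radius (CornerNet-style): largest r such that a
# corner displaced by r still gives IoU >= `overlap` with the object box.
gaussian_radius <- function(height, width, overlap = 0.7) {
  a1 <- 1; b1 <- height + width
  c1 <- width * height * (1 - overlap) / (1 + overlap)
  r1 <- (b1 - sqrt(max(b1^2 - 4 * a1 * c1, 0))) / (2 * a1)
  a2 <- 4; b2 <- 2 * (height + width)
  c2 <- (1 - overlap) * width * height
  r2 <- (b2 - sqrt(max(b2^2 - 4 * a2 * c2, 0))) / (2 * a2)
  a3 <- 4 * overlap; b3 <- -2 * overlap * (height + width)
  c3 <- (overlap - 1) * width * height
  r3 <- (b3 + sqrt(max(b3^2 - 4 * a3 * c3, 0))) / (2 * a3)
  max(0, min(r1, r2, r3))
}

# Per-object Gaussian sigma (in output cells) for an annotation.
object_sigma <- function(bead, z, stride) {
  fp_cells <- 2 * pattern_footprint_px(bead, z) / stride
  r <- gaussian_radius(fp_cells, fp_cells, 0.7)
  max(1, (2 * r + 1) / 6)
}

#' Encode annotations as heatmap / offset / depth target maps
#'
#' Converts sub-pixel particle annotations into the network's output
#' representation at output stride `S`: per-class center heatmaps (Gaussian
#' splats with size-adaptive sigma, combined across objects by elementwise
#' max, exactly 1 at each center cell), fractional-cell offsets and
#' normalized depth defined at center cells, and a boolean center mask.
#'
#' @param annotations data.frame with columns `class`, `x_px`, `y_px`,
#'   `z_um` (image coordinates, 0-based).
#' @param image_size square image edge length in px.
#' @param stride integer output stride `S` (map size is
#'   `ceil(image_size / S)`).
#' @param classes named list of [bead_class()] objects fixing the channel
#'   order.
#' @param config an [optical_config()] (z normalization and footprints).
#' @return A `target_maps` object: list with `heatmap` (Hs x Ws x C),
#'   `offset` (Hs x Ws x 2; x then y), `depth` (Hs x Ws matrix),
#'   `center_mask` (logical Hs x Ws), `stride`, `class_labels`, `z_min`,
#'   `z_max`, `image_size`.
#' @export
encode_targets <- function(annotations, image_size, stride, classes, config) {
  stopifnot(stride >= 1, image_size >= stride)
  Hs <- ceiling(image_size / stride); Ws <- Hs
  labels <- vapply(classes, `[[`, "", "label")
  heat <- array(0, c(Hs, Ws, length(labels)))
  off <- array(0, c(Hs, Ws, 2))
  depth <- matrix(0, Hs, Ws)
  mask <- matrix(FALSE, Hs, Ws)
  if (nrow(annotations)) {
    if (any(annotations$x_px < 0 | annotations$x_px > image_size - 1 |
            annotations$y_px < 0 | annotations$y_px > image_size - 1))
      stop("annotation outside image bounds")
    us <- matrix(seq_len(Ws) - 1, Hs, Ws, byrow = TRUE)
    vs <- matrix(seq_len(Hs) - 1, Hs, Ws)
    for (i in seq_len(nrow(annotations))) {
      lab <- annotations$class[i]
      ch <- match(lab, labels)
      if (is.na(ch)) stop("annotation class not in `classes`: ", lab)
      cx <- floor(annotations$x_px[i] / stride)
      cy <- floor(annotations$y_px[i] / stride)
      sg <- object_sigma(classes[[ch]], annotations$z_um[i], stride)
      g <- exp(-((us - cx)^2 + (vs - cy)^2) / (2 * sg^2))
      heat[, , ch] <- pmax(heat[, , ch], g)
      heat[cy + 1, cx + 1, ch] <- 1
      off[cy + 1, cx + 1, 1] <- annotations$x_px[i] / stride - cx
      off[cy + 1, cx + 1, 2] <- annotations$y_px[i] / stride - cy
      depth[cy + 1, cx + 1] <- z_normalize(annotations$z_um[i], config)
      mask[cy + 1, cx + 1] <- TRUE
    }
  }
  structure(list(heatmap = heat, offset = off, depth = depth,
                 center_mask = mask, stride = as.integer(stride),
                 class_labels = unname(labels),
                 z_min = config$z_min, z_max = config$z_max,
                 image_size = as.integer(image_size)),
            class = "target_maps")
}

#' Decode detections from heatmap / offset / depth maps
#'
#' Candidate cells are 3x3-neighbourhood local maxima of each class's
#' heatmap (a cell survives iff it equals its neighbourhood max; plateau
#' ties are kept).  Survivors are ranked by score, truncated to `top_k`,
#' and filtered at `score_threshold`.  Each survivor decodes to
#' `x = (cx + offset_x) * S`, `y = (cy + offset_y) * S`, de-normalized depth
#' (clamped to the calibrated z range and flagged when clamping occurred),
#' its channel's class label, and the heatmap value as score.
#'
#' @param maps a `target_maps`-shaped object (e.g. from [encode_targets()]
#'   or a network forward pass); heatmap values must already be in
#'   `[0, 1]`.
#' @param score_threshold minimum heatmap score.
#' @param top_k maximum number of detections.
#' @return A data.frame of detections: `class,x_px,y_px,z_um,score,
#'   z_clamped`, sorted by decreasing score.
#' @export
decode_detections <- function(maps, score_threshold = 0.3, top_k = 100L) {
  stopifnot(top_k >= 1)
  heat <- maps$heatmap
  if (length(heat) == 0) stop("empty heatmap")
  Hs <- dim(heat)[1]; Ws <- dim(heat)[2]; C <- dim(heat)[3]
  S <- maps$stride
  cfg <- list(z_min = maps$z_min, z_max = maps$z_max)
  out <- list()
  for (ch in seq_len(C)) {
    hm <- heat[, , ch]
    mx <- .cc_maxpool_forward(array(hm, c(Hs, Ws, 1)), 3L, 1L, 1L)$y[, , 1]
    keep <- which(hm == mx & hm >= score_threshold, arr.ind = TRUE)
    if (!nrow(keep)) next
    cy <- keep[, 1] - 1; cx <- keep[, 2] - 1
    sc <- hm[keep]
    zn <- maps$depth[keep]
    z <- z_denormalize(zn, cfg)
    zc <- z < cfg$z_min | z > cfg$z_max
    z <- pmin(pmax(z, cfg$z_min), cfg$z_max)
    out[[ch]] <- data.frame(
      class = maps$class_labels[ch],
      x_px = (cx + maps$offset[cbind(keep[, 1], keep[, 2], 1)]) * S,
      y_px = (cy + maps$offset[cbind(keep[, 1], keep[, 2], 2)]) * S,
      z_um = z, score = sc, z_clamped = zc)
  }
  det <- if (length(out)) do.call(rbind, out) else
    data.frame(class = character(), x_px = numeric(), y_px = numeric(),
               z_um = numeric(), score = numeric(), z_clamped = logical())
  det <- det[order(-det$score), , drop = FALSE]
  det <- head(det, top_k)
  rownames(det) <- NULL
  det
}

#' Write detections to CSV
#' @param detections data.frame from [decode_detections()].
#' @param image image file name to record.
#' @param path output CSV path; appends if the file exists.
#' @return `path`, invisibly.
#' @export
write_detections_csv <- function(detections, image, path) {
  df <- data.frame(image = image, class = detections$class,
                   x_px = detections$x_px, y_px = detections$y_px,
                   z_um = detections$z_um, score = detections$score)
  write.table(df, path, sep = ",", row.names = FALSE,
              col.names = !file.exists(path), append = file.exists(path))
  invisible(path)
}
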