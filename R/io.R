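#' Write a grayscale image
#'
#' Images are held in memory as `[0, 1]` double matrices (rows = y) and
#' quantized to the configured bit depth on write.  TIFF is the native
#' format; PNG is chosen by file extension.
#'
#' @param pixels numeric matrix in `[0, 1]`.
#' @param path output file path (`.tiff`/`.tif` or `.png`).
#' @param bit_depth 8 or 16.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(pixels, path, bit_depth = 16L) {
  stopifnot(is.matrix(pixels), bit_depth %in% c(8L, 16L))
  img <- pmin(pmax(pixels, 0), 1)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tiff", "tif")) {
    tiff::writeTIFF(img, path, bits.per.sample = as.integer(bit_depth))
  } else if (ext == "png") {
    png::writePNG(img, path)
  } else stop("unsupported image extension: ", ext)
  invisible(path)
}

#' Read a grayscale image written by [write_gray_image()]
#'
#' Accepts single-channel TIFF or PNG; multi-channel input is averaged to
#' one channel.  Returns intensities in `[0, 1]`.
#'
#' @param path image file path.
#' @return Numeric matrix (rows = y).
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tiff", "tif")) tiff::readTIFF(path)
         else if (ext == "png") png::readPNG(path)
         else stop("unsupported image extension: ", ext)
  if (length(dim(img)) == 3) img <- apply(img, c(1, 2), mean)
  img
}

#' Write a multi-frame grayscale video as a multi-page TIFF
#' @param frames list of `[0, 1]` matrices of identical size.
#' @param path output `.tiff` path.
#' @param bit_depth 8 or 16.
#' @return `path`, invisibly.
#' @export
write_video_tiff <- function(frames, path, bit_depth = 16L) {
  stopifnot(length(frames) > 0)
  tiff::writeTIFF(lapply(frames, function(f) pmin(pmax(f, 0), 1)), path,
                  bits.per.sample = as.integer(bit_depth))
  invisible(path)
}

#' Read video frames from a multi-page TIFF or a directory of images
#' @param path a multi-page TIFF file, or a directory of per-frame
#'   TIFF/PNG files (sorted by file name).
#' @return List of numeric matrices.
#' @export
read_video_frames <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tiff?|png)$",
                             full.names = TRUE, ignore.case = TRUE))
    if (!length(files)) stop("no frames found in ", path)
    return(lapply(files, read_gray_image))
  }
  frames <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(frames)) frames <- list(frames)
  lapply(frames, function(f) if (length(dim(f)) == 3) apply(f, c(1, 2), mean) else f)
}

#' Bilinear resize of a grayscale image
#' @param pixels numeric matrix.
#' @param out_h,out_w output size in pixels.
#' @return Resized matrix.
#' @export
resize_bilinear <- function(pixels, out_h, out_w = out_h) {
  H <- nrow(pixels); W <- ncol(pixels)
  if (H == out_h && W == out_w) return(pixels)
  # map output pixel centers into input coordinates (align corners = FALSE)
  ys <- pmin(pmax((seq_len(out_h) - 0.5) * H / out_h - 0.5, 0), H - 1)
  xs <- pmin(pmax((seq_len(out_w) - 0.5) * W / out_w - 0.5, 0), W - 1)
  y0 <- pmin(floor(ys), H - 2); x0 <- pmin(floor(xs), W - 2)
  fy <- ys - y0; fx <- xs - x0
  i0 <- y0 + 1; i1 <- i0 + 1; j0 <- x0 + 1; j1 <- j0 + 1
  a <- pixels[i0, j0, drop = FALSE]; b <- pixels[i0, j1, drop = FALSE]
  c_ <- pixels[i1, j0, drop = FALSE]; d <- pixels[i1, j1, drop = FALSE]
  fy <- matrix(fy, out_h, out_w); fx <- matrix(fx, out_h, out_w, byrow = TRUE)
  a * (1 - fy) * (1 - fx) + b * (1 - fy) * fx + c_ * fy * (1 - fx) + d * fy * fx
}
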