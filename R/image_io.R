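# Image and annotation input/output.
#
# All rasters use the (row, col) convention with origin at the top-left and
# 1-based indices, matching R's matrix indexing.  RGB images are integer
# arrays of dimension H x W x 3 with 8-bit channel values in 0..255.

#' Scene class codes
#'
#' The seven scene classes used by the pixel segmentation model, plus code 0
#' for unlabeled pixels in scribble annotations.  Head pixels are the three
#' head color classes (green, orange, white).
#'
#' @return Named integer vector mapping class names to codes 1-7.
#' @export
scene_classes <- function() {
  c(soil = 1L, shadow = 2L, dead_leaves = 3L, leaves = 4L,
    green_head = 5L, orange_head = 6L, white_head = 7L)
}

#' Codes of the three head classes
#' @return Integer vector `c(5, 6, 7)`.
#' @export
head_class_codes <- function() c(5L, 6L, 7L)

#' Construct an RGB image
#'
#' Validates and classes an H x W x 3 integer raster of 8-bit sRGB values.
#'
#' @param pixels numeric array of dimension H x W x 3, values in 0..255.
#' @return An object of class `rgb_image` (an integer array).
#' @export
rgb_image <- function(pixels) {
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L)
    stopf("`pixels` must be an H x W x 3 array, got dims [%s]",
          paste(d, collapse = ", "))
  if (d[1] < 1L || d[2] < 1L) stopf("image must have H >= 1 and W >= 1")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stopf("channel values must be finite and within [0, 255]")
  px <- array(as.integer(round(pixels)), dim = d)
  class(px) <- c("rgb_image", "array")
  px
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image> %d x %d pixels, 3 x 8-bit sRGB channels\n",
              d[1], d[2]))
  invisible(x)
}

image_size <- function(img) dim(img)[1:2]

#' Read an RGB image from disk
#'
#' Reads PNG, TIFF or JPEG.  Only 3-channel images are accepted; grayscale
#' (and RGBA) files are rejected.  16-bit TIFF samples are rescaled to 8 bits
#' by an integer right-shift of 8 (i.e. `value %/% 256`).
#'
#' @param path path to a `.png`, `.tif`/`.tiff`, `.jpg`/`.jpeg` file.
#' @return An [rgb_image()].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stopf("image file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    raw <- png::readPNG(path)
    px <- round(raw * 255)
  } else if (ext %in% c("tif", "tiff")) {
    raw <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(raw, "bits.per.sample")
    if (is.null(bits)) bits <- 8L
    px <- round(raw * (2^bits - 1))
    if (bits > 8L) px <- px %/% 256L
  } else if (ext %in% c("jpg", "jpeg")) {
    raw <- jpeg::readJPEG(path)
    px <- round(raw * 255)
  } else {
    stopf("unsupported image format '.%s' (PNG/TIFF/JPEG only)", ext)
  }
  if (length(dim(px)) != 3L || dim(px)[3] != 3L)
    stopf("%s: expected a 3-channel RGB image, got %s channel(s)",
          path, if (length(dim(px)) == 2L) "1" else dim(px)[3])
  rgb_image(px)
}

#' Write an RGB image to disk
#'
#' @param img an [rgb_image()].
#' @param path output path ending in `.png` or `.tif`/`.tiff`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  img <- rgb_image(img)
  arr <- array(img / 255, dim = dim(img))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(arr, path)
  else if (ext %in% c("tif", "tiff")) tiff::writeTIFF(arr, path)
  else stopf("unsupported output format '.%s' (PNG/TIFF only)", ext)
  invisible(path)
}

#' Crop the central window of an image
#'
#' Returns the centered `out_h` x `out_w` window.  When the number of rows
#' (or columns) to discard is odd, the extra row is dropped from the bottom
#' (extra column from the right): the window's top-left corner is at row
#' `(H - out_h) %/% 2 + 1`, column `(W - out_w) %/% 2 + 1`.  The default
#' window size is the central region used to sidestep lens distortion in
#' 5472 x 3648 frames.
#'
#' @param img an [rgb_image()].
#' @param out_h,out_w output height and width in pixels.
#' @return The cropped [rgb_image()].
#' @export
crop_center <- function(img, out_h = 1731L, out_w = 1154L) {
  img <- rgb_image(img)
  d <- dim(img)
  if (!is_count(out_h) || !is_count(out_w))
    stopf("`out_h` and `out_w` must be positive integers")
  if (out_h > d[1] || out_w > d[2])
    stopf("requested crop %d x %d exceeds image %d x %d",
          out_h, out_w, d[1], d[2])
  top <- (d[1] - out_h) %/% 2L
  left <- (d[2] - out_w) %/% 2L
  rgb_image(img[top + seq_len(out_h), left + seq_len(out_w), , drop = FALSE])
}

#' Read hand-labeled head center points
#'
#' Points are stored as CSV with header `image_id,row,col`, coordinates
#' 1-based with origin at the top-left.  Duplicate rows are dropped with a
#' warning; when `image_size` is supplied, out-of-bounds points raise an
#' error.
#'
#' @param path CSV file path.
#' @param image_size optional `c(H, W)` used to validate point bounds.
#' @return A data frame with columns `image_id` (character), `row`, `col`
#'   (integer), one row per labeled head center.
#' @export
read_point_labels <- function(path, image_size = NULL) {
  if (!file.exists(path)) stopf("point label file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), c("image_id", "row", "col")))
    stopf("%s: expected header 'image_id,row,col', got '%s'",
          path, paste(names(df), collapse = ","))
  if (nrow(df) == 0L) {
    return(data.frame(image_id = character(), row = integer(),
                      col = integer(), stringsAsFactors = FALSE))
  }
  bad <- which(!is.finite(df$row) | !is.finite(df$col) |
                 df$row != floor(df$row) | df$col != floor(df$col) |
                 df$row < 1 | df$col < 1)
  if (length(bad))
    stopf("%s: malformed point at data line %d", path, bad[1])
  dup <- duplicated(df)
  if (any(dup)) {
    warnf("%s: dropped %d duplicate point row(s)", path, sum(dup))
    df <- df[!dup, , drop = FALSE]
  }
  if (!is.null(image_size)) {
    oob <- df$row > image_size[1] | df$col > image_size[2]
    if (any(oob))
      stopf("%s: %d point(s) outside the %d x %d image bounds",
            path, sum(oob), image_size[1], image_size[2])
  }
  df$image_id <- as.character(df$image_id)
  df$row <- as.integer(df$row)
  df$col <- as.integer(df$col)
  rownames(df) <- NULL
  df
}

#' Write head center points
#'
#' @param points data frame with columns `image_id`, `row`, `col`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_point_labels <- function(points, path) {
  stopifnot(all(c("image_id", "row", "col") %in% names(points)))
  utils::write.csv(points[, c("image_id", "row", "col")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-pixel class annotation
#'
#' Scribble annotations assign scene class codes to a subset of pixels:
#' 0 marks unlabeled pixels and codes 1-7 the classes of [scene_classes()].
#' On disk the annotation is an 8-bit grayscale PNG whose gray level is the
#' class code itself; any level above 7 is rejected.
#'
#' @param path PNG file path.
#' @return Integer matrix of class codes in 0..7.
#' @export
read_class_annotation <- function(path) {
  if (!file.exists(path)) stopf("class annotation not found: %s", path)
  raw <- png::readPNG(path)
  if (length(dim(raw)) != 2L)
    stopf("%s: class annotations must be single-channel PNG", path)
  codes <- round(raw * 255)
  if (max(codes) > 7)
    stopf("%s: class code %d out of range 0-7", path, max(codes))
  matrix(as.integer(codes), nrow = nrow(codes))
}

#' Write a per-pixel class annotation
#'
#' @param labels integer matrix of codes in 0..7.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_class_annotation <- function(labels, path) {
  if (anyNA(labels) || min(labels) < 0 || max(labels) > 7)
    stopf("class codes must be in 0..7")
  png::writePNG(matrix(as.integer(labels), nrow = nrow(labels)) / 255, path)
  invisible(path)
}
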