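# The nine color features (r, g, b; H, S, V; L*, a*, b*) behind the pixel
# segmentation model, and assembly of labeled training tables.

FEATURE_NAMES <- c("r", "g", "b", "h", "s", "v", "L_star", "a_star", "b_star")

check_unit_range <- function(..., what = "channel") {
  vals <- c(...)
  if (anyNA(vals) || any(vals < 0) || any(vals > 1))
    stopf("%s values must lie in [0, 1]", what)
}

#' Convert sRGB channels to HSV
#'
#' Standard hexcone HSV with all components on the unit scale: hue in
#' `[0, 1)` (circular, 1 == 360 degrees), saturation and value in `[0, 1]`.
#' Gray pixels (S = 0) have H = 0 by convention.
#'
#' @param r,g,b numeric vectors of channel intensities in `[0, 1]`.
#' @return Numeric matrix with columns `h`, `s`, `v`.
#' @export
rgb_to_hsv <- function(r, g, b) {
  check_unit_range(r, g, b)
  hsv <- t(grDevices::rgb2hsv(rbind(r, g, b), maxColorValue = 1))
  hsv[hsv[, 1] >= 1, 1] <- 0  # wrap the circular endpoint
  dimnames(hsv) <- list(NULL, c("h", "s", "v"))
  hsv
}

#' Convert sRGB channels to CIE L*a*b*
#'
#' Standard sRGB linearization, the IEC 61966-2-1 sRGB-to-XYZ matrix and
#' the D65 reference white (0.95047, 1, 1.08883): L* in `[0, 100]`, a*/b*
#' opponent axes typically within about +/- 128.  Implemented with the
#' published constants directly so the conversion is the textbook one to
#' machine precision (grDevices::convertColor re-derives its matrix from
#' chromaticities and differs in the third decimal).
#'
#' @param r,g,b numeric vectors of sRGB channel intensities in `[0, 1]`.
#' @return Numeric matrix with columns `L_star`, `a_star`, `b_star`.
#' @export
rgb_to_lab <- function(r, g, b) {
  check_unit_range(r, g, b)
  lin <- function(v) ifelse(v <= 0.04045, v / 12.92,
                            ((v + 0.055) / 1.055)^2.4)
  srgb2xyz <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                       0.2126729, 0.7151522, 0.0721750,
                       0.0193339, 0.1191920, 0.9503041), 3L, byrow = TRUE)
  xyz <- cbind(lin(r), lin(g), lin(b)) %*% t(srgb2xyz)
  # reference white = image of RGB (1,1,1), so grays are exactly neutral
  white <- rowSums(srgb2xyz)
  d <- 6 / 29
  f <- function(t) ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
  fx <- f(xyz[, 1] / white[1])
  fy <- f(xyz[, 2] / white[2])
  fz <- f(xyz[, 3] / white[3])
  cbind(L_star = 116 * fy - 16, a_star = 500 * (fx - fy),
        b_star = 200 * (fy - fz))
}

# n x 9 feature matrix for the pixels of `img`, in column-major pixel order.
feature_matrix <- function(img) {
  rgb <- matrix(as.numeric(img), ncol = 3L) / 255
  m <- cbind(rgb,
             rgb_to_hsv(rgb[, 1], rgb[, 2], rgb[, 3]),
             rgb_to_lab(rgb[, 1], rgb[, 2], rgb[, 3]))
  colnames(m) <- FEATURE_NAMES
  m
}

#' Per-pixel color feature raster
#'
#' Computes the nine color features for every pixel of an image.
#'
#' @param img an [rgb_image()].
#' @return Numeric array of dimension H x W x 9; the third dimension is named
#'   `r, g, b, h, s, v, L_star, a_star, b_star`.
#' @export
pixel_features <- function(img) {
  img <- rgb_image(img)
  d <- dim(img)
  m <- feature_matrix(img)
  array(m, dim = c(d[1], d[2], 9L),
        dimnames = list(NULL, NULL, FEATURE_NAMES))
}

#' Collect labeled training pixels for the segmentation model
#'
#' Samples up to `max_per_class` scribble-annotated pixels per scene class,
#' uniformly without replacement, and returns their color features with
#' provenance.  The per-class cap keeps abundant background classes from
#' dominating tree training.  Sampling is reproducible for a fixed seed.
#'
#' @param img an [rgb_image()].
#' @param ann integer matrix of class codes 0..7, same H x W as `img`
#'   (see [read_class_annotation()]).
#' @param max_per_class maximum pixels sampled per class (default 2000).
#' @param seed integer RNG seed.
#' @param image_id provenance string recorded in the table.
#' @param classes class codes to collect; codes absent from `ann` are
#'   skipped with a warning (model training later validates coverage).
#' @return Data frame (class `feature_table`) with columns `image_id`,
#'   `row`, `col`, the nine features, and `class` (integer 1-7).
#' @export
collect_training_samples <- function(img, ann, max_per_class = 2000L,
                                     seed = 1L, image_id = "image",
                                     classes = sort(unique(ann[ann > 0L]))) {
  img <- rgb_image(img)
  d <- dim(img)
  if (!identical(dim(ann), d[1:2]))
    stopf("annotation size [%d x %d] does not match image [%d x %d]",
          nrow(ann), ncol(ann), d[1], d[2])
  if (!is_count(max_per_class)) stopf("`max_per_class` must be >= 1")
  if (all(ann == 0L)) stopf("annotation has no labeled pixels")
  classes <- as.integer(classes)
  if (any(classes < 1L | classes > 7L)) stopf("`classes` must be in 1..7")
  feats <- feature_matrix(img)
  picks <- with_seed(seed, {
    lapply(classes, function(cls) {
      avail <- which(ann == cls)
      if (!length(avail)) return(integer())
      if (length(avail) <= max_per_class) sort(avail)
      else sort(avail[sample.int(length(avail), max_per_class)])
    })
  })
  absent <- classes[lengths(picks) == 0L]
  if (length(absent))
    warnf("class(es) %s absent from annotation; skipped",
          paste(absent, collapse = ", "))
  idx <- unlist(picks)
  cls <- rep(classes, lengths(picks))
  out <- data.frame(
    image_id = image_id,
    row = ((idx - 1L) %% d[1]) + 1L,
    col = ((idx - 1L) %/% d[1]) + 1L,
    feats[idx, , drop = FALSE],
    class = cls,
    stringsAsFactors = FALSE
  )
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Combine feature tables from several images
#'
#' @param ... `feature_table` objects from [collect_training_samples()].
#' @return A single `feature_table`; duplicate (image_id, row, col) rows are
#'   an error.
#' @export
bind_feature_tables <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  key <- paste(out$image_id, out$row, out$col)
  if (anyDuplicated(key))
    stopf("duplicate (image_id, row, col) rows across tables")
  class(out) <- c("feature_table", "data.frame")
  out
}
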