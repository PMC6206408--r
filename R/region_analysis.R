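# Candidate head regions: 8-connected components of the head mask and the
# eleven morphological features used by the counting classifier.
#
# Feature conventions (recorded in model metadata because counting models do
# not transfer across conventions):
#   * perimeter = number of region pixels with at least one non-region
#     4-neighbor (boundary pixel count);
#   * ellipse axes from the normalized second central moments with the +1/12
#     per-pixel variance correction, so a single pixel has finite axes;
#   * convex area = number of pixel centers inside or on the convex hull of
#     the region's pixel centers;
#   * roundness = 4 * pi * filled_area / perimeter^2, clipped to 1.

REGION_FEATURE_NAMES <- c(
  "area", "eccentricity", "extent", "perimeter", "major_axis_length",
  "minor_axis_length", "convex_area", "filled_area", "equiv_diameter",
  "solidity", "roundness")

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels touching
# diagonally are merged with a small union-find over label ids.
label_components8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- EBImage::bwlabel(mask * 1L)
  lab <- matrix(as.integer(lab), nrow = h)
  nlab <- max(lab)
  if (nlab <= 1L || h == 1L || w == 1L) return(lab)
  a1 <- lab[-h, -w]; b1 <- lab[-1, -1]   # (r,c) ~ (r+1,c+1)
  a2 <- lab[-1, -w]; b2 <- lab[-h, -1]   # (r+1,c) ~ (r,c+1)
  keep1 <- a1 > 0L & b1 > 0L & a1 != b1
  keep2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- unique(rbind(cbind(a1[keep1], b1[keep1]),
                        cbind(a2[keep2], b2[keep2])))
  if (nrow(pairs)) {
    parent <- seq_len(nlab)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- vapply(seq_len(nlab), find, integer(1))
    remap <- c(0L, root)
    lab <- matrix(remap[lab + 1L], nrow = h)
  }
  lab
}

#' Extract candidate head regions from a head mask
#'
#' Candidate regions are the 8-connected components of the mask with at
#' least `min_area` pixels (smaller specks are treated as classification
#' noise).  Regions are returned in reading order of their bounding-box
#' top-left corner, so extraction is deterministic.
#'
#' @param mask logical H x W matrix from [head_mask()].
#' @param min_area minimum component size in pixels (default 20, about
#'   0.4 cm^2 at a 0.45 cm ground sampling distance — smaller than any
#'   sorghum head).
#' @return List of `head_region` objects, each with `region_id`, `pixels`
#'   (n x 2 matrix of (row, col)), `bbox` (top, left, height, width) and
#'   `centroid` (row, col, sub-pixel).
#' @export
extract_regions <- function(mask, min_area = 20L) {
  if (!is.matrix(mask)) stopf("`mask` must be a logical matrix")
  mask <- mask & !is.na(mask)
  lab <- label_components8(mask)
  idx <- which(lab > 0L)
  if (!length(idx)) return(list())
  h <- nrow(mask)
  rows <- ((idx - 1L) %% h) + 1L
  cols <- ((idx - 1L) %/% h) + 1L
  comp <- split(seq_along(idx), lab[idx])
  comp <- comp[lengths(comp) >= min_area]
  if (!length(comp)) return(list())
  regions <- lapply(comp, function(i) {
    r <- rows[i]; c <- cols[i]
    bbox <- c(top = min(r), left = min(c),
              height = max(r) - min(r) + 1L, width = max(c) - min(c) + 1L)
    structure(list(region_id = NA_integer_,
                   pixels = cbind(row = r, col = c),
                   bbox = bbox,
                   centroid = c(row = mean(r), col = mean(c))),
              class = "head_region")
  })
  ord <- order(vapply(regions, function(x) x$bbox[["top"]], numeric(1)),
               vapply(regions, function(x) x$bbox[["left"]], numeric(1)))
  regions <- unname(regions[ord])
  for (i in seq_along(regions)) regions[[i]]$region_id <- i
  regions
}

#' @export
print.head_region <- function(x, ...) {
  cat(sprintf(
    "<head_region %s> %d px, bbox (%d, %d) %d x %d, centroid (%.1f, %.1f)\n",
    x$region_id, nrow(x$pixels), x$bbox[["top"]], x$bbox[["left"]],
    x$bbox[["height"]], x$bbox[["width"]],
    x$centroid[["row"]], x$centroid[["col"]]))
  invisible(x)
}

# Local binary mask of a region within its bounding box.
region_local_mask <- function(region) {
  b <- region$bbox
  m <- matrix(FALSE, b[["height"]], b[["width"]])
  m[cbind(region$pixels[, 1] - b[["top"]] + 1L,
          region$pixels[, 2] - b[["left"]] + 1L)] <- TRUE
  m
}

# Boundary pixel count: region pixels with >= 1 non-region 4-neighbor
# (pixels outside the mask count as non-region).
boundary_pixel_count <- function(m) {
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- m
  core <- pad[2:(h + 1L), 2:(w + 1L)]
  n4 <- pad[1:h, 2:(w + 1L)] & pad[3:(h + 2L), 2:(w + 1L)] &
    pad[2:(h + 1L), 1:w] & pad[2:(h + 1L), 3:(w + 2L)]
  sum(core & !n4)
}

# Fill holes: background connected (4-connectivity) to the border stays
# background; enclosed background becomes foreground.
fill_holes <- function(m) {
  h <- nrow(m); w <- ncol(m)
  bg <- matrix(TRUE, h + 2L, w + 2L)
  bg[2:(h + 1L), 2:(w + 1L)] <- !m
  reach <- bg
  reach[2:(h + 1L), 2:(w + 1L)] <- FALSE  # start from the padded border
  repeat {
    grown <- reach
    grown[-1, ] <- grown[-1, ] | reach[-(h + 2L), ]
    grown[-(h + 2L), ] <- grown[-(h + 2L), ] | reach[-1, ]
    grown[, -1] <- grown[, -1] | reach[, -(w + 2L)]
    grown[, -(w + 2L)] <- grown[, -(w + 2L)] | reach[, -1]
    grown <- grown & bg
    if (identical(grown, reach)) break
    reach <- grown
  }
  !reach[2:(h + 1L), 2:(w + 1L)]
}

# Number of pixel centers inside or on the convex hull of the region's
# pixel centers.  Coordinates are integers, so edge tests are exact.
convex_hull_area <- function(r, c) {
  pts <- unique(cbind(c, r))          # (x, y)
  if (nrow(pts) == 1L) return(1L)
  hull <- pts[grDevices::chull(pts[, 1], pts[, 2]), , drop = FALSE]
  gx <- rep(min(pts[, 1]):max(pts[, 1]), each = diff(range(pts[, 2])) + 1L)
  gy <- rep(min(pts[, 2]):max(pts[, 2]), times = diff(range(pts[, 1])) + 1L)
  nh <- nrow(hull)
  if (nh <= 2L) {                      # collinear: lattice points on segment
    a <- hull[1, ]; b <- hull[nh, ]
    cross <- (b[1] - a[1]) * (gy - a[2]) - (b[2] - a[2]) * (gx - a[1])
    dot <- (gx - a[1]) * (b[1] - a[1]) + (gy - a[2]) * (b[2] - a[2])
    len2 <- sum((b - a)^2)
    return(sum(cross == 0 & dot >= 0 & dot <= len2))
  }
  area2 <- sum(hull[, 1] * hull[c(2:nh, 1), 2] -
                 hull[c(2:nh, 1), 1] * hull[, 2])
  if (area2 < 0) hull <- hull[nh:1, ]  # force counter-clockwise
  inside <- rep(TRUE, length(gx))
  for (i in seq_len(nh)) {
    a <- hull[i, ]; b <- hull[if (i == nh) 1L else i + 1L, ]
    inside <- inside &
      ((b[1] - a[1]) * (gy - a[2]) - (b[2] - a[2]) * (gx - a[1])) >= 0
  }
  sum(inside)
}

#' Morphological features of a candidate head region
#'
#' Computes the eleven shape descriptors used as predictors by the head
#' count classifier: area, eccentricity, extent, perimeter, major and minor
#' axis lengths of the moment-equivalent ellipse, convex area, filled area,
#' equivalent circle diameter, solidity and roundness.
#'
#' @param region a `head_region` from [extract_regions()].
#' @return Named numeric vector of length 11.
#' @export
region_features <- function(region) {
  if (!inherits(region, "head_region") || nrow(region$pixels) == 0L)
    stopf("`region` must be a non-empty head_region")
  r <- region$pixels[, 1]; c <- region$pixels[, 2]
  n <- length(r)
  m <- region_local_mask(region)
  area <- n
  extent <- n / (region$bbox[["height"]] * region$bbox[["width"]])
  perim <- boundary_pixel_count(m)
  filled <- sum(fill_holes(m))
  convex <- convex_hull_area(r, c)
  # moment-equivalent ellipse with the +1/12 per-pixel variance correction
  mu20 <- mean((r - mean(r))^2) + 1 / 12
  mu02 <- mean((c - mean(c))^2) + 1 / 12
  mu11 <- mean((r - mean(r)) * (c - mean(c)))
  common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  major <- 2 * sqrt(2 * (mu20 + mu02 + common))
  minor <- 2 * sqrt(2 * max(mu20 + mu02 - common, 0))
  ecc <- sqrt(max(1 - (minor / major)^2, 0))
  c(area = area,
    eccentricity = ecc,
    extent = extent,
    perimeter = perim,
    major_axis_length = major,
    minor_axis_length = minor,
    convex_area = convex,
    filled_area = filled,
    equiv_diameter = sqrt(4 * area / pi),
    solidity = area / convex,
    roundness = min(4 * pi * filled / perim^2, 1))
}

#' Feature table for a list of regions
#'
#' @param regions list of `head_region` objects.
#' @param image_id provenance string.
#' @return Data frame with `image_id`, `region_id`, bbox/centroid columns
#'   and the 11 features; carries the perimeter convention as an attribute
#'   so counting models can refuse mismatched features.
#' @export
region_feature_table <- function(regions, image_id = "image") {
  if (!length(regions)) {
    out <- as.data.frame(matrix(numeric(), 0, length(REGION_FEATURE_NAMES),
                                dimnames = list(NULL, REGION_FEATURE_NAMES)))
    out <- cbind(data.frame(image_id = character(), region_id = integer(),
                            stringsAsFactors = FALSE), out)
  } else {
    feats <- t(vapply(regions, region_features,
                      numeric(length(REGION_FEATURE_NAMES))))
    out <- data.frame(
      image_id = image_id,
      region_id = vapply(regions, `[[`, integer(1), "region_id"),
      feats, stringsAsFactors = FALSE)
  }
  attr(out, "perimeter_convention") <- PERIMETER_CONVENTION
  out
}

#' Crop per-region image thumbnails
#'
#' Cuts each region's bounding box out of the source image, optionally
#' zeroing pixels that do not belong to the region.
#'
#' @param img the [rgb_image()] the regions were detected in.
#' @param regions list of `head_region` objects.
#' @param mask_background if `TRUE`, non-region pixels are set to black.
#' @return List of [rgb_image()] patches.
#' @export
crop_region_thumbnails <- function(img, regions, mask_background = FALSE) {
  img <- rgb_image(img)
  lapply(regions, function(reg) {
    b <- reg$bbox
    rows <- b[["top"]]:(b[["top"]] + b[["height"]] - 1L)
    cols <- b[["left"]]:(b[["left"]] + b[["width"]] - 1L)
    patch <- img[rows, cols, , drop = FALSE]
    if (mask_background) {
      keep <- region_local_mask(reg)
      patch <- patch * array(keep, dim = dim(patch))
    }
    rgb_image(patch)
  })
}
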