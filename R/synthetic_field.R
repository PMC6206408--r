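# Synthetic sorghum-field image generator.
#
# Emulates the challenges of real breeding-trial imagery: four background
# classes (soil, shadow, dead leaves, green leaves), heads of four color
# morphs (white, green, orange, brown) with variable size/shape and
# multi-lobed "expanded" clusters, partial leaf occlusion, global
# illumination changes (sunny vs cloudy) and sensor noise — with exact
# ground truth (head centers, per-pixel class map, per-cluster counts)
# recorded before noise is added.
#
# Class colors live in disjoint HSV boxes.  Hue and saturation are invariant
# under the multiplicative illumination gain, so a segmentation model
# trained on some images transfers across lighting; value separates the
# classes (shadow vs white heads) whose hue/saturation overlap.

#' Parameters of the synthetic field generator
#'
#' Defaults emulate a two-row sorghum plot window at heading: about 100
#' heads per image at a 0.45 cm ground sampling distance, a white/green/
#' orange/brown morph mixture, a quarter of heads placed against a
#' neighbor (overlapping clusters), occasional leaf occlusion, and a
#' 0.6-1.2x illumination gain range spanning cloudy to sunny frames.
#'
#' @param height,width image size in pixels.
#' @param gsd ground sampling distance, cm/pixel.
#' @param heads_mean mean number of heads per image.
#' @param heads_dispersion negative-binomial size parameter for the head
#'   count (`Inf` gives Poisson).
#' @param morph_probs probabilities of the white/green/orange/brown morphs
#'   (must sum to 1).
#' @param head_major_range,minor_frac_range head ellipse major axis range
#'   (pixels) and minor/major ratio range.
#' @param lobe_probs probabilities that a head is drawn with 1, 2 or 3
#'   overlapping ellipse lobes (tiller/expanded shapes).
#' @param overlap_prob fraction of heads placed within one minor axis of an
#'   existing head, forming multi-head regions.
#' @param occlusion_prob fraction of heads partially covered by a leaf
#'   blob.
#' @param gain_range global multiplicative illumination gain range.
#' @param cast_sd standard deviation of the per-channel color cast
#'   multiplier.
#' @param background_weights approximate area fractions of the shadow,
#'   dead-leaf and leaf patches layered over the soil base (named vector).
#' @param noise_sd Gaussian pixel noise SD on the 8-bit scale.
#' @param color_boxes named list of 2-column HSV range matrices, one per
#'   paint class (the seven scene classes plus `brown_head`); the defaults
#'   are disjoint boxes calibrated to the white/green/orange/brown morph
#'   descriptions.
#' @return Object of class `field_sim_params`.
#' @export
field_sim_params <- function(height = 384L, width = 512L, gsd = 0.45,
                             heads_mean = 100, heads_dispersion = 20,
                             morph_probs = c(white = 0.30, green = 0.25,
                                             orange = 0.30, brown = 0.15),
                             head_major_range = c(9, 16),
                             minor_frac_range = c(0.45, 0.7),
                             lobe_probs = c(0.7, 0.2, 0.1),
                             overlap_prob = 0.25,
                             occlusion_prob = 0.10,
                             gain_range = c(0.6, 1.2),
                             cast_sd = 0.03,
                             background_weights = c(shadow = 0.20,
                                                    dead_leaves = 0.15,
                                                    leaves = 0.20),
                             noise_sd = 3,
                             color_boxes = paint_boxes()) {
  stopifnot(height >= 64, width >= 64,
            abs(sum(morph_probs) - 1) < 1e-8,
            all(morph_probs >= 0), all(lobe_probs >= 0),
            overlap_prob >= 0, overlap_prob <= 1,
            occlusion_prob >= 0, occlusion_prob <= 1,
            heads_mean >= 0, heads_dispersion > 0,
            all(head_major_range > 0), all(minor_frac_range > 0),
            noise_sd >= 0)
  structure(list(
    height = as.integer(height), width = as.integer(width), gsd = gsd,
    heads_mean = heads_mean, heads_dispersion = heads_dispersion,
    morph_probs = morph_probs, head_major_range = head_major_range,
    minor_frac_range = minor_frac_range,
    lobe_probs = lobe_probs / sum(lobe_probs),
    overlap_prob = overlap_prob, occlusion_prob = occlusion_prob,
    gain_range = gain_range, cast_sd = cast_sd,
    background_weights = background_weights, noise_sd = noise_sd,
    color_boxes = color_boxes
  ), class = "field_sim_params")
}

# Disjoint HSV boxes per paint class.  Paint classes are the seven scene
# classes plus "brown_head", which is rendered in brown but labeled as the
# orange_head class (the 7-class map has only three head color classes).
paint_boxes <- function() {
  list(
    soil        = rbind(h = c(0.050, 0.080), s = c(0.25, 0.42), v = c(0.42, 0.55)),
    shadow      = rbind(h = c(0.500, 0.650), s = c(0.00, 0.25), v = c(0.03, 0.12)),
    dead_leaves = rbind(h = c(0.115, 0.155), s = c(0.22, 0.40), v = c(0.70, 0.85)),
    leaves      = rbind(h = c(0.300, 0.380), s = c(0.45, 0.70), v = c(0.28, 0.45)),
    green_head  = rbind(h = c(0.190, 0.240), s = c(0.40, 0.60), v = c(0.60, 0.75)),
    orange_head = rbind(h = c(0.055, 0.090), s = c(0.55, 0.75), v = c(0.55, 0.70)),
    white_head  = rbind(h = c(0.000, 1.000), s = c(0.00, 0.08), v = c(0.85, 0.97)),
    brown_head  = rbind(h = c(0.030, 0.060), s = c(0.50, 0.65), v = c(0.28, 0.40))
  )
}

# Vectorized hexcone HSV -> sRGB (the generator paints in HSV space).
hsv_to_rgb <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6)
  f <- h6 - i
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r, g, b)
}

# Linear indices of the pixels of an ellipse at (cr, cc), full axes
# (major, minor), orientation theta, clipped to an h x w raster.
ellipse_pixels <- function(cr, cc, major, minor, theta, h, w) {
  a <- major / 2; b <- minor / 2
  ext <- ceiling(a) + 1L
  rows <- max(1L, floor(cr - ext)):min(h, ceiling(cr + ext))
  cols <- max(1L, floor(cc - ext)):min(w, ceiling(cc + ext))
  dr <- rep(rows - cr, times = length(cols))
  dc <- rep(cols - cc, each = length(rows))
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  keep <- (u / a)^2 + (v / b)^2 <= 1
  rr <- rep(rows, times = length(cols))[keep]
  cc2 <- rep(cols, each = length(rows))[keep]
  (cc2 - 1L) * h + rr
}

#' Generate one synthetic field image with ground truth
#'
#' Layers background patches over a soil base, places heads as filled
#' (multi-lobed) ellipses in morph-specific colors, applies partial leaf
#' occlusion, a global illumination gain and color cast, and Gaussian
#' noise.  All ground truth is recorded before noise.  Bit-identical output
#' for a fixed seed.
#'
#' @param params a [field_sim_params()].
#' @param seed integer RNG seed.
#' @param image_id id recorded in the ground-truth point set.
#' @return List with `image` (an [rgb_image()]) and `truth`: `points`
#'   (data frame `image_id`, `row`, `col` of head centers), `class_map`
#'   (H x W codes 1-7, pre-noise), `heads` (per-head ellipse parameters and
#'   morphs), and `n_heads`.
#' @export
generate_field_image <- function(params = field_sim_params(), seed = 1L,
                                 image_id = "img_001") {
  stopifnot(inherits(params, "field_sim_params"))
  with_seed(seed, {
    h <- params$height; w <- params$width
    npx <- h * w
    paint <- rep.int(1L, npx)               # paint class per pixel; 1 = soil
    # --- background patches -------------------------------------------------
    bg_codes <- c(shadow = 2L, dead_leaves = 3L, leaves = 4L)
    for (nm in names(bg_codes)) {
      target <- params$background_weights[[nm]] * npx
      placed <- 0
      while (placed < target) {
        major <- stats::runif(1, 30, 90)
        minor <- major * stats::runif(1, 0.4, 0.9)
        px <- ellipse_pixels(stats::runif(1, 1, h), stats::runif(1, 1, w),
                             major, minor, stats::runif(1, 0, pi), h, w)
        paint[px] <- bg_codes[[nm]]
        placed <- placed + length(px)
      }
    }
    # --- heads --------------------------------------------------------------
    n_heads <- as.integer(if (is.finite(params$heads_dispersion))
      stats::rnbinom(1, size = params$heads_dispersion,
                     mu = params$heads_mean)
      else stats::rpois(1, params$heads_mean))
    morphs <- character(0)
    if (n_heads > 0)
      morphs <- sample(names(params$morph_probs), n_heads, replace = TRUE,
                       prob = params$morph_probs)
    morph_paint <- c(white = 7L, green = 5L, orange = 6L, brown = 8L)
    morph_label <- c(white = 7L, green = 5L, orange = 6L, brown = 6L)
    inset <- ceiling(max(params$head_major_range)) + 2L
    # lobes reach at most ~0.575 * major from the center (offset 0.25 +
    # half of a 0.65-scaled lobe), so independent placements at 1.2 * major
    # plus margin can never fuse into one connected component
    min_sep <- 1.2 * max(params$head_major_range) + 3
    heads <- vector("list", n_heads)
    centers <- matrix(numeric(), 0, 2)
    head_px <- vector("list", n_heads)
    for (i in seq_len(n_heads)) {
      major <- stats::runif(1, params$head_major_range[1],
                            params$head_major_range[2])
      minor <- major * stats::runif(1, params$minor_frac_range[1],
                                    params$minor_frac_range[2])
      theta <- stats::runif(1, 0, pi)
      ok <- FALSE
      for (try in seq_len(200L)) {
        if (i > 1L && stats::runif(1) < params$overlap_prob) {
          # crowd against a previously placed head
          anchor <- centers[sample.int(nrow(centers), 1L), ]
          ang <- stats::runif(1, 0, 2 * pi)
          d <- stats::runif(1, 0.5, 1) * minor
          cr <- anchor[1] + d * cos(ang); cc <- anchor[2] + d * sin(ang)
          if (cr < inset || cr > h - inset || cc < inset || cc > w - inset)
            next
        } else {
          cr <- stats::runif(1, inset, h - inset)
          cc <- stats::runif(1, inset, w - inset)
          if (nrow(centers) &&
              min((centers[, 1] - cr)^2 + (centers[, 2] - cc)^2) <
                min_sep^2)
            next
        }
        key <- c(round(cr), round(cc))
        if (nrow(centers) &&
            any(round(centers[, 1]) == key[1] &
                  round(centers[, 2]) == key[2]))
          next  # integer centers must be unique
        ok <- TRUE
        break
      }
      if (!ok)
        stopf("could not place head %d within the overlap budget; density
too high for a %d x %d image", i, h, w)
      n_lobes <- sample.int(3L, 1L, prob = params$lobe_probs)
      px <- ellipse_pixels(cr, cc, major, minor, theta, h, w)
      if (n_lobes > 1L) {
        for (l in seq_len(n_lobes - 1L)) {
          ang <- stats::runif(1, 0, 2 * pi)
          off <- stats::runif(1, 0.15, 0.25) * major
          px <- union(px, ellipse_pixels(
            cr + off * cos(ang), cc + off * sin(ang),
            major * stats::runif(1, 0.45, 0.65),
            minor * stats::runif(1, 0.45, 0.65),
            stats::runif(1, 0, pi), h, w))
        }
      }
      paint[px] <- morph_paint[[morphs[i]]]
      centers <- rbind(centers, c(cr, cc))
      head_px[[i]] <- px
      heads[[i]] <- data.frame(
        row = as.integer(round(cr)), col = as.integer(round(cc)),
        major = major, minor = minor,
        theta = theta, morph = morphs[i], lobes = n_lobes,
        occluded = FALSE, stringsAsFactors = FALSE)
    }
    # --- partial leaf occlusion --------------------------------------------
    for (i in seq_len(n_heads)) {
      if (stats::runif(1) >= params$occlusion_prob) next
      hd <- heads[[i]]
      ang <- stats::runif(1, 0, 2 * pi)
      d <- stats::runif(1, 0.35, 0.5) * hd$major
      px <- ellipse_pixels(hd$row + d * cos(ang), hd$col + d * sin(ang),
                           hd$major * 0.5, hd$minor * 0.6,
                           stats::runif(1, 0, pi), h, w)
      # never cover a head center: manual labelers still mark these heads
      center_idx <- (round(centers[, 2]) - 1L) * h + round(centers[, 1])
      px <- setdiff(px, center_idx)
      paint[px] <- 4L
      heads[[i]]$occluded <- TRUE
    }
    # --- labels and colors --------------------------------------------------
    label <- paint
    label[paint == 8L] <- 6L                # brown morph -> orange_head class
    class_map <- matrix(label, nrow = h)
    boxes <- params$color_boxes
    hh <- ss <- vv <- numeric(npx)
    for (k in seq_along(boxes)) {
      idx <- which(paint == k)
      if (!length(idx)) next
      bx <- boxes[[k]]
      hh[idx] <- stats::runif(length(idx), bx["h", 1], bx["h", 2])
      ss[idx] <- stats::runif(length(idx), bx["s", 1], bx["s", 2])
      vv[idx] <- stats::runif(length(idx), bx["v", 1], bx["v", 2])
    }
    rgb <- hsv_to_rgb(hh, ss, vv)
    gain <- stats::runif(1, params$gain_range[1], params$gain_range[2])
    cast <- 1 + stats::rnorm(3, 0, params$cast_sd)
    rgb <- sweep(rgb, 2L, gain * cast, `*`)
    rgb <- rgb + stats::rnorm(length(rgb), 0, params$noise_sd / 255)
    rgb <- pmin(pmax(rgb, 0), 1)
    img <- rgb_image(array(round(rgb * 255), dim = c(h, w, 3L)))
    heads_df <- if (n_heads > 0) do.call(rbind, heads) else
      data.frame(row = integer(), col = integer(), major = numeric(),
                 minor = numeric(), theta = numeric(), morph = character(),
                 lobes = integer(), occluded = logical())
    points <- data.frame(image_id = rep(image_id, n_heads),
                         row = heads_df$row, col = heads_df$col,
                         stringsAsFactors = FALSE)
    list(image = img,
         truth = list(points = points, class_map = class_map,
                      heads = heads_df, n_heads = n_heads))
  })
}

#' Simulate clipped plot boundaries
#'
#' Emulates imperfect plot segmentation, where plot boundaries cut through
#' heads at the plot edges: the image is cropped at the column quantiles
#' `clip_fraction / 2` and `1 - clip_fraction / 2` of the head centers, so
#' roughly `clip_fraction` of heads end up truncated or removed.  Centers
#' that remain inside the cropped window are retained (and shifted); the
#' class map is cropped alongside.
#'
#' @param field a list `(image, truth)` from [generate_field_image()].
#' @param clip_fraction fraction of heads affected, in `[0, 1]`; 0 returns
#'   the input unchanged.
#' @return A list `(image, truth)` in the same format.
#' @export
degrade_plot_clipping <- function(field, clip_fraction = 0.3) {
  stopifnot(clip_fraction >= 0, clip_fraction <= 1)
  if (clip_fraction == 0 || nrow(field$truth$points) == 0L) return(field)
  cols <- field$truth$points$col
  lo <- as.integer(round(stats::quantile(cols, clip_fraction / 2,
                                         type = 1)))
  hi <- as.integer(round(stats::quantile(cols, 1 - clip_fraction / 2,
                                         type = 1)))
  keep <- lo:hi
  img <- rgb_image(field$image[, keep, , drop = FALSE])
  cmap <- field$truth$class_map[, keep, drop = FALSE]
  pts <- field$truth$points
  inside <- pts$col >= lo & pts$col <= hi
  pts <- pts[inside, , drop = FALSE]
  pts$col <- pts$col - lo + 1L
  heads <- field$truth$heads[inside, , drop = FALSE]
  heads$col <- heads$col - lo + 1L
  rownames(pts) <- rownames(heads) <- NULL
  list(image = img,
       truth = list(points = pts, class_map = cmap, heads = heads,
                    n_heads = nrow(pts)))
}

#' Generate an on-disk synthetic dataset
#'
#' Writes `n_images` synthetic field images in exactly the formats the
#' readers consume: PNG images under `images/`, full-coverage class
#' annotations under `classes/`, one `points.csv` of head centers, and a
#' `manifest.json` recording parameters and per-image seeds (derived from
#' the master seed).
#'
#' @param n_images number of images.
#' @param params a [field_sim_params()].
#' @param dir output directory (created if missing).
#' @param seed master RNG seed.
#' @return The manifest, invisibly (list with `images`, `points`, `seeds`,
#'   `params_file`).
#' @export
generate_dataset <- function(n_images, params = field_sim_params(),
                             dir = "synthetic_field", seed = 1L) {
  if (!is_count(n_images)) stopf("`n_images` must be >= 1")
  dir.create(file.path(dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "classes"), showWarnings = FALSE)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_images))
  ids <- sprintf("img_%03d", seq_len(n_images))
  pts <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    fld <- generate_field_image(params, seed = seeds[i], image_id = ids[i])
    write_image(fld$image, file.path(dir, "images",
                                     paste0(ids[i], ".png")))
    write_class_annotation(fld$truth$class_map,
                           file.path(dir, "classes",
                                     paste0(ids[i], ".png")))
    pts[[i]] <- fld$truth$points
  }
  write_point_labels(do.call(rbind, pts), file.path(dir, "points.csv"))
  manifest <- list(
    image_ids = ids,
    images = file.path("images", paste0(ids, ".png")),
    classes = file.path("classes", paste0(ids, ".png")),
    points = "points.csv",
    seeds = seeds, master_seed = as.integer(seed),
    height = params$height, width = params$width)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
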