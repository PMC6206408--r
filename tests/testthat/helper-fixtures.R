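# Shared fixtures: small, fast generator settings and toy geometry builders.

# Compact field settings for unit tests (full-size defaults are exercised
# in the end-to-end acceptance tests).
small_params <- function(...) {
  args <- utils::modifyList(
    list(height = 160L, width = 200L, heads_mean = 12,
         heads_dispersion = Inf), list(...))
  do.call(field_sim_params, args)
}

# Build head_region objects from a logical mask (all components).
regions_from_mask <- function(mask, min_area = 1L) {
  extract_regions(mask, min_area = min_area)
}

# A mask with a filled rectangle of the given extents.
rect_mask <- function(h, w, r0, r1, c0, c1) {
  m <- matrix(FALSE, h, w)
  m[r0:r1, c0:c1] <- TRUE
  m
}

# Random blobby mask: union of a few random discs, reproducible.
random_mask <- function(h, w, n_blobs = 3L, seed = 1L) {
  set.seed(seed)
  m <- matrix(FALSE, h, w)
  for (i in seq_len(n_blobs)) {
    cr <- runif(1, 1, h); cc <- runif(1, 1, w); rad <- runif(1, 1, 4)
    for (r in seq_len(h)) for (c in seq_len(w))
      if ((r - cr)^2 + (c - cc)^2 <= rad^2) m[r, c] <- TRUE
  }
  m
}

# Flat-color rgb_image.
solid_image <- function(h, w, rgb = c(0, 0, 0)) {
  rgb_image(array(rep(rgb, each = h * w), dim = c(h, w, 3L)))
}

# Perfectly separable count-labeled table: class-conditional features are
# far apart, so the SVM must reach CV accuracy 1.
separable_count_table <- function(n_per_class = 20L, seed = 7L) {
  set.seed(seed)
  one <- function(count, area_mu) {
    area <- rnorm(n_per_class, area_mu, 4)
    data.frame(
      image_id = "toy", region_id = seq_len(n_per_class),
      area = area, eccentricity = runif(n_per_class, 0.3, 0.7),
      extent = runif(n_per_class, 0.5, 0.9),
      perimeter = sqrt(area) * 4, major_axis_length = sqrt(area) * 1.4,
      minor_axis_length = sqrt(area) * 0.9, convex_area = area * 1.1,
      filled_area = area, equiv_diameter = sqrt(4 * area / pi),
      solidity = runif(n_per_class, 0.85, 1), roundness = runif(n_per_class, 0.6, 1),
      true_count = count)
  }
  tab <- rbind(one(1L, 60), one(2L, 400))
  attr(tab, "perimeter_convention") <- "boundary-pixel-count-4n"
  tab
}
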