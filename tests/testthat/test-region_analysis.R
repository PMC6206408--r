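test_that("regions are 8-connected components in deterministic order", {
  expect_identical(extract_regions(matrix(FALSE, 5, 5)), list())

  # diagonal touch: one region under 8-connectivity
  m <- matrix(FALSE, 5, 5); m[2, 2] <- m[3, 3] <- TRUE
  regs <- extract_regions(m, min_area = 1)
  expect_length(regs, 1L)
  expect_identical(nrow(regs[[1]]$pixels), 2L)

  # ordering by bounding-box (top, left); ids sequential
  m2 <- matrix(FALSE, 10, 10)
  m2[7:8, 1:2] <- TRUE; m2[1:2, 5:6] <- TRUE; m2[1:2, 1:2] <- TRUE
  regs2 <- extract_regions(m2, min_area = 1)
  tl <- t(vapply(regs2, function(r) r$bbox[c("top", "left")], numeric(2)))
  expect_identical(order(tl[, 1], tl[, 2]), seq_along(regs2))
  expect_identical(vapply(regs2, `[[`, integer(1), "region_id"),
                   seq_along(regs2))
})

test_that("labeling agrees with a brute-force flood fill on random masks", {
  for (seed in 1:6) {
    set.seed(seed * 100)
    mask <- matrix(runif(50 * 50) < 0.35, 50, 50)
    regs <- extract_regions(mask, min_area = 1)
    lab <- oracle_label8(mask)
    expect_identical(length(regs), max(lab))
    # identical pixel partitions (component ids may differ)
    got <- lapply(regs, function(r)
      unname(sort((r$pixels[, 2] - 1L) * 50L + r$pixels[, 1])))
    want <- unname(split(which(lab > 0), lab[lab > 0]))
    want <- lapply(want, sort)
    expect_identical(got[order(vapply(got, min, integer(1)))],
                     want[order(vapply(want, min, integer(1)))])
    # areas sum to mask cardinality when min_area = 1
    expect_identical(sum(lengths(got)), sum(mask))
  }
})

test_that("min_area filters small components", {
  m <- matrix(FALSE, 10, 10)
  m[1:3, 1:3] <- TRUE       # 9 px
  m[8, 8] <- TRUE           # 1 px
  expect_length(extract_regions(m, min_area = 2), 1L)
  expect_length(extract_regions(m, min_area = 1), 2L)
})

test_that("single-pixel and filled-square features match closed forms", {
  m <- matrix(FALSE, 3, 3); m[2, 2] <- TRUE
  f <- region_features(extract_regions(m, min_area = 1)[[1]])
  expect_equal(f[["area"]], 1)
  expect_equal(f[["extent"]], 1)
  expect_equal(f[["solidity"]], 1)
  expect_equal(f[["filled_area"]], 1)
  expect_equal(f[["perimeter"]], 1)
  expect_equal(f[["equiv_diameter"]], 2 / sqrt(pi))
  expect_equal(f[["major_axis_length"]], 4 * sqrt(1 / 12))
  expect_equal(f[["minor_axis_length"]], 4 * sqrt(1 / 12))
  expect_equal(f[["eccentricity"]], 0)
  expect_equal(f[["roundness"]], 1)  # 4*pi/1 clipped

  sq <- rect_mask(8, 8, 2, 5, 3, 6)  # 4x4 filled square
  fs <- region_features(extract_regions(sq, min_area = 1)[[1]])
  expect_equal(fs[["area"]], 16)
  expect_equal(fs[["extent"]], 1)
  expect_equal(fs[["filled_area"]], 16)
  expect_equal(fs[["convex_area"]], 16)
  expect_equal(fs[["solidity"]], 1)
  expect_equal(fs[["equiv_diameter"]], sqrt(64 / pi))
  expect_equal(fs[["eccentricity"]], 0)
  expect_equal(fs[["perimeter"]], 12)
})

test_that("holes are filled: hollow square has filled_area > area", {
  m <- rect_mask(7, 7, 2, 6, 2, 6)
  m[4, 4] <- FALSE
  f <- region_features(extract_regions(m, min_area = 1)[[1]])
  expect_equal(f[["area"]], 24)
  expect_equal(f[["filled_area"]], 25)
})

test_that("all 11 features match the brute-force oracle on random masks", {
  checked <- 0L
  for (seed in seq_len(250)) {
    set.seed(seed)
    h <- sample(5:20, 1); w <- sample(5:20, 1)
    mask <- random_mask(h, w, n_blobs = sample(1:3, 1), seed = seed)
    if (!any(mask)) next
    for (reg in extract_regions(mask, min_area = 1)) {
      got <- region_features(reg)
      want <- oracle_region_features(reg$pixels)
      expect_equal(got, want, tolerance = 1e-9)
      checked <- checked + 1L
    }
  }
  expect_gte(checked, 200L)
})

test_that("features are translation-invariant", {
  set.seed(31)
  mask <- random_mask(15, 15, 3, seed = 77)
  big <- matrix(FALSE, 40, 40)
  big[6:20, 4:18] <- mask
  shifted <- matrix(FALSE, 40, 40)
  shifted[18:32, 21:35] <- mask
  f1 <- lapply(extract_regions(big, min_area = 1), region_features)
  f2 <- lapply(extract_regions(shifted, min_area = 1), region_features)
  expect_equal(f1, f2)
})

test_that("90-degree rotation preserves the rotation-invariant features", {
  set.seed(32)
  mask <- random_mask(12, 18, 3, seed = 41)
  rot <- t(mask[nrow(mask):1, , drop = FALSE])
  f <- lapply(extract_regions(mask, min_area = 1), region_features)
  fr <- lapply(extract_regions(rot, min_area = 1), region_features)
  # component order may change under rotation: match by area then compare
  key <- function(l) l[order(vapply(l, `[[`, numeric(1), "area"),
                             vapply(l, `[[`, numeric(1), "perimeter"))]
  f <- key(f); fr <- key(fr)
  inv <- c("area", "perimeter", "solidity", "eccentricity", "extent",
           "convex_area", "filled_area", "equiv_diameter", "roundness",
           "major_axis_length", "minor_axis_length")
  expect_equal(lapply(f, `[`, inv), lapply(fr, `[`, inv), tolerance = 1e-9)
})

test_that("thumbnails crop the bounding box with optional masking", {
  set.seed(33)
  img <- rgb_image(array(sample(0:255, 10 * 10 * 3, TRUE), c(10L, 10L, 3L)))
  m <- matrix(FALSE, 10, 10)
  m[2:4, 3:5] <- TRUE                    # 3x3 block
  m[1, 1] <- m[1, 2] <- m[2, 1] <- TRUE  # corner region
  regs <- extract_regions(m, min_area = 1)
  th <- crop_region_thumbnails(img, regs)
  # patches equal source pixels at region coordinates
  for (i in seq_along(regs)) {
    b <- regs[[i]]$bbox
    expect_identical(unclass(th[[i]]),
                     unclass(img)[b[["top"]]:(b[["top"]] + b[["height"]] - 1),
                                  b[["left"]]:(b[["left"]] + b[["width"]] - 1),
                                  , drop = FALSE])
  }
  thm <- crop_region_thumbnails(img, regs, mask_background = TRUE)
  corner <- thm[[which(vapply(regs, function(r) r$bbox[["top"]], numeric(1))
                       == 1)]]
  expect_identical(as.integer(corner[2, 2, ]), c(0L, 0L, 0L))
})
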