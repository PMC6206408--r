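test_that("plot_polygons lays out the grid with the right spacing", {
  one <- plot_polygons(field_layout(1, 1))
  expect_length(one, 1L)
  expect_equal(one[[1]]$corners[1, ], c(0, 0))

  full <- plot_polygons(field_layout(36, 40))
  expect_length(full, 36L * 40L)

  lay <- field_layout(2, 3, plot_length = 5, inter_plot_gap = 1,
                      row_spacing = 0.76, margin = 0.76)
  polys <- plot_polygons(lay)
  cent <- t(vapply(polys, function(p) colMeans(p$corners), numeric(2)))
  ids <- t(vapply(polys, function(p) p$plot_id, integer(2)))
  # consecutive plots along a column are plot_length + gap apart
  r1 <- cent[ids[, 1] == 1 & ids[, 2] == 1, ]
  r2 <- cent[ids[, 1] == 1 & ids[, 2] == 2, ]
  expect_equal(sqrt(sum((r2 - r1)^2)), 5 + 1)
  # bearing rotates rigidly: pairwise distances unchanged
  lay_rot <- field_layout(2, 3, field_bearing = 30)
  polys_rot <- plot_polygons(lay_rot)
  d0 <- dist(t(vapply(polys, function(p) colMeans(p$corners), numeric(2))))
  d1 <- dist(t(vapply(polys_rot, function(p) colMeans(p$corners),
                      numeric(2))))
  expect_equal(as.vector(d1), as.vector(d0), tolerance = 1e-12)
})

test_that("projection applies the homography with perspective division", {
  rect <- rbind(c(0, 0), c(2, 0), c(2, 5), c(0, 5))
  geo_id <- list(image_id = "a", H = diag(3), size = c(100L, 100L))
  inst <- project_plot(rect + 10, geo_id)
  expect_equal(unname(inst$quad), unname(cbind(rect[, 2], rect[, 1]) + 10),
               ignore_attr = TRUE)
  expect_true(inst$valid)

  Ht <- diag(3); Ht[1, 3] <- 10; Ht[2, 3] <- 20   # translation (x+10, y+20)
  inst_t <- project_plot(rect + 20, list(image_id = "b", H = Ht,
                                         size = c(100L, 100L)))
  expect_equal(inst_t$quad[, "col"], rect[, 1] + 20 + 10)
  expect_equal(inst_t$quad[, "row"], rect[, 2] + 20 + 20)

  # a genuinely projective transform against a direct matrix oracle
  Hp <- matrix(c(1.2, 0.1, 5, -0.05, 0.9, 8, 1e-3, -2e-3, 1), 3, byrow = TRUE)
  inst_p <- project_plot(rect + 30, list(image_id = "c", H = Hp,
                                         size = c(200L, 200L)))
  for (i in 1:4) {
    v <- Hp %*% c(rect[i, ] + 30, 1)
    expect_equal(unname(inst_p$quad[i, ]), c(v[2], v[1]) / v[3],
                 tolerance = 1e-12)
  }

  # vertices projected outside the frame invalidate the instance
  inst_out <- project_plot(rect + 200, geo_id)
  expect_false(inst_out$valid)
})

test_that("best instance minimizes center distance with id tie-break", {
  mk <- function(id, d, valid = TRUE)
    structure(list(image_id = id, quad = diag(2), valid = valid,
                   center_distance = d), class = "plot_instance")
  expect_identical(select_best_instance(list(mk("x", 50)))$image_id, "x")
  picked <- select_best_instance(list(mk("a", 50), mk("b", 10),
                                      mk("c", 300)))
  expect_identical(picked$image_id, "b")
  tie <- select_best_instance(list(mk("zz", 10), mk("aa", 10)))
  expect_identical(tie$image_id, "aa")
  # permutation-invariant
  insts <- list(mk("a", 5), mk("b", 3), mk("c", 9), mk("d", 3, FALSE))
  expect_identical(select_best_instance(insts)$image_id,
                   select_best_instance(rev(insts))$image_id)
  expect_error(select_best_instance(list(mk("a", 1, FALSE))), "no valid")
})

test_that("axis-aligned quads rectify to a plain (resampled) crop", {
  set.seed(61)
  img <- rgb_image(array(sample(0:255, 60 * 40 * 3, TRUE), c(60L, 40L, 3L)))
  # 20x10 pixel block; ask for an output of exactly that size
  quad <- rbind(c(11, 6), c(11, 15), c(30, 15), c(30, 6))
  out <- crop_and_rotate(img, quad, plot_size = c(0.09, 0.045), gsd = 0.45)
  expect_identical(dim(out), c(20L, 10L, 3L))
  # the resampling grid coincides with the source lattice: exact crop
  expect_false(attr(out, "clipped"))
  plain <- unclass(out); attr(plain, "clipped") <- NULL
  expect_identical(plain, unclass(img)[11:30, 6:15, , drop = FALSE])
})

test_that("a rotated plot is rectified back upright", {
  # test pattern with distinct quadrants
  img <- array(0L, c(40L, 40L, 3L))
  img[1:40, 1:40, 1] <- 60L
  img[1:20, , 2] <- 200L      # top half green-ish
  img[, 1:20, 3] <- 200L      # left half blue-ish
  img <- rgb_image(img)
  # 90-degree rotated rectangle: long axis horizontal in the source;
  # sizes chosen so the resampling grid lands exactly on source pixels
  quad <- rbind(c(25, 5), c(5, 5), c(5, 35), c(25, 35))
  out <- crop_and_rotate(img, quad, plot_size = c(0.1395, 0.0945),
                         gsd = 0.45)
  expect_identical(dim(out), c(31L, 21L, 3L))
  # output (1,1) came from source (25,5): bottom half (no green), left
  # half (blue); output (31,21) from source (5,35): green, no blue
  expect_identical(as.integer(out[1, 1, 2:3]), c(0L, 200L))
  expect_identical(as.integer(out[31, 21, 2:3]), c(200L, 0L))
  # interior index remapping: out[r,c] == img[25-(c-1), 5+(r-1)]
  for (rc in list(c(15L, 10L), c(3L, 17L), c(28L, 2L)))
    expect_identical(as.integer(out[rc[1], rc[2], ]),
                     as.integer(img[25L - (rc[2] - 1L),
                                    5L + (rc[1] - 1L), ]))
})

test_that("degenerate and out-of-bounds quads are handled", {
  img <- solid_image(20, 20, c(50, 50, 50))
  degenerate <- rbind(c(5, 5), c(5, 5), c(5, 5), c(5, 5))
  expect_error(crop_and_rotate(img, degenerate), "degenerate")
  hanging <- rbind(c(-5, 1), c(-5, 10), c(10, 10), c(10, 1))
  out <- crop_and_rotate(img, hanging, plot_size = c(0.0675, 0.045),
                         gsd = 0.45)
  expect_true(attr(out, "clipped"))
  expect_identical(as.integer(out[1, 1, ]), c(0L, 0L, 0L))  # filled black
})

test_that("synthetically warped plots are recovered after rectification", {
  set.seed(62)
  # smooth source image so interpolation error is small
  base <- outer(seq_len(50), seq_len(60), function(r, c) 100 + r + 1.5 * c)
  img <- rgb_image(array(rep(pmin(base, 255), 3), c(50L, 60L, 3L)))
  quad <- rbind(c(6, 6), c(6, 45), c(45, 45), c(45, 6))
  out <- crop_and_rotate(img, quad, plot_size = c(0.18, 0.18), gsd = 0.45)
  expect_identical(dim(out)[1:2], c(40L, 40L))
  # compare against direct bilinear sampling of the source grid
  want <- outer(seq(6, 45, length.out = 40), seq(6, 45, length.out = 40),
                function(r, c) 100 + r + 1.5 * c)
  err <- abs(out[, , 1] - want)
  expect_lt(mean(err[3:38, 3:38]), 2)
})

test_that("layout and georefs round-trip through YAML and JSON", {
  tmp <- withr::local_tempdir()
  ly <- file.path(tmp, "layout.yaml")
  yaml::write_yaml(list(n_columns = 3, n_rows = 4, plot_length = 5,
                        row_spacing = 0.76, inter_plot_gap = 1), ly)
  lay <- read_field_layout(ly)
  expect_identical(lay$n_columns, 3L)
  expect_length(plot_polygons(lay), 12L)

  gj <- file.path(tmp, "georefs.json")
  jsonlite::write_json(
    list(list(image_id = "im1", height = 100L, width = 120L,
              homography = as.vector(t(diag(3)))),
         list(image_id = "im2", height = 100L, width = 120L,
              homography = as.vector(t(diag(3) * 2)))),
    gj, auto_unbox = TRUE, digits = NA)
  geos <- read_georefs(gj)
  expect_identical(names(geos), c("im1", "im2"))
  expect_equal(geos$im1$H, diag(3))
  expect_equal(geos$im2$H, diag(3) * 2)
})
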