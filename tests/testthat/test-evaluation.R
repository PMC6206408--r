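mk_regions <- function(mask) extract_regions(mask, min_area = 1)

test_that("match_detections counts points and empty regions correctly", {
  pts3 <- data.frame(row = c(1L, 5L, 9L), col = c(1L, 5L, 9L))
  expect_identical(match_detections(list(), pts3),
                   c(tp = 0L, fp = 0L, fn = 3L))

  m <- matrix(FALSE, 10, 10)
  m[4:6, 4:6] <- TRUE   # will contain 2 points
  m[1:2, 8:9] <- TRUE   # empty region
  regs <- mk_regions(m)
  pts <- data.frame(row = c(5L, 6L), col = c(5L, 4L))
  expect_identical(match_detections(regs, pts), c(tp = 2L, fp = 1L, fn = 0L))

  # random configurations against brute-force membership enumeration
  set.seed(51)
  for (rep in 1:5) {
    mask <- matrix(runif(225) < 0.3, 15, 15)
    regs <- mk_regions(mask)
    pts <- unique(data.frame(row = sample(15L, 20, TRUE),
                             col = sample(15L, 20, TRUE)))
    got <- match_detections(regs, pts)
    inside <- vapply(seq_len(nrow(pts)), function(i)
      mask[pts$row[i], pts$col[i]], logical(1))
    fp <- sum(vapply(regs, function(reg) {
      keys <- paste(reg$pixels[, 1], reg$pixels[, 2])
      !any(paste(pts$row, pts$col) %in% keys)
    }, logical(1)))
    expect_identical(got, c(tp = sum(inside), fn = sum(!inside), fp = fp)
                     [c("tp", "fp", "fn")])
    expect_identical(got[["tp"]] + got[["fn"]], nrow(pts))
  }
})

test_that("precision/recall/F reproduce the published contingency tables", {
  # whole-image dataset: 52 frames, 15,773 / 2,434 / 314
  d1 <- precision_recall_f(15773, 2434, 314)
  expect_identical(round(d1[["precision"]], 2), 0.87)
  expect_identical(round(d1[["recall"]], 2), 0.98)
  expect_identical(round(d1[["f_measure"]], 2), 0.92)
  # per-plot dataset: 40 plots, 2,762 / 587 / 44
  d2 <- precision_recall_f(2762, 587, 44)
  expect_identical(round(d2[["precision"]], 2), 0.82)
  expect_identical(round(d2[["recall"]], 2), 0.98)
  # the F value implied by these counts (the printed table's 0.89 is not
  # consistent with its own counts; we report the computed value)
  expect_equal(d2[["f_measure"]], 0.8974817, tolerance = 1e-6)

  expect_identical(unname(precision_recall_f(10, 0, 0)), c(1, 1, 1))
  expect_warning(p <- precision_recall_f(0, 0, 5), "precision undefined")
  expect_true(is.na(p[["precision"]]))
})

test_that("counting R^2 is the squared Pearson correlation", {
  expect_equal(counting_r2(c(3, 7, 11, 2), c(3, 7, 11, 2)), 1)
  # perfect negative linear relation also gives 1 by definition
  expect_equal(counting_r2(1:4, 4:1), 1)
  set.seed(52)
  a <- rnorm(30, 100, 20); b <- a + rnorm(30, 0, 10)
  n <- length(a)
  direct <- ((sum(a * b) - n * mean(a) * mean(b)) /
               sqrt((sum(a^2) - n * mean(a)^2) *
                      (sum(b^2) - n * mean(b)^2)))^2
  expect_equal(counting_r2(a, b), direct, tolerance = 1e-12)
  expect_warning(r <- counting_r2(rep(5, 4), 1:4), "zero variance")
  expect_true(is.na(r))
  expect_error(counting_r2(1:2, 1:2), "at least 3")
})

test_that("evaluate_dataset micro-averages and is batching-invariant", {
  m1 <- matrix(FALSE, 10, 10); m1[2:4, 2:4] <- TRUE
  m2 <- matrix(FALSE, 10, 10); m2[5:7, 5:7] <- TRUE; m2[1, 9:10] <- TRUE
  labels <- rbind(
    data.frame(image_id = "a", row = c(3L, 2L), col = c(3L, 4L)),
    data.frame(image_id = "b", row = c(6L, 9L), col = c(6L, 9L)))
  det <- list(a = mk_regions(m1), b = mk_regions(m2))
  rep_ab <- evaluate_dataset(det, labels)
  expect_identical(rep_ab$tp, 3L)   # 2 in a, 1 in b
  expect_identical(rep_ab$fp, 1L)   # the stray 1x2 region in b
  expect_identical(rep_ab$fn, 1L)   # point (9,9) in b uncovered
  expect_equal(rep_ab$precision, 3 / 4)
  expect_equal(rep_ab$recall, 3 / 4)
  # pooling by image equals pooling all at once
  ra <- match_detections(det$a, labels[labels$image_id == "a", ])
  rb <- match_detections(det$b, labels[labels$image_id == "b", ])
  expect_identical(rep_ab$tp, ra[["tp"]] + rb[["tp"]])
  expect_identical(rep_ab$fp, ra[["fp"]] + rb[["fp"]])
  expect_identical(rep_ab$fn, ra[["fn"]] + rb[["fn"]])

  expect_message(
    rep_skip <- evaluate_dataset(c(det, list(zz = mk_regions(m1))), labels),
    "no labels")
  expect_identical(rep_skip$n_images, 2L)
  expect_error(evaluate_dataset(list(), labels), "no images")
})

test_that("spurious regions hurt precision only; missed points recall only", {
  m <- matrix(FALSE, 10, 10); m[2:4, 2:4] <- TRUE
  labels <- data.frame(image_id = "a", row = 3L, col = 3L)
  base <- evaluate_dataset(list(a = mk_regions(m)), labels)
  # add an empty detected region
  m_extra <- m; m_extra[8:9, 8:9] <- TRUE
  more_regions <- evaluate_dataset(list(a = mk_regions(m_extra)), labels)
  expect_lt(more_regions$precision, base$precision)
  expect_identical(more_regions$recall, base$recall)
  # add an unlabeled (spurious) point outside every region
  labels2 <- rbind(labels, data.frame(image_id = "a", row = 10L, col = 1L))
  more_points <- evaluate_dataset(list(a = mk_regions(m)), labels2)
  expect_lt(more_points$recall, base$recall)
  expect_identical(more_points$precision, base$precision)
})

test_that("reports carry counting R^2 with slope diagnostics and serialize", {
  tmp <- withr::local_tempdir()
  masks <- lapply(1:4, function(i) {
    m <- matrix(FALSE, 12, 12); m[(2 * i):(2 * i + 1), 3:5] <- TRUE; m
  })
  det <- lapply(masks, mk_regions)
  names(det) <- paste0("im", 1:4)
  labels <- do.call(rbind, lapply(1:4, function(i)
    data.frame(image_id = paste0("im", i),
               row = rep(2L * i, i), col = seq(3L, length.out = i))))
  counts <- list(im1 = 1L, im2 = 2L, im3 = 3L, im4 = 4L)
  rep4 <- evaluate_dataset(det, labels, counts)
  expect_equal(rep4$r_squared, 1)
  expect_equal(rep4$slope, 1)
  p <- file.path(tmp, "report.json")
  write_eval_report(rep4, p)
  back <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(back$r_squared, 1)
  expect_identical(back$tp, rep4$tp)
  expect_true(file.exists(file.path(tmp, "report_per_image.csv")))
})
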