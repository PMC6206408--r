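# Detection and counting evaluation against hand-labeled head centers.
#
# Matching is by point-in-region containment: true positives and false
# negatives are counted over labeled points, false positives over detected
# regions containing no point.  This asymmetry is what makes TP + FN equal
# the total number of labeled heads.

#' Match detected regions against labeled head centers
#'
#' @param regions list of `head_region` objects for one image.
#' @param points data frame with `row`, `col` columns: the image's labeled
#'   head centers.
#' @return Named integer vector `c(tp, fp, fn)`: labeled points covered by
#'   some region, regions containing no point, and points in no region.
#' @export
match_detections <- function(regions, points) {
  pt_key <- paste(points$row, points$col)
  covered <- rep(FALSE, length(pt_key))
  fp <- 0L
  for (reg in regions) {
    inside <- pt_key %in% paste(reg$pixels[, 1], reg$pixels[, 2])
    if (!any(inside)) fp <- fp + 1L
    covered <- covered | inside
  }
  c(tp = sum(covered), fp = fp, fn = sum(!covered))
}

#' Precision, recall and F-measure from a detection contingency
#'
#' Standard formulas: precision = TP / (TP + FP), recall = TP / (TP + FN),
#' F = 2 P R / (P + R).  Values are returned at full precision; rounding
#' (to 2 decimals) happens only when reports are printed.  Undefined ratios
#' (zero denominators) are returned as `NA` with a warning.
#'
#' @param tp,fp,fn non-negative counts.
#' @return Named numeric vector `c(precision, recall, f_measure)`.
#' @export
precision_recall_f <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    warnf("precision undefined: no detected regions"); NA_real_
  }
  recall <- if (tp + fn > 0) tp / (tp + fn) else {
    warnf("recall undefined: no labeled points"); NA_real_
  }
  f <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  c(precision = precision, recall = recall, f_measure = f)
}

#' Coefficient of determination between manual and predicted counts
#'
#' Squared Pearson correlation of the per-image (manual total, predicted
#' total) pairs.  A perfect negative linear relation also gives 1; reports
#' therefore carry the regression slope alongside.
#'
#' @param manual,predicted numeric vectors of per-image head totals, same
#'   length, at least 3 images.
#' @return The squared correlation in `[0, 1]`, or `NA` with a warning when
#'   either vector has zero variance.
#' @export
counting_r2 <- function(manual, predicted) {
  if (length(manual) != length(predicted))
    stopf("`manual` and `predicted` must have equal length")
  if (length(manual) < 3L) stopf("need at least 3 images for R^2")
  if (stats::var(manual) == 0 || stats::var(predicted) == 0) {
    warnf("R^2 undefined: zero variance in counts")
    return(NA_real_)
  }
  stats::cor(manual, predicted)^2
}

#' Evaluate detection and counting over a dataset
#'
#' Pools the per-image contingencies before computing ratios
#' (micro-averaging) and computes the counting R-squared over per-image
#' totals (manual total = number of labeled points; predicted total = sum
#' of per-region predicted counts).
#'
#' @param detections named list, one entry per image id, each a list of
#'   `head_region` objects.
#' @param labels data frame of labeled points with columns `image_id`,
#'   `row`, `col` (see [read_point_labels()]).
#' @param counts optional named list parallel to `detections` giving each
#'   image's per-region predicted counts; enables the counting R-squared.
#' @return Object of class `head_eval_report`: pooled `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f_measure`, `r_squared` (with `slope` and
#'   `intercept` diagnostics) and a `per_image` data frame.
#' @export
evaluate_dataset <- function(detections, labels, counts = NULL) {
  if (!length(detections)) stopf("no images to evaluate")
  ids <- names(detections)
  if (is.null(ids) || any(ids == ""))
    stopf("`detections` must be a named list keyed by image id")
  labeled <- unique(labels$image_id)
  skip <- setdiff(ids, labeled)
  if (length(skip)) {
    message(sprintf("excluding %d image(s) with no labels: %s",
                    length(skip), paste(skip, collapse = ", ")))
    ids <- setdiff(ids, skip)
  }
  if (!length(ids)) stopf("no labeled images to evaluate")
  per <- lapply(ids, function(id) {
    pts <- labels[labels$image_id == id, , drop = FALSE]
    m <- match_detections(detections[[id]], pts)
    data.frame(image_id = id, tp = m[["tp"]], fp = m[["fp"]],
               fn = m[["fn"]], manual_total = nrow(pts),
               predicted_total = if (is.null(counts)) NA_integer_
               else count_image(counts[[id]]),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  prf <- precision_recall_f(sum(per$tp), sum(per$fp), sum(per$fn))
  r2 <- slope <- intercept <- NA_real_
  if (!is.null(counts) && nrow(per) >= 3L) {
    r2 <- counting_r2(per$manual_total, per$predicted_total)
    if (!is.na(r2)) {
      fit <- stats::lm(predicted_total ~ manual_total, data = per)
      slope <- unname(stats::coef(fit)[2])
      intercept <- unname(stats::coef(fit)[1])
    }
  }
  structure(list(
    tp = sum(per$tp), fp = sum(per$fp), fn = sum(per$fn),
    precision = prf[["precision"]], recall = prf[["recall"]],
    f_measure = prf[["f_measure"]],
    r_squared = r2, slope = slope, intercept = intercept,
    n_images = nrow(per), per_image = per
  ), class = "head_eval_report")
}

#' @export
print.head_eval_report <- function(x, digits = 2L, ...) {
  cat(sprintf("Head detection over %d image(s)\n", x$n_images))
  cat(sprintf("  TP %d  FP %d  FN %d\n", x$tp, x$fp, x$fn))
  cat(sprintf("  precision %.*f  recall %.*f  F-measure %.*f\n",
              digits, x$precision, digits, x$recall, digits, x$f_measure))
  if (!is.na(x$r_squared))
    cat(sprintf("  counting R^2 %.*f (slope %.2f, intercept %.1f)\n",
                digits, x$r_squared, x$slope, x$intercept))
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report a `head_eval_report`.
#' @param path output path; the per-image breakdown is written alongside
#'   as `<path without extension>_per_image.csv`.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  fields <- report[c("tp", "fp", "fn", "precision", "recall", "f_measure",
                     "r_squared", "slope", "intercept", "n_images")]
  jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  utils::write.csv(report$per_image,
                   paste0(tools::file_path_sans_ext(path), "_per_image.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
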