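# Per-region head counting: count labels from point annotations, the
# six-set model-assessment split, and the quadratic-kernel SVM classifier
# from 11 morphology features to a head count.

#' Label candidate regions with ground-truth head counts
#'
#' Each hand-labeled head center point is assigned to the (unique) region
#' whose pixel set contains it; a region's true count is the number of
#' points it contains.  Regions containing no point get count 0 (incorrect
#' detections); points inside no region contribute to no row.  Points on a
#' region's boundary pixels are inside (membership is per pixel).
#'
#' @param regions list of `head_region` objects from one image.
#' @param points data frame with `row`, `col` columns (the image's labeled
#'   head centers).
#' @param image_id provenance string.
#' @return Data frame: [region_feature_table()] columns plus `true_count`.
#' @export
label_regions_with_counts <- function(regions, points, image_id = "image") {
  tab <- region_feature_table(regions, image_id = image_id)
  pt_key <- paste(points$row, points$col)
  tab$true_count <- vapply(regions, function(reg) {
    sum(pt_key %in% paste(reg$pixels[, 1], reg$pixels[, 2]))
  }, integer(1))
  tab
}

#' Partition image ids into six balanced sets
#'
#' The model-assessment protocol partitions the images uniformly at random
#' into `n_sets` sets whose sizes differ by at most one (52 images give four
#' sets of 9 and two of 8); models are trained on all but the designated
#' held-out set.
#'
#' @param image_ids character vector of image ids.
#' @param seed integer RNG seed; the same seed always yields the same
#'   partition.
#' @param n_sets number of sets (default 6).
#' @param holdout index of the designated held-out set (default the last).
#' @return List with `sets` (list of id vectors) and `holdout` (integer).
#' @export
split_six_sets <- function(image_ids, seed = 1L, n_sets = 6L,
                           holdout = n_sets) {
  n <- length(image_ids)
  if (n < n_sets)
    stopf("need at least %d images to form %d sets, got %d", n_sets,
          n_sets, n)
  if (anyDuplicated(image_ids)) stopf("image ids must be unique")
  assign <- with_seed(seed, {
    sample(rep(seq_len(n_sets), length.out = n))
  })
  structure(list(sets = split(image_ids, assign),
                 holdout = as.integer(holdout)),
            class = "six_set_split")
}

#' @export
print.six_set_split <- function(x, ...) {
  cat(sprintf("Six-set split: sizes %s, held-out set %d\n",
              paste(lengths(x$sets), collapse = "/"), x$holdout))
  invisible(x)
}

count_feature_matrix <- function(table) {
  miss <- setdiff(REGION_FEATURE_NAMES, colnames(table))
  if (length(miss))
    stopf("missing region feature column(s): %s", paste(miss, collapse = ", "))
  as.matrix(as.data.frame(table)[, REGION_FEATURE_NAMES])
}

#' Fit the quadratic-SVM head count classifier
#'
#' Trains a multi-class support vector machine with a quadratic (degree-2
#' polynomial) kernel that maps a region's 11 morphology features to its
#' head count.  Features are standardized with training statistics; counts
#' above `cap` are pooled into the `cap` class; multi-class reduction is
#' one-vs-one.  k-fold cross-validated accuracy is computed with
#' fold-internal standardization (no leakage) and stored in the model.
#'
#' @param table a count-labeled table from [label_regions_with_counts()]
#'   (possibly row-bound over images): the 11 feature columns plus
#'   `true_count`.
#' @param folds number of cross-validation folds (default 5).
#' @param seed integer RNG seed for the fold assignment.
#' @param cost SVM box constraint C (default 1).
#' @param cap counts above this are pooled into one class (default 5).
#' @param gamma polynomial kernel scale; default 1/11 on the standardized
#'   features.
#' @return Object of class `head_count_model` with the fitted SVM, the
#'   observed count classes, CV accuracy and fold assignment, and the
#'   feature convention tag.
#' @export
head_count_model <- function(table, folds = 5L, seed = 1L, cost = 1,
                             cap = 5L, gamma = NULL) {
  conv <- attr(table, "perimeter_convention")
  if (!is.null(conv) && !identical(conv, PERIMETER_CONVENTION))
    stopf("feature table uses perimeter convention '%s'; this package fits
models under '%s'", conv, PERIMETER_CONVENTION)
  if (!"true_count" %in% colnames(table))
    stopf("`table` must contain a `true_count` column")
  x <- count_feature_matrix(table)
  n <- nrow(x)
  y <- pmin(as.integer(table$true_count), as.integer(cap))
  classes <- sort(unique(y))
  if (length(classes) < 2L)
    stopf("degenerate count table: need >= 2 distinct count classes")
  if (n < folds) stopf("need at least `folds` = %d rows, got %d", folds, n)
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  yf <- factor(y, levels = classes)
  fit_svm <- function(xt, yt) {
    e1071::svm(x = xt, y = droplevels(yt), scale = TRUE,
               kernel = "polynomial", degree = 2L, coef0 = 1,
               gamma = gamma, cost = cost)
  }
  fold_id <- with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  cv_pred <- integer(n)
  for (k in seq_len(folds)) {
    hold <- fold_id == k
    fit_k <- fit_svm(x[!hold, , drop = FALSE], yf[!hold])
    cv_pred[hold] <- as.integer(as.character(
      predict(fit_k, x[hold, , drop = FALSE])))
  }
  fit <- fit_svm(x, yf)
  structure(list(
    svm = fit,
    classes = classes,
    cap = as.integer(cap),
    folds = as.integer(folds),
    fold_id = fold_id,
    cv_accuracy = mean(cv_pred == y),
    cv_predictions = cv_pred,
    params = list(cost = cost, gamma = gamma),
    seed = as.integer(seed),
    n_train = n,
    feature_convention = PERIMETER_CONVENTION,
    schema_version = MODEL_SCHEMA_VERSION
  ), class = "head_count_model")
}

#' @export
print.head_count_model <- function(x, ...) {
  cat("Quadratic-SVM head count classifier\n")
  cat(sprintf("  count classes: %s (cap %d)\n",
              paste(x$classes, collapse = ", "), x$cap))
  cat(sprintf("  trained on %d regions; %d-fold CV accuracy %.3f\n",
              x$n_train, x$folds, x$cv_accuracy))
  invisible(x)
}

#' @export
summary.head_count_model <- function(object, ...) {
  print(object)
  cat(sprintf("  support vectors: %d; C = %g, gamma = %g\n",
              object$svm$tot.nSV, object$params$cost, object$params$gamma))
  invisible(object)
}

#' Predict per-region head counts
#'
#' @param object a [head_count_model()].
#' @param features data frame or matrix holding the 11 region feature
#'   columns (e.g. from [region_feature_table()]); a mismatching perimeter
#'   convention attribute is refused.
#' @param ... unused.
#' @return Integer vector of predicted counts, one per region (0 flags a
#'   region judged to be an incorrect detection).
#' @export
predict.head_count_model <- function(object, features, ...) {
  conv <- attr(features, "perimeter_convention")
  if (!is.null(conv) && !identical(conv, object$feature_convention))
    stopf("feature convention '%s' does not match the model's '%s'",
          conv, object$feature_convention)
  x <- count_feature_matrix(features)
  if (nrow(x) == 0L) return(integer())
  as.integer(as.character(predict(object$svm, x)))
}

#' Total head count of an image
#'
#' @param counts integer vector of per-region predicted counts.
#' @return Their sum (regions flagged 0 contribute nothing).
#' @export
count_image <- function(counts) {
  if (!length(counts)) return(0L)
  as.integer(sum(counts))
}
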