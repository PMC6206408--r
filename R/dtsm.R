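# Decision-tree segmentation model (DTSM): a CART classifier over the nine
# color features that assigns every pixel one of the seven scene classes.

#' Fit a decision-tree segmentation model
#'
#' Trains a CART decision tree (Gini impurity, axis-aligned splits) that maps
#' the nine color features of a pixel to one of the seven scene classes.
#' Ties in leaf majorities are broken toward the lowest class code, so
#' predictions are fully deterministic; the tree itself is a deterministic
#' function of the training table.
#'
#' @param table a `feature_table` from [collect_training_samples()] /
#'   [bind_feature_tables()]: nine feature columns plus `class`.
#' @param max_depth maximum tree depth (default 12).
#' @param min_leaf minimum number of training pixels per leaf (default 5).
#' @param cp complexity parameter passed to [rpart::rpart()]; the small
#'   default lets the tree grow to the depth/leaf limits.
#' @param seed integer recorded in the model metadata (tree fitting itself
#'   is deterministic).
#' @return An object of class `dtsm`: the fitted tree plus metadata
#'   (classes seen, per-class sample counts, resubstitution accuracy,
#'   schema version).
#' @seealso [predict.dtsm()], [head_mask()], [save_model()]
#' @export
dtsm <- function(table, max_depth = 12L, min_leaf = 5L, cp = 1e-6,
                 seed = 1L) {
  df <- as.data.frame(table)
  need <- c(FEATURE_NAMES, "class")
  if (!all(need %in% names(df)))
    stopf("training table must contain columns: %s",
          paste(need, collapse = ", "))
  if (nrow(df) == 0L) stopf("training table is empty")
  counts <- tabulate(df$class, nbins = 7L)
  classes <- which(counts > 0L)
  if (length(classes) < 2L)
    stopf("degenerate training set: need >= 2 distinct classes, got %d",
          length(classes))
  df$class <- factor(df$class, levels = classes)
  fit <- with_seed(seed, rpart::rpart(
    class ~ r + g + b + h + s + v + L_star + a_star + b_star,
    data = df, method = "class",
    parms = list(split = "gini"),
    control = rpart::rpart.control(maxdepth = max_depth,
                                   minbucket = min_leaf,
                                   minsplit = 2L * min_leaf,
                                   cp = cp, xval = 0L)
  ))
  resub <- mean(predict_tree_class(fit, df, classes) == as.integer(
    as.character(df$class)))
  structure(list(
    tree = fit,
    classes = classes,
    n_per_class = counts[classes],
    params = list(max_depth = max_depth, min_leaf = min_leaf, cp = cp),
    seed = as.integer(seed),
    resubstitution_accuracy = resub,
    schema_version = MODEL_SCHEMA_VERSION
  ), class = "dtsm")
}

# Deterministic class prediction: argmax over leaf class proportions with
# ties broken toward the lowest class code (columns are in code order).
predict_tree_class <- function(fit, newdata, classes) {
  prob <- predict(fit, newdata = newdata, type = "prob")
  classes[max.col(prob, ties.method = "first")]
}

#' Classify every pixel of an image
#'
#' Applies a fitted DTSM to an image, assigning each pixel one scene class.
#' The result is a pure function of the model and the image.
#'
#' @param object a [dtsm()] model.
#' @param img an [rgb_image()].
#' @param ... unused.
#' @return Integer H x W matrix of class codes (a "class map").
#' @export
predict.dtsm <- function(object, img, ...) {
  img <- rgb_image(img)
  d <- dim(img)
  feats <- as.data.frame(feature_matrix(img))
  cls <- predict_tree_class(object$tree, feats, object$classes)
  matrix(cls, nrow = d[1], ncol = d[2])
}

#' @export
print.dtsm <- function(x, ...) {
  cat("Decision-tree segmentation model (DTSM)\n")
  cat(sprintf("  classes: %s\n", paste(x$classes, collapse = ", ")))
  cat(sprintf("  training pixels per class: %s\n",
              paste(x$n_per_class, collapse = ", ")))
  cat(sprintf("  max depth %d, min leaf %d\n",
              x$params$max_depth, x$params$min_leaf))
  cat(sprintf("  resubstitution accuracy: %.4f\n",
              x$resubstitution_accuracy))
  invisible(x)
}

#' @export
summary.dtsm <- function(object, ...) {
  print(object)
  cat("\nTree:\n")
  print(object$tree)
  invisible(object)
}

#' Reduce a class map to the binary head mask
#'
#' Head pixels are those classified as any of the three head color classes
#' (green, orange or white heads); the mask is their union.
#'
#' @param cmap integer matrix of class codes 1..7.
#' @return Logical H x W matrix, `TRUE` at head pixels.
#' @export
head_mask <- function(cmap) {
  if (anyNA(cmap) || min(cmap) < 1L || max(cmap) > 7L)
    stopf("class map codes must be in 1..7")
  matrix(cmap %in% head_class_codes(), nrow = nrow(cmap))
}

#' Pseudo-color rendering of a class map
#'
#' Renders the seven scene classes with the display scheme used throughout
#' the package's figures: soil gray, shadow black, dead leaves off-white,
#' leaves green, green heads light orange, orange heads dark orange, white
#' heads yellow.
#'
#' @param cmap integer matrix of class codes 1..7.
#' @return An [rgb_image()].
#' @export
pseudo_color <- function(cmap) {
  pal <- rbind(
    soil = c(128, 128, 128),
    shadow = c(0, 0, 0),
    dead_leaves = c(245, 245, 220),
    leaves = c(0, 128, 0),
    green_head = c(255, 200, 120),
    orange_head = c(210, 105, 30),
    white_head = c(255, 255, 0)
  )
  if (anyNA(cmap) || min(cmap) < 1L || max(cmap) > 7L)
    stopf("class map codes must be in 1..7")
  rgb_image(array(pal[as.vector(cmap), ], dim = c(dim(cmap), 3L)))
}

#' Persist a fitted model
#'
#' Serializes a [dtsm()] or [head_count_model()] together with its schema
#' version; [load_model()] refuses files whose schema it does not know and
#' reloaded models predict identically.
#'
#' @param model a `dtsm` or `head_count_model` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, c("dtsm", "head_count_model")))
    stopf("`model` must be a dtsm or head_count_model")
  saveRDS(model, path, version = 3L)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stopf("model file not found: %s", path)
  model <- readRDS(path)
  if (!inherits(model, c("dtsm", "head_count_model")) ||
      !identical(model$schema_version, MODEL_SCHEMA_VERSION))
    stopf("%s is not a model file with schema version %d",
          path, MODEL_SCHEMA_VERSION)
  model
}
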