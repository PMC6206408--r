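# Pipeline orchestration: staged runs over an on-disk dataset directory
# (as written by generate_dataset()) and the in-memory end-to-end synthetic
# experiment used for validation.
#
# Every stage writes a run log (parameters, seeds, package version) next to
# its outputs so runs are reproducible and auditable.

write_run_log <- function(dir, stage, params) {
  log <- list(stage = stage,
              package_version = as.character(utils::packageVersion("headcount")),
              params = params)
  jsonlite::write_json(log, file.path(dir, paste0(stage, "_run.json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

read_manifest <- function(data_dir) {
  path <- file.path(data_dir, "manifest.json")
  if (!file.exists(path))
    stopf("no manifest.json in %s; run the simulate stage first", data_dir)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Pipeline stage: simulate a dataset
#'
#' @param out_dir dataset directory to create.
#' @param n_images number of images.
#' @param params a [field_sim_params()].
#' @param seed master seed.
#' @return The dataset manifest, invisibly.
#' @export
pipe_simulate <- function(out_dir, n_images = 52L,
                          params = field_sim_params(), seed = 1L) {
  man <- generate_dataset(n_images, params, dir = out_dir, seed = seed)
  write_run_log(out_dir, "simulate",
                list(n_images = n_images, seed = seed,
                     height = params$height, width = params$width))
  invisible(man)
}

#' Pipeline stage: train the segmentation model
#'
#' Collects labeled pixels from the dataset's class annotations (optionally
#' a subset of images) and fits a [dtsm()].
#'
#' @param data_dir dataset directory.
#' @param model_path where to persist the model.
#' @param train_ids image ids used for training (default: all).
#' @param max_per_class per-image, per-class pixel sampling cap.
#' @param max_depth,min_leaf tree hyper-parameters.
#' @param seed RNG seed.
#' @return The fitted `dtsm`, invisibly.
#' @export
pipe_train_seg <- function(data_dir, model_path, train_ids = NULL,
                           max_per_class = 1000L, max_depth = 12L,
                           min_leaf = 5L, seed = 1L) {
  man <- read_manifest(data_dir)
  ids <- if (is.null(train_ids)) man$image_ids else train_ids
  tabs <- lapply(seq_along(ids), function(i) {
    id <- ids[i]
    j <- match(id, man$image_ids)
    if (is.na(j)) stopf("image id '%s' not in manifest", id)
    img <- read_image(file.path(data_dir, man$images[j]))
    ann <- read_class_annotation(file.path(data_dir, man$classes[j]))
    collect_training_samples(img, ann, max_per_class = max_per_class,
                             seed = seed + i, image_id = id)
  })
  model <- dtsm(do.call(bind_feature_tables, tabs), max_depth = max_depth,
                min_leaf = min_leaf, seed = seed)
  save_model(model, model_path)
  write_run_log(dirname(model_path), "train_seg",
                list(train_ids = ids, max_per_class = max_per_class,
                     max_depth = max_depth, min_leaf = min_leaf,
                     seed = seed))
  invisible(model)
}

#' Pipeline stage: segment all images
#'
#' Writes each image's predicted class map (grayscale code PNG) and its
#' pseudo-color rendering.
#'
#' @param data_dir dataset directory.
#' @param model_path path to a persisted [dtsm()].
#' @param out_dir output directory for class maps.
#' @return Invisibly, the vector of written class-map paths.
#' @export
pipe_segment <- function(data_dir, model_path, out_dir) {
  man <- read_manifest(data_dir)
  model <- load_model(model_path)
  if (!inherits(model, "dtsm")) stopf("%s is not a dtsm model", model_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(man$image_ids))
  for (j in seq_along(man$image_ids)) {
    img <- read_image(file.path(data_dir, man$images[j]))
    cmap <- predict(model, img)
    paths[j] <- file.path(out_dir, paste0(man$image_ids[j], "_classes.png"))
    write_class_annotation(cmap, paths[j])
    write_image(pseudo_color(cmap),
                file.path(out_dir, paste0(man$image_ids[j], "_pseudo.png")))
  }
  write_run_log(out_dir, "segment", list(model = model_path))
  invisible(paths)
}

segmented_regions <- function(data_dir, seg_dir, min_area) {
  man <- read_manifest(data_dir)
  regions <- lapply(man$image_ids, function(id) {
    cmap <- read_class_annotation(file.path(seg_dir,
                                            paste0(id, "_classes.png")))
    extract_regions(head_mask(cmap), min_area = min_area)
  })
  names(regions) <- man$image_ids
  regions
}

#' Pipeline stage: train the head count classifier
#'
#' Splits the dataset's images into six sets, labels the segmented regions
#' of the five training sets with ground-truth counts, and fits the
#' quadratic-SVM count model with k-fold cross validation.
#'
#' @param data_dir dataset directory.
#' @param seg_dir directory written by [pipe_segment()].
#' @param model_path where to persist the model.
#' @param min_area region minimum area.
#' @param folds cross-validation folds.
#' @param seed RNG seed (split and fold assignment).
#' @return List with the fitted model and the split, invisibly.
#' @export
pipe_train_count <- function(data_dir, seg_dir, model_path, min_area = 20L,
                             folds = 5L, seed = 1L) {
  man <- read_manifest(data_dir)
  labels <- read_point_labels(file.path(data_dir, man$points))
  regions <- segmented_regions(data_dir, seg_dir, min_area)
  split <- split_six_sets(man$image_ids, seed = seed)
  train_ids <- unlist(split$sets[-split$holdout], use.names = FALSE)
  tabs <- lapply(train_ids, function(id) {
    label_regions_with_counts(regions[[id]],
                              labels[labels$image_id == id, , drop = FALSE],
                              image_id = id)
  })
  tab <- do.call(rbind, tabs)
  attr(tab, "perimeter_convention") <- PERIMETER_CONVENTION
  model <- head_count_model(tab, folds = folds, seed = seed)
  save_model(model, model_path)
  jsonlite::write_json(list(sets = split$sets, holdout = split$holdout),
                       file.path(dirname(model_path), "six_set_split.json"),
                       auto_unbox = TRUE)
  write_run_log(dirname(model_path), "train_count",
                list(min_area = min_area, folds = folds, seed = seed,
                     cv_accuracy = model$cv_accuracy))
  invisible(list(model = model, split = split))
}

#' Pipeline stage: count heads in every image
#'
#' @param data_dir dataset directory.
#' @param seg_dir segmentation output directory.
#' @param model_path path to a persisted [head_count_model()].
#' @param out_csv per-region prediction CSV to write.
#' @param min_area region minimum area.
#' @return Data frame of per-region predictions, invisibly.
#' @export
pipe_count <- function(data_dir, seg_dir, model_path, out_csv,
                       min_area = 20L) {
  model <- load_model(model_path)
  if (!inherits(model, "head_count_model"))
    stopf("%s is not a head_count_model", model_path)
  regions <- segmented_regions(data_dir, seg_dir, min_area)
  rows <- lapply(names(regions), function(id) {
    tab <- region_feature_table(regions[[id]], image_id = id)
    tab$predicted_count <- predict(model, tab)
    tab
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, out_csv, row.names = FALSE, quote = FALSE)
  write_run_log(dirname(out_csv), "count",
                list(model = model_path, min_area = min_area))
  invisible(out)
}

#' Pipeline stage: evaluate detection and counting
#'
#' @param data_dir dataset directory.
#' @param seg_dir segmentation output directory.
#' @param counts_csv per-region predictions from [pipe_count()].
#' @param out_json report path ("" to skip writing).
#' @param min_area region minimum area.
#' @param ids evaluate only these image ids (default: all).
#' @return The `head_eval_report`.
#' @export
pipe_evaluate <- function(data_dir, seg_dir, counts_csv, out_json = "",
                          min_area = 20L, ids = NULL) {
  man <- read_manifest(data_dir)
  labels <- read_point_labels(file.path(data_dir, man$points))
  regions <- segmented_regions(data_dir, seg_dir, min_area)
  preds <- utils::read.csv(counts_csv, stringsAsFactors = FALSE)
  if (!is.null(ids)) regions <- regions[ids]
  counts <- lapply(names(regions), function(id) {
    preds$predicted_count[preds$image_id == id]
  })
  names(counts) <- names(regions)
  report <- evaluate_dataset(regions, labels, counts)
  if (nzchar(out_json)) write_eval_report(report, out_json)
  report
}

# ---------------------------------------------------------------------------

#' Segment, count and evaluate a list of in-memory fields
#'
#' Applies trained segmentation and counting models to synthetic fields
#' (lists of `(image, truth)` as produced by [generate_field_image()]) and
#' evaluates detection and counting against the ground truth.
#'
#' @param seg_model a fitted [dtsm()].
#' @param count_model a fitted [head_count_model()] (or `NULL` to skip
#'   counting).
#' @param fields named list of `(image, truth)` fields.
#' @param min_area region minimum area.
#' @return List: `detections`, `labels`, `counts`, `count_tables` (with
#'   true and predicted per-region counts) and the evaluation `report`.
#' @export
evaluate_fields <- function(seg_model, count_model, fields,
                            min_area = 20L) {
  ids <- names(fields)
  detections <- vector("list", length(ids))
  count_tables <- vector("list", length(ids))
  counts <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    fld <- fields[[i]]
    cmap <- predict(seg_model, fld$image)
    regs <- extract_regions(head_mask(cmap), min_area = min_area)
    tab <- label_regions_with_counts(regs, fld$truth$points,
                                     image_id = ids[i])
    if (!is.null(count_model)) {
      attr(tab, "perimeter_convention") <- PERIMETER_CONVENTION
      tab$predicted_count <- predict(count_model, tab)
      counts[[i]] <- tab$predicted_count
    }
    detections[[i]] <- regs
    count_tables[[i]] <- tab
  }
  names(detections) <- names(counts) <- names(count_tables) <- ids
  labels <- do.call(rbind, lapply(fields, function(f) f$truth$points))
  rownames(labels) <- NULL
  report <- evaluate_dataset(detections, labels,
                             if (is.null(count_model)) NULL else counts)
  list(detections = detections, labels = labels, counts = counts,
       count_tables = count_tables, report = report)
}

#' Run the full synthetic end-to-end experiment
#'
#' Mirrors the real-data protocol at desk scale: a separate set of images
#' provides pixel scribbles to train the segmentation model; `n_images`
#' fields are then segmented; regions of five of six sets train the
#' quadratic-SVM count model with k-fold cross validation; the sixth set is
#' held out for detection and counting evaluation.
#'
#' The segmentation training set emulates a collection deliberately chosen
#' for lighting diversity: its images draw their illumination gains from
#' stratified sub-intervals covering the full gain range, so every lighting
#' condition the evaluation images can exhibit is represented.
#'
#' @param n_images number of evaluation images (default 52).
#' @param n_seg_train images generated for segmentation training
#'   (default 17).
#' @param params a [field_sim_params()].
#' @param seed master seed; all internal seeds derive from it.
#' @param min_area region minimum area.
#' @param folds count-model cross-validation folds.
#' @param max_per_class per-image per-class pixel sampling cap for
#'   segmentation training.
#' @return List: `seg_model`, `count_model`, `split`, `fields`,
#'   `holdout_ids`, `eval_holdout`, `eval_all` (each an
#'   [evaluate_fields()] result).
#' @export
run_synthetic_experiment <- function(n_images = 52L, n_seg_train = 17L,
                                     params = field_sim_params(),
                                     seed = 20181023L, min_area = 20L,
                                     folds = 5L, max_per_class = 1000L) {
  seeds <- with_seed(seed, sample.int(.Machine$integer.max,
                                      n_images + n_seg_train + 2L))
  # --- segmentation training on its own, lighting-stratified image set ----
  gain_edges <- seq(params$gain_range[1], params$gain_range[2],
                    length.out = n_seg_train + 1L)
  seg_tabs <- lapply(seq_len(n_seg_train), function(i) {
    p_i <- params
    p_i$gain_range <- c(gain_edges[i], gain_edges[i + 1L])
    fld <- generate_field_image(p_i, seed = seeds[i],
                                image_id = sprintf("seg_%02d", i))
    collect_training_samples(fld$image, fld$truth$class_map,
                             max_per_class = max_per_class,
                             seed = seeds[i], image_id = sprintf("seg_%02d", i))
  })
  seg_model <- dtsm(do.call(bind_feature_tables, seg_tabs),
                    seed = seeds[n_seg_train + 1L])
  # --- evaluation fields ---------------------------------------------------
  ids <- sprintf("img_%03d", seq_len(n_images))
  fields <- lapply(seq_len(n_images), function(i) {
    generate_field_image(params, seed = seeds[n_seg_train + 2L + i - 1L],
                         image_id = ids[i])
  })
  names(fields) <- ids
  # --- six-set split; count model on five sets ----------------------------
  split_seed <- seeds[n_seg_train + 1L] %% 100000L + 1L
  split <- split_six_sets(ids, seed = split_seed)
  holdout_ids <- split$sets[[split$holdout]]
  train_ids <- setdiff(ids, holdout_ids)
  train_eval <- evaluate_fields(seg_model, NULL, fields[train_ids],
                                min_area = min_area)
  train_tab <- do.call(rbind, train_eval$count_tables)
  attr(train_tab, "perimeter_convention") <- PERIMETER_CONVENTION
  count_model <- head_count_model(train_tab, folds = folds,
                                  seed = split_seed)
  # --- evaluation ----------------------------------------------------------
  eval_holdout <- evaluate_fields(seg_model, count_model,
                                  fields[holdout_ids], min_area = min_area)
  eval_all <- evaluate_fields(seg_model, count_model, fields,
                              min_area = min_area)
  list(seg_model = seg_model, count_model = count_model, split = split,
       fields = fields, holdout_ids = holdout_ids,
       eval_holdout = eval_holdout, eval_all = eval_all,
       params = params, min_area = min_area, seed = seed)
}
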