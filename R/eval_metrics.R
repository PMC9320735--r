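#' @title Class IOU and the four-step sucker-counting procedure
#'
#' @description
#' Segmentation accuracy is scored per class by intersection-over-union.
#' Sucker detection follows a four-step counting procedure: (1) binarize the
#' sucker class in prediction and ground truth, (2) remove predicted
#' connected regions smaller than an area threshold (`t = 160` px removes
#' most noise, and a real sucker must be large enough for a robot to grasp),
#' (3) split the ground-truth mask into its connected components, and
#' (4) a true sucker counts as detected when the elementwise sum of its
#' component mask and the filtered prediction mask reaches 2 anywhere, i.e.
#' when they overlap in at least one pixel.
#'
#' @name eval_metrics
NULL

#' Evaluation configuration
#'
#' @param noise_area_threshold minimum pixel area a predicted sucker region
#'   must reach to survive the noise filter (regions strictly smaller are
#'   removed; an area of exactly `t` survives).
#' @param connectivity pixel connectivity for component labeling, 4 or 8.
#' @return A list of class `eval_config`.
#' @export
eval_config <- function(noise_area_threshold = 160, connectivity = 8) {
  if (noise_area_threshold < 0) {
    tomseg_stop("noise_area_threshold must be >= 0", "tomseg_argument_error")
  }
  if (!connectivity %in% c(4, 8)) {
    tomseg_stop("connectivity must be 4 or 8", "tomseg_argument_error")
  }
  structure(list(noise_area_threshold = noise_area_threshold,
                 connectivity = connectivity), class = "eval_config")
}

#' Per-class intersection-over-union
#'
#' For each class `c`: `|pred = c & truth = c| / |pred = c | truth = c|`.
#' Classes absent from both maps are undefined (`NA`) and excluded from the
#' mean.
#'
#' @param pred,truth integer label matrices over `{0,1,2,3}` of equal shape.
#' @return A list with `per_class` (named numeric length 4) and `mean`.
#' @export
class_iou <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) {
    tomseg_stop("prediction and truth dimensions differ", "tomseg_argument_error")
  }
  per <- vapply(0:3, function(cl) {
    inter <- sum(pred == cl & truth == cl)
    uni <- sum(pred == cl | truth == cl)
    if (uni == 0) NA_real_ else inter / uni
  }, numeric(1))
  names(per) <- c("other", "stem", "branch", "sucker")
  list(per_class = per, mean = mean(per, na.rm = TRUE))
}

#' Binary sucker mask of a label map
#'
#' @param label integer label matrix.
#' @return Integer matrix, 1 where the class is sucker (3), else 0.
#' @export
sucker_binary <- function(label) {
  m <- matrix(0L, nrow(label), ncol(label))
  m[label == 3L] <- 1L
  m
}

#' Label connected components of a binary mask
#'
#' @param mask integer or logical matrix; non-zero pixels are foreground.
#' @param connectivity 4 or 8.
#' @return Integer matrix of component labels `1..n` (0 background).
#' @export
label_components <- function(mask, connectivity = 8) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  cpp_label_components(m, as.integer(connectivity))
}

#' Remove small connected regions from a binary mask
#'
#' Connected components with area strictly below the threshold are removed;
#' components with area at or above it are untouched. Idempotent.
#'
#' @param mask binary matrix.
#' @param config an [eval_config()].
#' @return Filtered binary integer matrix.
#' @export
filter_noise_regions <- function(mask, config = eval_config()) {
  lab <- label_components(mask, config$connectivity)
  if (max(lab) == 0) return(matrix(0L, nrow(mask), ncol(mask)))
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- which(areas >= config$noise_area_threshold)
  out <- matrix(0L, nrow(mask), ncol(mask))
  out[lab %in% keep] <- 1L
  out
}

#' Count correctly detected suckers
#'
#' Applies the four-step procedure: the predicted sucker mask is
#' noise-filtered, the ground-truth sucker mask is split into components
#' (annotations are trusted and not filtered), and each true component
#' counts as detected when its elementwise sum with the filtered prediction
#' reaches 2, i.e. they share at least one pixel.
#'
#' @param pred,truth integer label matrices of equal shape.
#' @param config an [eval_config()].
#' @return A list of class `sucker_count_result` with
#'   `n_ground_truth_suckers`, `n_prediction_regions_after_filter`,
#'   `n_correct` and the per-component logical `detected`.
#' @export
count_correct_suckers <- function(pred, truth, config = eval_config()) {
  if (!identical(dim(pred), dim(truth))) {
    tomseg_stop("prediction and truth dimensions differ", "tomseg_argument_error")
  }
  pmask <- filter_noise_regions(sucker_binary(pred), config)
  tlab <- label_components(sucker_binary(truth), config$connectivity)
  ng <- max(tlab)
  detected <- vapply(seq_len(ng), function(i) {
    max((tlab == i) + pmask) == 2L
  }, logical(1))
  structure(list(n_ground_truth_suckers = ng,
                 n_prediction_regions_after_filter =
                   max(label_components(pmask, config$connectivity)),
                 n_correct = sum(detected),
                 detected = detected),
            class = "sucker_count_result")
}

#' @export
print.sucker_count_result <- function(x, ...) {
  cat(sprintf("suckers: %d in ground truth, %d predicted regions after filter, %d detected\n",
              x$n_ground_truth_suckers, x$n_prediction_regions_after_filter,
              x$n_correct))
  invisible(x)
}

as_tomseg_model <- function(x) {
  if (inherits(x, "tomseg_model")) return(x)
  if (inherits(x, "tomseg_checkpoint")) return(x$model)
  tomseg_stop("expected a tomseg_model or tomseg_checkpoint", "tomseg_argument_error")
}

#' Evaluate a model over a labeled sample set
#'
#' Mean IOU aggregates summed intersections over summed unions per class
#' across all images, then averages over the classes present; it is
#' reported both over all four classes and excluding the background class.
#' Sucker detection is `100 * detected / ground-truth suckers` over the
#' whole set, or `NA` when the set contains no ground-truth sucker.
#'
#' @param model a `tomseg_model` or `tomseg_checkpoint`.
#' @param samples list of labeled [rgbd_sample()] objects.
#' @param config an [eval_config()].
#' @param t1 optional gating-threshold override.
#' @return A list of class `tomseg_report`: `mean_iou`,
#'   `mean_iou_foreground`, `per_class_iou`, `sucker_detection_pct`,
#'   `per_image` (data frame).
#' @export
evaluate_dataset <- function(model, samples, config = eval_config(), t1 = NULL) {
  model <- as_tomseg_model(model)
  if (!length(samples)) tomseg_stop("no samples to evaluate", "tomseg_argument_error")
  inter <- uni <- numeric(4)
  rows <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    if (is.null(s$label)) tomseg_stop("samples must be labeled", "tomseg_argument_error")
    pr <- predict_sample(model, s, t1 = if (is.null(t1)) model$config$t1 else t1)
    for (cl in 0:3) {
      inter[cl + 1] <- inter[cl + 1] + sum(pr$label == cl & s$label == cl)
      uni[cl + 1] <- uni[cl + 1] + sum(pr$label == cl | s$label == cl)
    }
    cs <- count_correct_suckers(pr$label, s$label, config)
    ci <- class_iou(pr$label, s$label)
    rows[[i]] <- data.frame(id = s$id, mean_iou = ci$mean,
                            n_suckers = cs$n_ground_truth_suckers,
                            n_detected = cs$n_correct)
  }
  per_class <- ifelse(uni > 0, inter / uni, NA_real_)
  names(per_class) <- c("other", "stem", "branch", "sucker")
  per_image <- do.call(rbind, rows)
  tot_suck <- sum(per_image$n_suckers)
  structure(list(
    mean_iou = mean(per_class, na.rm = TRUE),
    mean_iou_foreground = mean(per_class[2:4], na.rm = TRUE),
    per_class_iou = per_class,
    sucker_detection_pct = if (tot_suck == 0) NA_real_
                           else 100 * sum(per_image$n_detected) / tot_suck,
    per_image = per_image), class = "tomseg_report")
}

#' @export
print.tomseg_report <- function(x, ...) {
  cat(sprintf("mean IOU %.4f (foreground %.4f); sucker detection %s on %d images\n",
              x$mean_iou, x$mean_iou_foreground,
              if (is.na(x$sucker_detection_pct)) "undefined"
              else sprintf("%.1f%%", x$sucker_detection_pct),
              nrow(x$per_image)))
  invisible(x)
}

#' Measure inference throughput
#'
#' Wall-clock frames per second of [predict_sample()] after a warm-up,
#' reported for information only — the figure depends entirely on the host
#' hardware.
#'
#' @param model a `tomseg_model` or `tomseg_checkpoint`.
#' @param n_frames number of timed forward passes.
#' @param sample the sample to segment repeatedly; defaults to a small
#'   synthetic scene.
#' @param warmup untimed warm-up passes.
#' @return Frames per second (positive numeric).
#' @export
measure_throughput <- function(model, n_frames = 5, sample = NULL, warmup = 1) {
  model <- as_tomseg_model(model)
  if (is.null(sample)) {
    sample <- generate_scene(scene_params(height = 120, width = 160, seed = 1))
  }
  for (i in seq_len(warmup)) predict_sample(model, sample)
  t0 <- proc.time()[["elapsed"]]
  for (i in seq_len(n_frames)) predict_sample(model, sample)
  elapsed <- proc.time()[["elapsed"]] - t0
  n_frames / max(elapsed, 1e-9)
}
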