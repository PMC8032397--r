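# Informative/uninformative patch filtering: four image-level texture
# statistics feeding a Random Forest classifier applied at a confidence
# threshold.

#' Default feature-extraction parameters
#'
#' Window sizes and parameters of the four texture statistics. These are
#' frozen into a trained filter model and enforced at prediction time.
#'
#' @return named list: `lbp_points` (8), `lbp_radius` (1),
#'   `entropy_radius` (7, disk), `geomean_window` (5),
#'   `canny_sigma` (1), `canny_low`/`canny_high` (hysteresis thresholds as
#'   fractions of the maximum gradient magnitude, 0.1/0.2).
#' @export
default_feature_config <- function() {
  list(lbp_points = 8L, lbp_radius = 1L,
       entropy_radius = 7L,
       geomean_window = 5L,
       canny_sigma = 1, canny_low = 0.1, canny_high = 0.2)
}

#' Extract the four image-level statistics of a patch
#'
#' Computes, on an 8-bit patch: the standard deviation of the uniform
#' local-binary-pattern code map (`lbp_std`), the standard deviation of the
#' local entropy map over a disk neighbourhood (`entropy_std`, bits), the
#' median of the local geometric-mean filtered image (`geomean_median`,
#' intensity units; the filter runs on intensities + 1 to avoid log 0), and
#' the mean of the binary Canny edge map (`canny_mean`, fraction of edge
#' pixels).
#'
#' @param image 2D 8-bit matrix (any size; the pipeline uses 224x224).
#' @param feature_config parameters, see [default_feature_config()].
#' @return named numeric vector
#'   `c(lbp_std, entropy_std, geomean_median, canny_mean)`.
#' @export
extract_features <- function(image, feature_config = default_feature_config()) {
  if (!is.matrix(image)) stop("extract_features: input must be a 2D matrix")
  img <- as_uint8(round(image))
  fc <- feature_config
  # border pixels have no full LBP neighbourhood; the statistic uses the
  # interior of the code map
  lbp <- lbp_code_map(img)[2:(nrow(img) - 1L), 2:(ncol(img) - 1L)]
  ent <- local_entropy_map(img, fc$entropy_radius)
  gm <- exp(box_filter(log(img + 1), fc$geomean_window)) - 1
  smoothed <- gaussian_blur(matrix(as.numeric(img), nrow(img)), fc$canny_sigma)
  edges <- canny_map(smoothed, fc$canny_low, fc$canny_high)
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  c(lbp_std = pop_sd(as.numeric(lbp)),
    entropy_std = pop_sd(as.numeric(ent)),
    geomean_median = median(gm),
    canny_mean = mean(edges))
}

# feature matrix for a patch_set (rows = patches, in record order)
feature_matrix <- function(ps, feature_config = default_feature_config()) {
  t(vapply(ps$images, extract_features, numeric(4),
           feature_config = feature_config))
}

#' Train the informativeness filter
#'
#' Fits a Random Forest on the four texture statistics of a labeled patch
#' set. Class-1 (informative) probability is the fraction of trees voting
#' informative.
#'
#' @param train a labeled patch set from [make_filter_dataset()] (or any
#'   list with `patches` (a [patch_set()]) and `labels` (0/1, 1 =
#'   informative)); only the training split is used when a `split` field is
#'   present.
#' @param seed RNG seed recorded in the model.
#' @param ntree number of trees (default 500).
#' @param threshold confidence threshold stored with the model (default 0.5).
#' @param feature_config feature parameters, frozen into the model.
#' @return object of class `filter_model`.
#' @export
train_filter <- function(train, seed = 42L, ntree = 500L, threshold = 0.5,
                         feature_config = default_feature_config()) {
  ps <- train$patches
  labels <- train$labels
  if (!is.null(train$split)) {
    keep <- train$split == "train"
    ps <- subset_patches(ps, ps$records$patch_id[keep])
    labels <- labels[keep]
  }
  if (length(labels) < 20L) stop("train_filter: need at least 20 examples")
  if (length(unique(labels)) < 2L) {
    stop("train_filter: both classes must be present")
  }
  if (threshold < 0 || threshold > 1) stop("train_filter: threshold in [0,1]")
  X <- feature_matrix(ps, feature_config)
  y <- factor(labels, levels = c(0, 1))
  set.seed(seed)
  rf <- randomForest::randomForest(x = X, y = y, ntree = ntree)
  structure(list(classifier = rf, threshold = threshold, seed = seed,
                 ntree = ntree, feature_config = feature_config),
            class = "filter_model")
}

#' @export
print.filter_model <- function(x, ...) {
  cat(sprintf("<filter_model: random forest, %d trees, threshold %.2f>\n",
              x$ntree, x$threshold))
  invisible(x)
}

#' Score patches with a trained filter
#'
#' @param patches a [patch_set()] or a single image matrix.
#' @param model a [train_filter()] model.
#' @param feature_config must match the model's frozen configuration;
#'   defaults to it.
#' @return data.frame with `patch_id`, `prob` (informative-class
#'   probability) and `is_informative` (`prob >= threshold`; the boundary
#'   counts as informative).
#' @export
predict_informative <- function(patches, model, feature_config = NULL) {
  stopifnot(inherits(model, "filter_model"))
  if (!is.null(feature_config) &&
      !identical(feature_config, model$feature_config)) {
    stop("predict_informative: feature_config differs from the model's")
  }
  if (is.matrix(patches)) {
    patches <- patch_set(
      list(p1 = as_uint8(round(patches))),
      data.frame(patch_id = "p1", source_id = "adhoc", plane = "xy",
                 slice_index = 0L, y0 = 0L, x0 = 0L, edge_anchored = FALSE,
                 padded = FALSE, stage = "raw", prob = NA_real_,
                 stringsAsFactors = FALSE))
  }
  X <- feature_matrix(patches, model$feature_config)
  prob <- predict(model$classifier, X, type = "prob")[, "1"]
  data.frame(patch_id = patches$records$patch_id,
             prob = as.numeric(prob),
             is_informative = as.numeric(prob) >= model$threshold,
             stringsAsFactors = FALSE)
}

#' Area under the ROC curve (rank / Mann-Whitney form)
#'
#' Probability that a random positive is scored above a random negative;
#' ties receive half credit (midranks).
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels 0/1 labels.
#' @return AUROC in \[0, 1\].
#' @export
evaluate_auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("evaluate_auroc: both classes required")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Ground-truth informativeness label from synthetic region masks
#'
#' A patch is uninformative when 80% or more of its area is uniform
#' intensity, when its global contrast (intensity standard deviation) falls
#' below the configured floor, or when the generator flagged it as an
#' artifact/non-cellular frame.
#'
#' @param patch 8-bit matrix.
#' @param masks list with a binary `uniform` mask (1 = uniform-intensity
#'   region); may be `NULL` (treated as no uniform area).
#' @param artifact logical artifact flag from the generator.
#' @param config pipeline configuration (uses `contrast_floor`).
#' @return integer label: 1 = informative, 0 = uninformative.
#' @export
label_with_criteria <- function(patch, masks = NULL, artifact = FALSE,
                                config = default_config()) {
  uniform_frac <- if (!is.null(masks$uniform)) mean(masks$uniform) else 0
  contrast <- sd(as.numeric(patch))
  if (uniform_frac >= 0.8 || contrast < config$contrast_floor ||
      isTRUE(artifact)) 0L else 1L
}

#' Filter a corpus with a trained informativeness model
#'
#' @param ps a [patch_set()] (typically the deduplicated stage).
#' @param model a [train_filter()] model.
#' @return list with `kept` (informative patches, stage "filtered",
#'   probabilities recorded) and `report` (per-patch scores, counts,
#'   reduction fraction).
#' @export
filter_corpus <- function(ps, model) {
  stopifnot(inherits(ps, "patch_set"), inherits(model, "filter_model"))
  n0 <- length(ps)
  if (n0 == 0L) {
    return(list(kept = ps, report = list(n_before = 0L, n_after = 0L,
                                         reduction = 0, scores = NULL)))
  }
  scores <- predict_informative(ps, model)
  kept <- subset_patches(ps, scores$patch_id[scores$is_informative])
  kept$records$stage <- rep("filtered", nrow(kept$records))
  kept$records$prob <- scores$prob[match(kept$records$patch_id,
                                         scores$patch_id)]
  list(kept = kept,
       report = list(n_before = n0, n_after = length(kept),
                     reduction = 1 - length(kept) / n0, scores = scores))
}
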