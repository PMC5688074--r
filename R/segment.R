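#' Candidate vessel-voxel selection
#'
#' Coarse pre-filter on the WTV map: a voxel is a candidate when its WTV
#' strictly exceeds `mu + k * sigma`, with `mu` and `sigma` the mean and
#' standard deviation of all WTV voxel values and `k = 1.5` by default.
#' Only candidates are featurized and classified, which cuts the workload
#' by an order of magnitude while keeping essentially all enhancing
#' voxels.
#'
#' @param wtv a [volume3d] WTV map (nonnegative).
#' @param k threshold multiplier (> 0).
#' @return A [binary_mask] of candidate voxels. A constant WTV map (sigma
#'   = 0) yields an empty mask with a warning.
#' @export
select_candidates <- function(wtv, k = 1.5) {
  stopifnot(inherits(wtv, "volume3d"))
  if (k <= 0) stop("k must be positive")
  mu <- mean(wtv$data)
  sigma <- sd(as.vector(wtv$data))
  if (sigma == 0) {
    warning("constant WTV map: no candidates selected")
    return(binary_mask(array(FALSE, dim(wtv$data)), wtv$spacing))
  }
  binary_mask(wtv$data > mu + k * sigma, wtv$spacing)
}

#' Sample a balanced training set
#'
#' Positives are a uniform random subset (`fraction`, default 10%) of the
#' annotated vessel voxels; negatives are an equal-count uniform sample,
#' without replacement, of the non-annotated voxels inside the annotation
#' subvolumes. Every sampled voxel must be present in the feature matrix.
#'
#' @param features a `feature_matrix` covering at least the subvolume
#'   voxels (see [assemble_features()]).
#' @param annotations [binary_mask] of annotated vessel voxels, confined
#'   to the subvolumes.
#' @param subvolumes list of [subvolume_box] the annotations live in.
#' @param fraction fraction of annotated voxels used as positives, in
#'   (0, 1].
#' @param seed integer seed; the same seed reproduces the same index sets.
#' @return Object of class `training_set`: list with `x` (feature matrix),
#'   `y` (0/1 labels), `index`, `names` and sampling metadata `meta`.
#' @export
sample_training_set <- function(features, annotations, subvolumes,
                                fraction = 0.1, seed = 1L) {
  stopifnot(inherits(features, "feature_matrix"))
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  dims <- features$dims
  sv <- array(FALSE, dims)
  for (b in subvolumes) sv <- sv | box_to_mask(b, dims)
  ann_idx <- which(annotations$data)
  if (length(ann_idx) == 0L) stop("no annotated voxels")
  if (!all(annotations$data[!sv] == FALSE))
    stop("annotations must be confined to the subvolumes")
  neg_pool <- which(sv & !annotations$data)
  set.seed(seed)
  n_pos <- max(1L, as.integer(round(fraction * length(ann_idx))))
  pos <- sort(sample(ann_idx, n_pos))
  if (length(neg_pool) < n_pos)
    stop("fewer non-annotated subvolume voxels than required negatives")
  neg <- sort(sample(neg_pool, n_pos))
  rows <- match(c(pos, neg), features$index)
  if (anyNA(rows))
    stop("sampled voxels missing from the feature matrix; featurize the subvolumes")
  structure(list(
    x = features$x[rows, , drop = FALSE],
    y = rep(c(1L, 0L), times = c(n_pos, n_pos)),
    index = c(pos, neg),
    names = features$names,
    meta = list(fraction = fraction, seed = seed,
                n_pos = n_pos, n_neg = n_pos)
  ), class = "training_set")
}

#' Train the random-forest vessel classifier
#'
#' A probability random forest (ranger) with 100 trees and maximum depth
#' 30 by default, fit on a balanced training set. Training is
#' single-threaded and seeded so the model is reproducible bit-for-bit.
#'
#' @param ts a `training_set` from [sample_training_set()].
#' @param n_trees number of trees.
#' @param max_depth maximum tree depth.
#' @param seed integer seed for the forest.
#' @return Object of class `forest_model`: the fitted forest plus
#'   hyperparameters and the feature-column manifest.
#' @export
train_classifier <- function(ts, n_trees = 100L, max_depth = 30L, seed = 1L) {
  stopifnot(inherits(ts, "training_set"))
  if (length(unique(ts$y)) < 2L)
    stop("training set must contain both classes")
  df <- data.frame(ts$x, check.names = FALSE)
  df$.label <- factor(ts$y, levels = c(0L, 1L))
  fit <- ranger::ranger(
    dependent.variable.name = ".label", data = df,
    num.trees = n_trees, max.depth = max_depth,
    probability = TRUE, seed = seed, num.threads = 1,
    respect.unordered.factors = "order"
  )
  structure(list(forest = fit, n_trees = n_trees, max_depth = max_depth,
                 seed = seed, feature_names = ts$names),
            class = "forest_model")
}

#' @export
print.forest_model <- function(x, ...) {
  cat(sprintf("<forest_model> %d trees, max depth %d, %d features, OOB error %.4f\n",
              x$n_trees, x$max_depth, length(x$feature_names),
              x$forest$prediction.error))
  invisible(x)
}

#' Predict vessel probability on candidate voxels
#'
#' Applies the forest to the candidate voxels only; every non-candidate
#' voxel gets probability exactly 0 (the candidate gate is absolute). The
#' binary mask keeps candidates with probability at or above
#' `prob_threshold`.
#'
#' @param model a `forest_model`.
#' @param features `feature_matrix` of the candidate voxels; its column
#'   manifest must match the model's.
#' @param candidates the candidate [binary_mask] the features were drawn
#'   from.
#' @param prob_threshold decision threshold in `[0, 1]` (default 0.5; see
#'   [optimal_threshold()] for a Youden-J operating point).
#' @return list with `prob` (a [volume3d] probability map) and `mask` (a
#'   [binary_mask]).
#' @export
classify <- function(model, features, candidates, prob_threshold = 0.5) {
  stopifnot(inherits(model, "forest_model"),
            inherits(features, "feature_matrix"))
  if (!identical(model$feature_names, features$names))
    stop("feature manifest does not match the trained model")
  df <- data.frame(features$x, check.names = FALSE)
  pred <- predict(model$forest, data = df, num.threads = 1)$predictions
  p <- pred[, "1"]
  prob <- array(0, features$dims)
  prob[features$index] <- p
  mask <- candidates$data & (prob >= prob_threshold)
  list(prob = volume3d(prob, features$spacing),
       mask = binary_mask(mask, features$spacing))
}

#' Youden-J operating point
#'
#' Chooses the probability threshold maximizing Youden's J statistic
#' (sensitivity + specificity - 1) on labelled validation probabilities —
#' a reproducible alternative to picking the operating point by visual
#' inspection of ROC curves.
#'
#' @param prob predicted vessel probabilities.
#' @param truth 0/1 (or logical) reference labels.
#' @return The threshold (numeric scalar).
#' @export
optimal_threshold <- function(prob, truth) {
  truth <- as.integer(as.logical(truth))
  if (length(prob) != length(truth)) stop("length mismatch")
  if (length(unique(truth)) < 2L) stop("need both classes to compute J")
  cand <- sort(unique(prob))
  n_pos <- sum(truth == 1L); n_neg <- sum(truth == 0L)
  j <- vapply(cand, function(th) {
    sens <- sum(prob >= th & truth == 1L) / n_pos
    spec <- sum(prob < th & truth == 0L) / n_neg
    sens + spec - 1
  }, numeric(1))
  cand[which.max(j)]
}

#' Remove small connected components
#'
#' 26-connected components of the mask with fewer than `min_voxels` voxels
#' are discarded (strict inequality: a 25-voxel component survives the
#' default). At the protocol voxel size of 0.43 x 0.43 x 0.5 mm the
#' 25-voxel default corresponds to about 2.3 microliters; see
#' [component_volume_ul()].
#'
#' @param mask a [binary_mask].
#' @param min_voxels minimum surviving component size in voxels.
#' @return A [binary_mask]; surviving components are untouched.
#' @export
remove_small_components <- function(mask, min_voxels = 25L) {
  stopifnot(inherits(mask, "binary_mask"))
  labels <- label_components_cpp(mask$data, dim(mask$data), 26L)
  if (max(labels) == 0L) return(mask)
  sizes <- tabulate(labels)
  keep <- which(sizes >= min_voxels)
  binary_mask(array(labels %in% keep, dim(mask$data)), mask$spacing)
}

#' Volume of an n-voxel component in microliters
#'
#' @param n_voxels component size in voxels.
#' @param spacing voxel spacing in mm.
#' @return Volume in microliters (1 uL = 1 mm^3).
#' @export
component_volume_ul <- function(n_voxels, spacing = c(0.43, 0.43, 0.5)) {
  check_spacing(spacing)
  n_voxels * prod(spacing)
}

#' Iterative morphological hole filling
#'
#' Voting-based hole filling with a cubic structuring element: a
#' background voxel flips to foreground when at least `vote` of its
#' `(2*radius+1)^3 - 1` box neighbors are foreground (default: strict
#' majority, i.e. 14 of 26 for the default 3x3x3 kernel). Foreground is
#' never removed, so the result grows monotonically and becomes idempotent
#' once converged; at most `iterations` passes are applied. Fills the
#' centers of large under-segmented vessels without dilating thin ones.
#'
#' @param mask a [binary_mask].
#' @param radius structuring-element radius in voxels (1 = 3x3x3 kernel).
#' @param iterations maximum number of passes.
#' @param vote number of foreground neighbors required to flip a
#'   background voxel; `NULL` = strict majority of the neighborhood.
#' @return A [binary_mask].
#' @export
fill_holes <- function(mask, radius = 1L, iterations = 10L, vote = NULL) {
  stopifnot(inherits(mask, "binary_mask"))
  n_neigh <- (2L * radius + 1L)^3 - 1L
  if (is.null(vote)) vote <- n_neigh %/% 2L + 1L
  m <- mask$data
  dims <- dim(m)
  for (i in seq_len(iterations)) {
    cnt <- neighbor_count_cpp(m, dims, as.integer(radius))
    flips <- !m & (cnt >= vote)
    if (!any(flips)) break
    m <- m | flips
  }
  binary_mask(m, mask$spacing)
}

#' Run the full segmentation pipeline
#'
#' Composition of the three stages: (1) WTV computation and candidate
#' selection by the mean + k*sd threshold; (2) feature extraction and
#' random-forest classification of candidate voxels; (3) postprocessing —
#' first removal of 26-connected components below the minimum size, then
#' iterative hole filling. Deterministic given the model and
#' configuration.
#'
#' @param vol a [volume4d] (its `exposures` drive the temporal weights).
#' @param cavity intracranial-cavity [binary_mask].
#' @param model a trained `forest_model`.
#' @param config pipeline configuration, see [default_config()].
#' @return list with the final `mask` ([binary_mask]) plus intermediates:
#'   `prob`, `candidates`, `wtv`, `wta` and stage voxel counts `counts`.
#' @export
run_pipeline <- function(vol, cavity, model, config = default_config()) {
  w <- compute_weights(vol$exposures)
  wta <- weighted_temporal_average(vol, w)
  wtv <- weighted_temporal_variance(vol, w)
  candidates <- select_candidates(wtv, config$candidate_k)
  counts <- c(candidates = sum(candidates$data))
  if (counts["candidates"] == 0L) {
    empty <- binary_mask(array(FALSE, dim(wtv$data)), wtv$spacing)
    return(list(mask = empty, prob = volume3d(array(0, dim(wtv$data)), wtv$spacing),
                candidates = candidates, wtv = wtv, wta = wta,
                counts = c(counts, classified = 0L, after_components = 0L,
                           after_holes = 0L)))
  }
  fm <- assemble_features(vol, cavity, candidates, config)
  cls <- classify(model, fm, candidates, config$prob_threshold)
  counts["classified"] <- sum(cls$mask$data)
  m <- remove_small_components(cls$mask, config$min_component)
  counts["after_components"] <- sum(m$data)
  m <- fill_holes(m, config$hole_radius, config$hole_iterations,
                  config$hole_vote)
  counts["after_holes"] <- sum(m$data)
  list(mask = m, prob = cls$prob, candidates = candidates, wtv = wtv,
       wta = wta, counts = counts)
}
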