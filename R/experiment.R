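#' Phantom training/evaluation experiment
#'
#' The package's self-contained validation loop: generate synthetic 4D
#' cases with known vessel ground truth, train the classifier on the
#' annotated subvolumes of the training cases, segment a held-out case
#' with the full pipeline, and evaluate against its truth mask — both on
#' the whole volume and per annotation subvolume with the mean-CMD /
#' max-HD combination rule.
#'
#' @param train_seeds integer seeds of the training cases (>= 1 case).
#' @param test_seed seed of the held-out case.
#' @param spec the [phantom_spec] shared by all cases.
#' @param config pipeline configuration, see [default_config()].
#' @return list with `model` (the trained `forest_model`), `result` (the
#'   [run_pipeline()] output on the held-out case), `case` (the held-out
#'   `phantom_case`), `report` (whole-volume `evaluation_report` vs
#'   truth), `per_subvolume` (reports per annotation box) and `combined`
#'   (distance statistics combined across subvolumes).
#' @export
phantom_experiment <- function(train_seeds = c(101L, 102L, 103L),
                               test_seed = 104L,
                               spec = phantom_spec(),
                               config = default_config()) {
  if (length(train_seeds) < 1L) stop("need at least one training case")
  tsets <- vector("list", length(train_seeds))
  for (i in seq_along(train_seeds)) {
    case <- generate_phantom(spec, train_seeds[i])
    tsets[[i]] <- case_training_set(case, config, seed = config$seed + i)
  }
  model <- train_classifier(pool_training_sets(tsets), config$n_trees,
                            config$max_depth, seed = config$seed)
  test_case <- generate_phantom(spec, test_seed)
  result <- run_pipeline(test_case$volume, test_case$cavity, model, config)
  report <- evaluate_segmentation(result$mask, test_case$truth)
  per_sv <- lapply(test_case$subvolumes, function(b)
    evaluate_segmentation(result$mask, test_case$truth, roi = b))
  list(model = model, result = result, case = test_case, report = report,
       per_subvolume = per_sv, combined = combine_subvolumes(per_sv))
}
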