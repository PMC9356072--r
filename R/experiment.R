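#' Train/test evaluation with cross-validated hyperparameter selection
#'
#' Runs the full modeling workflow for one drug: a seeded 80/20
#' train/test split (random draw without replacement, not stratified), a
#' 5-fold cross-validation on the training part over a hyperparameter grid —
#' with the mRMR gene selection refit inside every fold — selection of the
#' best grid point, a final refit on the complete training set with genes
#' reselected on it, and a test-set evaluation report.
#'
#' Fold models that cannot be fitted (for example a fold whose training part
#' contains a single class while the model's weight scheme needs both) mark
#' the whole grid point as failed; failed grid points are logged and skipped
#' during selection.
#'
#' @param data A `drug_dataset`.
#' @param model One of `"sauron"` (weighted joint model), `"rrf"`
#'   (conventional regression forest, classified by threshold), `"crf"`
#'   (classification forest with derived continuous prediction), `"harf_sr"`
#'   (unweighted joint model with binary tree weighting), `"hierarchical"`
#'   (classify-then-regress).
#' @inheritParams sauron_rf
#' @param grid Data frame of hyperparameter combinations; must contain
#'   `k_features` and may override `trees`, `mtry`, `min_node`. Defaults to
#'   `k_features` in 20, 40, 60, 80, 100 (capped at the number of genes).
#' @param test_fraction Held-out fraction (default 0.2).
#' @param n_folds Cross-validation folds (default 5).
#' @param selection_metric `"auto"` (default: maximize mean validation MCC
#'   for classifying models, minimize mean validation MSE for `"rrf"`),
#'   `"mcc"` or `"mse"`.
#' @param n_bins Quantile bins for the mRMR mutual-information estimator.
#' @param seed Master seed governing the split, the folds and every fit.
#' @return An object of class `sauron_experiment` with the test-set `report`,
#'   per-fold `cv_results`, the chosen `best_params`, the final `fit`, the
#'   genes selected for it and the per-sample test `predictions`.
#' @export
run_experiment <- function(data,
                           model = c("sauron", "rrf", "crf", "harf_sr", "hierarchical"),
                           sample_weights = "simple", resampling = "none",
                           tree_weighting = "binary_sens",
                           grid = NULL, test_fraction = 0.2, n_folds = 5L,
                           selection_metric = c("auto", "mcc", "mse"),
                           trees = 500L, mtry = NULL, min_node = 5L,
                           n_bins = 10L, seed = 1L) {
  model <- match.arg(model)
  selection_metric <- match.arg(selection_metric)
  validate_drug_dataset(data)
  if (test_fraction <= 0 || test_fraction >= 1) abort("`test_fraction` must be in (0, 1)")
  if (n_folds < 2) abort("`n_folds` must be at least 2")
  p <- length(data$gene_ids)
  if (is.null(grid)) {
    ks <- unique(pmin(c(20L, 40L, 60L, 80L, 100L), p))
    grid <- tibble::tibble(k_features = ks)
  }
  grid <- tibble::as_tibble(grid)
  if (!"k_features" %in% names(grid)) abort("`grid` must contain a `k_features` column")
  if (selection_metric == "auto") {
    selection_metric <- if (model == "rrf") "mse" else "mcc"
  }

  n <- length(data$y)
  test_idx <- withr::with_seed(seed, sort(sample.int(n, round(test_fraction * n))))
  train_idx <- setdiff(seq_len(n), test_idx)
  ds_train <- ds_subset(data, train_idx)
  ds_test <- ds_subset(data, test_idx)
  folds <- withr::with_seed(seed + 1L,
                            sample(rep_len(seq_len(n_folds), length(train_idx))))

  opts <- list(sample_weights = sample_weights, resampling = resampling,
               tree_weighting = tree_weighting)
  cv_rows <- list()
  grid_failed <- logical(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    hp <- hyper_for(grid[g, ], trees, mtry, min_node)
    for (f in seq_len(n_folds)) {
      tr <- ds_subset(ds_train, which(folds != f))
      va <- ds_subset(ds_train, which(folds == f))
      res <- tryCatch({
        fs <- select_features(tr, k = min(hp$k_features, p), n_bins = n_bins)
        fit <- fit_variant(ds_select_genes(tr, fs$gene_id), model, opts, hp,
                           seed = seed + 100L * g + f)
        pr <- predict_variant(fit, va, model)
        evaluation_report(va$y, pr$.pred_value, va$Y, pr$.pred_class)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        grid_failed[g] <- TRUE
        inform(sprintf("grid point %d failed in fold %d: %s", g, f, conditionMessage(res)))
        break
      }
      cv_rows[[length(cv_rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(grid_point = g, k_features = hp$k_features, fold = f), res)
    }
  }
  cv_results <- dplyr::bind_rows(cv_rows)
  if (all(grid_failed)) abort("every grid point failed during cross-validation")

  cv_mean <- cv_results |>
    dplyr::filter(!.data$grid_point %in% which(grid_failed)) |>
    dplyr::group_by(.data$grid_point) |>
    dplyr::summarise(mcc = mean(.data$mcc), mse = mean(.data$mse), .groups = "drop")
  best_g <- if (selection_metric == "mcc") {
    cv_mean$grid_point[which.max(cv_mean$mcc)]
  } else {
    cv_mean$grid_point[which.min(cv_mean$mse)]
  }
  best <- hyper_for(grid[best_g, ], trees, mtry, min_node)

  fs <- select_features(ds_train, k = min(best$k_features, p), n_bins = n_bins)
  final_fit <- fit_variant(ds_select_genes(ds_train, fs$gene_id), model, opts, best,
                           seed = seed + 7L)
  pr <- predict_variant(final_fit, ds_test, model)
  report <- dplyr::bind_cols(
    tibble::tibble(model = model, k_features = best$k_features,
                   n_train = length(train_idx), n_test = length(test_idx)),
    evaluation_report(ds_test$y, pr$.pred_value, ds_test$Y, pr$.pred_class)
  )
  structure(
    list(
      model = model, report = report, cv_results = cv_results,
      best_params = c(best, opts, selection_metric = selection_metric),
      selected_genes = fs, fit = final_fit,
      predictions = dplyr::bind_cols(
        tibble::tibble(sample_id = ds_test$sample_ids, response = ds_test$y,
                       class = ds_test$Y), pr[c(".pred_class", ".pred_value")]),
      folds = folds, test_idx = test_idx, seed = seed
    ),
    class = "sauron_experiment"
  )
}

hyper_for <- function(grid_row, trees, mtry, min_node) {
  pick <- function(name, default) {
    if (name %in% names(grid_row)) grid_row[[name]] else default
  }
  m <- pick("mtry", mtry)
  list(
    k_features = as.integer(grid_row$k_features),
    trees = as.integer(pick("trees", trees)),
    mtry = if (is.null(m)) NULL else as.integer(m),
    min_node = as.integer(pick("min_node", min_node))
  )
}

fit_variant <- function(ds, model, opts, hp, seed) {
  switch(model,
    sauron = sauron_rf(ds, sample_weights = opts$sample_weights,
                       resampling = opts$resampling,
                       tree_weighting = opts$tree_weighting,
                       trees = hp$trees, mtry = hp$mtry, min_node = hp$min_node,
                       seed = seed),
    harf_sr = sauron_rf(ds, sample_weights = "uniform", resampling = "none",
                        tree_weighting = "binary", trees = hp$trees,
                        mtry = hp$mtry, min_node = hp$min_node, seed = seed),
    rrf = sauron_rf(ds, sample_weights = "uniform", resampling = "none",
                    tree_weighting = "uniform", trees = hp$trees,
                    mtry = hp$mtry, min_node = hp$min_node, seed = seed),
    crf = classification_rf(ds, sample_weights = opts$sample_weights,
                            resampling = opts$resampling, trees = hp$trees,
                            mtry = hp$mtry, min_node = hp$min_node, seed = seed),
    hierarchical = hierarchical_rf(ds, trees = hp$trees, mtry = hp$mtry,
                                   min_node = hp$min_node, seed = seed)
  )
}

predict_variant <- function(fit, ds, model) {
  pr <- predict(fit, ds)
  if (model == "rrf") pr$.pred_class <- rrf_classify(pr$.pred_value, fit$t)
  pr
}

#' @export
print.sauron_experiment <- function(x, ...) {
  cat(sprintf("<sauron_experiment> model '%s', best k = %d\n",
              x$model, x$report$k_features))
  print(x$report)
  invisible(x)
}
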