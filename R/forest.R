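#' Fit a simultaneous regression and classification random forest
#'
#' Trains a weighted regression forest on the continuous log-IC50 response
#' whose leaves additionally carry a sensitive/resistant class label (the
#' mode of the member classes), so a single model yields both a class call
#' and a continuous prediction. Class imbalance is counteracted either by
#' per-sample weights ([sample_weights()]) that enter the split criterion, or
#' by resampling the training data ([upsample()], [proportional_upsample()])
#' before growing the forest. At prediction time the trees are combined by a
#' class-aware tree-weighting scheme (see [predict.sauron_rf()]).
#'
#' Each of the `trees` trees is grown on an N-sized bootstrap of the training
#' data; at every node `mtry` genes are drawn without replacement and the
#' split maximizing the weighted-variance (MSE) improvement is taken, with
#' candidate split points at midpoints between consecutive distinct values
#' and ties broken by lower gene index, then lower split value. Growth stops
#' when a node cannot be split into children of at least `min_node` bootstrap
#' members each.
#'
#' @param data A `drug_dataset` (see [drug_dataset()], [simulate_drug_data()]).
#' @param sample_weights Weight scheme, see [sample_weights()].
#' @param resampling `"none"`, `"upsample"` or `"proportional"`; applied to
#'   the training data before weights are computed.
#' @param tree_weighting Default scheme used by `predict()`: one of
#'   `"binary_sens"` (default), `"uniform"`, `"binary"`, `"majority"`,
#'   `"majority_sens"`.
#' @param trees Number of trees B (default 500).
#' @param mtry Genes drawn per split; default `floor(P / 3)`, at least 1.
#' @param min_node Minimum bootstrap members per leaf (default 5).
#' @param seed Master seed; bootstraps and per-node feature draws derive from
#'   it, so fits are exactly reproducible.
#' @return An object of class `sauron_rf`.
#' @export
#' @examples
#' ds <- simulate_drug_data(n_samples = 120, n_genes = 20, seed = 7)
#' fit <- sauron_rf(ds, sample_weights = "simple", trees = 50, seed = 7)
#' predict(fit, ds)
sauron_rf <- function(data,
                      sample_weights = c("uniform", "simple", "linear", "quadratic"),
                      resampling = c("none", "upsample", "proportional"),
                      tree_weighting = c("binary_sens", "uniform", "binary",
                                         "majority", "majority_sens"),
                      trees = 500L, mtry = NULL, min_node = 5L, seed = 1L) {
  sample_weights <- match.arg(sample_weights)
  resampling <- match.arg(resampling)
  tree_weighting <- match.arg(tree_weighting)
  fit_forest(data, split_on = "response", sample_weights = sample_weights,
             resampling = resampling, tree_weighting = tree_weighting,
             trees = trees, mtry = mtry, min_node = min_node, seed = seed,
             subclass = "sauron_rf")
}

#' Fit a classification random forest baseline
#'
#' A conventional classification forest on the binary sensitive/resistant
#' labels: trees split on the 0/1 response (variance reduction on a binary
#' response is proportional to the Gini decrease) and vote by leaf majority.
#' A derived continuous prediction is available: the trees agreeing with the
#' forest's majority vote contribute the unweighted mean log IC50 of their
#' reached leaf's training members, averaged over those trees — this is the
#' `"binary"` tree-weighting applied to the unweighted leaf means.
#'
#' @inheritParams sauron_rf
#' @return An object of class `classification_rf` (also a `sauron_rf`).
#' @export
classification_rf <- function(data,
                              sample_weights = c("uniform", "simple", "linear", "quadratic"),
                              resampling = c("none", "upsample", "proportional"),
                              trees = 500L, mtry = NULL, min_node = 5L, seed = 1L) {
  sample_weights <- match.arg(sample_weights)
  resampling <- match.arg(resampling)
  fit_forest(data, split_on = "class", sample_weights = sample_weights,
             resampling = resampling, tree_weighting = "binary",
             trees = trees, mtry = mtry, min_node = min_node, seed = seed,
             subclass = c("classification_rf", "sauron_rf"))
}

fit_forest <- function(data, split_on, sample_weights, resampling, tree_weighting,
                       trees, mtry, min_node, seed, subclass) {
  validate_drug_dataset(data)
  trees <- as.integer(trees)
  min_node <- as.integer(min_node)
  if (trees < 1L) abort("`trees` must be at least 1")
  if (min_node < 1L) abort("`min_node` must be at least 1")

  withr::with_seed(seed, {
    train <- switch(resampling,
      none = data,
      upsample = upsample(data, seed = seed),
      proportional = proportional_upsample(data, seed = seed)
    )
    n <- length(train$y)
    p <- length(train$gene_ids)
    if (n < 2L * min_node) {
      abort(sprintf("need at least 2 * min_node = %d training samples, got %d",
                    2L * min_node, n))
    }
    if (is.null(mtry)) mtry <- max(1L, p %/% 3L)
    mtry <- as.integer(mtry)
    if (mtry > p) abort(sprintf("`mtry` (%d) exceeds the number of genes (%d)", mtry, p))

    w_tbl <- sample_weights(train, sample_weights)
    w <- w_tbl$w_star
    y_split <- if (split_on == "class") as.numeric(train$Y) else train$y

    tree_list <- vector("list", trees)
    boot_list <- vector("list", trees)
    for (b in seq_len(trees)) {
      boot <- sample.int(n, n, replace = TRUE)
      tree_list[[b]] <- cpp_build_tree(train$X, y_split, train$y, w, train$Y,
                                       boot, mtry, min_node)
      boot_list[[b]] <- boot
    }
  })

  structure(
    list(
      trees = tree_list,
      bootstrap = boot_list,
      w_star = w,
      train = train,
      gene_ids = train$gene_ids,
      t = train$t,
      params = list(
        trees = trees, mtry = mtry, min_node = min_node, seed = seed,
        sample_weights = sample_weights, resampling = resampling,
        tree_weighting = tree_weighting, split_on = split_on
      )
    ),
    class = subclass
  )
}

#' @export
print.sauron_rf <- function(x, ...) {
  p <- x$params
  cat(sprintf("<%s> %d trees, mtry %d, min_node %d\n", class(x)[1],
              p$trees, p$mtry, p$min_node))
  cat(sprintf("  sample weights: %s; resampling: %s; tree weighting: %s\n",
              p$sample_weights, p$resampling, p$tree_weighting))
  cat(sprintf("  trained on %d cell lines x %d genes\n",
              length(x$train$sample_ids), length(x$gene_ids)))
  invisible(x)
}

as_query_matrix <- function(object, new_data) {
  if (inherits(new_data, "drug_dataset")) new_data <- new_data$X
  if (is.data.frame(new_data)) {
    if (names(new_data)[1] == "sample_id") {
      ids <- as.character(new_data$sample_id)
      new_data <- as.matrix(new_data[setdiff(names(new_data), c("sample_id", "response", "class"))])
      rownames(new_data) <- ids
    } else {
      new_data <- as.matrix(new_data)
    }
  }
  if (!is.null(colnames(new_data))) {
    missing <- setdiff(object$gene_ids, colnames(new_data))
    if (length(missing) > 0) {
      abort(sprintf("new data lacks %d model gene(s), e.g. %s", length(missing),
                    paste(head(missing, 3), collapse = ", ")))
    }
    new_data <- new_data[, object$gene_ids, drop = FALSE]
  } else if (ncol(new_data) != length(object$gene_ids)) {
    abort(sprintf("new data has %d features but the forest was trained on %d",
                  ncol(new_data), length(object$gene_ids)))
  }
  storage.mode(new_data) <- "double"
  new_data
}

# Per-query tree-level quantities and the forest class vote (mode over tree
# leaf classes; ties go to resistant).
forest_traverse <- function(object, X) {
  tr <- cpp_forest_traverse(object$trees, X)
  B <- length(object$trees)
  votes_sens <- colSums(tr$class == 1L)
  tr$forest_class <- as.integer(votes_sens > B - votes_sens)
  tr
}

# Tree-weight matrix (B x n) for one scheme given traversal results.
scheme_weights <- function(tr, scheme) {
  B <- nrow(tr$class)
  n <- ncol(tr$class)
  uniform <- matrix(1 / B, B, n)
  if (scheme == "uniform") return(uniform)
  fc <- matrix(tr$forest_class, B, n, byrow = TRUE)
  if (scheme %in% c("binary", "binary_sens")) {
    agree <- (tr$class == fc) * 1
    n_agree <- colSums(agree)
    stopifnot(all(n_agree >= 1))  # forest class is the vote mode
    w <- sweep(agree, 2, n_agree, "/")
  } else if (scheme %in% c("majority", "majority_sens")) {
    mass <- ifelse(fc == 1, tr$w1, tr$w0)
    frac <- mass / (tr$w0 + tr$w1)
    w <- sweep(frac, 2, colSums(frac), "/")
  } else {
    abort(sprintf("unknown tree-weighting scheme '%s'", scheme))
  }
  if (scheme %in% c("binary_sens", "majority_sens")) {
    resistant <- tr$forest_class == 0L
    w[, resistant] <- uniform[, resistant]
  }
  w
}

#' Predict class and continuous response from a fitted forest
#'
#' Every tree votes the class label of the leaf reached by the query; the
#' forest class is the mode of the votes (ties are called resistant). The
#' continuous prediction is the tree-weighted average of the reached leaves'
#' stored response means, with per-tree weights set by the scheme:
#'
#' * `"uniform"`: `1/B`, the conventional regression-forest average.
#' * `"binary"`: only trees agreeing with the forest's class vote count,
#'   equally.
#' * `"binary_sens"`: `"binary"` for queries predicted sensitive, `"uniform"`
#'   for queries predicted resistant.
#' * `"majority"`: each tree is weighted by the weighted fraction of its
#'   reached leaf's training members whose class matches the forest vote,
#'   normalized over trees.
#' * `"majority_sens"`: `"majority"` for sensitive-predicted queries, else
#'   `"uniform"`.
#'
#' @param object A fitted `sauron_rf`.
#' @param new_data A `drug_dataset`, samples-by-genes matrix, or data frame
#'   with a `sample_id` column and gene columns.
#' @param scheme Tree-weighting scheme; defaults to the scheme the model was
#'   fitted with.
#' @param ... Unused.
#' @return A tibble with one row per query: `sample_id`, `.pred_class`
#'   (0/1) and `.pred_value` (log IC50).
#' @export
predict.sauron_rf <- function(object, new_data, scheme = NULL, ...) {
  scheme <- scheme %||% object$params$tree_weighting
  X <- as_query_matrix(object, new_data)
  tr <- forest_traverse(object, X)
  w <- scheme_weights(tr, scheme)
  vals <- if (inherits(object, "classification_rf")) tr$uvalue else tr$value
  tibble::tibble(
    sample_id = rownames(X) %||% paste0("q", seq_len(ncol(w))),
    .pred_class = tr$forest_class,
    .pred_value = colSums(w * vals)
  )
}

#' Per-tree predictions and tree weights for queries
#'
#' Exposes the ensemble internals behind [predict.sauron_rf()]: each tree's
#' reached-leaf response mean, class vote and normalized tree weight under
#' the chosen scheme. Weights sum to 1 per query.
#'
#' @inheritParams predict.sauron_rf
#' @return A tibble with columns `sample_id`, `tree`, `tree_value`,
#'   `tree_class`, `forest_class` and `weight`.
#' @export
predict_trees <- function(object, new_data, scheme = NULL) {
  stopifnot(inherits(object, "sauron_rf"))
  scheme <- scheme %||% object$params$tree_weighting
  X <- as_query_matrix(object, new_data)
  tr <- forest_traverse(object, X)
  w <- scheme_weights(tr, scheme)
  vals <- if (inherits(object, "classification_rf")) tr$uvalue else tr$value
  B <- nrow(w)
  n <- ncol(w)
  tibble::tibble(
    sample_id = rep(rownames(X) %||% paste0("q", seq_len(n)), each = B),
    tree = rep(seq_len(B), n),
    tree_value = as.vector(vals),
    tree_class = as.vector(tr$class),
    forest_class = rep(tr$forest_class, each = B),
    weight = as.vector(w)
  )
}

#' Impurity-decrease feature importance
#'
#' Sums, per gene, the weighted mean-squared-error improvement of every split
#' using that gene over all trees (each tree's contributions on the
#' root-weight-normalized scale), normalized so the importances sum to 1.
#'
#' @param object A fitted `sauron_rf`.
#' @return A tibble with columns `gene_id` and `importance`, sorted by
#'   decreasing importance.
#' @export
feature_importance <- function(object) {
  stopifnot(inherits(object, "sauron_rf"))
  total <- Reduce(`+`, lapply(object$trees, `[[`, "importance"))
  if (sum(total) > 0) total <- total / sum(total)
  tibble::tibble(gene_id = object$gene_ids, importance = total) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}
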