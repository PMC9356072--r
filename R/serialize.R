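#' Write a fitted forest to JSON
#'
#' Serializes the complete forest — parameters, per-node split structure and
#' leaf annotations (weighted and unweighted response means, class labels,
#' per-class weight mass and counts), the training sample weights and the
#' threshold — to a JSON file, so that predictions can be replayed
#' bit-identically without the training data.
#'
#' @param object A fitted `sauron_rf`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_forest_json <- function(object, path) {
  stopifnot(inherits(object, "sauron_rf"))
  payload <- list(
    format = "sauron_rf_forest",
    version = 1L,
    subclass = class(object),
    params = object$params,
    gene_ids = object$gene_ids,
    t = object$t,
    w_star = object$w_star,
    trees = object$trees
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' Read a fitted forest from JSON
#'
#' @param path Path written by [write_forest_json()].
#' @return A `sauron_rf` usable with [predict.sauron_rf()] and
#'   [predict_trees()] (training data and bootstrap indices are not stored).
#' @export
read_forest_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "sauron_rf_forest")) {
    abort(sprintf("'%s' is not a serialized forest", path))
  }
  trees <- lapply(seq_len(nrow_or_len(payload$trees)), function(i) {
    tr <- if (is.data.frame(payload$trees)) {
      lapply(payload$trees, function(col) col[[i]])
    } else {
      payload$trees[[i]]
    }
    tr$feature <- as.integer(tr$feature)
    tr$left <- as.integer(tr$left)
    tr$right <- as.integer(tr$right)
    tr$class <- as.integer(tr$class)
    tr$split <- as.numeric(tr$split)
    tr
  })
  structure(
    list(trees = trees, bootstrap = NULL, w_star = payload$w_star, train = NULL,
         gene_ids = payload$gene_ids, t = payload$t,
         params = payload$params),
    class = payload$subclass
  )
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
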