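#' Read a gene-expression matrix from delimited text
#'
#' Reads a TSV/CSV file with one header row and one leading identifier column
#' into a samples-by-genes tibble. Files stored genes-by-samples (one row per
#' gene, one column per cell line) are transposed on the way in.
#'
#' @param path Path to a delimited text file. The delimiter is taken from the
#'   file extension (`.csv` is comma-separated, anything else tab-separated).
#' @param orientation Either `"samples_by_genes"` (rows are cell lines) or
#'   `"genes_by_samples"` (rows are genes; the result is transposed).
#' @return A tibble whose first column `sample_id` holds unique cell-line
#'   identifiers and whose remaining columns are numeric gene-expression
#'   values, one column per gene.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("id\tg1\tg2", "A\t1\t2", "B\t3\t4"), tf)
#' load_expression(tf)
load_expression <- function(path, orientation = c("samples_by_genes", "genes_by_samples")) {
  orientation <- match.arg(orientation)
  raw <- read_delimited(path)
  ids <- as.character(raw[[1]])
  check_unique(ids, if (orientation == "samples_by_genes") "sample" else "gene", path)
  check_unique(names(raw)[-1], if (orientation == "samples_by_genes") "gene" else "sample", path)
  mat <- numeric_matrix(raw, path)
  rownames(mat) <- ids
  if (orientation == "genes_by_samples") mat <- t(mat)
  tibble::as_tibble(mat, rownames = "sample_id")
}

#' Read a drug-response table from delimited text
#'
#' Expects two columns: a sample identifier and a numeric response (log IC50).
#' Extra columns are ignored with a message.
#'
#' @inheritParams load_expression
#' @return A tibble with columns `sample_id` and `response`.
#' @export
load_response <- function(path) {
  raw <- read_delimited(path)
  if (ncol(raw) < 2) abort(sprintf("response file '%s' needs at least two columns", path))
  if (ncol(raw) > 2) inform(sprintf("ignoring %d extra column(s) in '%s'", ncol(raw) - 2L, path))
  ids <- as.character(raw[[1]])
  check_unique(ids, "sample", path)
  val <- raw[[2]]
  if (!is.numeric(val)) {
    bad <- which(is.na(suppressWarnings(as.numeric(val))) & !is.na(val))
    abort(sprintf("non-numeric response value at row %d of '%s'", bad[1], path))
  }
  tibble::tibble(sample_id = ids, response = as.numeric(val))
}

read_delimited <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: '%s'", path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::read_delim(path, delim = delim, show_col_types = FALSE, progress = FALSE,
                    name_repair = "minimal")
}

check_unique <- function(ids, what, path) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(sprintf("duplicated %s identifier(s) in '%s': %s",
                  what, path, paste(dup, collapse = ", ")))
  }
  invisible(ids)
}

numeric_matrix <- function(raw, path) {
  cols <- raw[-1]
  for (j in seq_along(cols)) {
    if (!is.numeric(cols[[j]])) {
      v <- suppressWarnings(as.numeric(cols[[j]]))
      bad <- which(is.na(v) & !is.na(cols[[j]]))
      if (length(bad) > 0) {
        abort(sprintf("non-numeric value '%s' at row %d, column '%s' of '%s'",
                      cols[[j]][bad[1]], bad[1], names(cols)[j], path))
      }
      cols[[j]] <- v
    }
  }
  out <- as.matrix(as.data.frame(cols, check.names = FALSE))
  storage.mode(out) <- "double"
  out
}

#' Binarize a continuous drug response at a threshold
#'
#' Cell lines with log IC50 strictly below the drug-specific threshold are
#' called sensitive (1); all others, including values exactly at the
#' threshold, are called resistant (0). Resistant is the conservative default
#' for the boundary case. Setting `sensitive_low = FALSE` inverts the
#' orientation for response measures where larger means more sensitive.
#'
#' @param y Numeric vector of continuous responses (log IC50). Must be finite.
#' @param t Finite scalar threshold in the same units as `y`.
#' @param sensitive_low If `TRUE` (default), sensitive means `y < t`;
#'   otherwise sensitive means `y > t`.
#' @return An integer vector of 0 (resistant) / 1 (sensitive).
#' @export
#' @examples
#' binarize(c(-2, 0, 3), t = 1)
binarize <- function(y, t, sensitive_low = TRUE) {
  if (!is.numeric(t) || length(t) != 1 || !is.finite(t)) {
    abort("`t` must be a finite scalar")
  }
  if (!is.numeric(y) || anyNA(y) || any(!is.finite(y))) {
    abort("`y` must be numeric with no missing or non-finite values")
  }
  if (sensitive_low) as.integer(y < t) else as.integer(y > t)
}

#' Assemble an aligned drug-response dataset
#'
#' Aligns a samples-by-genes expression table with a per-sample continuous
#' drug response, keeping only cell lines present in both (complete
#' information), and attaches the binary sensitive/resistant labels obtained
#' by comparing the response to the drug-specific threshold `t`. Samples are
#' ordered by sorted identifier so that all downstream randomness is governed
#' solely by seeds.
#'
#' @param expression A data frame whose first column is `sample_id` and whose
#'   remaining columns are numeric gene-expression values (as returned by
#'   [load_expression()]), or a numeric matrix with sample-identifier
#'   rownames.
#' @param response A data frame with columns `sample_id` and `response` (as
#'   returned by [load_response()]), or a named numeric vector.
#' @param t Finite scalar binarization threshold (log IC50 units).
#' @param classes Optional precomputed integer 0/1 class vector, named by
#'   sample identifier or ordered like `response`; checked for consistency
#'   with `binarize(y, t)`.
#' @param sensitive_low Passed to [binarize()].
#' @return An object of class `drug_dataset`: a list with `sample_ids`,
#'   `gene_ids`, the expression matrix `X` (samples x genes), the continuous
#'   response `y`, the binary response `Y` and the threshold `t`.
#' @export
drug_dataset <- function(expression, response, t, classes = NULL, sensitive_low = TRUE) {
  X <- as_expression_matrix(expression)
  resp <- as_response_vector(response)
  if (nrow(X) == 0 || length(resp) == 0) abort("expression and response must be non-empty")
  keep <- sort(intersect(rownames(X), names(resp)))
  if (length(keep) == 0) abort("no samples shared between expression and response")
  dropped <- (nrow(X) - length(keep)) + (length(resp) - length(keep))
  if (dropped > 0) {
    inform(sprintf("dropped %d sample(s) without complete expression and response information",
                   dropped))
  }
  X <- X[keep, , drop = FALSE]
  y <- unname(resp[keep])
  if (anyNA(X) || any(!is.finite(X))) abort("expression matrix contains missing or non-finite values")
  Y <- binarize(y, t, sensitive_low = sensitive_low)
  if (!is.null(classes)) {
    cls <- if (!is.null(names(classes))) as.integer(classes[keep]) else as.integer(classes)
    if (length(cls) != length(keep) || anyNA(cls) || !all(cls %in% c(0L, 1L))) {
      abort("`classes` must be a 0/1 vector covering every aligned sample")
    }
    if (!identical(cls, Y)) {
      abort("supplied `classes` disagree with binarize(y, t); check the threshold")
    }
  }
  new_drug_dataset(keep, colnames(X), X, y, Y, t)
}

new_drug_dataset <- function(sample_ids, gene_ids, X, y, Y, t) {
  ds <- structure(
    list(sample_ids = sample_ids, gene_ids = gene_ids, X = X, y = y, Y = Y, t = t),
    class = "drug_dataset"
  )
  validate_drug_dataset(ds)
}

validate_drug_dataset <- function(ds) {
  stopifnot(inherits(ds, "drug_dataset"))
  n <- length(ds$sample_ids)
  if (anyDuplicated(ds$sample_ids)) abort("duplicated sample identifiers")
  if (anyDuplicated(ds$gene_ids)) abort("duplicated gene identifiers")
  if (nrow(ds$X) != n || length(ds$y) != n || length(ds$Y) != n) {
    abort("sample_ids, X, y and Y must agree in length")
  }
  if (ncol(ds$X) != length(ds$gene_ids)) abort("gene_ids must match ncol(X)")
  if (anyNA(ds$X) || anyNA(ds$y)) abort("dataset contains missing values")
  if (!all(ds$Y %in% c(0L, 1L))) abort("Y must be 0/1")
  invisible(ds)
}

as_expression_matrix <- function(expression) {
  if (is.matrix(expression)) {
    if (is.null(rownames(expression))) abort("expression matrix needs sample rownames")
    storage.mode(expression) <- "double"
    return(expression)
  }
  if (!is.data.frame(expression)) abort("`expression` must be a data frame or matrix")
  ids <- as.character(expression[[1]])
  if (anyDuplicated(ids)) abort("duplicated sample identifiers in expression")
  mat <- as.matrix(expression[-1])
  if (!is.numeric(mat)) abort("expression columns must be numeric")
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  mat
}

as_response_vector <- function(response) {
  if (is.data.frame(response)) {
    ids <- as.character(response[[1]])
    if (anyDuplicated(ids)) abort("duplicated sample identifiers in response")
    val <- response[[2]]
    if (!is.numeric(val)) abort("response values must be numeric")
    return(setNames(as.numeric(val), ids))
  }
  if (is.numeric(response) && !is.null(names(response))) return(response)
  abort("`response` must be a data frame or a named numeric vector")
}

#' Count sensitive and resistant cell lines
#'
#' @param data A `drug_dataset`.
#' @return A one-row tibble with `n_sens`, `n_res` and `n`.
#' @export
class_counts <- function(data) {
  validate_drug_dataset(data)
  n_sens <- sum(data$Y == 1L)
  tibble::tibble(n_sens = n_sens, n_res = length(data$Y) - n_sens, n = length(data$Y))
}

# Row subset preserving all invariants; idx may repeat rows (upsampling),
# in which case repeated sample ids get a uniquifying suffix.
ds_subset <- function(ds, idx) {
  ids <- ds$sample_ids[idx]
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_dup")
  new_drug_dataset(ids, ds$gene_ids, `rownames<-`(ds$X[idx, , drop = FALSE], ids),
                   ds$y[idx], ds$Y[idx], ds$t)
}

# Column (gene) subset
ds_select_genes <- function(ds, genes) {
  stopifnot(all(genes %in% ds$gene_ids))
  new_drug_dataset(ds$sample_ids, genes, ds$X[, genes, drop = FALSE], ds$y, ds$Y, ds$t)
}

#' @export
print.drug_dataset <- function(x, ...) {
  cc <- class_counts(x)
  cat(sprintf("<drug_dataset> %d cell lines x %d genes\n", length(x$sample_ids),
              length(x$gene_ids)))
  cat(sprintf("  threshold t = %.4g; %d sensitive / %d resistant (%.1f%% sensitive)\n",
              x$t, cc$n_sens, cc$n_res, 100 * cc$n_sens / cc$n))
  invisible(x)
}

#' @export
as_tibble.drug_dataset <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(sample_id = x$sample_ids, response = x$y, class = x$Y),
    tibble::as_tibble(x$X)
  )
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble
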