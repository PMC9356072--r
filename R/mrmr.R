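#' Plug-in mutual information after quantile discretization
#'
#' Both vectors are independently discretized into `n_bins` equal-frequency
#' (quantile) bins and the mutual information of the resulting contingency
#' table is computed with the plug-in (maximum-likelihood) estimator, in
#' nats. Quantile binning is scale-free, which suits log-expression values.
#' A variable with at most `n_bins` distinct values (e.g. a binary label)
#' keeps its values as levels. A constant vector collapses to a single bin
#' and has mutual information 0; zero-probability cells contribute nothing.
#'
#' @param a,b Numeric vectors of equal length, at least `2 * n_bins` long.
#' @param n_bins Number of quantile bins per variable (default 10).
#' @return A single non-negative number: the estimated mutual information in
#'   nats.
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(500)
#' mutual_information(x, x, n_bins = 4)   # equals the entropy of binned x
mutual_information <- function(a, b, n_bins = 10L) {
  if (length(a) != length(b)) abort("`a` and `b` must have equal length")
  if (length(a) < 2L * n_bins) abort("need at least 2 * n_bins observations")
  if (anyNA(a) || anyNA(b)) abort("missing values are not allowed")
  da <- discretize_quantile(a, n_bins)
  db <- discretize_quantile(b, n_bins)
  mi_from_codes(da$codes, db$codes, da$n_levels, db$n_levels)
}

# Equal-frequency binning. A variable with at most n_bins distinct values
# (binary labels, few-valued scores) keeps its values as levels; otherwise
# duplicated quantile breaks (heavily tied data) merge bins, so the realized
# number of levels can fall below n_bins.
discretize_quantile <- function(x, n_bins) {
  ux <- sort(unique(x))
  if (length(ux) <= n_bins) {
    return(list(codes = match(x, ux), n_levels = length(ux)))
  }
  br <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1L),
                        names = FALSE, type = 7))
  if (length(br) < 2L) {
    return(list(codes = rep(1L, length(x)), n_levels = 1L))
  }
  codes <- findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
  list(codes = codes, n_levels = length(br) - 1L)
}

# Plug-in MI (nats) from integer codes in 1..na, 1..nb
mi_from_codes <- function(a, b, na, nb) {
  n <- length(a)
  joint <- tabulate(a + na * (b - 1L), nbins = na * nb) / n
  pa <- tabulate(a, nbins = na) / n
  pb <- tabulate(b, nbins = nb) / n
  outer_p <- as.vector(outer(pa, pb))
  pos <- joint > 0
  sum(joint[pos] * log(joint[pos] / outer_p[pos]))
}

shannon_entropy <- function(codes, n_levels) {
  p <- tabulate(codes, nbins = n_levels) / length(codes)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Greedy minimum-redundancy maximum-relevance gene selection
#'
#' Selects `k` genes sequentially: the first gene maximizes the mutual
#' information (MI) with the continuous drug response; each further gene
#' maximizes, by default, the difference between its relevance `MI(f, y)` and
#' its mean MI with the genes already selected (the MID score). The quotient
#' form MIQ, relevance divided by mean redundancy, is available via
#' `score = "quotient"`. All MI values use [mutual_information()] with the
#' same quantile discretization. Score ties are broken by lexicographic gene
#' identifier, so the selection is fully deterministic.
#'
#' @param data A `drug_dataset`, or a numeric samples-by-genes matrix with
#'   column names (then `y` must be given).
#' @param k Number of genes to select; must not exceed the number of genes.
#' @param n_bins Quantile bins for the MI estimator (default 10).
#' @param score `"difference"` (MID, default) or `"quotient"` (MIQ).
#' @param y Continuous response; ignored when `data` is a `drug_dataset`.
#' @return A tibble with one row per selected gene, in selection order:
#'   `rank`, `gene_id`, `relevance` (MI with the response, nats),
#'   `redundancy` (mean MI with previously selected genes at selection time;
#'   0 for the first gene) and `score`.
#' @export
select_features <- function(data, k, n_bins = 10L, score = c("difference", "quotient"),
                            y = NULL) {
  score <- match.arg(score)
  if (inherits(data, "drug_dataset")) {
    X <- data$X
    y <- data$y
  } else {
    X <- as.matrix(data)
    if (is.null(colnames(X))) abort("gene matrix needs column names")
    if (is.null(y)) abort("`y` is required when `data` is a matrix")
  }
  P <- ncol(X)
  if (k < 1 || k > P) abort(sprintf("`k` must be in 1..%d (number of genes)", P))

  genes <- colnames(X)
  disc <- lapply(seq_len(P), function(j) discretize_quantile(X[, j], n_bins))
  dy <- discretize_quantile(y, n_bins)
  relevance <- vapply(disc, function(d) mi_from_codes(d$codes, dy$codes, d$n_levels, dy$n_levels),
                      numeric(1))

  selected <- integer(0)
  red_sum <- numeric(P)        # running sum of MI(f, s) over selected s
  out_red <- numeric(k)
  out_score <- numeric(k)
  remaining <- rep(TRUE, P)
  for (step in seq_len(k)) {
    if (step == 1L) {
      sc <- relevance
      mean_red <- numeric(P)
    } else {
      last <- selected[step - 1L]
      idx <- which(remaining)
      red_sum[idx] <- red_sum[idx] + vapply(idx, function(j) {
        mi_from_codes(disc[[j]]$codes, disc[[last]]$codes,
                      disc[[j]]$n_levels, disc[[last]]$n_levels)
      }, numeric(1))
      mean_red <- red_sum / (step - 1L)
      sc <- if (score == "difference") {
        relevance - mean_red
      } else {
        relevance / pmax(mean_red, .Machine$double.eps)
      }
    }
    sc[!remaining] <- -Inf
    best <- which(sc == max(sc))
    if (length(best) > 1L) best <- best[order(genes[best])][1L]
    selected[step] <- best
    out_red[step] <- mean_red[best]
    out_score[step] <- sc[best]
    remaining[best] <- FALSE
  }
  tibble::tibble(
    rank = seq_len(k),
    gene_id = genes[selected],
    relevance = relevance[selected],
    redundancy = out_red,
    score = out_score
  )
}
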