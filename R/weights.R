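#' Per-sample weights counteracting class imbalance
#'
#' Computes the initial sample importance weights fed into weighted forest
#' training. Four schemes are available:
#'
#' * `"uniform"`: every sample gets weight 1 (the no-countermeasure baseline).
#' * `"simple"`: resistant samples get weight 1 and sensitive samples get
#'   `N_res / N_sens`, so the total weight mass of the two classes is equal.
#' * `"linear"` / `"quadratic"`: a sample's weight is its distance from the
#'   binarization threshold, `|y_i - t|^d` with `d = 1` or `2`, normalized
#'   within its class so that each class's weights sum to 0.5 (and all
#'   weights to 1). Samples far from the threshold — confidently sensitive or
#'   confidently resistant — dominate.
#'
#' @param data A `drug_dataset`.
#' @param scheme One of `"uniform"`, `"simple"`, `"linear"`, `"quadratic"`.
#' @return A tibble with columns `sample_id`, `class` and `w_star`, carrying
#'   the scheme (and distance exponent `d`, where applicable) as attributes.
#' @export
#' @examples
#' ds <- toy_fixture()
#' sample_weights(ds, "simple")
sample_weights <- function(data, scheme = c("uniform", "simple", "linear", "quadratic")) {
  scheme <- match.arg(scheme)
  validate_drug_dataset(data)
  Y <- data$Y
  w <- switch(scheme,
    uniform = rep(1, length(Y)),
    simple = simple_weights(Y),
    linear = distance_weights(data$y, Y, data$t, d = 1L),
    quadratic = distance_weights(data$y, Y, data$t, d = 2L)
  )
  out <- tibble::tibble(sample_id = data$sample_ids, class = Y, w_star = w)
  attr(out, "scheme") <- scheme
  if (scheme %in% c("linear", "quadratic")) {
    attr(out, "d") <- if (scheme == "linear") 1L else 2L
  }
  out
}

simple_weights <- function(Y) {
  n_sens <- sum(Y == 1L)
  n_res <- sum(Y == 0L)
  if (n_sens == 0L || n_res == 0L) {
    abort("simple sample weights need both classes present (class ratio undefined)")
  }
  ifelse(Y == 1L, n_res / n_sens, 1)
}

distance_weights <- function(y, Y, t, d) {
  if (sum(Y == 1L) == 0L || sum(Y == 0L) == 0L) {
    abort("distance sample weights need both classes present")
  }
  dist <- abs(y - t)^d
  per_class_sum <- c(sum(dist[Y == 0L]), sum(dist[Y == 1L]))
  if (any(per_class_sum == 0)) {
    abort("a class has all samples exactly at the threshold; distance weights undefined")
  }
  dist / (2 * per_class_sum[Y + 1L])
}

#' Upsample the sensitive minority class to parity
#'
#' Draws sensitive cell lines with replacement and appends the copies until
#' the sensitive class matches the resistant class in size. All original
#' rows are retained; duplicated rows get a uniquifying identifier suffix. An
#' already balanced dataset is returned unchanged.
#'
#' @param data A `drug_dataset` with both classes present and the sensitive
#'   class in the minority.
#' @param seed Integer seed controlling the draws.
#' @return A `drug_dataset` with equally many sensitive and resistant rows.
#' @export
upsample <- function(data, seed = 1L) {
  validate_drug_dataset(data)
  sens <- which(data$Y == 1L)
  res <- which(data$Y == 0L)
  if (length(sens) == 0L) abort("no sensitive samples to upsample")
  if (length(sens) > length(res)) abort("sensitive class is not the minority")
  n_extra <- length(res) - length(sens)
  if (n_extra == 0L) return(data)
  extra <- withr::with_seed(seed, sample(sens, n_extra, replace = TRUE))
  ds_subset(data, c(seq_along(data$Y), extra))
}

#' Proportional upsampling by distance from the threshold
#'
#' Duplicates sensitive cell lines proportionally to their distance from the
#' binarization threshold: the linear distance weights of the sensitive class
#' (which sum to 0.5) are doubled into per-sample importances summing to 1,
#' and each sensitive sample's total copy count is its importance times the
#' number of resistant samples, rounded half-to-even with a largest-remainder
#' repair so the class sizes balance exactly. A sensitive sample very close
#' to the threshold can receive zero copies and drop out.
#'
#' @inheritParams upsample
#' @param seed Unused (the procedure is deterministic); kept for interface
#'   symmetry with [upsample()].
#' @return A `drug_dataset` with equally many sensitive and resistant rows.
#' @export
proportional_upsample <- function(data, seed = 1L) {
  validate_drug_dataset(data)
  sens <- which(data$Y == 1L)
  res <- which(data$Y == 0L)
  if (length(sens) == 0L) abort("no sensitive samples to upsample")
  if (length(sens) > length(res)) abort("sensitive class is not the minority")
  dist <- abs(data$y[sens] - data$t)
  if (sum(dist) == 0) {
    abort("all sensitive samples lie exactly at the threshold; importances undefined")
  }
  importance <- dist / sum(dist)          # 2 x the linear class weights
  counts <- apportion_counts(importance * length(res), length(res))
  ds_subset(data, c(res, rep(sens, counts)))
}

# Round half-to-even, then repair the total by the largest-remainder rule
# (ties by lower index) so the counts sum to exactly `total`.
apportion_counts <- function(raw, total) {
  counts <- as.integer(round(raw))
  frac <- raw - floor(raw)
  diff <- total - sum(counts)
  if (diff > 0) {
    ord <- order(-frac, seq_along(raw))
    for (i in rep_len(ord, diff)) counts[i] <- counts[i] + 1L
  } else if (diff < 0) {
    ord <- order(frac, seq_along(raw))
    i <- 1L
    while (diff < 0L) {
      j <- ord[i]
      if (counts[j] > 0L) {
        counts[j] <- counts[j] - 1L
        diff <- diff + 1L
      }
      i <- if (i == length(ord)) 1L else i + 1L
    }
  }
  counts
}
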