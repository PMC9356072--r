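#' Simulate an imbalanced cell-line drug-response dataset
#'
#' Generates a synthetic panel with the structural features of public
#' cell-line drug screens: several hundred samples, high-dimensional
#' log-scale expression, a continuous log-IC50 response with a minority
#' "sensitive" mode well below the resistant bulk, and a known binarization
#' threshold.
#'
#' The latent class of each cell line is drawn Bernoulli(`frac_sensitive`).
#' The `n_informative` informative genes (positions drawn at random, recorded
#' in the `informative_genes` attribute) are unit-variance Gaussians whose
#' mean is shifted down by 1 in sensitive lines; the remaining genes are
#' standard Gaussian noise. The response is bimodal by construction: half of
#' the class separation is a direct class effect on the intercept and half is
#' mediated linearly through the informative genes, so that the sensitive
#' class mean lies `effect_size` below the resistant class mean and the
#' informative genes genuinely predict the response. Gaussian noise with sd
#' `noise_sd` is added, and the threshold `t` is the midpoint of the two
#' class means, so the binarized labels recover the latent class up to the
#' noise. The stored labels `Y` are always `binarize(y, t)`; the latent class
#' is kept in the `latent_class` attribute for benchmarking.
#'
#' @param n_samples Number of cell lines (default 800).
#' @param n_genes Number of genes (default 300).
#' @param n_informative Number of response-associated genes (default 20).
#' @param frac_sensitive Expected sensitive fraction, in (0, 0.5); default
#'   0.09, i.e. roughly one sensitive per ten resistant lines.
#' @param effect_size Separation of the class-conditional response means, in
#'   log-IC50 units (default 3).
#' @param noise_sd Standard deviation of the response noise (default 1).
#' @param seed Seed governing all draws.
#' @return A `drug_dataset` with attributes `latent_class` (integer 0/1) and
#'   `informative_genes` (character).
#' @export
#' @examples
#' ds <- simulate_drug_data(n_samples = 200, n_genes = 50, seed = 1)
#' class_counts(ds)
simulate_drug_data <- function(n_samples = 800L, n_genes = 300L, n_informative = 20L,
                               frac_sensitive = 0.09, effect_size = 3.0,
                               noise_sd = 1.0, seed = 1L) {
  if (n_informative > n_genes) abort("`n_informative` must not exceed `n_genes`")
  if (n_informative < 1L) abort("`n_informative` must be at least 1")
  if (frac_sensitive <= 0 || frac_sensitive >= 0.5) {
    abort("`frac_sensitive` must be in (0, 0.5)")
  }
  if (noise_sd < 0 || effect_size < 0) abort("`noise_sd` and `effect_size` must be non-negative")

  withr::with_seed(seed, {
    z <- rbinom(n_samples, 1L, frac_sensitive)
    X <- matrix(rnorm(n_samples * n_genes), n_samples, n_genes)
    informative <- sort(sample.int(n_genes, n_informative))
    X[, informative] <- X[, informative] - z          # sensitive lines shifted down by 1
    beta <- rep((effect_size / 2) / n_informative, n_informative)
    y <- -(effect_size / 2) * z + drop(X[, informative, drop = FALSE] %*% beta) +
      rnorm(n_samples, 0, noise_sd)
  })
  # E[y | resistant] = 0, E[y | sensitive] = -effect_size; t at the midpoint
  t <- -effect_size / 2

  ids <- sprintf("cl_%04d", seq_len(n_samples))
  genes <- sprintf("gene_%04d", seq_len(n_genes))
  dimnames(X) <- list(ids, genes)
  ds <- new_drug_dataset(ids, genes, X, y, binarize(y, t), t)
  attr(ds, "latent_class") <- z
  attr(ds, "informative_genes") <- genes[informative]
  ds
}

#' Tiny fixed dataset for exhaustive checks
#'
#' A hand-specified 12-cell-line, 3-gene dataset with both classes present
#' (4 sensitive, 8 resistant at threshold 0). It is built from embedded
#' constants, so repeated calls are identical; it is small enough that tree
#' splits can be verified by exhaustive enumeration.
#'
#' @return A `drug_dataset`.
#' @export
toy_fixture <- function() {
  ids <- sprintf("s%02d", 1:12)
  X <- cbind(
    g1 = c(0.5, 1.0, 1.5, 2.0, 2.5, 3.0, 3.5, 4.0, 4.5, 5.0, 5.5, 6.0),
    g2 = c(2.0, 1.0, 2.5, 0.5, 3.0, 1.5, 3.5, 2.2, 0.8, 2.9, 1.2, 3.3),
    g3 = c(1.0, 0.0, 1.0, 0.0, 1.0, 0.0, 0.0, 1.0, 0.0, 1.0, 0.0, 1.0)
  )
  rownames(X) <- ids
  y <- c(-3.0, -2.5, -2.0, -1.5, 1.0, 1.5, 2.0, 2.5, 3.0, 3.5, 4.0, 4.5)
  t <- 0
  new_drug_dataset(ids, colnames(X), X, y, binarize(y, t), t)
}
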