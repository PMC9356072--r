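# Independent oracles and hand-built forest scaffolding used across tests.
# These re-derive quantities from their definitions (node-normalized error
# improvement, plug-in mutual information on a contingency table) without
# touching the package's computational path.

# Best split by direct evaluation of the node-normalized weighted-MSE
# improvement: w_an(v) * (MSE(v) - w_ch(v_l) MSE(v_l) - w_ch(v_r) MSE(v_r)),
# with per-node weights w_i / sum(w) and node weights as weight-mass
# fractions. All (feature, midpoint) candidates are enumerated; ties keep
# the first candidate in (feature, split) order.
oracle_best_split <- function(X, ys, w, members, min_leaf, w_root) {
  wmse <- function(idx) {
    wn <- w[idx] / sum(w[idx])
    yhat <- sum(wn * ys[idx])
    sum(wn * (ys[idx] - yhat)^2)
  }
  Wv <- sum(w[members])
  w_an <- Wv / w_root
  tie_tol <- 1e-9 * w_an * wmse(members)  # same relative tie window as the builder
  best <- NULL
  for (f in seq_len(ncol(X))) {
    vals <- sort(unique(X[members, f]))
    if (length(vals) < 2) next
    for (i in seq_len(length(vals) - 1L)) {
      s <- (vals[i] + vals[i + 1L]) / 2
      li <- members[X[members, f] < s]
      ri <- members[X[members, f] >= s]
      if (length(li) < min_leaf || length(ri) < min_leaf) next
      gain <- w_an * (wmse(members) -
                        (sum(w[li]) / Wv) * wmse(li) -
                        (sum(w[ri]) / Wv) * wmse(ri))
      if (is.null(best) || gain > best$gain + tie_tol) {
        best <- list(feature = f, split = s, gain = gain)
      }
    }
  }
  best
}

# Recompute each node's member set (bootstrap indices with multiplicity) by
# dropping the tree's bootstrap sample down the stored split structure.
node_members <- function(tree, X, boot) {
  members <- vector("list", length(tree$feature))
  recurse <- function(node, idx) {
    members[[node]] <<- idx
    if (tree$feature[node] > 0L) {
      f <- tree$feature[node]
      s <- tree$split[node]
      recurse(tree$left[node], idx[X[idx, f] < s])
      recurse(tree$right[node], idx[X[idx, f] >= s])
    }
  }
  recurse(1L, boot)
  members
}

# Plug-in MI (nats) computed independently from a contingency table of
# integer codes.
oracle_mi_codes <- function(a, b) {
  tab <- table(a, b) / length(a)
  pa <- rowSums(tab)
  pb <- colSums(tab)
  total <- 0
  for (i in seq_along(pa)) {
    for (j in seq_along(pb)) {
      if (tab[i, j] > 0) total <- total + tab[i, j] * log(tab[i, j] / (pa[i] * pb[j]))
    }
  }
  unname(as.numeric(total))
}

oracle_entropy <- function(codes) {
  p <- as.numeric(table(codes)) / length(codes)
  -sum(p * log(p))
}

# A single-leaf tree with prescribed leaf annotations, in the exact node
# layout the fitted trees use.
leaf_tree <- function(value, class, w0, w1, uvalue = value, n0 = NULL, n1 = NULL) {
  list(
    feature = 0L, split = NA_real_, left = 0L, right = 0L,
    value = as.numeric(value), uvalue = as.numeric(uvalue),
    class = as.integer(class), w0 = as.numeric(w0), w1 = as.numeric(w1),
    n0 = as.integer(n0 %||% round(w0)), n1 = as.integer(n1 %||% round(w1)),
    importance = 0
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Wrap hand-built trees into a predictable forest object.
hand_forest <- function(trees, tree_weighting = "binary",
                        subclass = "sauron_rf", gene_ids = "g1", t = 0) {
  structure(
    list(trees = trees, bootstrap = NULL, w_star = NULL, train = NULL,
         gene_ids = gene_ids, t = t,
         params = list(trees = length(trees), mtry = 1L, min_node = 1L,
                       seed = 0L, sample_weights = "uniform",
                       resampling = "none", tree_weighting = tree_weighting,
                       split_on = "response")),
    class = subclass
  )
}

one_query <- function(p = 1) matrix(0, 1, p, dimnames = list("q1", paste0("g", seq_len(p))))

# Small random dataset for property-style loops.
random_dataset <- function(n = 30, p = 4, seed = 1, frac_sens = 0.3) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n) - 2 * rbinom(n, 1, frac_sens)
  })
  t <- unname(quantile(y, frac_sens))
  ids <- sprintf("r%03d", seq_len(n))
  genes <- paste0("g", seq_len(p))
  dimnames(X) <- list(ids, genes)
  sauronrf:::new_drug_dataset(ids, genes, X, y, binarize(y, t), t)
}
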