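test_that("a perfectly separating feature is split between the response plateaus", {
  n <- 12
  ids <- sprintf("p%02d", 1:n)
  X <- matrix(1:n, n, 1, dimnames = list(ids, "g1"))
  y <- rep(c(0, 5), each = n / 2)
  ds <- sauronrf:::new_drug_dataset(ids, "g1", X, y, binarize(y, 2.5), 2.5)
  fit <- sauron_rf(ds, trees = 1, mtry = 1, min_node = 1, seed = 4)
  tr <- fit$trees[[1]]
  expect_equal(tr$feature[1], 1L)
  # zero-impurity children force a single split between the plateaus
  kids <- c(tr$left[1], tr$right[1])
  expect_equal(sort(tr$value[kids]), c(0, 5))
  q <- matrix(c(3, 10), 2, 1, dimnames = list(c("lo", "hi"), "g1"))
  expect_equal(predict(fit, q)$.pred_value, c(0, 5))
})

test_that("fitted splits match the exhaustive improvement oracle on random nodes", {
  ds <- random_dataset(n = 12, p = 3, seed = 8)
  for (scheme in c("uniform", "simple")) {
    fit <- sauron_rf(ds, sample_weights = scheme, trees = 2, mtry = 3,
                     min_node = 2, seed = 31)
    w <- sample_weights(ds, scheme)$w_star
    for (b in seq_along(fit$trees)) {
      tr <- fit$trees[[b]]
      members <- node_members(tr, ds$X, fit$bootstrap[[b]])
      w_root <- sum(w[fit$bootstrap[[b]]])
      for (v in which(tr$feature > 0L)) {
        oracle <- oracle_best_split(ds$X, ds$y, w, members[[v]],
                                    min_leaf = 2, w_root = w_root)
        expect_equal(tr$feature[v], oracle$feature)
        expect_equal(tr$split[v], oracle$split)
      }
    }
  }
})

test_that("leaf annotations reproduce the weighted member statistics", {
  ds <- toy_fixture()
  fit <- sauron_rf(ds, sample_weights = "linear", trees = 3, mtry = 3,
                   min_node = 2, seed = 12)
  w <- sample_weights(ds, "linear")$w_star
  for (b in seq_along(fit$trees)) {
    tr <- fit$trees[[b]]
    members <- node_members(tr, ds$X, fit$bootstrap[[b]])
    for (v in which(tr$feature == 0L)) {
      idx <- members[[v]]
      expect_gte(length(idx), 2)  # min_node
      expect_equal(tr$value[v], sum(w[idx] * ds$y[idx]) / sum(w[idx]),
                   tolerance = 1e-12)
      expect_equal(tr$uvalue[v], mean(ds$y[idx]), tolerance = 1e-12)
      expect_equal(tr$w1[v], sum(w[idx][ds$Y[idx] == 1L]), tolerance = 1e-12)
      expect_equal(tr$n0[v], sum(ds$Y[idx] == 0L))
      # weighted-mass majority label, ties resistant
      expect_equal(tr$class[v], as.integer(tr$w1[v] > tr$w0[v]))
    }
  }
})

test_that("single-class training data yields constant class predictions", {
  n <- 20
  ids <- sprintf("c%02d", 1:n)
  withr::with_seed(2, {
    X <- matrix(rnorm(2 * n), n, 2, dimnames = list(ids, c("g1", "g2")))
    y <- rnorm(n) + 5
  })
  ds <- sauronrf:::new_drug_dataset(ids, c("g1", "g2"), X, y, binarize(y, 0), 0)
  fit <- sauron_rf(ds, trees = 10, seed = 3)
  pr <- predict(fit, ds)
  expect_true(all(pr$.pred_class == 0L))
})

test_that("forest vote is the mode of tree votes with resistant ties", {
  votes <- function(classes) {
    trees <- lapply(classes, function(cl) {
      leaf_tree(value = 1, class = cl, w0 = 1 - cl, w1 = cl)
    })
    predict(hand_forest(trees), one_query())$.pred_class
  }
  expect_equal(votes(c(1, 1, 0)), 1L)
  expect_equal(votes(c(0, 0, 0)), 0L)  # unanimity
  expect_equal(votes(c(1, 0)), 0L)     # tie -> resistant
})

test_that("tree-weight schemes follow their defining formulas", {
  # binary: classes (1,1,1,0), forest class 1 -> (1/3, 1/3, 1/3, 0)
  trees <- lapply(c(1, 1, 1, 0), function(cl) {
    leaf_tree(value = cl, class = cl, w0 = 1 - cl, w1 = cl)
  })
  fw <- predict_trees(hand_forest(trees), one_query(), scheme = "binary")
  expect_equal(fw$weight, c(1 / 3, 1 / 3, 1 / 3, 0))

  # binary_sens on a resistant-predicted query falls back to 1/B
  trees_res <- lapply(c(0, 0, 0, 1), function(cl) {
    leaf_tree(value = cl, class = cl, w0 = 1 - cl, w1 = cl)
  })
  fw2 <- predict_trees(hand_forest(trees_res), one_query(), scheme = "binary_sens")
  expect_equal(fw2$weight, rep(1 / 4, 4))

  # majority: leaf agree-fractions (1.0, 0.5) -> weights (2/3, 1/3)
  trees_m <- list(
    leaf_tree(value = 0, class = 1, w0 = 0, w1 = 1),
    leaf_tree(value = 0, class = 1, w0 = 0.5, w1 = 0.5)
  )
  fw3 <- predict_trees(hand_forest(trees_m), one_query(), scheme = "majority")
  expect_equal(fw3$weight, c(2 / 3, 1 / 3))

  expect_error(predict_trees(hand_forest(trees), one_query(), scheme = "nope"),
               "unknown")
})

test_that("tree weights sum to one and value is their weighted leaf-mean sum", {
  ds <- random_dataset(n = 40, p = 3, seed = 5)
  fit <- sauron_rf(ds, sample_weights = "simple", trees = 9, seed = 5)
  q <- random_dataset(n = 15, p = 3, seed = 6)
  for (scheme in c("uniform", "binary", "binary_sens", "majority", "majority_sens")) {
    ft <- predict_trees(fit, q, scheme = scheme)
    sums <- tapply(ft$weight, ft$sample_id, sum)
    expect_true(all(abs(sums - 1) < 1e-12))
    pv <- predict(fit, q, scheme = scheme)
    agg <- tapply(ft$weight * ft$tree_value, ft$sample_id, sum)
    expect_equal(as.numeric(agg[pv$sample_id]), pv$.pred_value, tolerance = 1e-12)
  }
})

test_that("uniform scheme equals the conventional regression-forest average", {
  ds <- random_dataset(n = 40, p = 3, seed = 15)
  fit <- sauron_rf(ds, trees = 7, seed = 15)
  ft <- predict_trees(fit, ds, scheme = "uniform")
  plain <- tapply(ft$tree_value, ft$sample_id, mean)
  pr <- predict(fit, ds, scheme = "uniform")
  expect_equal(as.numeric(plain[pr$sample_id]), pr$.pred_value, tolerance = 1e-12)
})

test_that("fit rejects impossible configurations", {
  ds <- toy_fixture()
  expect_error(sauron_rf(ds, min_node = 7), "2 \\* min_node")
  expect_error(sauron_rf(ds, mtry = 4, trees = 1), "exceeds")
  q_bad <- matrix(0, 1, 2)
  fit <- sauron_rf(ds, trees = 2, seed = 1)
  expect_error(predict(fit, q_bad), "trained on")
})

test_that("feature importances are normalized impurity contributions", {
  # one informative gene: stumps concentrate importance on it
  n <- 60
  ids <- sprintf("i%02d", 1:n)
  withr::with_seed(9, {
    g1 <- rnorm(n)
    noise <- rnorm(n)
  })
  X <- cbind(g1 = g1, g2 = noise)
  rownames(X) <- ids
  y <- 3 * g1
  ds <- sauronrf:::new_drug_dataset(ids, colnames(X), X, y, binarize(y, 0), 0)
  fit <- sauron_rf(ds, trees = 20, mtry = 2, min_node = 25, seed = 9)
  imp <- feature_importance(fit)
  expect_equal(sum(imp$importance), 1)
  expect_identical(imp$gene_id[1], "g1")
  expect_gt(imp$importance[1], 0.95)
})

test_that("informative genes rank first on simulated signal across seeds", {
  hits <- 0L
  for (s in 1:10) {
    ds <- simulate_drug_data(n_samples = 150, n_genes = 10, n_informative = 1,
                             effect_size = 6, noise_sd = 0.5, seed = s)
    fit <- sauron_rf(ds, trees = 30, seed = s)
    top <- feature_importance(fit)$gene_id[1]
    hits <- hits + (top == attr(ds, "informative_genes"))
  }
  expect_gte(hits, 9L)
})

test_that("JSON serialization replays predictions identically", {
  ds <- random_dataset(n = 30, p = 3, seed = 22)
  fit <- sauron_rf(ds, sample_weights = "simple", trees = 5, seed = 22)
  path <- tempfile(fileext = ".json")
  write_forest_json(fit, path)
  fit2 <- read_forest_json(path)
  q <- random_dataset(n = 10, p = 3, seed = 23)
  for (scheme in c("uniform", "binary_sens", "majority")) {
    expect_equal(predict(fit2, q, scheme = scheme), predict(fit, q, scheme = scheme))
  }
})
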