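test_that("confusion metrics follow their definitions", {
  # TP 1, FN 9, TN 10, FP 0
  truth <- c(rep(1, 10), rep(0, 10))
  est <- c(1, rep(0, 9), rep(0, 10))
  m <- classification_metrics(truth, est)
  expect_equal(m$sensitivity, 0.1)
  expect_equal(m$specificity, 1.0)
  expect_equal(m$tp + m$fp + m$tn + m$fn, 20)

  perfect <- classification_metrics(truth, truth)
  expect_equal(perfect$mcc, 1)

  # TP 2, FP 1, TN 8, FN 1 -> MCC = 15/27
  t2 <- c(1, 1, 1, rep(0, 9))
  e2 <- c(1, 1, 0, 1, rep(0, 8))
  expect_equal(classification_metrics(t2, e2)$mcc, 15 / 27)

  # all predictions one class: zero denominator factor -> MCC 0 by convention
  expect_equal(classification_metrics(t2, rep(0, 12))$mcc, 0)
  expect_error(classification_metrics(c(0, 1), c(1)), "length")
})

test_that("MCC is invariant under swapping both label sets", {
  for (s in 1:15) {
    withr::with_seed(s, {
      truth <- rbinom(40, 1, 0.3)
      est <- rbinom(40, 1, 0.4)
    })
    m1 <- classification_metrics(truth, est)$mcc
    m2 <- classification_metrics(1L - truth, 1L - est)$mcc
    expect_equal(m1, m2, tolerance = 1e-12)
  }
})

test_that("per-class regression errors are computed on true-label subsets", {
  y <- c(1, 2, 10, 20)
  cls <- c(1L, 1L, 0L, 0L)
  m <- regression_metrics(y, y, cls)
  expect_true(all(unlist(m) == 0))

  # errors (1, 3) in the sensitive class -> MSE (1+9)/2 = 5, median SE 5
  m2 <- regression_metrics(y, y + c(1, 3, 0, 0), cls)
  expect_equal(m2$mse_sens, 5)
  expect_equal(m2$medse_sens, 5)
  expect_equal(m2$mse_res, 0)

  # empty class subset reports NA, not zero
  m3 <- regression_metrics(y[3:4], y[3:4] + 1, cls[3:4])
  expect_true(is.na(m3$mse_sens) && is.na(m3$medse_sens))
  expect_equal(m3$mse, 1)
})

test_that("rRF classification is threshold comparison on predicted values", {
  expect_identical(rrf_classify(c(-2, 0, 3), t = 1), c(1L, 1L, 0L))
  expect_identical(rrf_classify(c(1, 0.999), t = 1), c(0L, 1L))
  expect_identical(rrf_classify(c(2, 3), t = 1), c(0L, 0L))
})

test_that("rRF on separable data recovers every sensitive line by threshold", {
  # a wide gap in both the feature and the response: every root split falls
  # inside the gap, so tree predictions never mix the two response groups
  n <- 12
  ids <- sprintf("s%02d", 1:n)
  X <- matrix(c(1:4, 101:108), n, 1, dimnames = list(ids, "g1"))
  y <- c(seq(-3.3, -3, length.out = 4), seq(3, 3.3, length.out = 8))
  ds <- sauronrf:::new_drug_dataset(ids, "g1", X, y, binarize(y, 0), 0)
  fit <- sauron_rf(ds, sample_weights = "uniform", tree_weighting = "uniform",
                   trees = 30, min_node = 1, seed = 2)
  pred <- predict(fit, ds, scheme = "uniform")$.pred_value
  cls <- rrf_classify(pred, ds$t)
  expect_equal(classification_metrics(ds$Y, cls)$sensitivity, 1)
  expect_equal(classification_metrics(ds$Y, cls)$specificity, 1)
})

test_that("cRF continuous prediction averages agreeing trees' leaf means", {
  # trees vote (1, 1, 0), forest class 1, unweighted leaf y-means (2, 4, 99):
  # prediction (2 + 4) / 2 = 3, the disagreeing tree excluded
  trees <- list(
    leaf_tree(value = 0, uvalue = 2, class = 1, w0 = 0, w1 = 1),
    leaf_tree(value = 0, uvalue = 4, class = 1, w0 = 0, w1 = 1),
    leaf_tree(value = 0, uvalue = 99, class = 0, w0 = 1, w1 = 0)
  )
  crf <- hand_forest(trees, tree_weighting = "binary",
                     subclass = c("classification_rf", "sauron_rf"))
  pr <- predict(crf, one_query())
  expect_equal(pr$.pred_class, 1L)
  expect_equal(pr$.pred_value, 3.0)

  # all trees agreeing on a shared leaf with y = (2, 4): plain average 3
  trees2 <- list(leaf_tree(value = 0, uvalue = 3, class = 0, w0 = 2, w1 = 0),
                 leaf_tree(value = 0, uvalue = 3, class = 0, w0 = 2, w1 = 0))
  expect_equal(predict(hand_forest(trees2, subclass = c("classification_rf", "sauron_rf")),
                       one_query())$.pred_value, 3.0)
})

test_that("single-tree cRF prediction equals the reached leaf's unweighted mean", {
  ds <- toy_fixture()
  fit <- classification_rf(ds, trees = 1, min_node = 2, seed = 6)
  tr <- fit$trees[[1]]
  members <- node_members(tr, ds$X, fit$bootstrap[[1]])
  pr <- predict(fit, ds)
  trv <- sauronrf:::forest_traverse(fit, ds$X)
  for (q in seq_along(ds$y)) {
    leaf <- trv$leaf[1, q]
    expect_equal(pr$.pred_value[q], mean(ds$y[members[[leaf]]]), tolerance = 1e-12)
  }
})

test_that("classification forest splits on the labels, not the response", {
  # y ordering conflicts with class structure carried by g1 only
  n <- 40
  ids <- sprintf("h%02d", 1:n)
  withr::with_seed(13, {
    cls_drive <- rep(c(0, 1), each = n / 2)
    X <- cbind(g1 = cls_drive * 4 + rnorm(n, sd = 0.3), g2 = rnorm(n))
    y <- ifelse(cls_drive == 1, -3, 3) + rnorm(n, sd = 0.2)
  })
  rownames(X) <- ids
  ds <- sauronrf:::new_drug_dataset(ids, colnames(X), X, y, binarize(y, 0), 0)
  fit <- classification_rf(ds, trees = 20, seed = 13)
  pr <- predict(fit, ds)
  expect_gt(classification_metrics(ds$Y, pr$.pred_class)$mcc, 0.9)
})

test_that("hierarchical baseline routes queries by the classifier's vote", {
  ds <- toy_fixture()
  fit <- hierarchical_rf(ds, trees = 25, min_node = 2, seed = 11)
  pr <- predict(fit, ds)
  cls <- predict(fit$classifier, ds)$.pred_class
  v_res <- predict(fit$regressors[[1]], ds)$.pred_value
  v_sens <- predict(fit$regressors[[2]], ds)$.pred_value
  expect_equal(pr$.pred_class, cls)
  expect_equal(pr$.pred_value, ifelse(cls == 1L, v_sens, v_res))

  # perfect training classification makes per-class MSE the sub-regressors' own
  expect_equal(cls, ds$Y)
  m <- regression_metrics(ds$y, pr$.pred_value, ds$Y)
  expect_equal(m$mse_sens,
               mean((ds$y[ds$Y == 1] - v_sens[ds$Y == 1])^2), tolerance = 1e-12)
  expect_equal(m$mse_res,
               mean((ds$y[ds$Y == 0] - v_res[ds$Y == 0])^2), tolerance = 1e-12)
})

test_that("hierarchical fitting refuses classes too small to regress on", {
  ds <- random_dataset(n = 30, p = 2, seed = 31)
  expect_error(hierarchical_rf(ds, min_node = 10), "sensitive")
})
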