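test_that("Kd converts to free energy by RT ln Kd", {
  expect_equal(kd_to_dg(1), 0)
  expect_equal(kd_to_dg(1, temperature = 500), 0)
  expect_equal(kd_to_dg(1e-6), -8.18, tolerance = 1e-2)
  # a 3-fold Kd ratio is worth RT ln 3, about 0.65 kcal/mol at 298.15 K
  ddg <- kd_to_dg(3e-6) - kd_to_dg(1e-6)
  expect_equal(ddg, 0.651, tolerance = 1e-3)
  expect_error(kd_to_dg(0), "positive")
  expect_error(kd_to_dg(-1), "positive")
  expect_error(kd_to_dg(1, temperature = -5), "positive")
})

test_that("constant labels give a base-only model that predicts the constant", {
  tab <- make_training_table(n_rows = 50, seed = 1)
  tab$label <- 2.5
  expect_warning(m <- fit_gbr(tab), "constant")
  expect_equal(predict(m, tab), rep(2.5, 50))
  m0 <- fit_gbr(make_training_table(50, seed = 2), n_trees = 0)
  expect_equal(unique(predict(m0, make_training_table(10, seed = 3))),
    mean(make_training_table(50, seed = 2)$label),
    tolerance = 1e-12
  )
})

test_that("a noise-free planted response is recovered to near-zero training error", {
  tab <- make_training_table(
    n_rows = 500, n_features = 5,
    planted = list(features = "f1", thresholds = 0.5, value = 1),
    noise_sd = 0, seed = 7
  )
  m <- fit_gbr(tab, n_trees = 13, max_depth = 3, learning_rate = 1)
  expect_lt(m$training_rmse, 0.05)
  # the planted threshold is recoverable from the exported ruleset within
  # the gap between adjacent sampled feature values
  exported <- jsonlite::fromJSON(export_trees(m))
  thr1 <- exported$trees[[1]]$threshold[!exported$trees[[1]]$is_leaf &
    exported$trees[[1]]$feature == "f1"]
  xs <- sort(tab$f1)
  gap <- max(diff(xs[abs(xs - 0.5) < 0.05]))
  expect_lt(min(abs(thr1 - 0.5)), gap + 1e-12)
})

test_that("refitting with identical inputs is bit-stable", {
  tab <- make_training_table(n_rows = 200, n_features = 8, noise_sd = 0.2, seed = 3)
  m1 <- fit_gbr(tab, n_trees = 10, learning_rate = 0.3, seed = 5)
  m2 <- fit_gbr(tab, n_trees = 10, learning_rate = 0.3, seed = 5)
  expect_identical(export_trees(m1), export_trees(m2))
})

test_that("ensemble predictions equal base + rate * sum of traversed leaves", {
  tab <- make_training_table(n_rows = 150, n_features = 4, noise_sd = 0.3, seed = 9)
  m <- fit_gbr(tab, n_trees = 6, learning_rate = 0.2)
  new <- make_training_table(n_rows = 40, n_features = 4, seed = 10)
  expect_equal(predict(m, new), traverse_exported(export_trees(m), new),
    tolerance = 1e-12
  )
})

test_that("a single exact-greedy tree matches an rpart anova tree", {
  tab <- make_training_table(
    n_rows = 300, n_features = 3,
    planted = list(features = c("f1", "f2"), thresholds = c(0.5, 0.5), value = 2),
    noise_sd = 0, seed = 11
  )
  mine <- fit_gbr(tab, n_trees = 1, max_depth = 2, learning_rate = 1)
  rp <- rpart::rpart(label ~ f1 + f2 + f3,
    data = tab, method = "anova",
    control = rpart::rpart.control(
      maxdepth = 2, cp = 0, minsplit = 2,
      minbucket = 1, xval = 0
    )
  )
  expect_equal(predict(mine, tab), unname(predict(rp, tab)), tolerance = 1e-9)
})

test_that("prediction image is finite: at most the product of leaf counts", {
  tab <- make_training_table(n_rows = 300, n_features = 3, noise_sd = 0.5, seed = 13)
  m <- fit_gbr(tab, n_trees = 3, max_depth = 2, learning_rate = 0.5)
  leaves <- vapply(m$trees, function(tr) sum(tr$is_leaf), integer(1))
  probe <- make_training_table(n_rows = 5000, n_features = 3, seed = 14)
  expect_lte(length(unique(predict(m, probe))), prod(leaves))
})

test_that("export/import round-trips predictions and structure", {
  tab <- make_training_table(n_rows = 200, n_features = 6, noise_sd = 0.2, seed = 15)
  m <- fit_gbr(tab, n_trees = 8, learning_rate = 0.25)
  path <- withr::local_tempfile(fileext = ".json")
  export_trees(m, path)
  m2 <- import_trees(path)
  probe <- make_training_table(n_rows = 500, n_features = 6, seed = 16)
  expect_identical(predict(m2, probe), predict(m, probe))
  expect_equal(sum(tidy(m2)$is_leaf), sum(tidy(m)$is_leaf))

  # a depth-1 single tree exports exactly one threshold rule
  stump <- fit_gbr(tab, n_trees = 1, max_depth = 1, learning_rate = 1)
  ex <- jsonlite::fromJSON(export_trees(stump))
  expect_equal(length(ex$trees), 1)
  expect_equal(sum(!ex$trees[[1]]$is_leaf), 1)

  expect_error(import_trees('{"format":"nope"}'), "format")
})

test_that("feature contracts are enforced by name", {
  tab <- make_training_table(n_rows = 100, n_features = 4, noise_sd = 0.1, seed = 17)
  m <- fit_gbr(tab, task = "affinity", n_trees = 2)
  bad <- make_training_table(n_rows = 5, n_features = 2, seed = 18)
  expect_error(predict(m, bad[, c("complex_id", "f1", "label")]), "contract|missing")
  expect_error(predict_affinity(fit_gbr(tab, task = "binder_score", n_trees = 1), tab), "affinity")
  expect_error(score_binder(m, tab), "binder_score")
})

test_that("tidy and glance summarize the ensemble", {
  tab <- make_training_table(n_rows = 100, n_features = 3, noise_sd = 0.1, seed = 19)
  m <- fit_gbr(tab, n_trees = 4)
  td <- tidy(m)
  expect_true(all(c("tree", "node", "is_leaf", "feature", "threshold", "value") %in% names(td)))
  expect_equal(max(td$tree), 4)
  gl <- glance(m)
  expect_equal(gl$n_trees, 4L)
  expect_equal(gl$n_leaves, sum(td$is_leaf))
})

test_that("impurity importance concentrates on planted features", {
  tab <- make_training_table(
    n_rows = 400, n_features = 10,
    planted = list(features = c("f3", "f7"), thresholds = c(0.4, 0.6), value = 3),
    noise_sd = 0.1, seed = 21
  )
  m <- fit_gbr(tab, n_trees = 30, learning_rate = 0.3)
  imp <- gbr_importance(m)
  expect_setequal(imp$feature[1:2], c("f3", "f7"))
  expect_gt(sum(imp$importance[1:2]), 0.9)
})

test_that("ablation keeps planted features and terminates on pure noise", {
  tab <- make_training_table(
    n_rows = 400, n_features = 12,
    planted = list(features = c("f2", "f5", "f9"), thresholds = c(0.5, 0.5, 0.5), value = 2),
    noise_sd = 0.1, seed = 23
  )
  X <- tab[, sprintf("f%d", 1:12)]
  sel <- select_features(X, tab$label, top_k = 8, n_trees = 30, seed = 1)
  expect_true(all(c("f2", "f5", "f9") %in% sel))

  set.seed(31)
  noise_y <- rnorm(400)
  sel0 <- select_features(X, noise_y, top_k = 8, n_trees = 10, seed = 2)
  expect_lte(length(sel0), 8)
  # determinism
  sel_again <- select_features(X, tab$label, top_k = 8, n_trees = 30, seed = 1)
  expect_identical(as.character(sel), as.character(sel_again))
})

test_that("roc_auc orients scores so binders rank high", {
  labels <- rep(c(1, 0), each = 50)
  scores <- c(rnorm(50, 2), rnorm(50, 0))
  expect_gt(roc_auc(labels, scores), 0.8)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(3, 4, 1, 2)), 1)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(1, 2, 3, 4)), 0)
})
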