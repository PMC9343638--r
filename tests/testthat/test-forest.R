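test_that("balanced bagging draws equal class counts in every tree's bag", {
  set.seed(8)
  n <- 800
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n),
                  label = rbinom(n, 1, 0.12))
  m <- train_balanced_forest(d, c("x1", "x2"), "label",
                             forest_config(n_trees = 60L, seed = 1L),
                             keep_inbag = TRUE)
  inbag <- simplify2array(m$fit$inbag.counts)  # n x trees
  c1 <- colSums(inbag[d$label == 1, ])
  c0 <- colSums(inbag[d$label == 0, ])
  expect_equal(mean(c1 / c0), 1, tolerance = 0.05)
  expect_equal(unname(c1), unname(c0))  # exactly equal by construction
  expect_equal(unique(c1), sum(d$label == 1))
})

test_that("the minority bagging rate is one minus the prevalence", {
  expect_equal(1 - 0.102, 0.898)
  set.seed(9)
  d <- data.frame(x = rnorm(1000), label = rbinom(1000, 1, 0.102))
  m <- train_balanced_forest(d, "x", "label",
                             forest_config(n_trees = 11L, seed = 1L))
  expect_equal(m$training_prevalence, mean(d$label))
})

test_that("separable data is fit perfectly and predictions are probabilities", {
  set.seed(10)
  d <- data.frame(x = c(rnorm(300, -3), rnorm(40, 3)),
                  label = rep(c(0, 1), c(300, 40)))
  m <- train_balanced_forest(d, "x", "label",
                             forest_config(n_trees = 51L, seed = 2L))
  p <- predict(m, d)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(auc(d$label, p), 1)
  expect_error(train_balanced_forest(d[d$label == 0, ], "x", "label"),
               "both classes")
})

test_that("predictions are deterministic and invariant to column order", {
  w <- small_world()
  m <- small_model()
  feats <- m$features
  m2 <- train_balanced_forest(w$tab, feats, "label",
                              forest_config(n_trees = 301L, seed = 301L))
  newd <- w$tab[1:200, ]
  expect_identical(predict(m, newd), predict(m2, newd))
  shuffled <- newd[, sample(ncol(newd))]
  expect_identical(predict(m, newd), predict(m, shuffled))
  # classification (vote-fraction) mode is deterministic too
  mc <- train_balanced_forest(w$tab, feats, "label",
                              forest_config(n_trees = 101L, seed = 301L,
                                            tree_type = "classification"))
  expect_identical(predict(mc, newd), predict(mc, newd))
})

test_that("balanced bagging raises sensitivity on imbalanced data", {
  w <- small_world()
  sp <- stratified_split(w$tab, "label", 0.8, seed = 5)
  feats <- c("cov01", "cov02", "cov03")
  sens_of <- function(balanced) {
    cfg <- forest_config(n_trees = 101L, balanced_bagging = balanced, seed = 4L)
    m <- train_balanced_forest(sp$train, feats, "label", cfg)
    confusion_metrics(sp$test$label,
                      predict(m, sp$test, type = "class"))$sensitivity
  }
  expect_gt(sens_of(TRUE), sens_of(FALSE))
})

test_that("node-size tuning picks the best candidate, smallest on ties", {
  w <- small_world()
  cfg <- forest_config(n_trees = 51L, seed = 6L)
  single <- tune_min_node_size(w$tab, c("cov01", "cov02"), "label", cfg,
                               candidates = 3, n_reps = 2)
  expect_identical(single$chosen, 3L)
  tuned <- tune_min_node_size(w$tab, c("cov01", "cov02", "cov03"), "label",
                              cfg, candidates = c(1, 5), n_reps = 2)
  rerun <- tune_min_node_size(w$tab, c("cov01", "cov02", "cov03"), "label",
                              cfg, candidates = c(1, 5), n_reps = 2)
  expect_identical(tuned, rerun)  # reproducible under the config seed
  expect_true(tuned$chosen %in% c(1L, 5L))
})

test_that("RFE removes 20% per iteration with the documented schedule", {
  # schedule oracle: repeatedly remove max(1, floor(0.2 p))
  sched <- function(p) {
    out <- p
    while (p > 1) { p <- p - max(1, floor(0.2 * p)); out <- c(out, p) }
    as.integer(out)
  }
  expect_identical(sched(62)[1:10],
                   c(62L, 50L, 40L, 32L, 26L, 21L, 17L, 14L, 12L, 10L))
  set.seed(12)
  n <- 120
  d <- data.frame(matrix(rnorm(n * 62), n, 62))
  d$label <- rbinom(n, 1, plogis(2 * d$X1))
  tr <- rfe_select(d, paste0("X", 1:62), "label",
                   forest_config(n_trees = 21L, seed = 3L))
  expect_identical(tr$trace$n_features, sched(62))
  expect_true(all(lengths(tr$sets) == tr$trace$n_features))
  expect_true(all(tr$chosen %in% paste0("X", 1:62)))
})

test_that("RFE keeps a single strong driver and drops pure noise", {
  set.seed(21)
  n <- 1500
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  # large effect: exceedance separable on x1 at its 90th percentile
  d$label <- as.integer(d$x1 > quantile(d$x1, 0.9))
  tr <- rfe_select(d, c("x1", "x2"), "label",
                   forest_config(n_trees = 101L, seed = 7L))
  expect_identical(tr$chosen, "x1")
  # chosen set appears in the trace and sets shrink strictly
  expect_true(any(vapply(tr$sets, identical, TRUE, tr$chosen)))
  expect_true(all(diff(tr$trace$n_features) < 0))
  # reproducible under the same seed
  tr2 <- rfe_select(d, c("x1", "x2"), "label",
                    forest_config(n_trees = 101L, seed = 7L))
  expect_identical(tr$trace, tr2$trace)
})

test_that("importance ranks informative covariates above noise", {
  set.seed(22)
  n <- 2000
  d <- data.frame(matrix(rnorm(n * 5), n, 5))
  d$label <- rbinom(n, 1, plogis(-2.5 + 1.5 * d$X1 + 1 * d$X2))
  m <- train_balanced_forest(d, paste0("X", 1:5), "label",
                             forest_config(n_trees = 301L, seed = 8L))
  imp <- feature_importance(m)
  expect_true(all(imp >= 0))
  expect_gt(min(imp[c("X1", "X2")]), max(imp[c("X3", "X4", "X5")]))
  std <- feature_importance(m, standardize = TRUE)
  expect_equal(max(std), 1)
  # single-feature model: standardized score is 1
  m1 <- train_balanced_forest(d, "X1", "label",
                              forest_config(n_trees = 51L, seed = 8L,
                                            features_per_node = 1L))
  expect_equal(unname(feature_importance(m1, standardize = TRUE)), 1)
})

test_that("a duplicated informative feature shares rank, both above noise", {
  set.seed(23)
  n <- 2000
  d <- data.frame(x = rnorm(n), noise = rnorm(n))
  d$x_copy <- d$x
  d$label <- rbinom(n, 1, plogis(-2.2 + 2 * d$x))
  m <- train_balanced_forest(d, c("x", "x_copy", "noise"), "label",
                             forest_config(n_trees = 301L, seed = 9L))
  imp <- feature_importance(m)
  expect_gt(imp[["x"]], imp[["noise"]])
  expect_gt(imp[["x_copy"]], imp[["noise"]])
})
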