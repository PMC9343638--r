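test_that("stratified splits hold the class proportions exactly", {
  d <- data.frame(x = rnorm(100), label = rep(c(1, 0), c(10, 90)))
  sp <- stratified_split(d, "label", 0.8, seed = 1)
  expect_equal(sum(sp$test$label), 2)
  expect_equal(sum(sp$train$label), 8)
  expect_equal(nrow(sp$train) + nrow(sp$test), 100)
  # disjoint and exhaustive
  expect_setequal(c(rownames(sp$train), rownames(sp$test)), rownames(d))
  # same seed -> identical; positive fraction has no binomial spread
  sp2 <- stratified_split(d, "label", 0.8, seed = 1)
  expect_identical(sp, sp2)
  pos_in_test <- vapply(1:50, function(s)
    sum(stratified_split(d, "label", 0.8, seed = s)$test$label), 0)
  expect_true(all(pos_in_test == 2))
  expect_error(stratified_split(data.frame(label = c(0, 0, 1)), "label"),
               "stratify")
})

test_that("confusion metrics match hand arithmetic", {
  perfect <- confusion_metrics(c(0, 1, 0, 1), c(0, 1, 0, 1))
  expect_equal(perfect$balanced_accuracy, 1)
  allneg <- confusion_metrics(c(0, 1, 0, 1), c(0, 0, 0, 0))
  expect_equal(c(allneg$sensitivity, allneg$specificity,
                 allneg$balanced_accuracy), c(0, 1, 0.5))
  # TP=40, FN=10, TN=30, FP=20
  lab <- rep(c(1, 1, 0, 0), c(40, 10, 30, 20))
  prd <- rep(c(1, 0, 0, 1), c(40, 10, 30, 20))
  cm <- confusion_metrics(lab, prd)
  expect_equal(c(cm$sensitivity, cm$specificity, cm$balanced_accuracy),
               c(0.8, 0.6, 0.7))
  onesided <- confusion_metrics(c(1, 1), c(1, 0))
  expect_true(is.na(onesided$specificity))
  expect_match(onesided$flag, "no negatives")
})

test_that("kappa adjusts accuracy by the no-information rate", {
  expect_equal(kappa_from_accuracy(0.82, 0.5), 0.64)
  expect_equal(kappa_from_accuracy(0.7, 0.7), 0)
  expect_equal(kappa_from_accuracy(1, 0.5), 1)
  expect_error(kappa_from_accuracy(0.9, 1))
  # on balanced data kappa = 2 acc - 1 identically
  for (acc in seq(0, 1, 0.1)) {
    expect_equal(kappa_from_accuracy(acc, 0.5), 2 * acc - 1)
  }
})

test_that("balanced kappa averages down-sampled confusion matrices", {
  # already balanced: equals the single-pass kappa
  lab <- rep(c(1, 0), each = 20)
  prd <- c(rep(1, 16), rep(0, 4), rep(0, 18), rep(1, 2))
  acc <- mean(lab == prd)
  expect_equal(balanced_kappa(lab, prd, n_downsamples = 5, seed = 2),
               kappa_from_accuracy(acc, 0.5))
  # perfect predictions give 1 regardless of down-sampling
  lab2 <- rep(c(1, 0), c(7, 70))
  expect_equal(balanced_kappa(lab2, lab2, seed = 3), 1)
  # reproducible under a fixed seed
  set.seed(4)
  lab3 <- rbinom(200, 1, 0.2); prd3 <- ifelse(runif(200) < 0.8, lab3, 1 - lab3)
  expect_identical(balanced_kappa(lab3, prd3, seed = 9),
                   balanced_kappa(lab3, prd3, seed = 9))
})

test_that("AUC matches the brute-force pair oracle and is rank-invariant", {
  expect_equal(auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  # 6-point set with a tie
  lab <- c(1, 0, 1, 0, 1, 0)
  sc <- c(0.9, 0.3, 0.5, 0.5, 0.2, 0.1)
  expect_equal(auc(lab, sc), auc_oracle(lab, sc))
  set.seed(5)
  for (i in 1:10) {
    n <- sample(10:50, 1)
    l <- c(0, 1, rbinom(n - 2, 1, 0.4))
    s <- round(runif(n), 1)  # coarse grid forces ties
    expect_equal(auc(l, s), auc_oracle(l, s))
    expect_equal(auc(l, exp(3 * s)), auc(l, s))  # monotone invariance
  }
  # independent scores: AUC near 1/2
  set.seed(6)
  l <- rbinom(4000, 1, 0.5); s <- runif(4000)
  expect_equal(auc(l, s), 0.5, tolerance = 0.05)
})

test_that("crossover sits at the symmetry point and maps through transforms", {
  set.seed(7)
  n <- 20000
  lab <- rbinom(n, 1, 0.5)
  sc <- ifelse(lab == 1, rnorm(n, 0.65, 0.1), rnorm(n, 0.35, 0.1))
  co <- crossover_cutoff(lab, sc)
  expect_equal(co, 0.5, tolerance = 0.02)
  # equivariance under strictly increasing transforms
  lab2 <- c(1, 1, 1, 0, 0, 0, 1, 0)
  sc2 <- c(0.9, 0.8, 0.4, 0.3, 0.2, 0.45, 0.7, 0.1)
  co2 <- crossover_cutoff(lab2, sc2)
  expect_equal(crossover_cutoff(lab2, sc2^2), co2^2)
  expect_error(crossover_cutoff(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("stratified metrics reduce to global metrics for one stratum", {
  set.seed(8)
  lab <- rbinom(300, 1, 0.3)
  prd <- ifelse(runif(300) < 0.85, lab, 1 - lab)
  sm <- stratified_metrics(lab, prd, rep("all", 300))
  cm <- confusion_metrics(lab, prd)
  expect_equal(sm$balanced_accuracy, cm$balanced_accuracy)
  # labels independent of depth: per-bin balanced accuracy is homogeneous
  depth <- runif(300, 0, 1000)
  sm2 <- stratified_metrics(lab, prd, depth, breaks = c(0, 300, 600, 1000))
  expect_equal(nrow(sm2), 3)
  expect_lt(max(sm2$balanced_accuracy) - min(sm2$balanced_accuracy), 0.25)
  # a stratum lacking one class is flagged
  sm3 <- stratified_metrics(c(1, 1, 0), c(1, 0, 0), c("a", "a", "b"))
  expect_match(sm3$flag[sm3$stratum == "b"], "no positives")
})

test_that("cross-validation report is internally consistent and reproducible", {
  w <- small_world()
  cfg <- forest_config(n_trees = 101L, seed = 11L)
  feats <- c("cov01", "cov02", "cov03")
  cv <- cross_validate(w$tab, feats, "label", cfg, n_repetitions = 3,
                       stratum_col = "depth", stratum_breaks = c(0, 600, Inf))
  # balanced accuracy identity holds exactly per repetition
  expect_equal(cv$per_rep$balanced_accuracy,
               (cv$per_rep$sensitivity + cv$per_rep$specificity) / 2)
  expect_true(all(cv$per_rep$auc >= 0.5 & cv$per_rep$auc <= 1))
  expect_true(all(cv$per_rep$kappa >= -1 & cv$per_rep$kappa <= 1))
  expect_gte(cv$mean["balanced_accuracy"], min(cv$per_rep$balanced_accuracy))
  expect_lte(cv$mean["balanced_accuracy"], max(cv$per_rep$balanced_accuracy))
  expect_s3_class(cv$strata, "data.frame")
  # a single repetition equals the single-split computation
  cv1 <- cross_validate(w$tab, feats, "label", cfg, n_repetitions = 1)
  expect_equal(unname(cv1$mean), unname(unlist(cv1$per_rep[1, -1])))
  # determinism
  cv1b <- cross_validate(w$tab, feats, "label", cfg, n_repetitions = 1)
  expect_identical(cv1$per_rep, cv1b$per_rep)
})
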