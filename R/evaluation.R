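#' Stratified train/test split
#'
#' Random split that holds the exceedance prevalence fixed: the training
#' count per class is `round(train_fraction * n_class)`, so the class
#' proportions of both partitions equal the pooled proportion up to
#' rounding, with no binomial spread across repeated draws.
#'
#' @param data data.frame with a binary label column.
#' @param label_col name of the 0/1 label column.
#' @param train_fraction share of rows assigned to training (default 0.8).
#' @param seed RNG seed for the draw.
#' @return list with disjoint, exhaustive data.frames `train` and `test`.
#' @export
stratified_split <- function(data, label_col = "label", train_fraction = 0.8,
                             seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  y <- data[[label_col]]
  stopifnot(all(y %in% 0:1))
  if (min(table(y)) < 2) stop("each class needs at least 2 rows to stratify")
  with_seed(seed, {
    train_idx <- unlist(lapply(c(0, 1), function(cl) {
      rows <- which(y == cl)
      sample(rows, round(train_fraction * length(rows)))
    }), use.names = FALSE)
  })
  list(train = data[sort(train_idx), , drop = FALSE],
       test = data[-sort(train_idx), , drop = FALSE])
}

#' Confusion-matrix metrics
#'
#' Sensitivity (true-positive rate), specificity (true-negative rate) and
#' balanced accuracy (their mean) from binary labels and predicted classes.
#' A metric whose class is absent from the labels is `NA` and flagged.
#'
#' @param labels 0/1 reference labels.
#' @param predicted 0/1 predicted classes.
#' @return list with `sensitivity`, `specificity`, `balanced_accuracy`,
#'   the raw counts `tp`, `fn`, `tn`, `fp`, and `flag` (character, empty if
#'   both classes present).
#' @export
confusion_metrics <- function(labels, predicted) {
  stopifnot(length(labels) == length(predicted),
            all(labels %in% 0:1), all(predicted %in% 0:1))
  tp <- sum(labels == 1 & predicted == 1)
  fn <- sum(labels == 1 & predicted == 0)
  tn <- sum(labels == 0 & predicted == 0)
  fp <- sum(labels == 0 & predicted == 1)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  flag <- c(if (tp + fn == 0) "no positives in labels",
            if (tn + fp == 0) "no negatives in labels")
  list(sensitivity = sens, specificity = spec,
       balanced_accuracy = mean(c(sens, spec)),
       tp = tp, fn = fn, tn = tn, fp = fp,
       flag = if (is.null(flag)) character(0) else flag)
}

#' Kappa from accuracy and the no-information rate
#'
#' `kappa = (acc - NIR) / (1 - NIR)`: accuracy adjusted for the rate
#' achievable by always predicting the majority class. On a class-balanced
#' test set (NIR = 0.5) this reduces to `2 * acc - 1`.
#'
#' @param acc observed accuracy in \[0, 1\].
#' @param nir no-information rate in \[0, 1).
#' @return kappa in \[-NIR/(1-NIR), 1\].
#' @export
kappa_from_accuracy <- function(acc, nir) {
  stopifnot(acc >= 0, acc <= 1, nir >= 0)
  if (any(nir >= 1)) stop("NIR must be < 1")
  (acc - nir) / (1 - nir)
}

#' Balanced kappa by majority down-sampling
#'
#' To make kappa interpretable under class imbalance, the majority class of
#' the test set is randomly down-sampled to the minority-class size, the
#' accuracy of the predictions on that balanced subset is converted to
#' kappa with NIR = 0.5, and the result is averaged over `n_downsamples`
#' seeded draws.
#'
#' @param labels 0/1 test labels.
#' @param predicted 0/1 predicted classes, aligned with `labels`.
#' @param n_downsamples number of down-sampling repetitions (default 10).
#' @param seed RNG seed for the draws.
#' @return mean kappa (scalar).
#' @export
balanced_kappa <- function(labels, predicted, n_downsamples = 10, seed = 1L) {
  stopifnot(length(labels) == length(predicted), all(labels %in% 0:1))
  idx1 <- which(labels == 1); idx0 <- which(labels == 0)
  if (!length(idx1) || !length(idx0)) stop("both classes must be present")
  minority <- if (length(idx1) <= length(idx0)) idx1 else idx0
  majority <- if (length(idx1) <= length(idx0)) idx0 else idx1
  kappas <- with_seed(seed, {
    vapply(seq_len(n_downsamples), function(i) {
      keep <- c(minority, sample(majority, length(minority)))
      acc <- mean(labels[keep] == predicted[keep])
      kappa_from_accuracy(acc, 0.5)
    }, 0)
  })
  mean(kappas)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with midrank tie correction: the
#' probability that a random exceedance case scores above a random
#' non-exceedance case, ties counting one half.
#'
#' @param labels 0/1 labels (both classes present).
#' @param scores numeric scores or probabilities.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores), all(labels %in% 0:1))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)  # midranks handle ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sensitivity-specificity crossover cutoff
#'
#' The probability threshold at which the model's sensitivity and
#' specificity on held-out data are equal — searched over the unique score
#' values (classifying positive at `score >= t`), minimizing
#' `|sensitivity - specificity|`; exact ties return the midpoint of the
#' tied thresholds. For a forest grown on balanced bootstraps this sits
#' near 0.5.
#'
#' @inheritParams auc
#' @return the crossover threshold (scalar).
#' @export
crossover_cutoff <- function(labels, scores) {
  stopifnot(length(labels) == length(scores), all(labels %in% 0:1))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  thr <- sort(unique(scores))
  gap <- vapply(thr, function(t) {
    pred <- scores >= t
    abs(sum(pred & labels == 1) / n1 - sum(!pred & labels == 0) / n0)
  }, 0)
  tied <- thr[gap <= min(gap) + 1e-12]
  (min(tied) + max(tied)) / 2
}

#' Per-stratum confusion metrics
#'
#' Balanced accuracy (with sensitivity and specificity) of predictions
#' within strata of a covariate such as well depth or region. Numeric
#' strata are cut at `breaks`; strata missing one of the classes are
#' flagged and reported with `NA` metrics.
#'
#' @param labels,predicted 0/1 vectors.
#' @param stratum vector (numeric or factor/character) defining strata.
#' @param breaks cut points for numeric strata (passed to [cut()]);
#'   ignored for non-numeric strata.
#' @return data.frame with one row per stratum: `stratum`, `n`,
#'   `sensitivity`, `specificity`, `balanced_accuracy`, `flag`.
#' @export
stratified_metrics <- function(labels, predicted, stratum, breaks = NULL) {
  stopifnot(length(labels) == length(stratum))
  ok <- !is.na(stratum)
  if (!any(ok)) stop("no stratum values present")
  labels <- labels[ok]; predicted <- predicted[ok]; stratum <- stratum[ok]
  if (is.numeric(stratum) && !is.null(breaks)) {
    stratum <- cut(stratum, breaks = breaks, include.lowest = TRUE)
  }
  lev <- if (is.factor(stratum)) levels(stratum) else sort(unique(stratum))
  rows <- lapply(lev, function(s) {
    in_s <- stratum == s
    if (!any(in_s)) {
      return(data.frame(stratum = s, n = 0L, sensitivity = NA_real_,
                        specificity = NA_real_, balanced_accuracy = NA_real_,
                        flag = "empty stratum"))
    }
    cm <- confusion_metrics(labels[in_s], predicted[in_s])
    data.frame(stratum = s, n = sum(in_s), sensitivity = cm$sensitivity,
               specificity = cm$specificity,
               balanced_accuracy = cm$balanced_accuracy,
               flag = paste(cm$flag, collapse = "; "))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Repeated stratified cross-validation of the balanced forest
#'
#' Monte-Carlo cross-validation: `n_repetitions` random stratified
#' train/test splits (80/20 by default, the exceedance prevalence held
#' fixed in both partitions). Each repetition trains the balanced forest
#' and records sensitivity, specificity and balanced accuracy at the 0.5
#' vote threshold, AUC, and the down-sampled balanced kappa. Metrics are
#' averaged over repetitions; the sensitivity-specificity crossover is
#' located on the pooled held-out predictions.
#'
#' @param data,features,label_col,config as in [train_balanced_forest()].
#' @param n_repetitions number of random splits (default 100).
#' @param train_fraction training share per split (default 0.8).
#' @param n_downsamples down-sampling draws per repetition for the balanced
#'   kappa (default 10).
#' @param stratum_col optional column name (e.g. depth) for per-stratum
#'   diagnostics on the pooled predictions.
#' @param stratum_breaks cut points if `stratum_col` is numeric.
#' @return an object of class `cv_report`: `per_rep` data.frame, `mean` and
#'   `sd` named vectors, `crossover_cutoff`, `pooled` (labels, scores and
#'   repetition ids of all held-out predictions), and optionally `strata`.
#' @export
cross_validate <- function(data, features, label_col = "label",
                           config = forest_config(), n_repetitions = 100,
                           train_fraction = 0.8, n_downsamples = 10,
                           stratum_col = NULL, stratum_breaks = NULL) {
  per <- vector("list", n_repetitions)
  pooled_lab <- list(); pooled_sc <- list(); pooled_strat <- list()
  for (r in seq_len(n_repetitions)) {
    sp <- stratified_split(data, label_col, train_fraction,
                           seed = derive_seed(config$seed, 4000L + r))
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 5000L + r)
    m <- train_balanced_forest(sp$train, features, label_col, cfg)
    prob <- predict(m, sp$test, type = "prob")
    pred <- as.integer(prob > 0.5)
    lab <- sp$test[[label_col]]
    cm <- confusion_metrics(lab, pred)
    per[[r]] <- data.frame(
      repetition = r, sensitivity = cm$sensitivity,
      specificity = cm$specificity,
      balanced_accuracy = cm$balanced_accuracy,
      auc = auc(lab, prob),
      kappa = balanced_kappa(lab, pred, n_downsamples,
                             seed = derive_seed(config$seed, 6000L + r)))
    pooled_lab[[r]] <- lab; pooled_sc[[r]] <- prob
    if (!is.null(stratum_col)) pooled_strat[[r]] <- sp$test[[stratum_col]]
  }
  per_rep <- do.call(rbind, per)
  metrics <- c("sensitivity", "specificity", "balanced_accuracy", "auc", "kappa")
  pooled <- data.frame(label = unlist(pooled_lab), score = unlist(pooled_sc),
                       repetition = rep(seq_len(n_repetitions),
                                        vapply(pooled_lab, length, 0L)))
  out <- list(per_rep = per_rep,
              mean = vapply(per_rep[metrics], mean, 0),
              sd = vapply(per_rep[metrics], stats::sd, 0),
              crossover_cutoff = crossover_cutoff(pooled$label, pooled$score),
              n_repetitions = n_repetitions,
              pooled = pooled)
  if (!is.null(stratum_col)) {
    out$strata <- stratified_metrics(pooled$label,
                                     as.integer(pooled$score > 0.5),
                                     unlist(pooled_strat), stratum_breaks)
  }
  structure(out, class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d repetitions\n", x$n_repetitions))
  m <- rbind(mean = x$mean, sd = x$sd)
  print(round(m, 4))
  cat(sprintf("sensitivity-specificity crossover: %.3f\n", x$crossover_cutoff))
  invisible(x)
}
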