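#' Configuration of the class-balanced random forest
#'
#' Defaults follow common practice for heavily imbalanced exceedance data:
#' 1001 trees, square-root feature subsampling at each node, a tuned minimum
#' node size (1-5), and balanced bagging — each tree is grown on an
#' equal-count stratified bootstrap (the minority-class count drawn, with
#' replacement, from *both* classes), which is equivalent in expectation to
#' bagging preferentially from exceedance cases at a rate of one minus the
#' prevalence.
#'
#' @param n_trees number of trees (default 1001).
#' @param features_per_node candidate features per split; `NULL` (default)
#'   means `floor(sqrt(p))` at fit time.
#' @param min_node_size minimum samples per terminal node; `NULL` (default)
#'   uses 10 for probability trees and 1 for classification trees, and
#'   [tune_min_node_size()] tunes it over 1-5.
#' @param balanced_bagging grow each tree on an equal-count class-stratified
#'   bootstrap (default `TRUE`).
#' @param tree_type `"probability"` (default) averages terminal-leaf class
#'   fractions across trees — the calibrated probability output used for
#'   hazard maps; `"classification"` grows hard-voting trees whose
#'   probability is the fraction of trees voting exceedance. The two
#'   coincide as leaves shrink to a single sample.
#' @param importance `"permutation"` (default; permutation decrease in
#'   out-of-bag accuracy) or `"impurity_corrected"` (bias-corrected Gini
#'   impurity decrease, robust to differing numbers of category levels).
#' @param seed master seed; per-tree streams derive from it.
#' @return an object of class `forest_config`.
#' @export
forest_config <- function(n_trees = 1001L, features_per_node = NULL,
                          min_node_size = NULL, balanced_bagging = TRUE,
                          tree_type = c("probability", "classification"),
                          importance = c("permutation", "impurity_corrected"),
                          seed = 1L) {
  stopifnot(n_trees >= 1, is.null(min_node_size) || min_node_size >= 1)
  importance <- match.arg(importance)
  tree_type <- match.arg(tree_type)
  structure(list(n_trees = as.integer(n_trees),
                 features_per_node = features_per_node,
                 min_node_size = if (is.null(min_node_size)) NULL
                                 else as.integer(min_node_size),
                 balanced_bagging = isTRUE(balanced_bagging),
                 tree_type = tree_type,
                 importance = importance,
                 seed = as.integer(seed)),
            class = "forest_config")
}

as_label_factor <- function(labels) {
  stopifnot(all(labels %in% 0:1))
  factor(labels, levels = c(0, 1))
}

#' Train a class-balanced random forest
#'
#' Classification forest in which, under balanced bagging, every tree's
#' bootstrap contains the two classes in (exactly) equal counts — the
#' minority-class size drawn with replacement from each class — so that the
#' forest's operating point is centred near probability 0.5 despite the
#' class imbalance of the training data. The predicted probability of
#' exceedance is the fraction of trees voting for the exceedance class.
#'
#' @param data data.frame holding the features and the label column.
#' @param features character vector of feature column names (no missing
#'   values allowed in these columns).
#' @param label_col name of the 0/1 exceedance label column.
#' @param config a [forest_config()].
#' @param keep_inbag retain per-tree in-bag counts (for auditing the
#'   balanced bootstrap; memory-heavy on large data).
#' @return an object of class `balanced_forest` with elements `fit` (the
#'   underlying ranger ensemble), `features`, `config`, `importance`
#'   (raw scores), `training_prevalence`, `oob` (out-of-bag balanced error
#'   and its binomial SD).
#' @export
train_balanced_forest <- function(data, features, label_col = "label",
                                  config = forest_config(),
                                  keep_inbag = FALSE) {
  stopifnot(is.data.frame(data), all(features %in% names(data)),
            label_col %in% names(data))
  x <- data[, features, drop = FALSE]
  if (anyNA(x)) stop("missing values in feature columns")
  y <- as_label_factor(data[[label_col]])
  n <- length(y)
  counts <- table(y)
  if (any(counts == 0)) stop("both classes must be present for training")
  mtry <- config$features_per_node
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(length(features))))
  if (config$balanced_bagging) {
    n_min <- min(counts)
    sample_fraction <- rep(n_min / n, 2)
  } else {
    sample_fraction <- 1
  }
  probability <- config$tree_type == "probability"
  min_node <- config$min_node_size
  if (is.null(min_node)) min_node <- if (probability) 10L else 1L
  df <- cbind(x, .label = y)
  fit <- ranger::ranger(
    dependent.variable.name = ".label", data = df,
    num.trees = config$n_trees, mtry = mtry,
    min.node.size = min_node, probability = probability,
    replace = TRUE, sample.fraction = sample_fraction,
    importance = config$importance, keep.inbag = keep_inbag,
    seed = config$seed, num.threads = 1)
  oob <- oob_balanced_error(fit$predictions, y)
  structure(list(fit = fit, features = features, config = config,
                 importance = fit$variable.importance,
                 training_prevalence = unname(counts["1"] / n),
                 oob = oob),
            class = "balanced_forest")
}

# balanced error (1 - balanced accuracy) of out-of-bag predictions (class
# factor or probability matrix), with a binomial-approximation SD
oob_balanced_error <- function(pred, y) {
  if (is.matrix(pred)) {
    cls <- rep(NA_integer_, nrow(pred))
    ok <- !is.na(pred[, "1"])
    cls[ok] <- as.integer(pred[ok, "1"] > 0.5)
  } else {
    ok <- !is.na(pred)
    cls <- as.integer(as.character(pred))
  }
  cm <- confusion_metrics(as.integer(as.character(y[ok])), cls[ok])
  e <- 1 - cm$balanced_accuracy
  list(error = e, sd = sqrt(e * (1 - e) / sum(ok)))
}

#' Predict exceedance probabilities or classes
#'
#' The probability of exceedance is the mean terminal-leaf exceedance
#' fraction across trees (probability forests) or the fraction of trees
#' voting exceedance (classification forests).
#'
#' @param object a `balanced_forest`.
#' @param data data.frame containing the model's feature columns.
#' @param type `"prob"` or `"class"` (probability thresholded at `cutoff`).
#' @param cutoff classification threshold for `type = "class"`.
#' @param chunk_size rows evaluated per block, to bound the n-by-trees vote
#'   matrix in memory.
#' @param ... unused.
#' @return numeric probability vector, or integer 0/1 vector.
#' @export
predict.balanced_forest <- function(object, data, type = c("prob", "class"),
                                    cutoff = 0.5, chunk_size = 50000L, ...) {
  type <- match.arg(type)
  x <- data[, object$features, drop = FALSE]
  if (anyNA(x)) stop("missing values in feature columns")
  n <- nrow(x)
  prob <- numeric(n)
  probability <- object$config$tree_type == "probability"
  starts <- seq(1L, n, by = chunk_size)
  for (s in starts) {
    idx <- s:min(s + chunk_size - 1L, n)
    if (probability) {
      prob[idx] <- stats::predict(object$fit, x[idx, , drop = FALSE],
                                  num.threads = 1)$predictions[, "1"]
    } else {
      votes <- stats::predict(object$fit, x[idx, , drop = FALSE],
                              predict.all = TRUE, num.threads = 1)$predictions
      prob[idx] <- rowMeans(votes == 2L)  # level 2 of c("0","1") = exceedance
    }
  }
  if (type == "prob") prob else as.integer(prob > cutoff)
}

#' Feature importance of a fitted forest
#'
#' Scores come from the estimator named in the model's configuration
#' (permutation decrease in out-of-bag accuracy by default, bias-corrected
#' impurity decrease as the alternative), floored at zero — a feature whose
#' permutation makes the forest *better* carries no usable signal.
#'
#' @param model a `balanced_forest`.
#' @param standardize divide by the maximum score (as in relative-importance
#'   bar charts).
#' @return named numeric vector over the model's features.
#' @export
feature_importance <- function(model, standardize = FALSE) {
  stopifnot(inherits(model, "balanced_forest"))
  imp <- pmax(model$importance, 0)
  if (standardize) {
    m <- max(imp)
    if (m > 0) imp <- imp / m
  }
  imp[model$features]
}

#' Tune the minimum node size by cross-validated balanced accuracy
#'
#' Evaluates each candidate node size with repeated stratified 80/20 splits
#' and returns the candidate with the highest mean balanced accuracy, ties
#' going to the smallest candidate.
#'
#' @param data,features,label_col as in [train_balanced_forest()].
#' @param config a [forest_config()]; its `min_node_size` is overridden per
#'   candidate.
#' @param candidates node sizes to try (default 1:5).
#' @param n_reps stratified splits per candidate.
#' @param train_fraction training share of each split.
#' @return list with `chosen` (the selected size) and `results` (data.frame
#'   of candidate and mean balanced accuracy).
#' @export
tune_min_node_size <- function(data, features, label_col = "label",
                               config = forest_config(), candidates = 1:5,
                               n_reps = 5, train_fraction = 0.8) {
  stopifnot(length(candidates) >= 1)
  candidates <- sort(unique(as.integer(candidates)))
  score <- numeric(length(candidates))
  for (j in seq_along(candidates)) {
    cfg <- config
    cfg$min_node_size <- candidates[j]
    accs <- numeric(n_reps)
    for (r in seq_len(n_reps)) {
      sp <- stratified_split(data, label_col, train_fraction,
                             seed = derive_seed(config$seed, 1000L + r))
      cfg$seed <- derive_seed(config$seed, 2000L + r)
      m <- train_balanced_forest(sp$train, features, label_col, cfg)
      pred <- predict(m, sp$test, type = "class")
      accs[r] <- confusion_metrics(sp$test[[label_col]], pred)$balanced_accuracy
    }
    score[j] <- mean(accs)
  }
  best <- max(score)
  chosen <- candidates[which(score >= best - 1e-12)][1]  # ties -> smallest
  list(chosen = chosen,
       results = data.frame(min_node_size = candidates,
                            balanced_accuracy = score))
}

#' Recursive feature elimination with the one-standard-deviation rule
#'
#' Iteratively fits the balanced forest, records the out-of-bag balanced
#' error (with a binomial-approximation SD), and removes the 20% (rounded
#' down, at least one) least-important features — importances re-ranked at
#' every iteration — until a single feature remains. The chosen set is the
#' *smallest* set whose error is within one SD of the minimum error over
#' all iterations.
#'
#' @param data,features,label_col,config as in [train_balanced_forest()].
#' @param drop_fraction fraction of features removed per iteration.
#' @return an object of class `rfe_trace`: list with `trace` (data.frame of
#'   `n_features`, `error`, `error_sd`, `features` as a `;`-joined string),
#'   `sets` (list of feature sets per iteration) and `chosen` (character
#'   vector).
#' @export
rfe_select <- function(data, features, label_col = "label",
                       config = forest_config(), drop_fraction = 0.2) {
  stopifnot(length(features) >= 2, drop_fraction > 0, drop_fraction < 1)
  current <- features
  sets <- list(); err <- c(); sdv <- c()
  it <- 0L
  while (TRUE) {
    it <- it + 1L
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 3000L + it)
    m <- train_balanced_forest(data, current, label_col, cfg)
    sets[[it]] <- current
    err[it] <- m$oob$error
    sdv[it] <- m$oob$sd
    if (length(current) == 1L) break
    n_drop <- max(1L, floor(drop_fraction * length(current)))
    imp <- feature_importance(m)
    keep <- names(sort(imp, decreasing = TRUE))[seq_len(length(current) - n_drop)]
    current <- current[current %in% keep]  # preserve original order
  }
  i_min <- which.min(err)
  ok <- which(err <= err[i_min] + sdv[i_min])
  chosen_i <- ok[which.min(lengths(sets)[ok])]
  structure(list(
    trace = data.frame(n_features = lengths(sets), error = err,
                       error_sd = sdv,
                       features = vapply(sets, paste, "", collapse = ";")),
    sets = sets, chosen = sets[[chosen_i]]),
    class = "rfe_trace")
}

#' @export
print.rfe_trace <- function(x, ...) {
  cat("<rfe_trace>\n")
  print(x$trace[, c("n_features", "error", "error_sd")], row.names = FALSE)
  cat("chosen:", paste(x$chosen, collapse = ", "), "\n")
  invisible(x)
}
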