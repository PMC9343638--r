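# Shared fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, make) {
  if (!exists(key, .fixture_cache)) assign(key, make(), .fixture_cache)
  get(key, .fixture_cache)
}

# Compact strong-signal scenario: fast to generate, separable enough for
# model-behaviour tests.
small_scenario <- function(seed = 301L) {
  synthetic_scenario(seed = seed, grid_shape = c(60L, 60L),
                     n_covariates = 8L, informative_indices = 1:3,
                     n_wells = 1200L, smoothness = 6, n_countries = 4L)
}

small_world <- function(seed = 301L) {
  memo(paste0("world", seed), function() {
    sc <- small_scenario(seed)
    stack <- gen_covariate_rasters(sc)
    truth <- gen_truth_surface(stack, sc)
    raw <- gen_measurements(truth, sc)
    wells <- dedupe_wells(raw)
    wells$label <- binarize(wells$concentration)
    tab <- extract_covariates(wells, stack)
    pop <- gen_population_and_usage(sc)
    list(scenario = sc, stack = stack, truth = truth, raw = raw,
         wells = wells, tab = tab, pop = pop)
  })
}

small_model <- function(seed = 301L) {
  memo(paste0("model", seed), function() {
    w <- small_world(seed)
    train_balanced_forest(w$tab, names(w$stack$bands), "label",
                          forest_config(n_trees = 301L, seed = seed))
  })
}

# The full-size study conditions used by the acceptance suite: 200 x 200
# grid, 12 covariates with 3 informative, 5000 wells at ~10% prevalence,
# 301 trees, 20 stratified 80/20 repetitions.
acceptance_conditions <- function(seed = 1L) {
  memo(paste0("acc", seed), function() {
    sc <- synthetic_scenario(seed = seed)
    stack <- gen_covariate_rasters(sc)
    truth <- gen_truth_surface(stack, sc)
    raw <- gen_measurements(truth, sc)
    wells <- dedupe_wells(raw)
    wells$label <- binarize(wells$concentration)
    tab <- extract_covariates(wells, stack)
    cfg <- forest_config(n_trees = 301L, seed = seed + 1L)
    rfe <- rfe_select(tab, names(stack$bands), "label", cfg)
    cv <- cross_validate(tab, rfe$chosen, "label", cfg, n_repetitions = 20)
    list(scenario = sc, stack = stack, truth = truth, tab = tab,
         cfg = cfg, rfe = rfe, cv = cv)
  })
}

# O(k^2) Kendall tau-b oracle by pair enumeration.
kendall_oracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
    if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
    else if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) conc <- conc + 1
    else disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# O(n^2) AUC oracle: pair enumeration with half-credit for ties.
auc_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}
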