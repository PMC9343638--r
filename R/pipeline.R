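#' Default end-to-end run configuration
#'
#' A compact synthetic configuration that exercises every stage in seconds:
#' a 60 x 60 grid with 8 covariates (3 informative), 1200 wells at ~10%
#' exceedance prevalence, a 151-tree balanced forest, 5 cross-validation
#' repetitions, and the standard estimator cutoffs. Any field can be
#' overridden before [run_pipeline()]; configurations can also be stored as
#' YAML and loaded with [read_run_config()].
#'
#' @param seed master seed for every stochastic stage.
#' @return nested configuration list.
#' @export
default_run_config <- function(seed = 1L) {
  list(seed = as.integer(seed),
       scenario = list(grid_shape = c(60L, 60L), n_covariates = 8L,
                       informative_indices = 1:3,
                       effect_sizes = c(4, -3, 2),
                       target_prevalence = 0.102, smoothness = 6,
                       n_wells = 1200L, duplicate_rate = 0.1,
                       n_countries = 4L),
       threshold = 1.5,
       forest = list(n_trees = 151L, balanced_bagging = TRUE),
       rfe = list(enabled = TRUE, drop_fraction = 0.2),
       tune = list(enabled = FALSE, candidates = 1:5, n_reps = 3),
       cv = list(n_repetitions = 5L, train_fraction = 0.8,
                 n_downsamples = 10L),
       cutoffs = list(low = 0.5, hybrid = 0.25),
       association = list(parameters = c("ec", "ca")))
}

#' Read a run configuration from YAML
#' @param path YAML file with the fields of [default_run_config()] (missing
#'   fields fall back to the defaults).
#' @return configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(default_run_config(cfg$seed %||% 1L), cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_error <- function(stage, parent) {
  stop(structure(class = c("fluorisk_stage_error", "error", "condition"),
                 list(message = sprintf("stage '%s' failed: %s", stage,
                                        conditionMessage(parent)),
                      call = NULL, stage = stage)))
}

run_stage <- function(stage, manifest_env, out_files, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) stage_error(stage, e))
  manifest_env$stages[[stage]] <- list(
    artifacts = out_files,
    md5 = unname(tools::md5sum(out_files)),
    seconds = round(proc.time()[["elapsed"]] - t0, 3))
  res
}

#' Run the full synthetic pipeline
#'
#' Chains simulate, ingest, associate, fit (RFE, optional node-size tuning,
#' final forest), evaluate, map and risk, writing one artifact set per
#' stage under `out_dir` plus a JSON manifest of artifact hashes, stage
#' timings and the seed. Deterministic: rerunning with the same
#' configuration reproduces every artifact. A failure in any stage raises a
#' `fluorisk_stage_error` naming the stage.
#'
#' @param config configuration list from [default_run_config()] or
#'   [read_run_config()], or a path to a YAML file.
#' @param out_dir output directory (created if needed).
#' @return the manifest (invisibly also written to `manifest.json`),
#'   with the in-memory stage results attached as attribute `"results"`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = tempfile("run_")) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)
  env <- new.env(); env$stages <- list()

  sim <- run_stage("simulate", env,
                   c(pth("measurements.csv"), pth("truth.asc"), pth("usage.csv")), {
    sc <- do.call(synthetic_scenario, c(list(seed = config$seed), config$scenario))
    stack <- gen_covariate_rasters(sc)
    truth <- gen_truth_surface(stack, sc)
    raw <- gen_measurements(truth, sc)
    pop <- gen_population_and_usage(sc)
    utils::write.csv(raw, pth("measurements.csv"), row.names = FALSE)
    write_ascii_grid(truth, pth("truth.asc"))
    utils::write.csv(pop$usage, pth("usage.csv"), row.names = FALSE)
    list(scenario = sc, stack = stack, truth = truth, raw = raw, pop = pop)
  })

  ing <- run_stage("ingest", env, pth("table.csv"), {
    wells <- dedupe_wells(sim$raw)
    wells$label <- binarize(wells$concentration, config$threshold)
    tab <- extract_covariates(wells, sim$stack)
    utils::write.csv(tab, pth("table.csv"), row.names = FALSE)
    tab
  })

  assoc <- run_stage("associate", env, pth("association.csv"), {
    params <- intersect(config$association$parameters, names(ing))
    res <- lapply(params, function(pm)
      binned_association(ing[[pm]], ing$label, name = pm))
    summ <- data.frame(parameter = params,
                       n = vapply(res, `[[`, 0L, "n"),
                       k = vapply(res, `[[`, 0L, "k"),
                       tau = vapply(res, `[[`, 0, "tau"),
                       p_value = vapply(res, `[[`, 0, "p_value"))
    utils::write.csv(summ, pth("association.csv"), row.names = FALSE)
    res
  })

  fit <- run_stage("fit", env, c(pth("rfe_trace.csv"), pth("importance.csv")), {
    feats <- names(sim$stack$bands)
    cfg <- forest_config(n_trees = config$forest$n_trees,
                         min_node_size = config$forest$min_node_size,
                         balanced_bagging = config$forest$balanced_bagging,
                         seed = derive_seed(config$seed, 8001L))
    trace <- NULL
    if (isTRUE(config$rfe$enabled)) {
      trace <- rfe_select(ing, feats, "label", cfg,
                          drop_fraction = config$rfe$drop_fraction)
      feats <- trace$chosen
      utils::write.csv(trace$trace, pth("rfe_trace.csv"), row.names = FALSE)
    } else {
      utils::write.csv(data.frame(), pth("rfe_trace.csv"), row.names = FALSE)
    }
    if (isTRUE(config$tune$enabled)) {
      tuned <- tune_min_node_size(ing, feats, "label", cfg,
                                  candidates = config$tune$candidates,
                                  n_reps = config$tune$n_reps)
      cfg$min_node_size <- tuned$chosen
    }
    model <- train_balanced_forest(ing, feats, "label", cfg)
    imp <- feature_importance(model, standardize = TRUE)
    utils::write.csv(data.frame(feature = names(imp), importance = imp),
                     pth("importance.csv"), row.names = FALSE)
    list(model = model, trace = trace, config = cfg)
  })

  ev <- run_stage("evaluate", env, pth("cv_report.json"), {
    rep <- cross_validate(ing, fit$model$features, "label", fit$config,
                          n_repetitions = config$cv$n_repetitions,
                          train_fraction = config$cv$train_fraction,
                          n_downsamples = config$cv$n_downsamples,
                          stratum_col = "depth",
                          stratum_breaks = c(0, 200, 600, Inf))
    jsonlite::write_json(
      list(mean = as.list(rep$mean), sd = as.list(rep$sd),
           crossover_cutoff = rep$crossover_cutoff,
           n_repetitions = rep$n_repetitions),
      pth("cv_report.json"), auto_unbox = TRUE, digits = NA)
    rep
  })

  hz <- run_stage("map", env, pth("hazard.asc"), {
    map <- predict_map(fit$model, sim$stack)
    write_ascii_grid(map, pth("hazard.asc"))
    map
  })

  risk <- run_stage("risk", env, c(pth("exposure_countries.csv"),
                                   pth("exposure_totals.json")), {
    consuming <- groundwater_population(sim$pop$rural, sim$pop$urban,
                                        sim$pop$usage, sim$pop$countries)
    hi <- exposed_high(consuming, hz)
    lo <- exposed_low(consuming, hz, cutoff = config$cutoffs$low)
    hy <- exposed_hybrid(consuming, hz, cutoff = config$cutoffs$hybrid)
    agg <- aggregate_exposure(hi, lo, hy, sim$pop$countries,
                              sim$pop$continents,
                              population = gw_raster(
                                sim$pop$rural$values + sim$pop$urban$values,
                                cellsize = sim$pop$rural$cellsize))
    utils::write.csv(agg$country_table, pth("exposure_countries.csv"),
                     row.names = FALSE)
    jsonlite::write_json(as.list(agg$totals), pth("exposure_totals.json"),
                         auto_unbox = TRUE, digits = NA)
    list(high = hi, low = lo, hybrid = hy, aggregate = agg)
  })

  manifest <- list(seed = config$seed,
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   stages = env$stages)
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  attr(manifest, "results") <- list(simulate = sim, ingest = ing,
                                    associate = assoc, fit = fit,
                                    evaluate = ev, map = hz, risk = risk)
  manifest
}
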