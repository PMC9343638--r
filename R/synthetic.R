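#' Synthetic study scenario
#'
#' Bundles every knob of the synthetic-data generator: a planar covariate
#' grid, a sparse logistic ground-truth exceedance process with a target
#' prevalence of about 10% (the share of fluoride measurements above
#' 1.5 mg/L in large compilations), well sampling with duplicate
#' measurements, and a clustered population split across countries.
#'
#' @param seed master seed; every stochastic step derives its own stream
#'   from it deterministically.
#' @param grid_shape integer `(rows, cols)` of the fine grid.
#' @param cell_size planar cell side length (abstract map units).
#' @param n_covariates number of covariate bands; the last band is a binary
#'   categorical layer (a lithology-style indicator), the rest continuous.
#' @param informative_indices which covariates truly drive exceedance.
#' @param effect_sizes logit-scale coefficients for the informative
#'   covariates (same length and order as `informative_indices`).
#' @param intercept logit-scale intercept; `NULL` (default) calibrates it by
#'   bisection so the spatial mean exceedance probability equals
#'   `target_prevalence`.
#' @param target_prevalence spatial mean exceedance probability used when
#'   `intercept` is `NULL`.
#' @param smoothness correlation length of the random fields, in cells of
#'   the band's own grid (scalar or one value per covariate); 0 means white
#'   noise.
#' @param coarse_factor integer cell-size multiple for the coarse bands
#'   (even-numbered continuous bands are stored coarse, emulating mixed
#'   1 km / 250 m predictor resolutions).
#' @param n_wells number of distinct wells sampled.
#' @param duplicate_rate fraction of wells that carry 2-3 replicate
#'   measurements.
#' @param n_countries number of countries tiling the grid as meridional
#'   strips.
#' @param continent_assignment named character vector mapping country id
#'   (as character) to continent label; `NULL` splits countries evenly over
#'   two continents.
#' @return an object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(seed = 1L,
                               grid_shape = c(200L, 200L),
                               cell_size = 1,
                               n_covariates = 12L,
                               informative_indices = 1:3,
                               effect_sizes = c(4, -3, 2),
                               intercept = NULL,
                               target_prevalence = 0.102,
                               smoothness = 10,
                               coarse_factor = 4L,
                               n_wells = 5000L,
                               duplicate_rate = 0.1,
                               n_countries = 4L,
                               continent_assignment = NULL) {
  stopifnot(length(grid_shape) == 2, all(grid_shape >= 1),
            n_covariates >= 1, n_wells >= 1, n_countries >= 1,
            duplicate_rate >= 0, duplicate_rate <= 1,
            length(informative_indices) == length(effect_sizes),
            all(informative_indices >= 1),
            all(informative_indices <= n_covariates),
            coarse_factor >= 1)
  smoothness <- rep_len(smoothness, n_covariates)
  if (any(smoothness < 0)) stop("smoothness must be >= 0")
  beta <- numeric(n_covariates)
  beta[informative_indices] <- effect_sizes
  if (is.null(continent_assignment)) {
    half <- ceiling(n_countries / 2)
    continent_assignment <- stats::setNames(
      rep(c("continent_A", "continent_B"),
          c(half, n_countries - half))[seq_len(n_countries)],
      as.character(seq_len(n_countries)))
  }
  structure(list(seed = as.integer(seed),
                 grid_shape = as.integer(grid_shape),
                 cell_size = cell_size,
                 n_covariates = as.integer(n_covariates),
                 informative_indices = as.integer(informative_indices),
                 true_coefficients = beta,
                 intercept = intercept,
                 target_prevalence = target_prevalence,
                 smoothness = smoothness,
                 coarse_factor = as.integer(coarse_factor),
                 n_wells = as.integer(n_wells),
                 duplicate_rate = duplicate_rate,
                 n_countries = as.integer(n_countries),
                 continent_assignment = continent_assignment),
            class = "synthetic_scenario")
}

# deterministic sub-stream seeds, kept well below 2^31
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) %% 65521) * 9973 + k * 101 + 17)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Gaussian random field: white noise convolved with a truncated Gaussian
# kernel (correlation length = kernel SD, in cells), then standardized to
# zero mean / unit variance over the grid. Separable convolution with
# edge renormalization via row-stochastic band operators.
gaussian_field <- function(nr, nc, sd_cells) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (sd_cells > 0) {
    z <- smooth_operator(nr, sd_cells) %*% z %*% t(smooth_operator(nc, sd_cells))
  }
  (z - mean(z)) / stats::sd(as.vector(z))
}

smooth_operator <- function(n, sd_cells) {
  r <- ceiling(3 * sd_cells)
  K <- outer(seq_len(n), seq_len(n),
             function(i, j) ifelse(abs(i - j) <= r,
                                   stats::dnorm(j - i, sd = sd_cells), 0))
  K / rowSums(K)
}

#' Generate the synthetic covariate stack
#'
#' Continuous bands are spatially autocorrelated Gaussian random fields
#' standardized to zero mean and unit variance; even-numbered continuous
#' bands are stored at a coarser (integer-multiple) cell size to exercise
#' resolution harmonization. The last band is a binary categorical layer
#' obtained by thresholding a smooth field at its 80th percentile (a
#' lithology-style indicator such as acidic igneous rock).
#'
#' @param scenario a [synthetic_scenario()].
#' @return a [covariate_stack()].
#' @export
gen_covariate_rasters <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  nr <- scenario$grid_shape[1]; nc <- scenario$grid_shape[2]
  cs <- scenario$cell_size
  f <- scenario$coarse_factor
  p <- scenario$n_covariates
  bands <- vector("list", p)
  kind <- character(p)
  names(bands) <- band_names(p)
  for (i in seq_len(p)) {
    categorical <- (i == p && p > 1)
    coarse <- !categorical && i %% 2 == 0 && f > 1 &&
      nr %% f == 0 && nc %% f == 0
    bnr <- if (coarse) nr %/% f else nr
    bnc <- if (coarse) nc %/% f else nc
    bcs <- if (coarse) cs * f else cs
    sm <- scenario$smoothness[i] / if (coarse) f else 1
    field <- with_seed(derive_seed(scenario$seed, i),
                       gaussian_field(bnr, bnc, sm))
    if (categorical) {
      field <- (field > stats::quantile(field, 0.8)) * 1
      kind[i] <- "categorical"
    } else {
      kind[i] <- "continuous"
    }
    bands[[i]] <- gw_raster(field, xmin = 0, ymin = 0, cellsize = bcs)
  }
  covariate_stack(bands, kind)
}

band_names <- function(p) {
  nm <- sprintf("cov%02d", seq_len(p))
  if (p > 1) nm[p] <- "acidic_rock"
  nm
}

#' Calibrate the logistic intercept to a target mean probability
#'
#' Bisection on the intercept so that the spatial mean of
#' `plogis(intercept + eta)` equals `target` (monotone in the intercept, so
#' bisection is exact to tolerance).
#'
#' @param eta matrix of logit-scale linear-predictor values (no intercept).
#' @param target desired spatial mean probability in (0, 1).
#' @param tol tolerance on the achieved mean probability.
#' @return the calibrated intercept (scalar).
#' @export
calibrate_intercept <- function(eta, target, tol = 1e-6) {
  stopifnot(target > 0, target < 1)
  lo <- -40; hi <- 40
  repeat {
    mid <- (lo + hi) / 2
    m <- mean(stats::plogis(mid + eta))
    if (abs(m - target) < tol || hi - lo < 1e-12) return(mid)
    if (m < target) lo <- mid else hi <- mid
  }
}

#' Ground-truth exceedance probability surface
#'
#' Cellwise `p = plogis(intercept + sum(beta_i * cov_i))` on the harmonized
#' (finest-resolution) grid. When the scenario's intercept is `NULL` it is
#' calibrated by bisection so the spatial mean probability equals the
#' scenario's target prevalence; the value used is attached as attribute
#' `"intercept"`.
#'
#' @param stack the covariate stack from [gen_covariate_rasters()].
#' @param scenario the matching [synthetic_scenario()].
#' @return a `gw_raster` of probabilities, aligned to the finest grid.
#' @export
gen_truth_surface <- function(stack, scenario) {
  stopifnot(inherits(stack, "covariate_stack"),
            inherits(scenario, "synthetic_scenario"))
  if (length(stack$bands) != scenario$n_covariates)
    stop("coefficient vector length must equal the number of bands")
  hs <- harmonize_stack(stack)
  g <- hs$bands[[which.min(stack_cellsizes(hs))]]
  eta <- matrix(0, nrow(g$values), ncol(g$values))
  beta <- scenario$true_coefficients
  for (i in seq_along(hs$bands)) {
    if (beta[i] != 0) eta <- eta + beta[i] * hs$bands[[i]]$values
  }
  b0 <- scenario$intercept
  if (is.null(b0)) b0 <- calibrate_intercept(eta, scenario$target_prevalence)
  p <- stats::plogis(b0 + eta)
  out <- gw_raster(p, xmin = g$xmin, ymin = g$ymin, cellsize = g$cellsize)
  attr(out, "intercept") <- b0
  out
}

# truncated-lognormal draws: resample until within (lo, hi]
rlnorm_trunc <- function(n, meanlog, sdlog, lo = -Inf, hi = Inf) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    x <- stats::rlnorm(length(todo), meanlog, sdlog)
    ok <- x > lo & x <= hi
    out[todo[ok]] <- x[ok]
    todo <- todo[!ok]
  }
  out
}

#' Sample synthetic well measurements from a truth surface
#'
#' Wells are placed at uniformly random cells; the exceedance label is
#' Bernoulli in the cell's true probability. Concentrations are drawn
#' consistently with the label: lognormal(log 0.3, 0.8) truncated at
#' <= 1.5 mg/L for negatives, 1.5 + lognormal(log 0.8, 0.8) for positives
#' (pooled median near 0.3 mg/L). A `duplicate_rate` fraction of wells
#' receive 2-3 replicate rows with multiplicatively jittered concentrations
#' clamped to the same side of 1.5. Depths follow a lognormal(log 70, 1.4)
#' truncated to 0-600 m for 83% of wells and Uniform(600, 3000) m
#' otherwise, with 10% missing. Two in-situ hydrochemistry columns are
#' attached: `ec` increases monotonically with the exceedance logit and
#' `ca` is V-shaped against it.
#'
#' @param truth the probability raster from [gen_truth_surface()].
#' @param scenario the matching [synthetic_scenario()].
#' @return data.frame with columns `well_id`, `lon`, `lat`,
#'   `concentration`, `depth`, `ec`, `ca` (one row per measurement;
#'   duplicates share `well_id` and coordinates). The per-well truth
#'   (sampled probability and label) is attached as attribute `"truth"`.
#' @export
gen_measurements <- function(truth, scenario) {
  stopifnot(inherits(truth, "gw_raster"),
            inherits(scenario, "synthetic_scenario"),
            scenario$n_wells >= 1)
  n <- scenario$n_wells
  with_seed(derive_seed(scenario$seed, 51L), {
    nr <- nrow(truth$values); nc <- ncol(truth$values)
    row <- sample.int(nr, n, replace = TRUE)
    col <- sample.int(nc, n, replace = TRUE)
    p <- truth$values[cbind(row, col)]
    label <- stats::rbinom(n, 1, p)
    lon <- truth$xmin + (col - 0.5) * truth$cellsize
    lat <- truth$ymin + (nr - row + 0.5) * truth$cellsize
    conc <- numeric(n)
    neg <- label == 0
    conc[neg] <- rlnorm_trunc(sum(neg), log(0.3), 0.8, hi = 1.5)
    conc[!neg] <- 1.5 + stats::rlnorm(sum(!neg), log(0.8), 0.8)
    shallow <- stats::runif(n) < 0.83
    depth <- numeric(n)
    depth[shallow] <- rlnorm_trunc(sum(shallow), log(70), 1.4, hi = 600)
    depth[!shallow] <- stats::runif(sum(!shallow), 600, 3000)
    depth[stats::runif(n) < 0.10] <- NA_real_
    eta <- stats::qlogis(pmin(pmax(p, 1e-12), 1 - 1e-12))
    ec <- 800 * exp(0.5 * eta + stats::rnorm(n, 0, 0.4))
    arm <- sample(c(-1, 1), n, replace = TRUE)
    ca <- 80 + arm * (eta - min(eta)) * 30 * exp(stats::rnorm(n, 0, 0.2))
    ca <- pmax(ca, 0.5)
    well_id <- sprintf("w%06d", seq_len(n))
    tab <- data.frame(well_id = well_id, lon = lon, lat = lat,
                      concentration = conc, depth = depth,
                      ec = ec, ca = ca, stringsAsFactors = FALSE)
    n_dup <- round(scenario$duplicate_rate * n)
    if (n_dup > 0) {
      which_dup <- sample.int(n, n_dup)
      reps <- sample(1:2, n_dup, replace = TRUE)  # 1-2 extra rows => 2-3 total
      extra <- tab[rep(which_dup, reps), , drop = FALSE]
      jit <- extra$concentration * exp(stats::rnorm(nrow(extra), 0, 0.05))
      lab_extra <- rep(label[which_dup], reps)
      jit[lab_extra == 0] <- pmin(jit[lab_extra == 0], 1.5)
      jit[lab_extra == 1] <- pmax(jit[lab_extra == 1], 1.5 + 1e-9)
      extra$concentration <- jit
      tab <- rbind(tab, extra)
      tab <- tab[order(tab$well_id), , drop = FALSE]
      rownames(tab) <- NULL
    }
    attr(tab, "truth") <- data.frame(well_id = well_id, p = p,
                                     label = label,
                                     stringsAsFactors = FALSE)
    tab
  })
}

#' Generate clustered population rasters and groundwater-usage rates
#'
#' Countries tile the grid as meridional strips. Rural population is a
#' log-Gaussian field; urban population is a sum of sharp Gaussian
#' settlement bumps. Usage rates (fraction of domestic water from untreated
#' groundwater) are drawn per country: rural in \[0.3, 0.9\], urban in
#' \[0.1, 0.6\].
#'
#' @param scenario a [synthetic_scenario()].
#' @return list with elements `rural`, `urban` (population `gw_raster`s),
#'   `countries` (`gw_raster` of integer country ids), `usage` (data.frame
#'   `country_id`, `rural_fraction`, `urban_fraction`) and `continents`
#'   (data.frame `country_id`, `continent`).
#' @export
gen_population_and_usage <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  nr <- scenario$grid_shape[1]; nc <- scenario$grid_shape[2]
  k <- scenario$n_countries
  if (k > nc) stop("more countries than grid columns")
  with_seed(derive_seed(scenario$seed, 77L), {
    country_of_col <- ceiling(seq_len(nc) * k / nc)
    countries <- gw_raster(matrix(country_of_col, nr, nc, byrow = TRUE),
                           cellsize = scenario$cell_size)
    rural <- exp(0.8 * gaussian_field(nr, nc, max(scenario$smoothness[1], 1))) * 20
    urban <- matrix(0, nr, nc)
    n_blob <- 3L * k
    cr <- stats::runif(n_blob, 1, nr); cc <- stats::runif(n_blob, 1, nc)
    amp <- stats::runif(n_blob, 1000, 5000)
    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    for (b in seq_len(n_blob)) {
      d2 <- (rows - cr[b])^2 + (cols - cc[b])^2
      urban <- urban + amp[b] * exp(-d2 / (2 * 3^2))
    }
    urban[urban < 1] <- 0
    usage <- data.frame(country_id = seq_len(k),
                        rural_fraction = stats::runif(k, 0.3, 0.9),
                        urban_fraction = stats::runif(k, 0.1, 0.6))
    continents <- data.frame(
      country_id = seq_len(k),
      continent = unname(scenario$continent_assignment[as.character(seq_len(k))]),
      stringsAsFactors = FALSE)
    list(rural = gw_raster(rural, cellsize = scenario$cell_size),
         urban = gw_raster(urban, cellsize = scenario$cell_size),
         countries = countries, usage = usage, continents = continents)
  })
}
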