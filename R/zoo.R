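#' Ready-made case-study model configurations
#'
#' Six published indicator models expressed as ready-to-fit configurations:
#'
#' * `b3_u5mr` — under-five mortality: log scale, population-specific linear
#'   trend around the mid-observation year, cubic B-splines (knots every 2.5
#'   years) whose coefficients follow a second-order random walk anchored at
#'   the reference spline and by a sum-to-zero constraint on first
#'   differences; smoothing variances hierarchical; logarithmic-pooling
#'   projections.
#' * `gbd_u5mr` — under-five mortality: log10 scale, non-linear regression on
#'   LDI, female education and HIV death rate with fixed coefficients, fixed
#'   file-based offsets from smoothed residuals, Matern Gaussian-process
#'   smoothing with fixed hyperparameters.
#' * `fpem_total_use` — total contraceptive use: logit scale, logistic
#'   transition systematic component (asymptote, rate, level hierarchically
#'   estimated; 3 levels for rate and level, 1 for the asymptote), AR(1)
#'   smoothing on the rate of change.
#' * `igme_nmr` — ratio of neonatal to other under-five mortality: log
#'   scale, piecewise-linear regression on U5MR with a cut-off, B-spline
#'   RW(1) smoothing with an all-coefficient sum-to-zero constraint.
#' * `bmat_mmr` — proportion of maternal deaths: log scale, linear
#'   regression on log(GDP), log(GFR) and SAB with hierarchical intercepts,
#'   ARMA(1,1) smoothing after one difference anchored at 1990,
#'   population-specific smoothing sds `sigma_w * (1 + lambda_c)` with
#'   truncated-normal multipliers.
#' * `subnational_mortality` — age-specific mortality by area: log scale,
#'   regression on principal components of standard mortality age schedules
#'   with time-varying coefficients shrunk towards RW(2)-smoothed component
#'   means; independent deviations with age-group-specific variances.
#'   Each (area, age-group) pair is treated as a population on the shared
#'   time grid.
#'
#' Numeric coefficient values shipped with the entries (regression
#' coefficients, kernel hyperparameters, truth values for synthetic
#' scenarios) are illustrative placeholders for synthetic use, not published
#' estimates.
#'
#' @param name One of the six names above.
#' @param grid A [time_grid()] the configuration should be anchored to.
#' @param populations Population ids for the matched synthetic scenario.
#' @return An object of class `tmmp_zoo_entry`: fields `name`, `model` (a
#'   validated [tmmp_model()]), `note` (citation/simplification notes),
#'   `truth` (placeholder generating values) and `scenario` (a function
#'   `(seed)` returning `observations`, `covariates`, `offsets`,
#'   `groupings`, `truth` for the matched synthetic experiment).
#' @export
zoo <- function(name = c("b3_u5mr", "gbd_u5mr", "fpem_total_use", "igme_nmr",
                         "bmat_mmr", "subnational_mortality"),
                grid = time_grid(1990, 20, 25),
                populations = paste0("C", 1:5)) {
  name <- match.arg(name)
  entry <- switch(name,
    b3_u5mr = zoo_b3(grid, populations),
    gbd_u5mr = zoo_gbd(grid, populations),
    fpem_total_use = zoo_fpem(grid, populations),
    igme_nmr = zoo_nmr(grid, populations),
    bmat_mmr = zoo_bmat(grid, populations),
    subnational_mortality = zoo_subnational(grid, populations))
  entry$name <- name
  entry$grid <- grid
  class(entry) <- "tmmp_zoo_entry"
  entry
}

#' @export
print.tmmp_zoo_entry <- function(x, ...) {
  cat(sprintf("<tmmp_zoo_entry> %s\n", x$name))
  print(x$model)
  cat("note:", x$note, "\n")
  invisible(x)
}

# reference spline index: the basis column peaking at the mid estimation year
b3_kstar <- function(grid) {
  B <- build_basis(basis_spec("bspline"), seq_len(grid$T))
  unname(which.max(B[round((1 + grid$T) / 2), ]))
}

zoo_b3 <- function(grid, pops) {
  B <- build_basis(basis_spec("bspline"), seq_len(grid$T))
  K <- ncol(B)
  kstar <- b3_kstar(grid)
  model <- tmmp_model(
    name = "b3_u5mr",
    indicator = list(name = "U5MR", scale = "per 1 live birth"),
    transform = "log",
    systematic = list(kind = "linear_trend", strategy = "prior"),
    smoothing = list(basis = list(kind = "bspline", degree = 3, knot_spacing = 2.5),
                     kernel = list(family = "iid", sigma = 0.05),
                     r = 2, constraint = list(kstar, seq_len(K - 1)),
                     sigma = "hierarchical"),
    data_model = list(family = "normal", variance = "fixed"),
    hierarchy = list(sigma_delta = list(strategy = "hierarchical", levels = 1)),
    projection = list(method = "log_pooling", W = 0.5),
    priors = list(alpha0 = list(dist = "normal", mean = 0, sd = 5),
                  alpha1 = list(dist = "normal", mean = 0, sd = 1)),
    inference = list(seed = 1, chains = 2, draws = 900, warmup = 900))
  set.seed(substream_seed(20, "zoo", "b3"))
  truth <- list(alpha0 = setNames(log(stats::runif(length(pops), 0.03, 0.12)), pops),
                alpha1 = setNames(stats::runif(length(pops), -0.05, -0.01), pops),
                sigma_delta = setNames(stats::runif(length(pops), 0.02, 0.06), pops))
  scenario <- function(seed = 1) {
    pat <- missingness_pattern(pops, grid, prop_observed = 0.5,
                               sources = c(survey = 0.12, vr = 0.05),
                               seed = substream_seed(seed, "pat"))
    sim <- generate_tmmp(model, truth, pat, grid, relative_sd = TRUE, seed = seed)
    list(observations = sim$observations, covariates = NULL, offsets = NULL,
         groupings = NULL, truth = sim$truth)
  }
  list(model = model, truth = truth, scenario = scenario,
       note = paste("Projection pooling weight W is a placeholder (the source",
                    "model fixes it by out-of-sample validation). Data model",
                    "chosen as normal with fixed sampling sds (the source",
                    "leaves the data model unspecified)."))
}

zoo_gbd <- function(grid, pops) {
  betas <- c(-0.35, -0.03, 1.0, 5.0)
  model <- tmmp_model(
    name = "gbd_u5mr",
    indicator = list(name = "U5MR", scale = "per 1 live birth"),
    transform = "log10",
    covariate = list(kind = "gbd_nonlinear", columns = c("LDI", "EDU", "HIV"),
                     betas = betas, strategy = "fixed"),
    smoothing = list(basis = list(kind = "identity"),
                     kernel = list(family = "matern", kappa = 0.06, ell = 4, nu = 2.5),
                     r = 0, constraint = "none", sigma = "fixed"),
    data_model = list(family = "normal", variance = "fixed"),
    inference = list(seed = 1, chains = 2, draws = 500, warmup = 500))
  covariates <- gbd_covariates(grid, pops)
  truth <- list(betas = betas, sigma_delta = 0.06, ell = 4, nu = 2.5)
  scenario <- function(seed = 1) {
    pat <- missingness_pattern(pops, grid, prop_observed = 0.6,
                               sources = c(survey = 0.1, vr = 0.04),
                               seed = substream_seed(seed, "pat"))
    sim <- generate_tmmp(model, truth, pat, grid, covariates = covariates,
                         relative_sd = TRUE, seed = seed)
    list(observations = sim$observations, covariates = covariates,
         offsets = NULL, groupings = NULL, truth = sim$truth)
  }
  list(model = model, truth = truth, scenario = scenario,
       note = paste("Regression coefficients and Matern hyperparameters are",
                    "fixed placeholders (the source fixes them from separate",
                    "fits). The source's stage-1 mixed-effects bias",
                    "adjustment is simplified away: offsets come from",
                    "gbd_offsets_simplified() on raw residuals."))
}

gbd_covariates <- function(grid, pops) {
  set.seed(substream_seed(20, "zoo", "gbdcov"))
  rows <- list()
  for (p in pops) {
    ldi0 <- stats::runif(1, 1000, 15000)
    gr <- stats::runif(1, 0.01, 0.04)
    edu0 <- stats::runif(1, 3, 9)
    hiv <- stats::runif(1, 0, 0.003)
    t <- seq_len(grid$T_star)
    rows[[p]] <- data.frame(population = p, time = t,
                            LDI = ldi0 * exp(gr * (t - 1)),
                            EDU = edu0 + 0.1 * (t - 1),
                            HIV = hiv * exp(-0.03 * (t - 1)))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

zoo_fpem <- function(grid, pops) {
  model <- tmmp_model(
    name = "fpem_total_use",
    indicator = list(name = "total contraceptive use", scale = "proportion"),
    transform = "logit",
    systematic = list(kind = "logistic_transition",
                      t_star = round((1 + grid$T) / 2)),
    smoothing = list(basis = list(kind = "identity"),
                     kernel = list(family = "ar1", kappa = 0.1, rho = 0.7),
                     r = 0, constraint = "none", sigma = "shared"),
    data_model = list(family = "logit_normal", variance = "fixed"),
    hierarchy = list(Omega = list(strategy = "hierarchical", levels = 3),
                     Pstar = list(strategy = "hierarchical", levels = 1),
                     wstar = list(strategy = "hierarchical", levels = 3)),
    inference = list(seed = 1, chains = 2, draws = 1000, warmup = 1000))
  C <- length(pops)
  half <- ceiling(C / 2)
  groupings <- data.frame(
    population = pops,
    subregion = c(rep("s1", half), rep("s2", C - half)),
    region = c(rep("r1", half), rep("r2", C - half)))
  set.seed(substream_seed(20, "zoo", "fpem"))
  truth <- list(Omega = setNames(stats::qlogis(stats::runif(C, 0.1, 0.4)), pops),
                P_tilde = setNames(stats::runif(C, 0.75, 0.9), pops),
                omega = setNames(stats::runif(C, 0.15, 0.3), pops),
                sigma_delta = 0.08, rho = 0.7)
  scenario <- function(seed = 1) {
    pat <- missingness_pattern(pops, grid, prop_observed = 0.5,
                               sources = c(survey = 0.15),
                               seed = substream_seed(seed, "pat"))
    sim <- generate_tmmp(model, truth, pat, grid, seed = seed)
    list(observations = sim$observations, covariates = NULL, offsets = NULL,
         groupings = groupings, truth = sim$truth)
  }
  list(model = model, truth = truth, scenario = scenario,
       note = paste("Total use only; the source's split into traditional and",
                    "modern methods and unmet need is out of scope. The",
                    "developed/developing split of the level hierarchy is",
                    "collapsed to the three-level form. The AR(1)",
                    "autocorrelation is fixed at a placeholder value (the",
                    "smoothing scale is estimated)."))
}

zoo_nmr <- function(grid, pops) {
  B <- build_basis(basis_spec("bspline"), seq_len(grid$T))
  K <- ncol(B)
  model <- tmmp_model(
    name = "igme_nmr",
    indicator = list(name = "NMR/(U5MR-NMR)", scale = "ratio"),
    transform = "log",
    covariate = list(kind = "piecewise_nmr", columns = "U5MR",
                     beta2 = 30, intercept = "hierarchical"),
    smoothing = list(basis = list(kind = "bspline", degree = 3, knot_spacing = 2.5),
                     kernel = list(family = "iid", sigma = 0.05),
                     r = 1, constraint = list(seq_len(K)),
                     sigma = "hierarchical"),
    data_model = list(family = "normal", variance = "fixed"),
    hierarchy = list(beta0 = list(strategy = "hierarchical", levels = 1),
                     sigma_delta = list(strategy = "hierarchical", levels = 1)),
    inference = list(seed = 1, chains = 2, draws = 1400, warmup = 1400))
  set.seed(substream_seed(20, "zoo", "nmr"))
  C <- length(pops)
  truth <- list(beta0 = setNames(stats::rnorm(C, -0.5, 0.15), pops),
                beta1 = -0.55, beta2 = 30,
                sigma_delta = setNames(stats::runif(C, 0.02, 0.05), pops))
  covariates <- nmr_covariates(grid, pops)
  scenario <- function(seed = 1) {
    pat <- missingness_pattern(pops, grid, prop_observed = 0.5,
                               sources = c(survey = 0.1, vr = 0.04),
                               seed = substream_seed(seed, "pat"))
    sim <- generate_tmmp(model, truth, pat, grid, covariates = covariates,
                         relative_sd = TRUE, seed = seed)
    list(observations = sim$observations, covariates = covariates,
         offsets = NULL, groupings = NULL, truth = sim$truth)
  }
  list(model = model, truth = truth, scenario = scenario,
       note = paste("Indicator is the neonatal to other child mortality",
                    "ratio; U5MR enters as a covariate (deaths per 1000).",
                    "Cut-off beta2 fixed at a placeholder value."))
}

nmr_covariates <- function(grid, pops) {
  set.seed(substream_seed(20, "zoo", "nmrcov"))
  rows <- list()
  for (p in pops) {
    u0 <- stats::runif(1, 40, 120)
    rate <- stats::runif(1, 0.02, 0.05)
    t <- seq_len(grid$T_star)
    rows[[p]] <- data.frame(population = p, time = t,
                            U5MR = u0 * exp(-rate * (t - 1)))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

zoo_bmat <- function(grid, pops) {
  model <- tmmp_model(
    name = "bmat_mmr",
    indicator = list(name = "proportion of maternal deaths", scale = "proportion of deaths"),
    transform = "log",
    covariate = list(kind = "linear", columns = c("log_GDP", "log_GFR", "SAB"),
                     intercept = "hierarchical"),
    smoothing = list(basis = list(kind = "identity"),
                     kernel = list(family = "arma11", sigma = 0.05, rho = 0.6,
                                   theta = -0.2),
                     r = 1, constraint = list(1L),
                     sigma = "bmat_lambda", estimate = c("rho", "theta")),
    data_model = list(family = "normal", variance = "fixed"),
    hierarchy = list(beta0 = list(strategy = "hierarchical", levels = 2)),
    inference = list(seed = 1, chains = 2, draws = 600, warmup = 600))
  C <- length(pops)
  half <- ceiling(C / 2)
  groupings <- data.frame(population = pops,
                          region = c(rep("r1", half), rep("r2", C - half)))
  set.seed(substream_seed(20, "zoo", "bmat"))
  truth <- list(beta0 = setNames(stats::rnorm(C, -3.2, 0.2), pops),
                betas = c(-0.15, 0.3, -0.6),
                sigma_delta = setNames(0.05 * (1 + stats::runif(C, -0.4, 0.8)), pops),
                rho = 0.6, theta = -0.2)
  covariates <- bmat_covariates(grid, pops)
  scenario <- function(seed = 1) {
    pat <- missingness_pattern(pops, grid, prop_observed = 0.5,
                               sources = c(dhs = 0.15, vr = 0.06),
                               seed = substream_seed(seed, "pat"))
    sim <- generate_tmmp(model, truth, pat, grid, covariates = covariates,
                         relative_sd = TRUE, seed = seed)
    list(observations = sim$observations, covariates = covariates,
         offsets = NULL, groupings = groupings, truth = sim$truth)
  }
  list(model = model, truth = truth, scenario = scenario,
       note = paste("Non-AIDS proportion only; the source's AIDS/non-AIDS",
                    "death split is out of scope. Smoothing anchored at the",
                    "first year (1990)."))
}

bmat_covariates <- function(grid, pops) {
  set.seed(substream_seed(20, "zoo", "bmatcov"))
  rows <- list()
  for (p in pops) {
    g0 <- stats::runif(1, 7, 10)      # log GDP per capita
    f0 <- stats::runif(1, 3.5, 5)     # log GFR
    s0 <- stats::runif(1, 0.4, 0.9)   # skilled attendance at birth
    t <- seq_len(grid$T_star)
    rows[[p]] <- data.frame(population = p, time = t,
                            log_GDP = g0 + 0.02 * (t - 1),
                            log_GFR = f0 - 0.01 * (t - 1),
                            SAB = pmin(0.99, s0 + 0.01 * (t - 1)))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

zoo_subnational <- function(grid, counties) {
  # three areas by three age groups keeps the joint coefficient update
  # tractable while exercising the area/age sharing structure
  counties <- utils::head(counties, 3)
  ages <- c("a0_4", "a5_14", "a15_59")
  pops <- as.vector(outer(counties, ages, paste, sep = ":"))
  age_of <- setNames(rep(ages, each = length(counties)), pops)
  county_of <- setNames(rep(counties, times = length(ages)), pops)
  # synthetic principal components of standard mortality age schedules
  X_pc <- rbind(a0_4 = c(1.0, 0.8, 0.1),
                a5_14 = c(0.6, -0.4, 0.7),
                a15_59 = c(0.8, -0.2, -0.5))
  model <- tmmp_model(
    name = "subnational_mortality",
    indicator = list(name = "age-specific mortality rate", scale = "per 1"),
    transform = "log",
    covariate = list(kind = "pca_linear", columns = c("PC1", "PC2", "PC3"),
                     groups = as.list(county_of)),
    smoothing = list(basis = list(kind = "identity"),
                     kernel = list(family = "iid", sigma = 0.05),
                     r = 0, constraint = "none", sigma = "per_age_group",
                     groups = as.list(age_of)),
    data_model = list(family = "normal", variance = "fixed"),
    inference = list(seed = 1, chains = 2, draws = 800, warmup = 800))
  set.seed(substream_seed(20, "zoo", "subnat"))
  Tn <- grid$T_star
  beta_pc <- list()
  for (co in counties) {
    b1 <- -4.2 + cumsum(c(0, stats::rnorm(Tn - 1, -0.01, 0.004)))
    b2 <- 0.3 + cumsum(c(0, stats::rnorm(Tn - 1, 0, 0.004)))
    b3 <- 0.1 + cumsum(c(0, stats::rnorm(Tn - 1, 0, 0.003)))
    bmat <- cbind(b1, b2, b3)
    for (a in ages) beta_pc[[paste(co, a, sep = ":")]] <- bmat
  }
  truth <- list(populations = pops, beta_pc = beta_pc,
                sigma_delta = setNames(c(0.06, 0.04, 0.03)[match(age_of, ages)], pops))
  covariates <- do.call(rbind, c(lapply(pops, function(p)
    data.frame(population = p, time = seq_len(Tn),
               PC1 = unname(X_pc[age_of[[p]], 1]),
               PC2 = unname(X_pc[age_of[[p]], 2]),
               PC3 = unname(X_pc[age_of[[p]], 3]))), list(make.row.names = FALSE)))
  scenario <- function(seed = 1) {
    pat <- missingness_pattern(pops, grid, prop_observed = 0.6,
                               sources = c(vital = 0.1),
                               seed = substream_seed(seed, "pat"))
    sim <- generate_tmmp(model, truth, pat, grid, covariates = covariates,
                         relative_sd = TRUE, seed = seed)
    list(observations = sim$observations, covariates = covariates,
         offsets = NULL, groupings = NULL, truth = sim$truth)
  }
  list(model = model, truth = truth, scenario = scenario,
       note = paste("Each (area, age-group) pair is one population; the",
                    "principal-component loadings are shared within an area",
                    "across age groups and vary over time around",
                    "RW(2)-smoothed component means. PC vectors are synthetic",
                    "stand-ins for components of standard mortality",
                    "schedules. Component-mean variances are constant over",
                    "time (the source allows them to vary)."))
}

#' Simplified smoothed-residual offsets
#'
#' A documented simplification of the multi-stage offset construction used
#' for the GBD-style under-five mortality model: (1) the covariate component
#' is fitted to the transformed observations (fixed coefficients supplied, or
#' estimated by least squares on the log10 scale with the HIV term dropped);
#' (2) raw residuals on the natural scale are smoothed for every population
#' and time by kernel-weighted averages, with spatial weight 0.99 for
#' within-population residuals versus 0.01 for residuals from other
#' populations in the same region, times a Gaussian temporal kernel; (3)
#' offsets are `log10(eta_hat + r_smooth) - log10(eta_hat)`. Where
#' `eta_hat + r_smooth` would be nonpositive the smoothed residual is floored
#' at `-0.9 * eta_hat` with a warning.
#'
#' The source model's stage-1 mixed-effects bias adjustment (random effects
#' per data source) is deliberately not replicated.
#'
#' @param observations Observation table (natural scale).
#' @param covariates Covariate table with `LDI`, `EDU`, `HIV` columns over
#'   `1..T_star`.
#' @param grid A [time_grid()].
#' @param betas Fixed covariate coefficients (length 4), or `NULL` to
#'   estimate the linearized (HIV-free) form by least squares.
#' @param region_map Named vector population -> region (defaults to a single
#'   shared region).
#' @param weights Spatial weights, `c(within = 0.99, region = 0.01)`.
#' @param temporal_bandwidth Gaussian kernel bandwidth in grid units
#'   (required; the source does not publish its temporal weighting).
#' @return List with `offsets` (populations x `T_star` matrix on the log10
#'   scale), `betas` and `eta_hat`.
#' @export
gbd_offsets_simplified <- function(observations, covariates, grid,
                                   betas = NULL, region_map = NULL,
                                   weights = c(within = 0.99, region = 0.01),
                                   temporal_bandwidth = 2) {
  observations$population <- as.character(observations$population)
  covariates$population <- as.character(covariates$population)
  pops <- sort(unique(c(observations$population, covariates$population)))
  region_map <- region_map %||% setNames(rep("all", length(pops)), pops)
  covm <- function(col) {
    M <- matrix(NA_real_, length(pops), grid$T_star, dimnames = list(pops, NULL))
    M[cbind(match(covariates$population, pops), covariates$time)] <- covariates[[col]]
    M
  }
  LDI <- covm("LDI"); EDU <- covm("EDU"); HIV <- covm("HIV")
  if (is.null(betas)) {
    oi <- cbind(match(observations$population, pops), observations$time)
    df <- data.frame(ly = log10(observations$value),
                     lldi = log(LDI[oi]), edu = EDU[oi])
    fit <- stats::lm(ly ~ lldi + edu, data = df)
    betas <- c(stats::coef(fit)[["lldi"]] * log(10),
               stats::coef(fit)[["edu"]] * log(10),
               stats::coef(fit)[["(Intercept)"]] * log(10), 0)
  }
  eta_hat <- 10^covariate_gbd(LDI, EDU, HIV, betas)
  ri <- observations$value -
    eta_hat[cbind(match(observations$population, pops), observations$time)]
  r_sm <- matrix(0, length(pops), grid$T_star, dimnames = list(pops, NULL))
  for (p in pops) {
    same_region <- pops[region_map[pops] == region_map[[p]]]
    wsp <- ifelse(observations$population == p, weights[["within"]],
           ifelse(observations$population %in% same_region, weights[["region"]], 0))
    for (t in seq_len(grid$T_star)) {
      wt <- wsp * exp(-0.5 * ((observations$time - t) / temporal_bandwidth)^2)
      r_sm[p, t] <- if (sum(wt) > 0) sum(wt * ri) / sum(wt) else 0
    }
  }
  floor_at <- -0.9 * eta_hat
  if (any(r_sm < floor_at)) {
    warning(sprintf("%d smoothed residual(s) floored to keep offsets finite",
                    sum(r_sm < floor_at)), call. = FALSE)
    r_sm <- pmax(r_sm, floor_at)
  }
  offsets <- log10(eta_hat + r_sm) - log10(eta_hat)
  list(offsets = offsets, betas = betas, eta_hat = eta_hat)
}
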