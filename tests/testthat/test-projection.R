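# a tiny fitted AR(1) toy used across projection tests
ar1_toy_fit <- function(rho = 0.7, kappa = 1.2, T_est = 8, T_star = 14,
                        draws = 400) {
  mod <- tmmp_model(
    name = "ar1_toy", transform = "identity",
    smoothing = list(basis = list(kind = "identity"),
                     kernel = list(family = "ar1", kappa = kappa, rho = rho),
                     r = 0, constraint = "none", sigma = "fixed"),
    data_model = list(family = "normal", variance = "fixed"),
    inference = list(seed = 1, chains = 2, draws = draws, warmup = 200))
  set.seed(31)
  y <- arima.sim(list(ar = rho), T_est, sd = kappa * sqrt(1 - rho^2))
  dat <- data.frame(population = "A", time = 1:T_est, value = as.numeric(y),
                    sampling_sd = 0.05, source = "s", denominator = NA_integer_)
  fit_tmmp(mod, dat, time_grid(2000, T_est, T_star))
}

test_that("stationary AR(1) projections decay at rate rho towards zero", {
  rho <- 0.7; kappa <- 1.2
  fit <- ar1_toy_fit(rho, kappa)
  pr <- project_tmmp(fit, seed = 2)
  eta_T <- mean(fit$draws$eta[, , 1, 8])
  med <- apply(pr$eta[, , 1, ], 3, mean)
  h <- seq_len(6)
  mc_se <- kappa / sqrt(fit$n_draws * fit$chains) * 3
  expect_true(all(abs(med - rho^h * eta_T) < 3 * mc_se + 0.05))
  # variance approaches the stationary variance with the horizon
  v <- apply(pr$eta[, , 1, ], 3, function(m) var(as.vector(m)))
  expect_true(all(diff(v) > -0.15))
  expect_equal(v[6], kappa^2 * (1 - rho^(2 * 6)), tolerance = 0.25)
})

test_that("an empty projection period returns an empty projection", {
  fit <- ar1_toy_fit(T_star = 8, draws = 50)
  pr <- project_tmmp(fit, seed = 1)
  expect_equal(length(pr$times), 0)
  expect_equal(dim(pr$eta)[4], 0)
})

# a fitted B3-style RW(2) spline model shared by the default/pooling tests
b3_toy_fit <- function(T_est = 20, T_star = 28) {
  pops <- c("A", "B", "C")
  mod <- b3_family_model(draws = 400, warmup = 400)
  mod$systematic$t_star <- 10
  truth <- b3_family_truth(pops, seed = 7)
  g <- time_grid(1990, T_est, T_star)
  pat <- missingness_pattern(pops, g, prop_observed = 0.7,
                             sources = c(s = 0.05), seed = 2)
  sim <- generate_tmmp(mod, truth, pat, g, relative_sd = TRUE, seed = 3)
  suppressWarnings(fit_tmmp(mod, sim$observations, g, seed = 4))
}

b3fit_cached <- b3_toy_fit()

test_that("RW(2) spline projections continue the last log-linear trend", {
  fit <- b3fit_cached
  pr <- project_tmmp(fit, method = "default_conditional", seed = 5)
  # median path on the log scale has (near) zero second differences
  med <- log(apply(pr$eta[, , 1, ], 3, median))
  expect_lt(max(abs(diff(med, differences = 2))), 0.08)
})

test_that("log pooling collapses to its documented limits in W", {
  fit <- b3fit_cached
  gv <- compute_pooling_targets(fit)
  expect_true(is.finite(gv["G"]) && gv["V"] >= 0)
  # W = 1: every projected second difference is drawn from N(G, V)
  pr1 <- project_tmmp(fit, method = "log_pooling", W = 1,
                      G = 0.004, V = 1e-6, seed = 6)
  arr <- log(pr1$eta[, , 2, ])
  flat <- matrix(arr, prod(dim(arr)[1:2]), dim(arr)[3])
  d2 <- apply(flat, 1, function(x) diff(x, differences = 2))
  # per-time-step curvature equals the coefficient-level second difference
  # scaled by the squared knot spacing
  expect_equal(mean(d2) * 2.5^2, 0.004, tolerance = 0.15)
  # W = 0 seeded at a zero last estimated difference reduces to the default
  # RW(2) law: iid N(0, sigma^2) second differences. Checked by simulation
  # against the closed-form conditional of the iid kernel.
  set.seed(13)
  sig <- 0.3
  draws0 <- replicate(1e4, tmmp:::pooling_draw(c(0.1, -0.05, 0), K_added = 5,
                                               W = 0, G = 9, V = 9,
                                               sigma_c = sig))
  expect_equal(rowMeans(draws0), rep(0, 5), tolerance = 0.01)
  expect_equal(apply(draws0, 1, var), rep(sig^2, 5), tolerance = 0.05)
  spec <- smoothing_spec(basis_spec("identity"), kernel_spec("iid", sigma = sig),
                         r = 2, constraint = "minimum_norm")
  delta_hat <- recover_levels(c(0.1, -0.05, 0), 2)   # last 2nd difference 0
  cnd <- condition_projection(spec, delta_hat, K_added = 5)
  expect_equal(cnd$mean, rep(0, 5), tolerance = 1e-9)
  expect_equal(diag(cnd$cov), rep(sig^2, 5), tolerance = 1e-6)
})

test_that("pooling targets match a sort-based median oracle", {
  set.seed(12)
  x <- rnorm(1000)
  xs <- sort(x)
  manual <- (xs[500] + xs[501]) / 2
  expect_equal(unname(median(x)), manual)
  # degenerate pooled sets
  fit <- ar1_toy_fit(T_star = 8, draws = 30)
  expect_error(project_tmmp(fit, method = "log_pooling", W = 1.5), "W")
})
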