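test_that("the posterior matches the conjugate normal-normal oracle", {
  sig_d <- 2; sd_obs <- 1
  y <- c(1.0, -0.5, 2.0, 0.3, -1.2)
  mod <- conjugate_toy_model(sigma_delta = sig_d)
  fit <- fit_tmmp(mod, conjugate_toy_data(y, sd_obs), toy_grid(5))
  shrink <- sig_d^2 / (sig_d^2 + sd_obs^2)
  post_mean <- y * shrink
  post_var <- sig_d^2 * sd_obs^2 / (sig_d^2 + sd_obs^2)
  em <- apply(fit$draws$eta, 4, mean)
  ev <- apply(fit$draws$eta, 4, var)
  n_eff <- fit$n_draws * fit$chains
  se_mean <- sqrt(post_var / n_eff)
  se_var <- post_var * sqrt(2 / n_eff)
  expect_true(all(abs(em - post_mean) < 3 * se_mean))
  expect_true(all(abs(ev - post_var) < 3 * se_var))
})

test_that("fits are reproducible under a fixed seed", {
  mod <- conjugate_toy_model(draws = 50, warmup = 20)
  dat <- conjugate_toy_data(c(0.5, -0.5, 1))
  f1 <- fit_tmmp(mod, dat, toy_grid(3), seed = 42)
  f2 <- fit_tmmp(mod, dat, toy_grid(3), seed = 42)
  expect_identical(f1$draws$pars, f2$draws$pars)
  expect_identical(f1$draws$eta, f2$draws$eta)
  f3 <- fit_tmmp(mod, dat, toy_grid(3), seed = 43)
  expect_false(identical(f1$draws$eta, f3$draws$eta))
})

test_that("populations without data get prior-predictive latent draws", {
  sig_d <- 1.7
  mod <- conjugate_toy_model(sigma_delta = sig_d, draws = 2000, warmup = 200)
  dat <- conjugate_toy_data(c(1, 1, 1))
  dat$population <- "observed"
  none <- data.frame(population = "empty", time = 1, value = 0.5,
                     sampling_sd = 1, source = "s", denominator = NA_integer_)
  fit <- fit_tmmp(mod, rbind(dat, none[0, ]), toy_grid(3), seed = 8)
  expect_equal(dim(fit$draws$eta)[3], 1L)
  # an explicitly dataless population (declared through the groupings table):
  # its latent moments equal the prior N(0, sig_d^2)
  grp <- data.frame(population = c("observed", "empty"))
  fit2 <- fit_tmmp(mod, dat, toy_grid(3), groupings = grp, seed = 8)
  e_empty <- fit2$draws$eta[, , "empty", ]
  expect_lt(abs(mean(e_empty)), 3 * sig_d / sqrt(200))
  expect_equal(var(as.vector(e_empty)), sig_d^2, tolerance = 0.15)
})

test_that("doubling observations at a cell contracts the posterior", {
  mod <- conjugate_toy_model(draws = 1500, warmup = 300)
  one <- conjugate_toy_data(c(0.8, 0.2, -0.1))
  two <- rbind(one, one[1, ])
  f1 <- fit_tmmp(mod, one, toy_grid(3), seed = 2)
  f2 <- fit_tmmp(mod, two, toy_grid(3), seed = 2)
  v1 <- var(as.vector(f1$draws$eta[, , 1, 1]))
  v2 <- var(as.vector(f2$draws$eta[, , 1, 1]))
  expect_lt(v2, v1)
  # analytic check: precision gains one observation's worth
  expect_equal(v2, 1 / (1 / 4 + 2), tolerance = 0.1)
})

test_that("the sampler's log-posterior equals independently composed terms", {
  pops <- c("A", "B")
  mod <- b3_family_model()
  truth <- b3_family_truth(pops)
  g <- time_grid(1990, 30)
  pat <- missingness_pattern(pops, g, prop_observed = 0.4,
                             sources = c(s = 0.1), seed = 4)
  sim <- generate_tmmp(mod, truth, pat, g, relative_sd = TRUE, seed = 5)
  plan <- tmmp:::compile_model(mod, sim$observations, g)
  st <- tmmp:::new_state(plan)
  set.seed(1)
  tmmp:::one_sweep(plan, st)
  lp <- tmmp:::total_logpost(plan, st)
  # independent recomposition: data model + smoothing prior + hierarchy +
  # scalar priors, from the module-level functions
  eta <- t(sapply(plan$pops, function(p) tmmp:::pop_eta(plan, st, p)))
  rownames(eta) <- plan$pops
  ll <- total_loglik(sim$observations, eta, data_model_spec("normal"))
  pri <- sum(vapply(plan$blocks, function(b) b$prior_logdens(st), 0))
  spri <- sum(vapply(plan$scalars, function(s) s$logprior(st$sc[[s$id]], st), 0))
  expect_equal(lp, ll + pri + spri, tolerance = 1e-8)
})

test_that("split-Rhat and ESS behave on reference draw sets", {
  # identical chains of a constant parameter: rhat exactly 1
  const <- array(1.7, c(500, 2, 1), dimnames = list(NULL, NULL, "c"))
  expect_equal(diagnose(const)$rhat, 1)
  # independent standard normal draws: rhat near 1, ESS near total
  set.seed(99)
  iid <- array(rnorm(4 * 1000), c(1000, 4, 1), dimnames = list(NULL, NULL, "z"))
  d <- diagnose(iid)
  expect_gt(d$rhat, 0.99); expect_lt(d$rhat, 1.01)
  expect_gt(d$ess, 0.8 * 4000)
  # strongly autocorrelated draws: ESS much smaller than the draw count
  ar <- as.vector(arima.sim(list(ar = 0.95), 2000))
  arr <- array(c(ar[1:1000], ar[1001:2000]), c(1000, 2, 1),
               dimnames = list(NULL, NULL, "a"))
  expect_lt(diagnose(arr)$ess, 500)
})

test_that("a warning is attached when chains disagree", {
  # two 'chains' manufactured from different distributions via a crafted fit
  # are hard to fake honestly; instead check the warning plumbing on a fast
  # fit with far too few draws to converge
  mod <- b3_family_model(draws = 12, warmup = 0)
  pops <- paste0("P", 1:3)
  truth <- b3_family_truth(pops)
  g <- time_grid(1990, 30)
  pat <- missingness_pattern(pops, g, sources = c(s = 0.1), seed = 1)
  sim <- generate_tmmp(mod, truth, pat, g, relative_sd = TRUE, seed = 1)
  expect_warning(fit_tmmp(mod, sim$observations, g, seed = 1), "Rhat")
})
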