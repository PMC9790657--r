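test_that("per-record log-likelihoods match their family definitions", {
  nm <- data_model_spec("normal")
  expect_equal(loglik_record(nm, y = 0.4, eta = 0.4, sd = 1), -0.5 * log(2 * pi))
  bi <- data_model_spec("binomial")
  expect_equal(loglik_record(bi, y = 1, eta = 0.25, n = 1), log(0.25))
  ln <- data_model_spec("logit_normal")
  y <- 0.3; eta <- 0.42; s <- 0.5
  expect_equal(loglik_record(ln, y, eta, sd = s),
               dnorm(qlogis(y), qlogis(eta), s, log = TRUE) - log(y * (1 - y)))
  nb <- data_model_spec("negative_binomial", phi = 4)
  expect_equal(loglik_record(nb, y = 7, eta = 0.1, n = 50),
               dnbinom(7, size = 4, mu = 5, log = TRUE))
})

test_that("each density integrates or sums to one over its support", {
  # logit-normal via quadrature (change-of-variables oracle)
  ln <- data_model_spec("logit_normal")
  for (pars in list(c(0.3, 0.4), c(0.9, 1.2))) {
    total <- integrate(function(y) exp(loglik_record(ln, y, pars[1], sd = pars[2])),
                       0, 1, rel.tol = 1e-9)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
  nm <- data_model_spec("normal")
  total <- integrate(function(y) exp(loglik_record(nm, y, 0.2, sd = 0.05)),
                     -Inf, Inf)$value
  expect_equal(total, 1, tolerance = 1e-6)
  bi <- data_model_spec("binomial")
  expect_equal(sum(exp(loglik_record(bi, 0:50, eta = 0.3, n = 50))), 1,
               tolerance = 1e-9)
  nb <- data_model_spec("negative_binomial", phi = 2.5)
  expect_equal(sum(exp(loglik_record(nb, 0:5000, eta = 0.4, n = 50))), 1,
               tolerance = 1e-6)
})

test_that("negative binomial concentrates to its mean as phi grows", {
  set.seed(11)
  n <- 50; eta <- 0.3; mu <- n * eta
  draws_small <- rnbinom(1e5, size = 2, mu = mu)
  draws_big <- rnbinom(1e5, size = 1e4, mu = mu)
  expect_equal(mean(draws_small), mu, tolerance = 0.02)
  expect_equal(mean(draws_big), mu, tolerance = 0.02)
  # variance ratio approaches mu * (1 + mu / phi) in both regimes
  expect_equal(var(draws_small) / (mu * (1 + mu / 2)), 1, tolerance = 0.05)
  expect_equal(var(draws_big) / (mu * (1 + mu / 1e4)), 1, tolerance = 0.05)
})

test_that("total log-likelihood sums records independently of order", {
  g <- toy_grid(4)
  eta <- matrix(c(0.2, 0.25, 0.3, 0.35), 1, 4, dimnames = list("A", NULL))
  tab <- data.frame(population = "A", time = c(1, 1, 3), value = c(0.21, 0.18, 0.4),
                    sampling_sd = 0.05, source = "s", denominator = NA_integer_)
  spec <- data_model_spec("normal")
  ll <- total_loglik(tab, eta, spec)
  expect_equal(ll, sum(dnorm(tab$value, eta[1, tab$time], 0.05, log = TRUE)))
  expect_equal(total_loglik(tab[c(3, 1, 2), ], eta, spec), ll, tolerance = 1e-12)
  expect_equal(total_loglik(tab[0, ], eta, spec), 0)
  # two identical records double one record's contribution
  one <- tab[1, ]
  expect_equal(total_loglik(rbind(one, one), eta, spec),
               2 * total_loglik(one, eta, spec), tolerance = 1e-12)
})

test_that("estimated observation sds are resolved by source label", {
  eta <- matrix(0.5, 1, 2, dimnames = list("A", NULL))
  tab <- data.frame(population = "A", time = c(1, 2), value = c(0.5, 0.6),
                    sampling_sd = c(NA, 0.1), source = c("dhs", "vr"),
                    denominator = NA_integer_)
  spec <- data_model_spec("normal", variance = "per_source")
  ll <- total_loglik(tab, eta, spec, sds = c(dhs = 0.2))
  expect_equal(ll, dnorm(0.5, 0.5, 0.2, log = TRUE) + dnorm(0.6, 0.5, 0.1, log = TRUE))
  expect_error(total_loglik(tab, eta, spec), "sd supplied")
  expect_error(total_loglik(tab, eta, data_model_spec("normal", "fixed")), "fixed")
})
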