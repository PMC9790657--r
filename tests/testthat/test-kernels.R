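test_that("autocovariance closed forms match their definitions", {
  expect_equal(autocovariance(kernel_spec("ar1", kappa = 2, rho = 0.5), 0), 4)
  expect_equal(autocovariance(kernel_spec("ar1", kappa = 2, rho = 0.5), 3), 4 * 0.5^3)
  expect_equal(autocovariance(kernel_spec("squared_exponential", kappa = 1, ell = 1), 1),
               exp(-0.5), tolerance = 1e-12)
  expect_equal(autocovariance(kernel_spec("iid", sigma = 1.5), c(0, 1, 7)),
               c(2.25, 0, 0))
})

test_that("Matern reduces to its exponential and 3/2 closed forms", {
  h <- 0:20
  m12 <- autocovariance(kernel_spec("matern", kappa = 1.3, ell = 2, nu = 0.5), h)
  expect_equal(m12, 1.3^2 * exp(-h / 2), tolerance = 1e-10)
  m32 <- autocovariance(kernel_spec("matern", kappa = 0.7, ell = 3, nu = 1.5), h)
  a <- sqrt(3) * h / 3
  expect_equal(m32, 0.7^2 * (1 + a) * exp(-a), tolerance = 1e-10)
  # general-nu Bessel path agrees with the closed forms at those nu
  m12b <- autocovariance(kernel_spec("matern", kappa = 1.3, ell = 2, nu = 0.5 + 1e-9), h)
  expect_equal(m12b, m12, tolerance = 1e-6)
})

test_that("ARMA(1,1) autocovariance matches a simulation oracle", {
  sig <- 0.8; rho <- 0.6; theta <- -0.3
  k <- kernel_spec("arma11", sigma = sig, rho = rho, theta = theta)
  s_theory <- autocovariance(k, 0:5)
  # brute-force oracle: simulate the ARMA recursion across many paths
  n_paths <- 2e4; burn <- 60; keep <- 56
  sd_e <- sig / sqrt((1 + 2 * rho * theta + theta^2) / (1 - rho^2))
  set.seed(99)
  x <- rnorm(n_paths, 0, sig)
  e_prev <- rnorm(n_paths, 0, sd_e)
  out <- matrix(NA_real_, n_paths, keep)
  for (t in seq_len(burn + keep)) {
    e <- rnorm(n_paths, 0, sd_e)
    x <- rho * x + e + theta * e_prev
    e_prev <- e
    if (t > burn) out[, t - burn] <- x
  }
  s_emp <- sapply(0:5, function(h)
    mean(out[, 1:(keep - h)] * out[, (1 + h):keep]))
  expect_equal(s_emp, s_theory, tolerance = 0.03)
})

test_that("kernel covariance matrices are Toeplitz and positive semidefinite", {
  expect_equal(build_covariance(kernel_spec("iid", sigma = 1), 3), diag(3),
               tolerance = 1e-9)
  S <- build_covariance(kernel_spec("ar1", kappa = 1.2, rho = 0.8), 5)
  expect_equal(S[1, 4], 1.2^2 * 0.8^3, tolerance = 1e-9)
  for (k in list(kernel_spec("squared_exponential", kappa = 1, ell = 3),
                 kernel_spec("matern", kappa = 1, ell = 2, nu = 2.5),
                 kernel_spec("arma11", sigma = 1, rho = 0.7, theta = -0.4))) {
    S <- build_covariance(k, 30)
    expect_equal(S, t(S))
    expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), -1e-9)
  }
})

test_that("all non-iid kernels decay to zero at long range", {
  grid_pars <- expand.grid(rho = c(0.3, 0.9), ell = c(1, 5))
  for (i in seq_len(nrow(grid_pars))) {
    ks <- list(kernel_spec("ar1", kappa = 1, rho = grid_pars$rho[i]),
               kernel_spec("squared_exponential", kappa = 1, ell = grid_pars$ell[i]),
               kernel_spec("matern", kappa = 1, ell = grid_pars$ell[i], nu = 1.5),
               kernel_spec("arma11", sigma = 1, rho = grid_pars$rho[i], theta = -0.2))
    for (k in ks)
      expect_lt(autocovariance(k, 1000) / autocovariance(k, 0), 1e-6)
  }
})

test_that("out-of-range hyperparameters are rejected", {
  expect_error(kernel_spec("ar1", kappa = -1, rho = 0.5), "range")
  expect_error(kernel_spec("ar1", kappa = 1, rho = 1), "range")
  expect_error(kernel_spec("arma11", sigma = 1, rho = 0.5, theta = 0.5), "range")
  expect_error(kernel_spec("matern", kappa = 1, ell = 1), "requires")
  expect_error(autocovariance(kernel_spec("iid", sigma = 1), -1), "nonnegative")
})
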