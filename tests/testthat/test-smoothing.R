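test_that("prior draws of the smoothing component have the kernel variance", {
  g <- toy_grid(10)
  spec <- smoothing_spec(basis_spec("identity"), kernel_spec("iid", sigma = 1.4),
                         r = 0)
  E <- sample_smoothing(spec, g, n_draws = 5e4, seed = 1)
  v <- apply(E, 2, var)
  se <- 1.4^2 * sqrt(2 / 5e4)  # var of a sample variance of normals
  expect_true(all(abs(v - 1.4^2) < 3 * se))
  expect_equal(dim(sample_smoothing(spec, g, 0)), c(0, 10))
})

test_that("anchored draws satisfy their constraints exactly", {
  g <- toy_grid(20)
  B <- build_basis(basis_spec("bspline"), 1:20)
  K <- ncol(B)
  spec <- smoothing_spec(basis_spec("bspline"), kernel_spec("iid", sigma = 1),
                         r = 2, constraint = anchor_sets(4L, seq_len(K - 1)))
  # reconstruct the coefficients from a draw and check the anchors
  mats <- tmmp:::smoothing_matrices(spec, 1:20)
  set.seed(5)
  gam <- rnorm(mats$m)
  delta <- drop(mats$A %*% gam)
  expect_lt(abs(delta[4]), 1e-10)
  expect_lt(abs(sum(diff(delta))), 1e-10)
})

test_that("draws are reproducible under a fixed seed", {
  g <- toy_grid(8)
  spec <- smoothing_spec(basis_spec("identity"),
                         kernel_spec("ar1", kappa = 1, rho = 0.6), r = 0)
  expect_identical(sample_smoothing(spec, g, 10, seed = 7),
                   sample_smoothing(spec, g, 10, seed = 7))
})

test_that("generic Gaussian conditioning matches the AR(1) closed form", {
  k <- kernel_spec("ar1", kappa = 1.5, rho = 0.7)
  Tn <- 12
  spec <- smoothing_spec(basis_spec("identity"), k, r = 0)
  eps_T <- 2.3
  cnd <- condition_projection(spec, delta_hat = c(rep(0, Tn - 1), eps_T),
                              K_added = 6)
  h <- 1:6
  expect_equal(cnd$mean, 0.7^h * eps_T, tolerance = 1e-8)
  expect_equal(diag(cnd$cov), 1.5^2 * (1 - 0.7^(2 * h)), tolerance = 1e-8)
  # and against a brute-force conditional from the full joint covariance
  S <- build_covariance(k, Tn + 6)
  bf <- gaussian_conditional(S, seq_len(Tn), c(rep(0, Tn - 1), eps_T))
  expect_equal(cnd$mean, bf$mean, tolerance = 1e-8)
  expect_equal(cnd$cov, bf$cov, tolerance = 1e-8)
})

test_that("RW(2) conditionals extrapolate the last linear trend", {
  spec <- smoothing_spec(basis_spec("identity"), kernel_spec("iid", sigma = 0.3),
                         r = 2, constraint = "minimum_norm")
  delta_hat <- c(0, 0.5, 1.2, 2.1, 3.2)   # arbitrary levels
  cnd <- condition_projection(spec, delta_hat, K_added = 4)
  # iid second differences: conditional mean of new differences is zero
  expect_equal(cnd$mean, rep(0, 4), tolerance = 1e-10)
  ext <- extend_levels(delta_hat, 2, cnd$mean)
  expect_lt(max(abs(diff(ext, differences = 2)[4:7])), 1e-8)
  # linear continuation of the last trend
  expect_equal(diff(ext)[5:8], rep(diff(delta_hat)[4], 4), tolerance = 1e-8)
})

test_that("independent kernels make projection-period draws unconditional", {
  spec <- smoothing_spec(basis_spec("identity"), kernel_spec("iid", sigma = 2),
                         r = 0)
  cnd <- condition_projection(spec, delta_hat = rnorm(5), K_added = 1)
  expect_equal(cnd$mean, 0, tolerance = 1e-10)
  expect_equal(drop(cnd$cov), 4, tolerance = 1e-6)
})
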