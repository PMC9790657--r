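test_that("transforms are exact and invertible, without silent clamping", {
  for (nm in c("identity", "log", "log10", "logit")) {
    tr <- transform_spec(nm)
    x <- 0.137
    expect_equal(transform_invert(transform_apply(x, tr), tr), x,
                 tolerance = 1e-12)
  }
  expect_equal(transform_apply(0.5, "logit"), 0)
  expect_equal(transform_apply(1000, "log10"), 3)
  expect_error(transform_apply(0, "log"), "domain")
  expect_error(transform_apply(1, "logit"), "domain")
})

test_that("covariate components evaluate their formulas", {
  expect_equal(covariate_linear(c(1, 1, 1), 1, c(2, 3, 4)), 10)
  expect_equal(covariate_linear(c(1, 2), 0, c(0, 0)), 0)
  expect_error(covariate_linear(c(1, 2), 0, c(1, 2, 3)), "slopes")

  # log10(exp(b3)) identity and HIV-free reduction
  expect_equal(covariate_gbd(1, 0, 0, c(0, 0, 2, 0)), 2 / log(10))
  LDI <- 5000; EDU <- 8
  expect_equal(covariate_gbd(LDI, EDU, 0, c(-0.3, -0.05, 1, 7)),
               (-0.3 * log(LDI) - 0.05 * EDU + 1) / log(10), tolerance = 1e-12)
  expect_equal(covariate_gbd(LDI, EDU, 0, c(-0.3, -0.05, 1, 99)),
               covariate_gbd(LDI, EDU, 0, c(-0.3, -0.05, 1, 0)))
  expect_error(covariate_gbd(1, 0, 0, c(0, 0, -50, 0)), NA)  # tiny but positive

  # piecewise form: flat below the cut-off, slope 1 in log units above
  expect_equal(covariate_piecewise_nmr(20, -0.4, -0.6, 30), -0.4)
  expect_equal(covariate_piecewise_nmr(exp(1) * 30, -0.4, -0.6, 30),
               -0.4 - 0.6, tolerance = 1e-12)
  lo <- covariate_piecewise_nmr(30 - 1e-9, -0.4, -0.6, 30)
  hi <- covariate_piecewise_nmr(30 + 1e-9, -0.4, -0.6, 30)
  expect_equal(lo, hi, tolerance = 1e-8)

  expect_equal(covariate_pca(c(1, 2, 3), c(0.5, -1, 2)), 0.5 - 2 + 6)
  expect_equal(covariate_pca(c(1, 1, 1), c(2, 3, 4)),
               covariate_linear(c(1, 1, 1), 0, c(2, 3, 4)))
})

test_that("linear systematic trend behaves as a centred line", {
  expect_equal(systematic_linear(15, -2, 0.3, 15), -2)
  expect_equal(systematic_linear(1:10, 4, 0, 5), rep(4, 10))
  expect_equal(diff(systematic_linear(1:10, 4, -0.2, 5)), rep(-0.2, 9))
})

test_that("logistic transition steps rise towards the asymptote", {
  expect_equal(systematic_logistic_step(0.9, 0.8, 0.3), qlogis(0.9))
  expect_gt(systematic_logistic_step(0.4, 0.8, 0.3), qlogis(0.4))
  for (eta in c(0.05, 0.2, 0.5, 0.79))
    expect_gt(systematic_logistic_step(eta, 0.8, 0.25), qlogis(eta))
  # the backstep inverts the forward step exactly
  for (eta in c(0.1, 0.3, 0.6)) {
    fwd <- plogis(systematic_logistic_step(eta, 0.8, 0.3))
    expect_equal(systematic_logistic_backstep(fwd, 0.8, 0.3), eta,
                 tolerance = 1e-12)
  }
})

test_that("noise-free logistic paths are monotone, bounded and anchored", {
  P <- 0.85; om <- 0.2; t_star <- 3; Omega <- qlogis(0.1)
  path <- logistic_path(Omega, P, om, t_star, eps = rep(0, 500))
  expect_equal(qlogis(path[t_star]), Omega, tolerance = 1e-10)
  expect_true(all(diff(path) >= -1e-14))
  expect_true(all(path <= P + 1e-12))
  expect_equal(path[500], P, tolerance = 1e-6)   # converges to the asymptote
})

test_that("trapezoid component rises, plateaus and falls", {
  f <- function(t) systematic_trapezoid(t, xi = 0.06, gamma0 = 5,
                                        lambda1 = 4, lambda2 = 6, lambda3 = 5)
  expect_equal(f(4), 0)
  expect_equal(f(7), 0.06 / 2)           # midpoint of the rise
  expect_equal(f(12), 0.06)              # plateau
  expect_equal(f(22), 0)                 # after gamma3 = 20
  expect_equal(f(17.5), 0.06 / 2)        # midpoint of the fall
})

test_that("component assembly is additive on the transformed scale", {
  # offsets-only model: eta = g1^{-1}(a)
  g <- toy_grid(6)
  mod <- tmmp_model(name = "off", transform = "log",
                    smoothing = list(basis = list(kind = "identity"),
                                     kernel = list(family = "iid", sigma = 1e-12),
                                     r = 0, constraint = "none", sigma = "fixed"))
  offs <- matrix(seq(-1, 0.5, length.out = 6), 1, 6,
                 dimnames = list("A", NULL))
  truth <- list(populations = "A")
  pat <- data.frame(population = "A", time = 1:3, source = "s", sampling_sd = 1e-9)
  sim <- generate_tmmp(mod, truth, pat, g, offsets = offs, seed = 1)
  expect_equal(sim$truth$eta["A", ], exp(offs["A", ]), tolerance = 1e-6)
})

test_that("latent-field assembly is additive and order-free on the transformed scale", {
  eps <- array(0, c(2, 1, 4))
  expect_equal(assemble_eta(eps, "log")[1, 1, ], rep(1, 4))
  # offsets-only model: eta = g1^{-1}(a)
  offs <- matrix(c(-1, 0, 0.5, 1), 1, 4)
  expect_equal(assemble_eta(eps, "log", offsets = offs)[2, 1, ], exp(offs[1, ]))
  # component order is immaterial
  g2 <- matrix(0.3, 1, 4); g3 <- matrix(-0.8, 1, 4)
  a1 <- assemble_eta(eps, "logit", g2 = g2, g3 = g3, offsets = offs)
  a2 <- assemble_eta(eps, "logit", g2 = g3, g3 = offs, offsets = g2)
  expect_equal(a1, a2, tolerance = 1e-12)
  # linear systematic trend with zero deviations: log eta exactly linear
  tr <- systematic_linear(1:4, -2, -0.1, 2)
  out <- assemble_eta(eps, "log", g3 = matrix(tr, 1, 4))
  expect_equal(diff(log(out[1, 1, ])), rep(-0.1, 3), tolerance = 1e-12)
  # recursive logistic assembly matches the path function directly
  ee <- array(rnorm(4, 0, 0.1), c(1, 1, 4))
  la <- list(Omega = qlogis(0.2), P_tilde = 0.8, omega = 0.3, t_star = 2)
  out2 <- assemble_eta(ee, "logit", logistic = la)
  expect_equal(out2[1, 1, ],
               logistic_path(qlogis(0.2), 0.8, 0.3, 2, ee[1, 1, ]))
})
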