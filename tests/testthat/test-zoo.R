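zoo_names <- c("b3_u5mr", "gbd_u5mr", "fpem_total_use", "igme_nmr",
               "bmat_mmr", "subnational_mortality")

test_that("every zoo entry validates and carries the documented structure", {
  g <- time_grid(1990, 20, 25)
  b3 <- zoo("b3_u5mr", g)
  expect_equal(b3$model$smoothing$r, 2)
  expect_equal(b3$model$transform, "log")
  expect_equal(b3$model$projection$method, "log_pooling")
  gbd <- zoo("gbd_u5mr", g)
  expect_equal(gbd$model$smoothing$kernel$family, "matern")
  expect_equal(gbd$model$smoothing$r, 0)
  expect_equal(gbd$model$transform, "log10")
  bmat <- zoo("bmat_mmr", g)
  expect_equal(bmat$model$smoothing$kernel$family, "arma11")
  # anchored at the first year of the grid (1990)
  expect_equal(bmat$model$smoothing$constraint$K0, 1L)
  nmr <- zoo("igme_nmr", g)
  K <- ncol(build_basis(basis_spec("bspline"), 1:20))
  expect_equal(nmr$model$smoothing$constraint$K0, seq_len(K))
  fp <- zoo("fpem_total_use", g)
  expect_equal(fp$model$systematic$kind, "logistic_transition")
  expect_equal(fp$model$hierarchy$wstar$levels, 3)
  expect_equal(fp$model$hierarchy$Pstar$levels, 1)
  expect_error(zoo("not_a_model"), "arg")
})

test_that("templates render completely and round trip their configuration", {
  g <- time_grid(1990, 20, 25)
  for (nm in zoo_names) {
    e <- zoo(nm, g)
    txt <- render_template(e)
    expect_true(grepl("Process model formula", txt))
    expect_true(grepl("Machine-readable configuration", txt))
    # every template field row is populated (value column never empty)
    rows <- regmatches(txt, gregexpr("\\| [^|]+ \\| *\\|", txt))[[1]]
    expect_length(rows, 0)
    m2 <- template_parse(unclass(txt))
    expect_equal(tmmp:::unclass_deep(e$model), tmmp:::unclass_deep(m2))
  }
  b3txt <- render_template(zoo("b3_u5mr", g))
  expect_true(grepl("\\| g1 \\| log \\|", b3txt))
  expect_true(grepl("Differencing order r \\| 2", b3txt))
  gbdtxt <- render_template(zoo("gbd_u5mr", g))
  expect_true(grepl("\\| Hierarchical \\| · \\|", gbdtxt))
})

test_that("simplified smoothed-residual offsets follow their formula", {
  g <- time_grid(1990, 3)
  cov <- expand.grid(population = c("A", "B"), time = 1:3)
  cov$LDI <- 5000; cov$EDU <- 6; cov$HIV <- 0
  betas <- c(-0.3, -0.05, 1, 0)
  eta_hat <- 10^covariate_gbd(5000, 6, 0, betas)
  # all residuals zero -> offsets all zero
  obs0 <- data.frame(population = "A", time = 1:3, value = eta_hat)
  r0 <- gbd_offsets_simplified(obs0, cov, g, betas = betas)
  expect_equal(max(abs(r0$offsets)), 0, tolerance = 1e-12)
  # single population, constant residual: exact log10 adjustment
  obs1 <- data.frame(population = "A", time = 1:3, value = eta_hat + 0.01)
  r1 <- gbd_offsets_simplified(obs1, cov, g, betas = betas)
  expect_equal(unique(round(unname(r1$offsets["A", ]), 10)),
               round(log10(eta_hat + 0.01) - log10(eta_hat), 10))
  # two-population toy: hand-computed spatial/temporal weighting
  obs2 <- data.frame(population = c("A", "B"), time = c(1, 1),
                     value = eta_hat + c(0.02, -0.01))
  r2 <- gbd_offsets_simplified(obs2, cov, g, betas = betas,
                               region_map = c(A = "r", B = "r"),
                               temporal_bandwidth = 2)
  w <- c(0.99, 0.01)
  rhatA <- sum(w * c(0.02, -0.01)) / sum(w)
  expect_equal(unname(r2$offsets["A", 1]),
               log10(eta_hat + rhatA) - log10(eta_hat), tolerance = 1e-10)
  # temporal kernel: at t = 3 both residuals (at t = 1) get the same decay,
  # so the weighted average is unchanged
  expect_equal(unname(r2$offsets["A", 3]), unname(r2$offsets["A", 1]),
               tolerance = 1e-10)
})
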