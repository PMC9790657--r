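test_that("the generator is deterministic and order-invariant", {
  pops <- c("A", "B", "C")
  mod <- b3_family_model()
  truth <- b3_family_truth(pops)
  g <- time_grid(1990, 30)
  pat <- missingness_pattern(pops, g, sources = c(s = 0.1), seed = 2)
  s1 <- generate_tmmp(mod, truth, pat, g, relative_sd = TRUE, seed = 9)
  s2 <- generate_tmmp(mod, truth, pat, g, relative_sd = TRUE, seed = 9)
  expect_identical(s1$observations, s2$observations)
  expect_identical(s1$truth$eta, s2$truth$eta)
  # per-population substreams: dropping a population leaves the others alone
  pat_b <- pat[pat$population != "B", ]
  s3 <- generate_tmmp(mod, truth, pat_b, g, relative_sd = TRUE, seed = 9)
  expect_equal(s3$truth$eta["A", ], s1$truth$eta["A", ])
  expect_equal(s3$observations$value[s3$observations$population == "A"],
               s1$observations$value[s1$observations$population == "A"])
})

test_that("a degenerate generator lays observations on the systematic line", {
  pops <- "A"
  mod <- b3_family_model()
  mod$smoothing$kernel$sigma <- 1e-12
  truth <- list(alpha0 = c(A = log(0.06)), alpha1 = c(A = -0.03),
                sigma_delta = c(A = 1e-12))
  g <- time_grid(1990, 30)
  pat <- data.frame(population = "A", time = c(3, 10, 22), source = "s",
                    sampling_sd = 1e-12)
  sim <- generate_tmmp(mod, truth, pat, g, seed = 1)
  line <- exp(log(0.06) - 0.03 * (c(3, 10, 22) - 15))
  expect_equal(sim$observations$value, line, tolerance = 1e-6)
})

test_that("observation noise has the declared moments", {
  mod <- conjugate_toy_model()
  g <- toy_grid(2)
  pat <- data.frame(population = "A", time = rep(1, 4000), source = "s",
                    sampling_sd = 0.37)
  truth <- list(populations = "A", sigma_delta = 1)
  sim <- generate_tmmp(mod, truth, pat, g, seed = 3)
  expect_equal(sd(sim$observations$value), 0.37, tolerance = 0.03)
})

test_that("unobserved populations still get a latent trajectory", {
  pops <- c("A", "B")
  mod <- b3_family_model()
  truth <- b3_family_truth(pops)
  g <- time_grid(1990, 30)
  pat <- missingness_pattern(pops, g, sources = c(s = 0.1),
                             unobserved = "B", seed = 2)
  sim <- generate_tmmp(mod, truth, pat, g, relative_sd = TRUE, seed = 4)
  expect_equal(sum(sim$observations$population == "B"), 0)
  expect_true(all(is.finite(sim$truth$eta["B", ])))
})

test_that("the default scenario has the documented shape", {
  pops <- paste0("P", 1:15)
  g <- time_grid(1990, 30)
  pat <- missingness_pattern(pops, g, unobserved = "P15", seed = 1)
  expect_equal(sort(unique(pat$population)), sort(setdiff(pops, "P15")))
  per_pop <- table(pat$population)
  expect_true(all(per_pop == round(0.4 * 30)))
  expect_setequal(unique(pat$source), c("survey", "vr"))
  r <- unique(pat$sampling_sd[pat$source == "survey"]) /
    unique(pat$sampling_sd[pat$source == "vr"])
  expect_equal(r, 3)
})

test_that("oracle recovery on dense noiseless data is essentially exact", {
  # all parameters fixed to truth; only the latent field is estimated
  g <- toy_grid(5)
  mod <- conjugate_toy_model(sigma_delta = 1, draws = 300, warmup = 100)
  pat <- data.frame(population = "A", time = rep(1:5, each = 4), source = "s",
                    sampling_sd = 1e-4)
  truth <- list(populations = "A", sigma_delta = 1)
  sim <- generate_tmmp(mod, truth, pat, g, seed = 6)
  fit <- fit_tmmp(mod, sim$observations, g, seed = 7)
  est <- apply(fit$draws$eta[, , 1, ], 3, mean)
  expect_equal(est, unname(sim$truth$eta["A", ]), tolerance = 1e-3)
})

test_that("more observation noise widens the posterior", {
  pops <- c("A", "B")
  mod <- b3_family_model(draws = 300, warmup = 300)
  truth <- b3_family_truth(pops)
  g <- time_grid(1990, 30)
  width <- sapply(c(0.05, 0.2), function(cv) {
    pat <- missingness_pattern(pops, g, sources = c(s = cv), seed = 3)
    sim <- generate_tmmp(mod, truth, pat, g, relative_sd = TRUE, seed = 8)
    fit <- suppressWarnings(fit_tmmp(mod, sim$observations, g, seed = 9))
    mean(apply(log(fit$draws$eta), c(3, 4), sd))
  })
  expect_gt(width[2], width[1])
})
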