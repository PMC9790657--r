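test_that("bounded transform maps the real line onto (lo, hi)", {
  expect_equal(bounded_transform(0, 0.5, 1), 0.75)
  expect_equal(bounded_transform(40, 0.5, 1), 1, tolerance = 1e-12)
  expect_equal(bounded_transform(-40, 0.01, 0.5), 0.01, tolerance = 1e-12)
  expect_equal(bounded_transform_inv(bounded_transform(1.3, 0.01, 0.5), 0.01, 0.5),
               1.3, tolerance = 1e-10)
  expect_error(bounded_transform(0, 1, 0.5), "lo < hi")
})

test_that("one-level hierarchies reduce to a plain normal prior", {
  spec <- hierarchy_spec("gamma", strategy = "hierarchical", levels = 1)
  pops <- c("A", "B", "C")
  vals <- c(A = 0.1, B = -0.4, C = 0.2)
  ld <- hierarchy_logdens(spec, pops, vals, level_means = list(0.05), scales = 0.3)
  expect_equal(ld, sum(dnorm(vals, 0.05, 0.3, log = TRUE)))
  # degenerate case: one population, one level
  ld1 <- hierarchy_logdens(spec, "A", c(A = 0.1), list(0.05), 0.3)
  expect_equal(ld1, dnorm(0.1, 0.05, 0.3, log = TRUE))
})

test_that("three-level hierarchies accumulate every level's density", {
  grp <- data.frame(population = c("A", "B", "C", "D"),
                    subregion = c("s1", "s1", "s2", "s2"),
                    region = c("r1", "r1", "r2", "r2"))
  spec <- hierarchy_spec("omega", strategy = "hierarchical", levels = 3,
                         groupings = grp)
  vals <- c(A = 0.1, B = 0.2, C = -0.1, D = 0)
  sub_means <- c(s1 = 0.15, s2 = -0.05)
  reg_means <- c(r1 = 0.1, r2 = 0)
  ld <- hierarchy_logdens(spec, grp$population, vals,
                          level_means = list(sub_means, reg_means, 0.02),
                          scales = c(0.1, 0.2, 0.5))
  manual <- sum(dnorm(vals, sub_means[c("s1", "s1", "s2", "s2")], 0.1, log = TRUE)) +
    sum(dnorm(sub_means, reg_means[c("r1", "r2")], 0.2, log = TRUE)) +
    sum(dnorm(reg_means, 0.02, 0.5, log = TRUE))
  expect_equal(ld, manual)
  expect_error(hierarchy_logdens(spec, c("A", "Z"), c(A = 1, Z = 2),
                                 list(sub_means, reg_means, 0), c(0.1, 0.2, 0.5)),
               "Z")
})

test_that("truncated-normal population levels renormalize and bound", {
  spec <- hierarchy_spec("lambda", strategy = "hierarchical", levels = 1,
                         truncation = c(-1, 2))
  vals <- c(A = 0.4, B = -0.6)
  ld <- hierarchy_logdens(spec, c("A", "B"), vals, list(0), 0.5)
  manual <- sum(dnorm(vals, 0, 0.5, log = TRUE) -
                  log(pnorm(2, 0, 0.5) - pnorm(-1, 0, 0.5)))
  expect_equal(ld, manual)
  expect_equal(hierarchy_logdens(spec, "A", c(A = 2.5), list(0), 0.5), -Inf)
  # implied bmat-style scale range: sigma_c = sigma_w (1 + lambda) in (0, 3 sigma_w)
  sw <- 0.07
  expect_true(all(sw * (1 + c(-0.999, 1.999)) > 0 &
                    sw * (1 + c(-0.999, 1.999)) < 3 * sw))
})

test_that("hierarchical shrinkage pulls data-poor populations towards the group", {
  # two populations, one data-rich and one with a single noisy observation;
  # the poor population's posterior mean must land between its own
  # observation (the flat-prior estimate) and the group mean
  g <- toy_grid(4)
  mod <- tmmp_model(
    name = "shrink", transform = "identity",
    covariate = list(kind = "linear", columns = character(0), strategy = "fixed",
                     intercept = "hierarchical"),
    smoothing = list(basis = list(kind = "identity"),
                     kernel = list(family = "iid", sigma = 1e-6),
                     r = 0, constraint = "none", sigma = "fixed"),
    data_model = list(family = "normal", variance = "fixed"),
    hierarchy = list(beta0 = list(strategy = "hierarchical", levels = 1)),
    inference = list(seed = 1, chains = 2, draws = 600, warmup = 400))
  rich <- data.frame(population = "R", time = 1:4, value = c(2.0, 2.1, 1.9, 2.0),
                     sampling_sd = 0.05, source = "s", denominator = NA_integer_)
  poor <- data.frame(population = "P", time = 2, value = 3.5,
                     sampling_sd = 1.5, source = "s", denominator = NA_integer_)
  fit <- suppressWarnings(fit_tmmp(mod, rbind(rich, poor), g, seed = 3))
  flat <- tmmp:::flatten_draws(fit)
  post_poor <- mean(flat[, "beta0[P]"])
  group_mean <- mean(flat[, "mu_w[beta0]"])
  expect_lt(post_poor, 3.5)          # pulled below its own MLE
  expect_gt(post_poor, group_mean - 0.2)  # but not past the group mean
})
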