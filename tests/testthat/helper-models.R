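# Shared fixtures: small models and synthetic scenarios built in code.

toy_grid <- function(T_est = 5, T_star = T_est) time_grid(2000, T_est, T_star)

# one-population conjugate toy: identity transform, iid smoothing, fixed
# observation sds -> analytic normal-normal posterior per time point
conjugate_toy_model <- function(sigma_delta = 2, chains = 2, draws = 800,
                                warmup = 400) {
  tmmp_model(
    name = "conjugate_toy", transform = "identity",
    smoothing = list(basis = list(kind = "identity"),
                     kernel = list(family = "iid", sigma = sigma_delta),
                     r = 0, constraint = "none", sigma = "fixed"),
    data_model = list(family = "normal", variance = "fixed"),
    inference = list(seed = 1, chains = chains, draws = draws, warmup = warmup))
}

conjugate_toy_data <- function(y, sd = 1) {
  data.frame(population = "A", time = seq_along(y), value = y,
             sampling_sd = sd, source = "s", denominator = NA_integer_)
}

# B3-style family used in recovery experiments: log scale, linear systematic
# trend, spline RW(2) smoothing, hierarchical smoothing scales
b3_family_model <- function(draws = 600, warmup = 600) {
  tmmp_model(
    name = "b3_family", transform = "log",
    systematic = list(kind = "linear_trend", strategy = "prior", t_star = 15),
    smoothing = list(basis = list(kind = "bspline", degree = 3, knot_spacing = 2.5),
                     kernel = list(family = "iid", sigma = 0.05),
                     r = 2, constraint = "minimum_norm", sigma = "hierarchical"),
    data_model = list(family = "normal", variance = "fixed"),
    priors = list(alpha0 = list(dist = "normal", mean = 0, sd = 5),
                  alpha1 = list(dist = "normal", mean = 0, sd = 1)),
    inference = list(seed = 1, chains = 2, draws = draws, warmup = warmup))
}

b3_family_truth <- function(pops, seed = 42) {
  set.seed(seed)
  list(alpha0 = setNames(log(runif(length(pops), 0.02, 0.15)), pops),
       alpha1 = setNames(runif(length(pops), -0.06, -0.01), pops),
       sigma_delta = setNames(runif(length(pops), 0.02, 0.08), pops))
}
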