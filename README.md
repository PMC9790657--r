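# tmmp — temporal models for multiple populations

`tmmp` estimates and projects latent temporal trends of demographic and
global-health indicators (under-five mortality, neonatal and maternal
mortality, contraceptive use, age-specific death rates, ...) observed
noisily, sparsely and irregularly across many populations — the situation
faced by anyone producing country-level indicator estimates from a mix of
surveys, censuses and vital registration.

Models are assembled from two parts. A **data model** links each observation
to the latent indicator `eta[c, t]`:

    y_i ~ pi(y_i | eta[c_i, t_i], theta)        (normal, logit-normal,
                                                 binomial, negative binomial)

and a **process model** describes the indicator's evolution on a transformed
scale as a sum of interpretable components:

    g1(eta[c,t]) = g2(X[c,t], beta)      covariate component
                 + g3(t, eta, alpha_c)   systematic component
                 + a[c,t]                fixed offset
                 + eps[c,t]              stochastic smoothing component

with `eps_c = B_c delta_c` and `diff^r(delta_c) ~ N(0, Sigma(kappa))` —
B-spline or identity bases, AR(1) / squared-exponential / Matérn /
ARMA(1,1) / independent kernels, differencing order `r` in {0, 1, 2} under
explicit anchoring constraints. Parameters are fixed, given priors, or
shared across populations through nested normal hierarchies. Fitting is by
an exact Gibbs/MCMC scheme (conjugate and Gaussianized joint updates,
elliptical slice sampling, interweaved scale updates); projections extend
the estimation model through closed-form Gaussian conditionals, or by
logarithmic pooling of second-order differences towards a global
distribution of rates of change.

The package also ships a synthetic-data generator with parameter-recovery
scoring, six ready-made case-study model configurations (`zoo()`), a
standardized model-reporting template renderer, and a thin command-line
front end (`inst/cli/tmmp`).

## Worked example

Simulate a sparse 5-population dataset from a spline-RW(2) mortality model
with known truth, fit it, and project with logarithmic pooling:

```r
library(tmmp)

grid <- time_grid(1990, 20, 25)            # estimate 1990-2009, project to 2014
entry <- zoo("b3_u5mr", grid)              # log scale, linear trend, RW(2) splines
scen <- entry$scenario(seed = 3)           # synthetic observations + retained truth

fit <- fit_tmmp(entry$model, scen$observations, grid, seed = 7)
head(eta_summary(fit), 3)
#>   population time year    mean    q2.5     q50  q97.5
#> 1         C1    1 1990 0.09032 0.06823 0.08764 0.1290
#> 2         C1    2 1991 0.08574 0.06835 0.08425 0.1136
#> 3         C1    3 1992 0.08154 0.06815 0.08066 0.1004

proj <- project_tmmp(fit, method = "log_pooling", W = 0.5, seed = 1)
round(apply(proj$eta[, , "C1", ], 3, quantile, c(.025, .5, .975)), 4)
#>         [,1]   [,2]   [,3]   [,4]   [,5]
#> 2.5%  0.0542 0.0530 0.0518 0.0503 0.0480
#> 50%   0.0607 0.0616 0.0625 0.0633 0.0640
#> 97.5% 0.0691 0.0744 0.0812 0.0898 0.1012
```

The first table is the posterior of the latent indicator on its natural
scale (here U5MR per live birth) over the estimation period: for 1990 in
population C1 the point estimate is 0.090 with 95% interval (0.068, 0.129),
and the truth used by the generator (`scen$truth$eta["C1", 1]`) is 0.0934 —
inside the interval. The projection block shows the five projected years:
uncertainty widens with the horizon as the pooled second-order differences
accumulate. `render_template(entry)` prints the model as a standardized
comparison table with a machine-readable YAML appendix, and
`recovery_experiment()` scores bias, RMSE and interval coverage over
repeated simulate-fit cycles.

(Numbers above are the output of this exact code; MCMC draws are seeded and
reproducible for a fixed library version.)

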