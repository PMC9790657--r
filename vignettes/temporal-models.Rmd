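---
title: "Temporal models for multiple populations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal models for multiple populations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmmp)
```

## The estimation problem

Demographic and global-health indicators — under-five mortality, neonatal
mortality, maternal mortality, contraceptive use, age-specific death rates —
must be estimated for many populations at once from data that are sparse,
irregular and noisy: a country may have a handful of surveys decades apart,
several conflicting sources for the same year, or no data at all. The
indicator of interest, $\eta_{c,t}$ for population $c$ and time $t$, is never
observed directly; observations $y_i$ are noisy, possibly biased measurements
of it.

`tmmp` implements a composable model class for this setting built on one
structural distinction:

* a **data model** links observations to the latent indicator,
  $y_i \sim \pi(y_i \mid \eta_{c[i],t[i]}, \theta)$, and
* a **process model** describes the indicator's evolution on a transformed
  scale,
  $$g_1(\eta_{c,t}) \;=\; \underbrace{g_2(X_{c,t},\beta)}_{\text{covariates}}
    + \underbrace{g_3(t, \eta_{c,s\ne t}, \alpha_c)}_{\text{systematic}}
    + \underbrace{a_{c,t}}_{\text{offset}}
    + \underbrace{\epsilon_{c,t}}_{\text{smoothing}}.$$

Because the latent trend is modelled at every time point, missing data are
handled naturally, and populations with few or no observations borrow
strength through hierarchical priors and through the structure of the process
model itself.

## Process-model components

**Transforms** $g_1$: identity, $\log$, $\log_{10}$ or logit. All components
act additively on the transformed scale; the declared natural scale of the
indicator (per 1, per 1000, ...) is never rescaled implicitly.

**Covariate components** $g_2$: four forms are built in — a linear
regression with population intercepts; the non-linear under-five-mortality
form $\log_{10}\{\exp(\beta_1\log\mathrm{LDI} + \beta_2\mathrm{EDU} +
\beta_3) + \beta_4\,\mathrm{HIV}\}$; a piecewise-linear function of
$\log\mathrm{U5MR}$ with a cut-off; and a principal-component regression
with time-varying loadings for age-schedule models.

**Systematic components** $g_3$: a population-specific linear trend
$\alpha_{c,0} + \alpha_{c,1}(t - t^*_c)$ centred at the middle of the
observation period (centring decorrelates intercept and slope); a logistic
transition that moves the indicator in an S-shape towards an asymptote
$\tilde P_c$ at rate $\omega_c$, anchored at level $\Omega_c$ in a reference
year; and a trapezoid pulse. The logistic transition is recursive: the level
at $t$ depends on the realized level at $t-1$. Forward of the reference year
the one-step map
$\eta_t = \tilde P\,\mathrm{logit}^{-1}\{\mathrm{logit}(\eta_{t-1}/\tilde P)
+ \omega\}$ applies; backwards we invert this map exactly, a choice we make
explicit because only the forward form is standard. By default the recursion
carries the realized level including that period's smoothing deviation, so
deviations act on the rate of change and accumulate over the projection
horizon; `include_eps_in_recursion = FALSE` switches to a systematic-only
recursion for sensitivity analysis.

**Offsets** $a_{c,t}$ are fixed, externally computed additive adjustments on
the transformed scale (default zero). `gbd_offsets_simplified()` builds the
smoothed-residual offsets used by the GBD-style mortality configuration: a
fixed-coefficient covariate fit, kernel-weighted residual smoothing with
spatial weights 0.99 (within population) versus 0.01 (same region) and a
Gaussian temporal kernel whose bandwidth the user must choose (the original
procedure's temporal weighting is not public), and the
$\log_{10}(\hat\eta + \hat r) - \log_{10}(\hat\eta)$ map. The original
multi-stage bias adjustment with per-source random effects is deliberately
not reproduced; this simplification is stated on the configuration itself.

**Smoothing component.** $\epsilon_c = B_c\,\delta_c$ with
$\Delta^r \delta_c \sim N(0, \Sigma_c)$,
$\Sigma_{c,t_1,t_2} = s(|t_1 - t_2|, \kappa)$. The basis is the identity or
cubic B-splines with evenly spaced knots (default spacing 2.5 grid units);
exterior knots continue the spacing rather than being clamped, so extending
the basis into the projection period appends columns without altering
existing ones. Kernels: AR(1), squared exponential, Matérn (via the modified
Bessel function, with exact shortcuts at $\nu = 1/2, 3/2, 5/2$), stationary
ARMA(1,1) parametrized by its stationary standard deviation, and independent
increments. For $r > 0$ the level of $\delta$ is unidentified and must be
anchored. Two constraint modes are provided because the literature states
both and they are not identical: `minimum_norm` returns the solution
$D'(DD')^{-1}\gamma$ orthogonal to the null space of the differencing
matrix, and `anchored` solves the declared equations exactly (e.g. a
reference coefficient set to zero together with first differences summing to
zero). Each mode's own contract is what the tests assert. We orient $D$ as
$(K-r)\times K$ so that $D\delta = \Delta^r\delta$ type-checks.

## Data models

Normal, logit-normal, binomial and negative-binomial likelihoods, with
conditional independence across records. Observation variances come from the
per-record `sampling_sd` column when present (design-based sampling errors);
otherwise one standard deviation is estimated globally or per source label.
The negative binomial uses mean $n_i\eta$ and overdispersion $\phi$ with
variance $\mu(1 + \mu/\phi)$ — stated prominently because this
parametrization is a known dialect hazard. Systematic source biases are out
of scope.

## Parameter estimation strategies

Each parameter can be **fixed** (with a recorded provenance note),
given a **prior**, or modelled **hierarchically** with normal levels nested
population → subregion → region → world through user-supplied groupings;
bounded parameters (such as a logistic asymptote in $(0.5, 1)$ and rate in
$(0.01, 0.5)$) are transformed to the real line first. Default weak priors,
overridable per parameter in the configuration: $N(0, 10^2)$ for unbounded
locations on the transformed scale, half-normal$(0,5^2)$ for
free-standing scales, $U(0,1)$ for autoregressive parameters, $U(-1,0)$ for
the moving-average parameter, and half-normal$(0,1^2)$ for every
*hierarchy-level* scale — the spread of populations around group means and
of log-scales around their mean. Hierarchy-level spreads act on transformed
(log/logit) parameter spaces where cross-population variation is $O(1)$; a
5-sd half-normal would put real mass on spreads beyond $e^{10}$, letting a
weakly-identified bounded parameter saturate its bounds on a near-flat prior
plateau. For the same reason the world mean of a log-smoothing-scale
hierarchy defaults to $N(\log 0.05, 2^2)$ — centred on few-percent-per-year
deviations and spanning about two orders of magnitude each way — rather than
the sd-10 location default, which on a log scale is improper-like. The
Bmat-style smoothing-scale hierarchy
$\sigma_{\delta,c} = \sigma_{\delta,w}(1+\lambda_c)$ with
$\lambda_c \sim N(0,\sigma_\lambda^2)$ truncated to $(-1,2)$ is built in;
the unstated world-level prior for $\sigma_{\delta,w}$ defaults to the
half-normal and is flagged as a package choice.

## Posterior computation

The joint posterior of all coefficients, the hierarchy and the latent field
is sampled by a Gibbs scheme composed entirely of exact MCMC moves. We chose
this over a gradient-based probabilistic-programming backend so the sampler
could exploit the class's conditional structure directly:

* **Coefficient blocks.** For linear-mean models under normal or
  logit-normal data models, all coupled coefficient blocks — per-population
  trend/intercept/smoothing coefficients, shared regression slopes,
  hierarchy location means (held as one-dimensional blocks), and
  RW(2)-smoothed component means — are updated jointly by an independence
  Metropolis–Hastings step whose proposal is the conjugate posterior of the
  Gaussianized working model $g_1(y_i) \sim N(z_i, (s_i\,g_1'(y_i))^2)$.
  When the transform matches the data model (identity/normal,
  logit/logit-normal) the working model is exact and the step is plain Gibbs;
  otherwise the exact likelihood enters through the MH correction and an
  elliptical-slice refinement pass follows. Logistic-transition models are
  nonlinear in the recursion and use elliptical slice sampling throughout,
  with coordinate refreshes for the three transition parameters.
* **Smoothing coefficients** are stored non-centred
  ($\gamma_c = \sigma_c L u_c$, $u_c \sim N(0, I)$, $L$ the unit-scale kernel
  Cholesky factor), so anchoring constraints hold exactly in every draw and
  the scale enters the likelihood rather than the prior.
* **Scalar hyperparameters** use stepping-out slice sampling, each followed
  by an interweaved second update in the complementary parametrization:
  scales are re-sampled holding $\gamma$ fixed (rescaling $u$), kernel shape
  parameters holding $\gamma$ fixed (re-factorizing $L$), hierarchy means by
  translating mean and children together, and scale-of-scale parameters by
  rescaling the spread of the child scales. Smoothing scales additionally
  get a collapsed move — a random-walk proposal on the scale paired with a
  redraw of the affected coefficient block(s) from the working-model
  conditional at the proposed scale, accepted jointly — which crosses the
  scale/coefficient funnel that single-site updates cannot. These moves are
  what removes the funnels and ridges that otherwise dominate hierarchical
  variance parameters; without them centred and non-centred updates each
  stall on one side of the geometry, which is also why we did not adopt a
  single global non-centred parametrization.
* **Logistic-transition extras.** The transition parameters admit exact
  likelihood-invariant updates: the anchor level trades one-for-one with
  the reference-year deviation (a 1-d Gaussian conditional), and the
  asymptote and rate can be moved holding the realized logit path fixed,
  re-deriving the deviations by inverting the recursion (a unit-Jacobian
  change of variables, so the conditional is prior times the standard-normal
  density of the implied deviations). The whole path is refreshed by a
  Taylor-expanded MH step in path space, where the logit-normal likelihood
  is Gaussian and diagonal and the deviation prior is linearized through the
  banded derivative of the recursion inverse, with an exact MH correction.

Populations without observations receive latent-field draws from their
prior (prior-predictive behaviour). Convergence is summarized by split-
$\hat R$ and autocorrelation-based effective sample sizes for every stored
parameter and latent-field cell; any $\hat R > 1.05$ attaches a warning to
the returned object rather than failing silently. Draws are reproducible for
a fixed (seed, configuration, library version) triple; per-population random
streams are keyed by hashed substreams so results do not depend on
population ordering.

## Projections

The default projection extends the estimation model: per posterior draw the
basis is extended at the original knot spacing, the projection-period
differenced coefficients are drawn from their closed-form Gaussian
conditional given the estimation-period differences (computed at unit kernel
scale and rescaled, so only the correlation shape is factorized), levels are
rebuilt through the difference recursion, and the process model is
re-assembled; covariates must be supplied through the projection horizon —
projecting covariates themselves is explicitly out of scope. For stationary
($r=0$) smoothers the projected deviations revert to zero at the kernel's
correlation decay and the variance approaches the stationary variance; for
random-walk-type smoothers the projected variance grows with the horizon.

The logarithmic-pooling variant for RW(2) spline models draws future second
differences $\gamma_k \sim N(\Gamma_k, \Theta_k)$ with
$\Gamma_k = W G + (1-W)\Gamma_{k-1}$ and
$\Theta_k = W V + (1-W)\Theta_{k-1}$, seeded at the last estimated second
difference and the population's smoothing variance. We implement the moment
recursions deterministically (draws independent across $k$): with the
horizon the distribution of rates of change then converges geometrically to
the global $(G, V)$, which is the stated purpose of the construction, and at
$W=0$ (zero seed) it reduces to the default extrapolation law. Feeding each
realized draw back into the mean recursion instead would turn the second
differences into a random walk and destroy both properties, so we document
this as a deliberate reading of an ambiguous recursion. $G$ and $V$ default
to the median and variance of the posterior-median differenced coefficients
pooled across all populations and coefficient indices (estimation-period
edge coefficients included; both choices can be overridden), and $W$ is a
fixed input — the validation exercise that would choose it is not part of
the package.

## Synthetic data and recovery experiments

`generate_tmmp()` draws the latent field and observations from a fully
specified model with known truth, using direct forward simulation (never the
posterior-sampling code path, so recovery experiments are not circular).
The default missingness scenario reflects the problem statement the class
addresses: 15 populations, 30 time points, 40% of population-years observed,
two source types with a 1:3 sampling-sd ratio, and one fully unobserved
population. Sampling sds can be declared relative (coefficients of
variation), which we use in all log-scale scenarios: design-based sampling
errors scale with the level of an indicator, and absolute errors spanning
populations whose levels differ by a factor of 30 would otherwise routinely
produce negative observations under the normal data model.

`recovery_experiment()` repeats generate → fit → score and reports bias,
RMSE and empirical 95%-interval coverage with Monte-Carlo standard errors;
fits with $\hat R > 1.05$ are counted and flagged, never dropped. The
generator emulates sparse multi-source noise but not survey-design effects
(clustering, stratification), source-specific biases, or covariate
measurement error — passing recovery tests therefore demonstrates
self-consistency of estimation under the model's own assumptions, not
robustness to real-data pathologies.

Problem sizes used by the shipped tests and the acceptance script — chosen
so a full run completes comfortably on a single core — are: the conjugate
toy at $T=5$ with $4\times1000$ draws; recovery at $C=10$, $T=30$, 6–10
replicates at $2\times500$ draws; and the six case-study scenarios at
$C\approx5$ (the subnational model uses 3 areas × 3 age groups), $T=20$
with 5 projection years and $2\times500$–$1200$ draws. The same machinery
scales to the 50-replicate recovery design by raising `n_sims`.

## Case-study configurations and reporting templates

`zoo()` ships six ready configurations: the spline-RW(2) under-five
mortality model with logarithmic-pooling projections; the covariate-driven
log10 mortality model with fixed Matérn smoothing and file-based offsets;
the logistic contraceptive-use transition with AR(1) deviations and 1/3/3-
level hierarchies; the neonatal-ratio model with a piecewise covariate and
sum-to-zero RW(1) splines; the maternal-mortality regression with anchored
ARMA(1,1) deviations and truncated-normal scale multipliers; and the
subnational age-specific mortality model with principal-component loadings
shrunk towards RW(2)-smoothed means. Numeric coefficients shipped with the
entries are illustrative placeholders for synthetic use, not published
estimates, and each entry's `note` records its documented simplifications.
`render_template()` prints any configuration as a standardized
model-comparison table (indicator, transform, formula, each component,
smoothing structure, projection rule, estimation strategies) with a
machine-readable YAML appendix that `template_parse()` round-trips back to
the configuration.

## Numerical choices and degenerate inputs

Covariance matrices receive a one-time diagonal jitter of
$10^{-10}\,s(0,\kappa)$ before factorization and fail loudly if still not
positive semidefinite. Transform domain violations raise errors naming the
offending value — there is no silent clamping. Observations with values
outside the transform's domain (possible under the normal data model, e.g. a
negative measured rate) are kept in the exact likelihood but excluded from
the Gaussianized proposal. Smoothed-residual offsets that would make
$\hat\eta + \hat r$ nonpositive are floored at $-0.9\hat\eta$ with a
warning. Empty data sections, zero-draw requests and an empty projection
horizon are all valid inputs returning empty results.

## Known limitations

One MCMC backend; no INLA/TMB or variational alternatives. No spatial
(CAR/ICAR) or other cross-population correlation structures beyond the
hierarchy. No measurement-bias adjustment or correlated observation errors.
Covariates must be supplied over the full projection horizon. The
subnational model's component-mean variances are constant over time. Kernel
hyperparameter estimation is limited to the scale plus the shape parameters
listed in `smoothing$estimate`; cross-parameter priors are not supported.
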