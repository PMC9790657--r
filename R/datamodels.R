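#' Data model specification
#'
#' The data model gives each observation's log-likelihood contribution given
#' the latent indicator, assuming conditional independence across records.
#' Four families are supported:
#'
#' * `normal`: `y ~ N(eta, sd^2)` on the indicator's natural scale.
#' * `logit_normal`: `qlogis(y) ~ N(qlogis(eta), sd^2)`; `y, eta` in (0, 1).
#' * `binomial`: `y ~ Binom(n, eta)`; `eta` in (0, 1).
#' * `negative_binomial`: mean `n * eta`, overdispersion `phi`, variance
#'   `mu * (1 + mu / phi)` (i.e. `dnbinom(mu = n * eta, size = phi)`). This
#'   parametrization matters: as `phi -> Inf` the family approaches the
#'   Poisson with mean `n * eta`.
#'
#' Observation variances come from the per-record `sampling_sd` column when
#' present (fixed design-based sampling errors); otherwise a single sd is
#' used, either global or per source label, supplied at evaluation time (and
#' typically estimated as a model parameter).
#'
#' @param family Family name.
#' @param variance `"fixed"` (per-record `sampling_sd` required), `"global"`
#'   (one estimated sd) or `"per_source"` (one per source label). Ignored for
#'   the counting families.
#' @param phi Overdispersion for `negative_binomial` (fixed value, or `NULL`
#'   if supplied at evaluation time).
#' @return An object of class `tmmp_datamodel`.
#' @export
data_model_spec <- function(family = c("normal", "logit_normal", "binomial", "negative_binomial"),
                            variance = c("fixed", "global", "per_source"),
                            phi = NULL) {
  family <- match.arg(family)
  variance <- match.arg(variance)
  if (!is.null(phi)) check_scalar(phi, "phi", 0, open_lo = TRUE)
  structure(list(family = family, variance = variance, phi = phi),
            class = "tmmp_datamodel")
}

#' Per-record log-likelihood
#'
#' @param spec A [data_model_spec()].
#' @param y Observed value(s).
#' @param eta Latent indicator value(s) at the record's population-time.
#' @param sd Observation sd (normal / logit-normal families).
#' @param n Denominator (binomial / negative binomial).
#' @param phi Overdispersion (negative binomial; overrides the spec's value).
#' @return Log-density / log-mass, vectorized.
#' @export
loglik_record <- function(spec, y, eta, sd = NULL, n = NULL, phi = NULL) {
  switch(spec$family,
    normal = {
      if (is.null(sd) || any(sd <= 0)) stop_tmmp("normal data model needs sd > 0")
      stats::dnorm(y, eta, sd, log = TRUE)
    },
    logit_normal = {
      if (is.null(sd) || any(sd <= 0)) stop_tmmp("logit-normal data model needs sd > 0")
      if (any(y <= 0 | y >= 1)) stop_tmmp("logit-normal observations must lie in (0, 1)")
      if (any(eta <= 0 | eta >= 1)) stop_tmmp("logit-normal latent values must lie in (0, 1)")
      stats::dnorm(stats::qlogis(y), stats::qlogis(eta), sd, log = TRUE) -
        log(y * (1 - y))
    },
    binomial = {
      if (is.null(n)) stop_tmmp("binomial data model needs a denominator n")
      if (any(eta <= 0 | eta >= 1)) stop_tmmp("binomial probability must lie in (0, 1)")
      stats::dbinom(y, n, eta, log = TRUE)
    },
    negative_binomial = {
      if (is.null(n)) stop_tmmp("negative binomial data model needs a denominator n")
      phi <- phi %||% spec$phi
      if (is.null(phi)) stop_tmmp("negative binomial data model needs overdispersion phi")
      if (any(eta <= 0)) stop_tmmp("negative binomial mean must be positive")
      stats::dnbinom(y, size = phi, mu = n * eta, log = TRUE)
    })
}

#' Total data log-likelihood of an observation table
#'
#' Sums per-record contributions (conditional independence) over all rows of
#' an observation table, evaluating the latent field at each record's
#' population and time.
#'
#' @param table An observation table (see [read_observations()]).
#' @param eta A populations-by-time matrix of latent values on the natural
#'   scale (rownames = population ids).
#' @param spec A [data_model_spec()].
#' @param sds Named vector of estimated observation sds (names = source
#'   labels, or the single name `"global"`), used for rows without a
#'   `sampling_sd` when the variance mode requires it.
#' @param phi Overdispersion (negative binomial).
#' @return The total log-likelihood (0 for an empty table).
#' @export
total_loglik <- function(table, eta, spec, sds = NULL, phi = NULL) {
  if (nrow(table) == 0) return(0)
  ci <- match(table$population, rownames(eta))
  if (anyNA(ci))
    stop_tmmp("population(s) %s missing from the latent field",
              paste(unique(table$population[is.na(ci)]), collapse = ", "))
  eta_i <- eta[cbind(ci, table$time)]
  sd_i <- NULL
  if (spec$family %in% c("normal", "logit_normal")) {
    sd_i <- table$sampling_sd
    if (is.null(sd_i)) sd_i <- rep(NA_real_, nrow(table))
    need <- is.na(sd_i)
    if (any(need)) {
      if (spec$variance == "fixed")
        stop_tmmp("variance mode 'fixed' but %d rows lack sampling_sd", sum(need))
      key <- if (spec$variance == "global") rep("global", sum(need))
             else as.character(table$source[need])
      got <- sds[key]
      if (is.null(sds) || anyNA(got))
        stop_tmmp("no estimated sd supplied for source(s): %s",
                  paste(unique(key[is.na(got)]), collapse = ", "))
      sd_i[need] <- got
    }
  }
  sum(loglik_record(spec, table$value, eta_i, sd = sd_i,
                    n = table$denominator, phi = phi))
}
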