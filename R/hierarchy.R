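#' Bounding transform for constrained parameters
#'
#' Maps an unconstrained real to the open interval `(lo, hi)` through a scaled
#' inverse-logit, `lo + (hi - lo) * plogis(x)`. Used e.g. to constrain a
#' logistic-transition asymptote to (0.5, 1) and its rate to (0.01, 0.5)
#' while modelling the unconstrained value hierarchically.
#'
#' @param x Unconstrained value(s).
#' @param lo,hi Interval bounds, `lo < hi`.
#' @return Value(s) in `(lo, hi)`.
#' @export
bounded_transform <- function(x, lo, hi) {
  if (!(lo < hi)) stop_tmmp("bounded_transform needs lo < hi")
  lo + (hi - lo) * stats::plogis(x)
}

#' @rdname bounded_transform
#' @param y Value(s) in `(lo, hi)`.
#' @export
bounded_transform_inv <- function(y, lo, hi) {
  if (!(lo < hi)) stop_tmmp("bounded_transform needs lo < hi")
  stats::qlogis((y - lo) / (hi - lo))
}

#' Parameter estimation strategy
#'
#' Declares how a population-level parameter is estimated: fixed to a known
#' value, given a prior, or modelled hierarchically with normal (optionally
#' truncated) levels nested through grouping maps up to a world level. An
#' optional bounding transform constrains the natural-scale value while the
#' hierarchy acts on the unconstrained scale.
#'
#' @param parameter Parameter name.
#' @param strategy `"fixed"`, `"prior"` or `"hierarchical"`.
#' @param value Fixed value (strategy `"fixed"`).
#' @param source Free-text provenance note for a fixed value (printed by the
#'   reporting template).
#' @param prior For `"prior"`: a list `list(dist, mean, sd, lo, hi)`;
#'   `dist` one of `"normal"`, `"halfnormal"`, `"uniform"`,
#'   `"truncated_normal"`.
#' @param levels Number of hierarchy levels (1 = populations around a world
#'   mean).
#' @param groupings For multi-level hierarchies, a data frame mapping
#'   `population` to grouping columns (e.g. `subregion`, `region`), innermost
#'   first.
#' @param scale_priors Optional list of priors for the per-level scales
#'   (default half-normal(0, 5)).
#' @param bounds Optional `c(lo, hi)` bounding transform.
#' @param truncation Optional `c(lo, hi)` truncation for truncated-normal
#'   population levels.
#' @return An object of class `tmmp_hierarchy`.
#' @export
hierarchy_spec <- function(parameter, strategy = c("hierarchical", "prior", "fixed"),
                           value = NULL, source = NULL, prior = NULL,
                           levels = 1L, groupings = NULL, scale_priors = NULL,
                           bounds = NULL, truncation = NULL) {
  strategy <- match.arg(strategy)
  if (strategy == "fixed" && is.null(value))
    stop_tmmp("fixed strategy for '%s' needs a value", parameter)
  if (strategy == "hierarchical") {
    if (!is_count(levels) || levels < 1) stop_tmmp("'levels' must be >= 1")
    if (levels > 1 && is.null(groupings))
      stop_tmmp("a %d-level hierarchy needs a groupings table", levels)
  }
  if (!is.null(bounds) && !(length(bounds) == 2 && bounds[1] < bounds[2]))
    stop_tmmp("'bounds' must be c(lo, hi) with lo < hi")
  structure(list(parameter = parameter, strategy = strategy, value = value,
                 source = source, prior = prior, levels = as.integer(levels),
                 groupings = groupings, scale_priors = scale_priors,
                 bounds = bounds, truncation = truncation),
            class = "tmmp_hierarchy")
}

# log-density of a declared scalar prior
prior_logdens <- function(prior, x) {
  switch(prior$dist,
    normal = stats::dnorm(x, prior$mean %||% 0, prior$sd %||% 10, log = TRUE),
    halfnormal = {
      if (x <= 0) return(-Inf)
      log(2) + stats::dnorm(x, 0, prior$sd %||% 5, log = TRUE)
    },
    uniform = {
      lo <- prior$lo %||% 0; hi <- prior$hi %||% 1
      if (x < lo || x > hi) -Inf else -log(hi - lo)
    },
    truncated_normal = {
      lo <- prior$lo %||% -Inf; hi <- prior$hi %||% Inf
      if (x < lo || x > hi) return(-Inf)
      m <- prior$mean %||% 0; s <- prior$sd %||% 1
      stats::dnorm(x, m, s, log = TRUE) -
        log(stats::pnorm(hi, m, s) - stats::pnorm(lo, m, s))
    },
    stop_tmmp("unknown prior distribution '%s'", prior$dist))
}

#' Evaluate a hierarchy's log-density
#'
#' Builds the joint log-density of population-level parameter values given
#' group-level parameters, recursively to the world level:
#' `sum over levels and units of log pi(unit | parent, scale)`. With one
#' level this reduces to `sum dnorm(gamma_c, world, scale)`.
#'
#' @param spec A [hierarchy_spec()] with strategy `"hierarchical"`.
#' @param populations Character vector of population ids.
#' @param values Named numeric vector of population-level values (on the
#'   unconstrained scale if the spec has bounds).
#' @param level_means List of named vectors of group means, innermost level
#'   first; the last element is the length-1 world mean.
#' @param scales Numeric vector of per-level scales (length = number of
#'   levels).
#' @return The log-density.
#' @export
hierarchy_logdens <- function(spec, populations, values, level_means, scales) {
  if (spec$strategy != "hierarchical")
    stop_tmmp("hierarchy_logdens needs a hierarchical spec")
  L <- spec$levels
  if (length(level_means) != L || length(scales) != L)
    stop_tmmp("expected %d level means and scales", L)
  g <- spec$groupings
  parent_of <- function(units, lvl) {
    # lvl 1: parent of populations; beyond: parent of groups
    if (L == 1) return(rep("world", length(units)))
    cols <- c("population", setdiff(names(g), "population"))
    key <- match(units, g[[cols[lvl]]])
    if (anyNA(key)) stop_tmmp("unit(s) %s missing from the groupings table",
                              paste(units[is.na(key)], collapse = ", "))
    if (lvl + 1 > length(cols)) rep("world", length(units))
    else as.character(g[[cols[lvl + 1]]][key])
  }
  ld <- 0
  units <- populations
  vals <- values[populations]
  for (lvl in seq_len(L)) {
    parents <- parent_of(units, lvl)
    pm <- level_means[[lvl]]
    mu <- if (identical(unique(parents), "world") && length(pm) == 1) rep(pm, length(units))
          else pm[parents]
    if (anyNA(mu)) stop_tmmp("missing group mean(s) at level %d", lvl)
    if (!is.null(spec$truncation) && lvl == 1) {
      lo <- spec$truncation[1]; hi <- spec$truncation[2]
      if (any(vals < lo | vals > hi)) return(-Inf)
      ld <- ld + sum(stats::dnorm(vals, mu, scales[lvl], log = TRUE) -
                       log(stats::pnorm(hi, mu, scales[lvl]) -
                             stats::pnorm(lo, mu, scales[lvl])))
    } else {
      ld <- ld + sum(stats::dnorm(vals, mu, scales[lvl], log = TRUE))
    }
    # move one level up
    nxt <- unique(parents)
    if (identical(nxt, "world")) break
    units <- nxt
    vals <- level_means[[lvl]][units]
  }
  ld
}
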