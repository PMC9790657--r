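#' Specify a temporal model for multiple populations
#'
#' Assembles a full model specification: the indicator and its transform, the
#' covariate / systematic / offset components, the stochastic smoothing
#' component, the data model, parameter-estimation strategies and the
#' projection rule. The object is a plain nested list (class `tmmp_model`)
#' that serializes losslessly to YAML via [serialize_config()] /
#' [parse_config()].
#'
#' @param name Model name.
#' @param indicator List `list(name, scale)` describing the indicator and its
#'   declared natural scale (e.g. deaths per 1000 live births). Transforms
#'   operate on the declared scale unchanged.
#' @param transform `"identity"`, `"log"`, `"log10"` or `"logit"`.
#' @param covariate List describing the covariate component `g2`:
#'   `kind` one of `"none"`, `"linear"`, `"gbd_nonlinear"`,
#'   `"piecewise_nmr"`, `"pca_linear"` plus kind-specific fields
#'   (`columns`, fixed `betas`, `beta2`, `n_components`, ...).
#' @param systematic List describing `g3`: `kind` one of `"none"`,
#'   `"linear_trend"`, `"logistic_transition"`, `"trapezoid"` plus
#'   kind-specific fields (`t_star`, fixed parameter lists, ...).
#' @param offset `"none"`, or a list `list(kind = "table", path = ...)`;
#'   offsets default to zero where not supplied and always act on the
#'   transformed scale.
#' @param smoothing List: `basis = list(kind, degree, knot_spacing)`,
#'   `kernel = list(family, <hyperparameters>)`, `r`, `constraint`
#'   (`"none"`, `"minimum_norm"` or a list of anchoring index sets), and
#'   `sigma` strategy for the kernel scale
#'   (`"fixed"`, `"shared"`, `"hierarchical"`, `"per_age_group"`).
#' @param data_model List `list(family, variance, phi)`; see
#'   [data_model_spec()].
#' @param hierarchy Named list of per-parameter strategy declarations, each
#'   `list(strategy = "fixed"|"prior"|"hierarchical", ...)`.
#' @param projection List `list(method, W, G, V)` with `method` one of
#'   `"joint"`, `"default_conditional"`, `"log_pooling"`.
#' @param priors Named list of prior overrides
#'   (`list(dist, mean, sd, lo, hi)` entries).
#' @param inference List `list(seed, chains, draws, warmup)`.
#' @return An object of class `tmmp_model`.
#' @export
tmmp_model <- function(name = "tmmp",
                       indicator = list(name = "indicator", scale = "per 1"),
                       transform = "identity",
                       covariate = list(kind = "none"),
                       systematic = list(kind = "none"),
                       offset = "none",
                       smoothing = list(basis = list(kind = "identity"),
                                        kernel = list(family = "iid", sigma = 1),
                                        r = 0, constraint = "none",
                                        sigma = "shared"),
                       data_model = list(family = "normal", variance = "fixed"),
                       hierarchy = list(),
                       projection = list(method = "default_conditional"),
                       priors = list(),
                       inference = list(seed = 1, chains = 2, draws = 1000, warmup = 1000)) {
  # canonicalize anchoring sets as a named mapping K0, K1, ... so the
  # structure survives YAML round trips regardless of set lengths
  con <- smoothing$constraint %||% "none"
  if (!is.character(con)) {
    sets <- if (is.list(con)) con else list(con)
    smoothing$constraint <- setNames(lapply(sets, as.integer),
                                     paste0("K", seq_along(sets) - 1L))
  }
  m <- list(name = name, indicator = indicator, transform = transform,
            covariate = covariate, systematic = systematic, offset = offset,
            smoothing = smoothing, data_model = data_model,
            hierarchy = hierarchy, projection = projection, priors = priors,
            inference = inference)
  validate_model(m)
  structure(m, class = "tmmp_model")
}

model_choices <- list(
  transform = c("identity", "log", "log10", "logit"),
  covariate = c("none", "linear", "gbd_nonlinear", "piecewise_nmr", "pca_linear"),
  systematic = c("none", "linear_trend", "logistic_transition", "trapezoid"),
  kernel = c("ar1", "squared_exponential", "matern", "arma11", "iid"),
  data_model = c("normal", "logit_normal", "binomial", "negative_binomial"),
  projection = c("joint", "default_conditional", "log_pooling")
)

validate_model <- function(m) {
  chk <- function(value, what) {
    if (!value %in% model_choices[[what]])
      stop_tmmp("unknown %s '%s'; choose one of: %s", what, value,
                paste(model_choices[[what]], collapse = ", "))
  }
  chk(m$transform, "transform")
  chk(m$covariate$kind %||% "none", "covariate")
  chk(m$systematic$kind %||% "none", "systematic")
  chk(m$data_model$family, "data_model")
  chk(m$projection$method %||% "default_conditional", "projection")
  k <- m$smoothing$kernel
  chk(k$family, "kernel")
  # instantiating the kernel validates hyperparameter presence and ranges
  do.call(kernel_spec, k)
  r <- m$smoothing$r %||% 0
  if (!r %in% 0:2) stop_tmmp("smoothing r must be 0, 1 or 2")
  con <- m$smoothing$constraint %||% "none"
  if (r == 0 && !identical(con, "none"))
    stop_tmmp("r = 0 smoothers take constraint = \"none\"")
  if (r > 0 && identical(con, "none"))
    stop_tmmp("r = %d requires constraint \"minimum_norm\" or anchoring index sets", r)
  if (is.list(con) && length(con) != r)
    stop_tmmp("anchored constraint needs %d index sets, got %d", r, length(con))
  if (identical(m$projection$method, "log_pooling")) {
    W <- m$projection$W
    if (is.null(W) || W < 0 || W > 1)
      stop_tmmp("log_pooling projection needs a weight W in [0, 1]")
  }
  invisible(m)
}

#' @export
print.tmmp_model <- function(x, ...) {
  cat(sprintf("<tmmp_model> %s\n", x$name))
  cat(sprintf("  indicator : %s (%s), transform %s\n",
              x$indicator$name, x$indicator$scale %||% "per 1", x$transform))
  cat(sprintf("  covariate : %s\n", x$covariate$kind %||% "none"))
  cat(sprintf("  systematic: %s\n", x$systematic$kind %||% "none"))
  cat(sprintf("  smoothing : %s basis, %s kernel, r = %d\n",
              x$smoothing$basis$kind, x$smoothing$kernel$family, x$smoothing$r %||% 0))
  cat(sprintf("  data model: %s\n", x$data_model$family))
  cat(sprintf("  projection: %s\n", x$projection$method %||% "default_conditional"))
  invisible(x)
}

# kernel spec from a model, with optional hyperparameter overrides
model_kernel <- function(m, override = list()) {
  k <- m$smoothing$kernel
  k[names(override)] <- override
  do.call(kernel_spec, k)
}

model_smoothing_spec <- function(m, override = list()) {
  b <- m$smoothing$basis
  bs <- basis_spec(b$kind, degree = b$degree %||% 3L,
                   knot_spacing = b$knot_spacing %||% 2.5)
  con <- m$smoothing$constraint %||% "none"
  if (is.list(con)) con <- do.call(anchor_sets, con)
  smoothing_spec(bs, model_kernel(m, override), r = m$smoothing$r %||% 0L,
                 constraint = con)
}

#' Serialize / parse model configurations
#'
#' A `tmmp_model` round-trips losslessly through YAML: numeric values are
#' written at full precision and list structure is preserved.
#'
#' @param model A [tmmp_model()].
#' @param path File path; for [serialize_config()] `NULL` returns the YAML
#'   string instead of writing.
#' @return [parse_config()] returns a validated `tmmp_model`;
#'   [serialize_config()] returns the path (or YAML string) invisibly.
#' @export
serialize_config <- function(model, path = NULL) {
  txt <- yaml::as.yaml(unclass_deep(model), precision = 15L)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' @rdname serialize_config
#' @export
parse_config <- function(path) {
  txt <- if (length(path) == 1 && !grepl("\n", path) && file.exists(path))
    paste(readLines(path), collapse = "\n") else paste(path, collapse = "\n")
  m <- yaml::yaml.load(txt)
  m <- do.call(tmmp_model, m)
  m
}

unclass_deep <- function(x) {
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  x
}
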