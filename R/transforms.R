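#' Transformations of the latent indicator
#'
#' The process model is specified on a transformed scale `g1(eta)`. Four
#' transforms are supported: `identity`, `log`, `log10` and `logit`. Values
#' outside the transform's domain raise an error; there is no silent clamping.
#'
#' @param name One of `"identity"`, `"log"`, `"log10"`, `"logit"`.
#' @return An object of class `tmmp_transform` with elements `name`,
#'   `forward`, `inverse` and `domain` (an open interval).
#' @examples
#' tr <- transform_spec("logit")
#' tr$forward(0.5)       # 0
#' tr$inverse(tr$forward(0.137))
#' @export
transform_spec <- function(name = c("identity", "log", "log10", "logit")) {
  name <- match.arg(name)
  spec <- switch(name,
    identity = list(domain = c(-Inf, Inf),
                    forward = function(x) x, inverse = function(z) z),
    log      = list(domain = c(0, Inf),
                    forward = function(x) log(x), inverse = function(z) exp(z)),
    log10    = list(domain = c(0, Inf),
                    forward = function(x) log10(x), inverse = function(z) 10^z),
    logit    = list(domain = c(0, 1),
                    forward = function(x) stats::qlogis(x),
                    inverse = function(z) stats::plogis(z))
  )
  structure(c(list(name = name), spec), class = "tmmp_transform")
}

#' Apply a transform (with domain checking)
#'
#' @param x Values on the natural scale.
#' @param spec A [transform_spec()] (or its name).
#' @return Transformed values.
#' @export
transform_apply <- function(x, spec) {
  if (is.character(spec)) spec <- transform_spec(spec)
  d <- spec$domain
  bad <- !is.na(x) & (x <= d[1] | x >= d[2])
  if (spec$name == "identity") bad <- rep(FALSE, length(x))
  if (any(bad))
    stop_tmmp("value(s) %s outside the open domain (%g, %g) of transform '%s'",
              paste(utils::head(x[bad], 3), collapse = ", "), d[1], d[2], spec$name)
  spec$forward(x)
}

#' @rdname transform_apply
#' @param z Values on the transformed scale.
#' @export
transform_invert <- function(z, spec) {
  if (is.character(spec)) spec <- transform_spec(spec)
  spec$inverse(z)
}
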