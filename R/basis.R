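#' Basis specification for the smoothing component
#'
#' The smoothing component is `epsilon = B %*% delta`. The basis `B` is either
#' the identity (one coefficient per time point) or a cubic-by-default
#' B-spline basis with evenly spaced knots.
#'
#' @param kind `"identity"` or `"bspline"`.
#' @param degree Spline degree (B-splines; default 3, cubic).
#' @param knot_spacing Knot spacing in grid units (B-splines; e.g. 2.5).
#' @return An object of class `tmmp_basis_spec`.
#' @export
basis_spec <- function(kind = c("identity", "bspline"), degree = 3L, knot_spacing = 2.5) {
  kind <- match.arg(kind)
  if (kind == "bspline") {
    if (!is_count(degree) || degree < 1) stop_tmmp("'degree' must be a positive integer")
    check_scalar(knot_spacing, "knot_spacing", 0, open_lo = TRUE)
  }
  structure(list(kind = kind, degree = as.integer(degree), knot_spacing = knot_spacing),
            class = "tmmp_basis_spec")
}

#' Build the basis matrix over a population's span
#'
#' For the identity basis this is the `T x T` identity over the evaluation
#' times. For B-splines, interior knots are placed at `knot_spacing` intervals
#' from `span[1]` until the span is covered, with `degree` additional
#' equally-spaced exterior knots beyond each boundary (not repeated/clamped
#' knots, so extending the basis to later times appends columns without
#' altering existing ones). With `m` interior intervals the basis has
#' `K = m + degree` columns, and rows evaluated within the span sum to 1.
#'
#' @param spec A [basis_spec()].
#' @param times Evaluation times (grid indices, typically `1:T`).
#' @param span Length-2 numeric: first and last time covered by the basis
#'   (defaults to `range(times)`).
#' @return A `length(times) x K` matrix with attributes `knots`, `degree`,
#'   `spacing` and `span` (B-splines) used by [extend_basis()].
#' @examples
#' B <- build_basis(basis_spec("bspline"), times = 1:26, span = c(1, 26))
#' ncol(B)  # ceiling(25 / 2.5) + 3 = 13
#' @export
build_basis <- function(spec, times, span = range(times)) {
  if (!inherits(spec, "tmmp_basis_spec")) stop_tmmp("'spec' must be a basis_spec()")
  if (spec$kind == "identity") {
    B <- diag(length(times))
    attr(B, "kind") <- "identity"
    return(B)
  }
  h <- spec$knot_spacing
  width <- span[2] - span[1]
  if (width < h)
    stop_tmmp("span (%g units) is shorter than one knot interval (%g)", width, h)
  m <- ceiling(width / h)          # interior intervals covering the span
  d <- spec$degree
  knots <- span[1] + h * seq(-d, m + d)
  B <- splines::splineDesign(knots, x = times, ord = d + 1L, outer.ok = TRUE)
  if (qr(B)$rank < ncol(B))
    warning("B-spline basis is rank deficient over the supplied times")
  attr(B, "kind") <- "bspline"
  attr(B, "knots") <- knots
  attr(B, "degree") <- d
  attr(B, "spacing") <- h
  attr(B, "span") <- span
  B
}

#' Extend a B-spline basis into the projection period
#'
#' Appends knots at the original spacing until the basis covers `to_time`,
#' adding columns for the new coefficients while leaving the original columns
#' (restricted to the original times) bit-identical.
#'
#' @param B A basis matrix from [build_basis()] (B-spline kind).
#' @param times Evaluation times for the extended basis (e.g. `1:T_star`).
#' @param to_time Last time the extended basis must cover.
#' @return Extended basis matrix with the same attributes, plus
#'   `K_added`, the number of appended columns.
#' @export
extend_basis <- function(B, times, to_time = max(times)) {
  if (identical(attr(B, "kind"), "identity")) {
    B2 <- diag(length(times))
    attr(B2, "kind") <- "identity"
    attr(B2, "K_added") <- length(times) - ncol(B)
    return(B2)
  }
  knots <- attr(B, "knots")
  h <- attr(B, "spacing")
  d <- attr(B, "degree")
  span <- attr(B, "span")
  last <- knots[length(knots)]
  extra <- 0L
  while (last + (extra - d) * h < to_time) extra <- extra + 1L
  new_knots <- c(knots, last + h * seq_len(extra))
  B2 <- splines::splineDesign(new_knots, x = times, ord = d + 1L, outer.ok = TRUE)
  attr(B2, "kind") <- "bspline"
  attr(B2, "knots") <- new_knots
  attr(B2, "degree") <- d
  attr(B2, "spacing") <- h
  attr(B2, "span") <- c(span[1], to_time)
  attr(B2, "K_added") <- extra
  B2
}
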