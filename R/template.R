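#' Render a standardized model-reporting template
#'
#' Produces a structured markdown document describing a model configuration
#' row by row: indicator, transform, process-model formula, covariate
#' component, systematic component, offsets, smoothing component (basis,
#' kernel, differencing order, anchoring sets), projection rule, and the
#' parameter-estimation strategies (fixed / vague priors / informative
#' priors / hierarchical, with distribution, number of levels and
#' groupings). Fields a model does not use are printed as a middle dot.
#' A machine-readable YAML appendix carries the full configuration, so
#' [template_parse()] recovers the `tmmp_model` from the rendered text.
#'
#' @param model A [tmmp_model()] (or a zoo entry).
#' @return A character scalar (markdown) of class `tmmp_template`.
#' @export
render_template <- function(model) {
  if (inherits(model, "tmmp_zoo_entry")) model <- model$model
  dot <- "·"
  cov <- model$covariate$kind %||% "none"
  sys <- model$systematic$kind %||% "none"
  sm <- model$smoothing
  fml <- {
    parts <- c(if (cov != "none") "g2(X, beta)",
               if (sys != "none") "g3(t, eta, alpha)",
               if (!identical(model$offset, "none")) "a",
               "eps")
    paste0("g1(eta) = ", paste(parts, collapse = " + "))
  }
  cov_cols <- if (cov == "none") dot else
    paste(unlist(model$covariate$columns) %||% dot, collapse = ", ")
  g2 <- switch(cov,
    none = dot,
    linear = "beta0_c + sum_k X_k beta_k",
    gbd_nonlinear = "log10(exp(b1 log LDI + b2 EDU + b3) + b4 HIV)",
    piecewise_nmr = "beta0_c + beta1 (log X - log beta2) 1[X > beta2]",
    pca_linear = "sum_k X_k beta_{c,t,k}")
  g3 <- switch(sys,
    none = dot,
    linear_trend = "alpha0_c + alpha1_c (t - t*_c)",
    logistic_transition = "logistic transition towards asymptote P~_c at rate omega_c",
    trapezoid = "trapezoid(xi_c; gamma0_c, lambda_{1..3,c})")
  basis <- if (sm$basis$kind == "identity") "B = I" else
    sprintf("cubic B-splines, knots every %s grid units", sm$basis$knot_spacing %||% 2.5)
  con <- sm$constraint %||% "none"
  con_txt <- if (identical(con, "none")) dot
    else if (identical(con, "minimum_norm")) "minimum-norm (orthogonal to null space)"
    else paste(vapply(seq_along(con), function(d)
      sprintf("K_%d = {%s}", d - 1, paste(con[[d]], collapse = ",")), ""),
      collapse = "; ")
  kern <- model$smoothing$kernel
  kern_txt <- paste0(kern$family, "(",
                     paste(names(kern)[-1], unlist(kern[-1]), sep = " = ",
                           collapse = ", "), ")")
  proj <- model$projection$method %||% "default_conditional"
  proj_txt <- switch(proj,
    default_conditional = "default: r-th order differenced estimation model",
    joint = "joint estimation to T*",
    log_pooling = sprintf(
      "logarithmic pooling of second-order differences, W = %s", model$projection$W))
  est <- estimation_rows(model)
  lines <- c(
    sprintf("# Model reporting template: %s", model$name),
    "",
    "| Field | Value |",
    "|---|---|",
    sprintf("| Indicator eta | %s (%s) |", model$indicator$name,
            model$indicator$scale %||% "per 1"),
    sprintf("| g1 | %s |", model$transform),
    sprintf("| Process model formula | %s |", fml),
    sprintf("| Covariate component g2 | %s |", g2),
    sprintf("| Covariates | %s |", cov_cols),
    sprintf("| Systematic component g3 | %s |", g3),
    sprintf("| Systematic parameters alpha | %s |",
            if (sys == "none") dot else switch(sys,
              linear_trend = "alpha0_c (intercept), alpha1_c (slope), t*_c",
              logistic_transition = "P~_c (asymptote), omega_c (rate), Omega_c (level at t*)",
              trapezoid = "xi_c, gamma0_c, lambda1_c, lambda2_c, lambda3_c")),
    sprintf("| Offsets a | %s |",
            if (identical(model$offset, "none")) dot else "file-based, transformed scale"),
    sprintf("| Smoothing basis B | %s |", basis),
    sprintf("| Smoothing kernel s | %s |", kern_txt),
    sprintf("| Differencing order r | %d |", sm$r %||% 0L),
    sprintf("| Anchoring K_d | %s |", con_txt),
    sprintf("| Projections | %s |", proj_txt),
    sprintf("| Data model | %s (variance: %s) |", model$data_model$family,
            model$data_model$variance %||% "fixed"),
    "",
    "## Parameter estimation",
    "",
    "| Strategy | Parameters |",
    "|---|---|",
    sprintf("| Fixed | %s |", est$fixed),
    sprintf("| Vague priors | %s |", est$vague),
    sprintf("| Informative priors | %s |", est$informative),
    sprintf("| Hierarchical | %s |", est$hier),
    sprintf("| Hierarchical distribution pi | %s |", est$hier_dist),
    sprintf("| Hierarchy levels | %s |", est$hier_levels),
    sprintf("| Hierarchical groupings | %s |", est$hier_groups),
    "",
    "## Machine-readable configuration",
    "",
    "```yaml",
    sub("\n$", "", serialize_config(model)),
    "```")
  structure(paste(lines, collapse = "\n"), class = "tmmp_template")
}

estimation_rows <- function(model) {
  dot <- "·"
  fixed <- character(); vague <- character(); hier <- character()
  hier_levels <- integer()
  cov <- model$covariate$kind %||% "none"
  sys <- model$systematic$kind %||% "none"
  if (cov == "gbd_nonlinear" || identical(model$covariate$strategy, "fixed"))
    fixed <- c(fixed, "covariate coefficients beta")
  else if (cov %in% c("linear", "piecewise_nmr")) vague <- c(vague, "covariate slopes beta")
  if (cov == "piecewise_nmr") fixed <- c(fixed, "cut-off beta2")
  if (cov %in% c("linear", "piecewise_nmr") &&
      !identical(model$covariate$intercept, "none")) {
    lv <- model$hierarchy$beta0$levels %||% 1L
    hier <- c(hier, "intercepts beta0_c"); hier_levels <- c(hier_levels, lv)
  }
  if (cov == "pca_linear") {
    hier <- c(hier, "component loadings beta_{c,t,k}")
    hier_levels <- c(hier_levels, 1L)
  }
  if (sys == "linear_trend") {
    if (identical(model$systematic$strategy, "fixed"))
      fixed <- c(fixed, "alpha0_c, alpha1_c")
    else vague <- c(vague, "alpha0_c, alpha1_c")
  }
  if (sys == "trapezoid") fixed <- c(fixed, "trapezoid parameters")
  if (sys == "logistic_transition")
    for (par in c("Omega", "Pstar", "wstar")) {
      lv <- model$hierarchy[[par]]$levels %||% 1L
      hier <- c(hier, par); hier_levels <- c(hier_levels, lv)
    }
  sig_mode <- model$smoothing$sigma %||% "shared"
  if (sig_mode == "fixed") fixed <- c(fixed, "smoothing kernel hyperparameters")
  else if (sig_mode == "shared") vague <- c(vague, "smoothing scale sigma_delta")
  else if (sig_mode %in% c("hierarchical", "bmat_lambda")) {
    hier <- c(hier, "smoothing scales sigma_delta_c")
    hier_levels <- c(hier_levels, 1L)
  } else if (sig_mode == "per_age_group")
    vague <- c(vague, "per-age-group smoothing scales")
  if (identical(model$projection$method, "log_pooling"))
    fixed <- c(fixed, "pooling weight W, global moments (G, V)")
  fx <- function(x) if (length(x)) paste(x, collapse = "; ") else dot
  list(fixed = fx(fixed), vague = fx(vague), informative = dot,
       hier = fx(hier),
       hier_dist = if (length(hier)) "Normal (truncated normal for Bmat lambda_c)" else dot,
       hier_levels = if (length(hier)) paste(hier_levels, collapse = "; ") else dot,
       hier_groups = if (length(hier))
         if (any(hier_levels > 1)) "populations within subregion/region, world"
         else "populations within world" else dot)
}

#' @rdname render_template
#' @param text Rendered template text (or a file path).
#' @return [template_parse()] returns the embedded `tmmp_model`.
#' @export
template_parse <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    text <- paste(readLines(text), collapse = "\n")
  text <- paste(text, collapse = "\n")
  m <- regmatches(text, regexpr("(?s)```yaml\n.*?\n```", text, perl = TRUE))
  if (!length(m)) stop_tmmp("no machine-readable yaml block found")
  yml <- sub("^```yaml\n", "", sub("\n```$", "", m))
  parse_config(yml)
}

#' @export
print.tmmp_template <- function(x, ...) {
  cat(unclass(x), "\n")
  invisible(x)
}
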