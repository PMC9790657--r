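#' Read an observation table
#'
#' Reads a long-format CSV of observations (columns
#' `population,time,value[,sampling_sd,source,denominator]`), maps calendar
#' years onto the model grid and validates values against the declared data
#' model's support. Multiple rows per population-time are allowed (multiple
#' sources); populations may have few or no observations.
#'
#' @param path CSV file path.
#' @param grid A [time_grid()]; `time` values must be grid year labels (or
#'   grid indices).
#' @param data_model Optional [data_model_spec()] used to validate value
#'   support (e.g. (0, 1) for logit-normal).
#' @return A `data.frame` of class `tmmp_observations` with columns
#'   `population`, `time` (grid index), `value`, `sampling_sd`, `source`,
#'   `denominator`.
#' @export
read_observations <- function(path, grid, data_model = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  mandatory <- c("population", "time", "value")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols))
    stop_tmmp("observations file lacks mandatory column(s): %s",
              paste(missing_cols, collapse = ", "))
  if (nrow(raw) == 0) {
    return(structure(data.frame(population = character(), time = integer(),
                                value = numeric(), sampling_sd = numeric(),
                                source = character(), denominator = integer()),
                     class = c("tmmp_observations", "data.frame")))
  }
  for (col in c("time", "value", "sampling_sd", "denominator")) {
    if (col %in% names(raw) && !is.numeric(raw[[col]])) {
      conv <- suppressWarnings(as.numeric(raw[[col]]))
      bad <- which(is.na(conv) & !is.na(raw[[col]]) & raw[[col]] != "")
      if (length(bad))
        stop_tmmp("non-numeric '%s' at data row %d: '%s'", col, bad[1], raw[[col]][bad[1]])
      raw[[col]] <- conv
    }
  }
  obs <- data.frame(
    population = as.character(raw$population),
    time = year_to_index(grid, raw$time),
    value = raw$value,
    sampling_sd = if ("sampling_sd" %in% names(raw)) raw$sampling_sd else NA_real_,
    source = if ("source" %in% names(raw)) as.character(raw$source) else "default",
    denominator = if ("denominator" %in% names(raw)) as.integer(raw$denominator) else NA_integer_,
    stringsAsFactors = FALSE
  )
  if (any(!is.na(obs$sampling_sd) & obs$sampling_sd < 0))
    stop_tmmp("sampling_sd must be nonnegative")
  if (!is.null(data_model)) validate_support(obs, data_model)
  structure(obs, class = c("tmmp_observations", "data.frame"))
}

validate_support <- function(obs, data_model) {
  fam <- data_model$family
  if (fam %in% c("logit_normal")) {
    bad <- which(obs$value <= 0 | obs$value >= 1)
    if (length(bad))
      stop_tmmp("value %g at row %d outside (0, 1) under a %s data model",
                obs$value[bad[1]], bad[1], fam)
  }
  if (fam %in% c("binomial", "negative_binomial")) {
    if (any(is.na(obs$denominator)))
      stop_tmmp("%s data model requires a denominator column", fam)
    bad <- which(obs$value < 0 | obs$value != round(obs$value))
    if (length(bad))
      stop_tmmp("value %g at row %d is not a nonnegative count", obs$value[bad[1]], bad[1])
  }
  invisible(obs)
}

#' Read a covariate table
#'
#' Long-format CSV with columns `population,time,<covariate columns>`.
#' Covariates used by a model must be complete over the whole grid `1..T*`
#' for every population, since projections need covariate values to `T*`.
#'
#' @inheritParams read_observations
#' @param required Character vector of covariate columns that must be present
#'   and complete.
#' @return A `data.frame` with `time` mapped to grid indices.
#' @export
read_covariates <- function(path, grid, required = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("population", "time") %in% names(raw)))
    stop_tmmp("covariates file needs 'population' and 'time' columns")
  raw$population <- as.character(raw$population)
  raw$time <- year_to_index(grid, raw$time)
  check_covariates(raw, grid, required)
  raw
}

check_covariates <- function(cov, grid, required = NULL) {
  for (col in required %||% character())
    if (!col %in% names(cov))
      stop_tmmp("covariate column '%s' is missing", col)
  if (!is.null(required)) {
    for (p in unique(cov$population)) {
      have <- sort(cov$time[cov$population == p])
      if (!identical(have, seq_len(grid$T_star)))
        stop_tmmp("covariates for population '%s' do not cover 1..%d", p, grid$T_star)
      if (anyNA(cov[cov$population == p, required]))
        stop_tmmp("missing covariate values for population '%s'", p)
    }
  }
  invisible(cov)
}

#' Read an offset table
#'
#' CSV with columns `population,time,offset`, values on the transformed
#' (`g1`) scale. Missing population-times default to offset 0.
#'
#' @inheritParams read_observations
#' @return A populations-by-`T_star` matrix of offsets (rownames =
#'   populations).
#' @export
read_offsets <- function(path, grid) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("population", "time", "offset") %in% names(raw)))
    stop_tmmp("offsets file needs population, time, offset columns")
  if (any(!is.finite(raw$offset))) stop_tmmp("offsets must be finite")
  pops <- unique(as.character(raw$population))
  A <- matrix(0, length(pops), grid$T_star, dimnames = list(pops, NULL))
  A[cbind(match(raw$population, pops), year_to_index(grid, raw$time))] <- raw$offset
  A
}

#' Write posterior estimates of the latent field
#'
#' Summarizes the latent-field draws into a CSV with columns
#' `population,time,q025,median,q975` on the indicator's natural scale,
#' with `time` written as the grid's calendar-year label.
#'
#' @param posterior A `tmmp_posterior` from [fit_tmmp()] (or any object with
#'   an `eta` draw array `draws x populations x times`).
#' @param path Output CSV path.
#' @param grid Optional [time_grid()] for year labels (defaults to the
#'   posterior's grid).
#' @return Invisibly, the written data frame.
#' @export
write_estimates <- function(posterior, path, grid = NULL) {
  eta <- if (is.array(posterior)) posterior else posterior$draws$eta
  if (is.null(eta)) stop_tmmp("posterior contains no latent-field draws")
  grid <- grid %||% posterior$grid
  pops <- dimnames(eta)[[3]] %||% paste0("pop", seq_len(dim(eta)[3]))
  Tn <- dim(eta)[4]
  qs <- apply(eta, c(3, 4), stats::quantile, probs = c(0.025, 0.5, 0.975), names = FALSE)
  out <- data.frame(
    population = rep(pops, each = Tn),
    time = rep(if (!is.null(grid)) grid$years[seq_len(Tn)] else seq_len(Tn),
               times = length(pops)),
    q025 = as.vector(t(qs[1, , ])),
    median = as.vector(t(qs[2, , ])),
    q975 = as.vector(t(qs[3, , ]))
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}
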