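#' Define the model time grid
#'
#' All model components index time on a contiguous 1-based integer grid
#' `1..T_star`, where `1..T` is the estimation period and `(T+1)..T_star` the
#' projection period. Calendar years are labels only: observations supplied in
#' calendar years are mapped onto the grid before any modelling.
#'
#' @param start_year Calendar year labelling grid index 1.
#' @param T_est Last estimation time index (number of estimation periods).
#' @param T_star Last projection time index; defaults to `T_est` (no
#'   projection period).
#' @return An object of class `tmmp_grid` with fields `T`, `T_star` and
#'   `years` (a length-`T_star` vector of calendar-year labels).
#' @examples
#' g <- time_grid(1990, 31, 41)
#' year_to_index(g, c(1990, 2020))
#' @export
time_grid <- function(start_year, T_est, T_star = T_est) {
  if (!is_count(T_est) || T_est < 1) stop_tmmp("'T_est' must be a positive integer")
  if (!is_count(T_star) || T_star < T_est)
    stop_tmmp("'T_star' (%s) must be an integer >= T_est (%s)", T_star, T_est)
  if (!is_count(start_year)) stop_tmmp("'start_year' must be an integer calendar year")
  structure(
    list(T = as.integer(T_est), T_star = as.integer(T_star),
         years = as.integer(start_year) + seq_len(T_star) - 1L),
    class = "tmmp_grid"
  )
}

#' @export
print.tmmp_grid <- function(x, ...) {
  cat(sprintf("<tmmp_grid> estimation 1..%d (%d..%d), projection to %d (%d)\n",
              x$T, x$years[1], x$years[x$T], x$T_star, x$years[x$T_star]))
  invisible(x)
}

#' Map calendar years to grid indices
#'
#' @param grid A [time_grid()].
#' @param year Vector of calendar years (or, if already within `1..T_star` and
#'   not overlapping the year labels, grid indices are accepted as-is).
#' @return Integer grid indices.
#' @export
year_to_index <- function(grid, year) {
  idx <- match(year, grid$years)
  if (anyNA(idx)) {
    # allow direct indices when they cannot be confused with year labels
    direct <- year >= 1 & year <= grid$T_star & year == round(year) &
      !(year %in% grid$years)
    idx[is.na(idx) & direct] <- as.integer(year[is.na(idx) & direct])
  }
  if (anyNA(idx))
    stop_tmmp("time value(s) %s are not on the grid %d..%d",
              paste(unique(year[is.na(idx)]), collapse = ", "),
              grid$years[1], grid$years[grid$T_star])
  as.integer(idx)
}
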