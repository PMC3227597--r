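#' County-by-year screening coverage
#'
#' Tabulates, for every county and calendar year with at least one birth,
#' the number of births, the number with valid screening information, and
#' the coverage fraction. Electronic laboratory records were adopted at
#' different times across regions, so coverage ramps up county by county.
#'
#' @param births Birth table carrying `county`, `delivery_date` (or a `year`
#'   column) and a logical `has_screening` flag (see [flag_screening()]).
#' @param complete If `TRUE`, the county-by-year grid is completed over the
#'   full observed year range: county-years without any birth appear with
#'   `n_births = 0` and an undefined (`NA`) coverage. By default such cells
#'   are omitted.
#' @return Tibble with columns `county`, `year`, `n_births`,
#'   `n_with_screening`, `coverage`.
#' @export
coverage_table <- function(births, complete = FALSE) {
  check_columns(births, c("county", "has_screening"), "birth table")
  if (!"year" %in% names(births)) {
    check_columns(births, "delivery_date", "birth table")
    births$year <- as.integer(format(births$delivery_date, "%Y"))
  }
  out <- births |>
    dplyr::group_by(.data$county, .data$year) |>
    dplyr::summarise(
      n_births = dplyr::n(),
      n_with_screening = sum(.data$has_screening),
      .groups = "drop"
    )
  if (complete && nrow(out) > 0) {
    out <- tidyr::complete(
      out, .data$county, year = tidyr::full_seq(.data$year, 1),
      fill = list(n_births = 0L, n_with_screening = 0L)
    )
  }
  out |>
    dplyr::mutate(coverage = ifelse(.data$n_births > 0,
                                    .data$n_with_screening / .data$n_births,
                                    NA_real_)) |>
    dplyr::arrange(.data$county, .data$year)
}

#' First year of sustained coverage per county
#'
#' Applies the sustained-coverage inclusion rule: a county enters the study
#' population in the earliest year from which its coverage is at or above
#' the threshold in that year *and every subsequent year* through
#' `study_end_year`. A single sub-threshold year restarts the clock;
#' counties that never achieve a sustained run are marked never included
#' (`NA`). A county-year without any birth (undefined coverage, see
#' [coverage_table()] with `complete = TRUE`) cannot violate the threshold
#' and does not break a run.
#'
#' @param cells Coverage table from [coverage_table()]; years must be
#'   contiguous within each county.
#' @param threshold Coverage threshold (default 0.80); the comparison is
#'   `>=`.
#' @param study_end_year Last study year through which the run must hold.
#' @return Tibble with columns `county` and `first_included_year` (`NA` =
#'   never).
#' @export
#' @examples
#' cells <- tibble::tibble(
#'   county = "A", year = 1982:1986, n_births = 100,
#'   n_with_screening = c(50, 85, 79, 90, 92),
#'   coverage = c(0.50, 0.85, 0.79, 0.90, 0.92)
#' )
#' sustained_inclusion(cells, 0.8, 1986)
sustained_inclusion <- function(cells, threshold = 0.8, study_end_year) {
  check_columns(cells, c("county", "year", "coverage"), "coverage table")
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    abort("`threshold` must be in (0, 1]", class = "rbcscreen_config_error")
  }
  one_county <- function(df) {
    yrs <- sort(df$year)
    if (length(yrs) > 1 && any(diff(yrs) != 1)) {
      abort(sprintf("county %s has non-contiguous years", df$county[1]),
            class = "rbcscreen_data_error")
    }
    df <- df[order(df$year), ]
    eval_years <- df$year <= study_end_year
    vacuous <- is.na(df$coverage)
    ok <- (vacuous | df$coverage >= threshold) & eval_years
    # the run must extend through study_end_year; unobserved trailing years
    # cannot be verified and block inclusion
    if (max(df$year) < study_end_year) return(NA_integer_)
    ok_eval <- ok[eval_years]
    yrs_eval <- df$year[eval_years]
    sustained <- rev(cumprod(rev(ok_eval))) == 1
    if (!any(sustained)) return(NA_integer_)
    yrs_eval[which(sustained)[1]]
  }
  cells |>
    dplyr::group_by(.data$county) |>
    dplyr::group_modify(~ tibble(first_included_year = one_county(.x |>
      dplyr::mutate(county = .y$county)))) |>
    dplyr::ungroup()
}

#' Restrict births to the included study population
#'
#' Retains births whose county-year is at or after the county's first
#' included year *and* which carry valid screening information; this defines
#' the denominator used for prevalence rates. Births in included
#' county-years without screening records count toward coverage only and
#' are dropped here.
#'
#' @param births Birth table with `county`, `has_screening`, and
#'   `delivery_date` or `year`.
#' @param inclusion Output of [sustained_inclusion()].
#' @param require_screening Keep only births with screening information
#'   (default `TRUE`).
#' @return The retained births, with a per-year retention summary in
#'   attribute `"inclusion_summary"`.
#' @export
apply_inclusion <- function(births, inclusion, require_screening = TRUE) {
  check_columns(births, c("county", "has_screening"), "birth table")
  check_columns(inclusion, c("county", "first_included_year"), "inclusion map")
  if (!"year" %in% names(births)) {
    births$year <- as.integer(format(births$delivery_date, "%Y"))
  }
  joined <- dplyr::left_join(births, inclusion, by = "county")
  keep <- !is.na(joined$first_included_year) &
    joined$year >= joined$first_included_year
  if (require_screening) keep <- keep & joined$has_screening
  out <- joined[keep, setdiff(names(joined), "first_included_year"), drop = FALSE]
  summary <- out |>
    dplyr::count(.data$year, name = "n_retained")
  attr(out, "inclusion_summary") <- summary
  out
}
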