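#' Calendar period bins
#'
#' Builds and validates an ordered set of inclusive year ranges used to
#' stratify tabulations. Bins must be non-overlapping and contiguous.
#' [default_period_bins()] gives the canonical four periods 1982--1986,
#' 1987--1991, 1992--1996, 1997--2002.
#'
#' @param start,end Integer vectors of first/last year per bin.
#' @return Tibble with columns `start`, `end`, `label`.
#' @export
period_bins <- function(start, end) {
  stopifnot(length(start) == length(end), all(end >= start))
  o <- order(start)
  start <- as.integer(start[o]); end <- as.integer(end[o])
  if (length(start) > 1 && any(start[-1] != head(end, -1) + 1L)) {
    abort("period bins must be contiguous and non-overlapping",
          class = "rbcscreen_config_error")
  }
  tibble(start = start, end = end,
         label = sprintf("%d-%d", start, end))
}

#' @rdname period_bins
#' @export
default_period_bins <- function() {
  period_bins(c(1982, 1987, 1992, 1997), c(1986, 1991, 1996, 2002))
}

assign_period <- function(year, bins) {
  idx <- findInterval(year, bins$start)
  idx[idx < 1 | year > bins$end[pmax(idx, 1)]] <- NA_integer_
  bins$label[idx]
}

#' Prevalence per 10,000 births
#'
#' @param k Count of positive births.
#' @param n Denominator (births at risk); must be positive.
#' @param digits Decimals to round to (half away from zero), default 1 as in
#'   printed prevalence tables.
#' @return `k / n` expressed per 10,000 births, rounded.
#' @export
#' @examples
#' prevalence_rate(1296, 920903)
prevalence_rate <- function(k, n, digits = 1) {
  if (any(n == 0)) {
    abort("prevalence rate undefined for a zero denominator",
          class = "rbcscreen_undefined_rate_error")
  }
  stopifnot(all(k >= 0), all(k <= n))
  round_half_away(1e4 * k / n, digits)
}

#' Tabulate antibody prevalence by stratum and period
#'
#' Produces one row per stratum (each catalogue antibody, each blood-group
#' system, "any antibody", and "non-anti-D antibodies") and period
#' (including `"overall"`), with the positive-birth count `k`, denominator
#' `N`, rate per 10,000 births, and percentage of antibody-positive births.
#' A birth carrying anti-D along with another antibody counts in both the
#' anti-D and the non-anti-D rows (the two overlap; they do not partition
#' the positives). Antibody rows are split into panels by their overall
#' unrounded rate: `"main"` for at least 1/10,000, `"rare"` below.
#'
#' @param profiles Antibody profiles from [classify_births()], covering
#'   exactly the study population.
#' @param births The study-population birth table (see [apply_inclusion()]).
#' @param bins Period bins from [period_bins()]; must cover every delivery
#'   year.
#' @param catalogue The `antibody_catalogue` used for classification.
#' @return Tibble with columns `stratum_type`, `stratum`, `system`,
#'   `period`, `k`, `N`, `rate_per_10k`, `pct_of_ab_positive`, `panel`.
#' @export
tabulate_prevalence <- function(profiles, births, bins = default_period_bins(),
                                catalogue = default_catalogue()) {
  check_columns(profiles, c("birth_id", "antibody_key", "any_antibody"),
                "profile table")
  check_columns(births, "birth_id", "birth table")
  if (!setequal(profiles$birth_id, births$birth_id) ||
      nrow(profiles) != nrow(births)) {
    abort("profiles must cover exactly the study population",
          class = "rbcscreen_consistency_error")
  }
  if (!"year" %in% names(births)) {
    births$year <- as.integer(format(births$delivery_date, "%Y"))
  }
  period <- assign_period(births$year, bins)
  if (anyNA(period)) {
    abort("period bins do not cover every delivery year",
          class = "rbcscreen_config_error")
  }
  prof <- dplyr::left_join(
    tibble(birth_id = births$birth_id, period = period),
    profiles[, c("birth_id", "antibody_key", "any_antibody")],
    by = "birth_id"
  )

  denom <- prof |>
    dplyr::group_by(.data$period) |>
    dplyr::summarise(N = dplyr::n(), K = sum(.data$any_antibody), .groups = "drop")
  denom <- dplyr::bind_rows(
    denom, tibble(period = "overall", N = nrow(prof), K = sum(prof$any_antibody))
  )

  pos <- prof[prof$any_antibody, , drop = FALSE]
  pairs <- if (nrow(pos) > 0) {
    sets <- strsplit(pos$antibody_key, ";", fixed = TRUE)
    tibble(
      birth_id = rep.int(pos$birth_id, lengths(sets)),
      period = rep.int(pos$period, lengths(sets)),
      name = unlist(sets, use.names = FALSE)
    )
  } else {
    tibble(birth_id = character(), period = character(), name = character())
  }
  pairs$system <- unname(catalogue$systems[pairs$name])

  count_stratum <- function(df, type, stratum_col) {
    per <- df |>
      dplyr::distinct(.data$birth_id, .data$period,
                      stratum = .data[[stratum_col]]) |>
      dplyr::count(.data$stratum, .data$period, name = "k")
    tot <- df |>
      dplyr::distinct(.data$birth_id, stratum = .data[[stratum_col]]) |>
      dplyr::count(.data$stratum, name = "k") |>
      dplyr::mutate(period = "overall")
    dplyr::bind_rows(per, tot) |> dplyr::mutate(stratum_type = type)
  }

  ab_counts <- count_stratum(pairs, "antibody", "name")
  sys_counts <- count_stratum(pairs, "system", "system")
  any_counts <- pos |>
    dplyr::count(.data$period, name = "k") |>
    dplyr::bind_rows(tibble(period = "overall", k = nrow(pos))) |>
    dplyr::mutate(stratum = "any antibody", stratum_type = "any")
  non_d_birth <- pairs |>
    dplyr::filter(.data$name != "anti-D") |>
    dplyr::distinct(.data$birth_id, .data$period)
  non_d_counts <- non_d_birth |>
    dplyr::count(.data$period, name = "k") |>
    dplyr::bind_rows(tibble(period = "overall",
                            k = length(unique(non_d_birth$birth_id)))) |>
    dplyr::mutate(stratum = "non-anti-D antibodies", stratum_type = "non_anti_D")

  # complete antibody/system rows with zero counts so every catalogue entry
  # appears in every period
  all_periods <- denom$period
  grid_ab <- tidyr::expand_grid(stratum = catalogue$entries$name,
                                period = all_periods) |>
    dplyr::mutate(stratum_type = "antibody")
  grid_sys <- tidyr::expand_grid(stratum = unique(catalogue$entries$system),
                                 period = all_periods) |>
    dplyr::mutate(stratum_type = "system")

  rows <- dplyr::bind_rows(
    dplyr::left_join(dplyr::bind_rows(
      tibble(stratum = "any antibody", period = all_periods,
             stratum_type = "any"),
      tibble(stratum = "non-anti-D antibodies", period = all_periods,
             stratum_type = "non_anti_D")
    ), dplyr::bind_rows(any_counts, non_d_counts),
    by = c("stratum", "period", "stratum_type")),
    dplyr::left_join(grid_sys, sys_counts,
                     by = c("stratum", "period", "stratum_type")),
    dplyr::left_join(grid_ab, ab_counts,
                     by = c("stratum", "period", "stratum_type"))
  ) |>
    dplyr::mutate(k = dplyr::coalesce(.data$k, 0L)) |>
    dplyr::left_join(denom, by = "period")

  overall_rate <- rows |>
    dplyr::filter(.data$period == "overall") |>
    dplyr::mutate(main = .data$k / .data$N >= 1e-4) |>
    dplyr::select("stratum_type", "stratum", "main")

  rows |>
    dplyr::left_join(overall_rate, by = c("stratum_type", "stratum")) |>
    dplyr::mutate(
      system = dplyr::if_else(.data$stratum_type == "antibody",
                              unname(catalogue$systems[.data$stratum]),
                              NA_character_),
      rate_per_10k = round_half_away(1e4 * .data$k / .data$N, 1),
      pct_of_ab_positive = ifelse(.data$K > 0,
                                  round_half_away(100 * .data$k / .data$K, 1),
                                  NA_real_),
      panel = dplyr::if_else(.data$main, "main", "rare")
    ) |>
    dplyr::select("stratum_type", "stratum", "system", "period", "k", "N",
                  "rate_per_10k", "pct_of_ab_positive", "panel") |>
    dplyr::arrange(factor(.data$stratum_type,
                          c("any", "non_anti_D", "system", "antibody")),
                   .data$stratum, .data$period)
}

#' Count multi-antibody combinations
#'
#' Counts births by their detected antibody combination (two or more
#' antibodies), by default over the exact detected set, so the counts
#' partition the multi-antibody births. With `mode = "subset"` a birth
#' contributes to every listed combination contained in its set.
#'
#' @param profiles Antibody profiles from [classify_births()].
#' @param mode `"exact"` (default) or `"subset"`.
#' @return Tibble sorted by descending count: `antibody_key`, `antibodies`
#'   (list-column), `n_births`, `pct_of_ab_positive` (denominator: all
#'   antibody-positive births).
#' @export
combination_counts <- function(profiles, mode = c("exact", "subset")) {
  mode <- match.arg(mode)
  check_columns(profiles, c("antibody_key", "n_antibodies", "any_antibody"),
                "profile table")
  K <- sum(profiles$any_antibody)
  multi <- profiles[profiles$n_antibodies >= 2, , drop = FALSE]
  if (nrow(multi) == 0) {
    return(tibble(antibody_key = character(), antibodies = list(),
                  n_births = integer(), pct_of_ab_positive = numeric()))
  }
  if (mode == "exact") {
    out <- multi |>
      dplyr::count(.data$antibody_key, name = "n_births")
  } else {
    combos <- unique(multi$antibody_key)
    combo_sets <- strsplit(combos, ";", fixed = TRUE)
    all_sets <- strsplit(profiles$antibody_key[profiles$any_antibody], ";",
                         fixed = TRUE)
    n <- vapply(combo_sets, function(cs) {
      sum(vapply(all_sets, function(s) all(cs %in% s), logical(1)))
    }, integer(1))
    out <- tibble(antibody_key = combos, n_births = n)
  }
  out |>
    dplyr::mutate(
      antibodies = strsplit(.data$antibody_key, ";", fixed = TRUE),
      pct_of_ab_positive = round_half_away(100 * .data$n_births / K, 1)
    ) |>
    dplyr::arrange(dplyr::desc(.data$n_births), .data$antibody_key) |>
    dplyr::select("antibody_key", "antibodies", "n_births",
                  "pct_of_ab_positive")
}

#' Cohort characteristics by calendar period
#'
#' Summarises the study population per period and overall: births, distinct
#' women, maternal age (mean, SD), mean parity, percent male infants, and
#' the maternal ABO/RhD and country-of-birth distributions. A woman giving
#' birth in several periods is counted once per period but only once
#' overall, so the overall women count is not the row sum.
#'
#' @param births Study-population birth table with maternal covariates.
#' @param bins Period bins.
#' @return Long tibble with columns `period`, `measure`, `group`, `value`.
#' @export
characteristics_table <- function(births, bins = default_period_bins()) {
  check_columns(births, c("birth_id", "mother_id", "maternal_age", "parity",
                          "abo_rhd", "infant_sex", "country_of_birth"),
                "birth table")
  if (!"year" %in% names(births)) {
    births$year <- as.integer(format(births$delivery_date, "%Y"))
  }
  births$period <- assign_period(births$year, bins)
  if (anyNA(births$period)) {
    abort("period bins do not cover every delivery year",
          class = "rbcscreen_config_error")
  }
  summarise_block <- function(df, label) {
    scalars <- tibble(
      period = label,
      measure = c("births", "women", "maternal_age_mean", "maternal_age_sd",
                  "parity_mean", "male_pct"),
      group = NA_character_,
      value = c(nrow(df), length(unique(df$mother_id)),
                round_half_away(mean(df$maternal_age), 1),
                round_half_away(stats::sd(df$maternal_age), 1),
                round_half_away(mean(df$parity), 1),
                round_half_away(100 * mean(df$infant_sex == "male"), 1))
    )
    pct_of <- function(col, measure) {
      df |>
        dplyr::count(group = .data[[col]]) |>
        dplyr::mutate(period = label, measure = measure,
                      value = round_half_away(100 * .data$n / nrow(df), 1)) |>
        dplyr::select("period", "measure", "group", "value")
    }
    dplyr::bind_rows(scalars, pct_of("abo_rhd", "abo_rhd_pct"),
                     pct_of("country_of_birth", "country_pct"))
  }
  per <- lapply(bins$label, function(lbl) {
    summarise_block(births[births$period == lbl, , drop = FALSE], lbl)
  })
  dplyr::bind_rows(c(per, list(summarise_block(births, "overall"))))
}

#' Per-year prevalence rates for trend displays
#'
#' @param profiles Antibody profiles covering the study population.
#' @param births Study-population birth table.
#' @param strata Canonical antibody names to tabulate; `"any antibody"` and
#'   `"non-anti-D antibodies"` are always included.
#' @return Tibble with `stratum`, `year`, `k`, `N`, `rate_per_10k`.
#' @export
yearly_prevalence <- function(profiles, births,
                              strata = c("anti-D", "anti-E", "anti-c", "anti-K")) {
  check_columns(births, "birth_id", "birth table")
  if (!"year" %in% names(births)) {
    births$year <- as.integer(format(births$delivery_date, "%Y"))
  }
  prof <- dplyr::left_join(births[, c("birth_id", "year")],
                           profiles[, c("birth_id", "antibody_key",
                                        "any_antibody")],
                           by = "birth_id")
  denom <- prof |> dplyr::count(.data$year, name = "N")
  sets <- strsplit(prof$antibody_key, ";", fixed = TRUE)
  pairs <- tibble(
    birth_id = rep.int(prof$birth_id, lengths(sets)),
    year = rep.int(prof$year, lengths(sets)),
    name = unlist(sets, use.names = FALSE)
  )
  counts <- dplyr::bind_rows(
    pairs |> dplyr::filter(.data$name %in% strata) |>
      dplyr::count(stratum = .data$name, .data$year, name = "k"),
    prof |> dplyr::filter(.data$any_antibody) |>
      dplyr::count(.data$year, name = "k") |>
      dplyr::mutate(stratum = "any antibody"),
    pairs |> dplyr::filter(.data$name != "anti-D") |>
      dplyr::distinct(.data$birth_id, .data$year) |>
      dplyr::count(.data$year, name = "k") |>
      dplyr::mutate(stratum = "non-anti-D antibodies")
  )
  tidyr::expand_grid(stratum = unique(counts$stratum), year = denom$year) |>
    dplyr::left_join(counts, by = c("stratum", "year")) |>
    dplyr::mutate(k = dplyr::coalesce(.data$k, 0L)) |>
    dplyr::left_join(denom, by = "year") |>
    dplyr::mutate(rate_per_10k = round_half_away(1e4 * .data$k / .data$N, 1)) |>
    dplyr::arrange(.data$stratum, .data$year)
}
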