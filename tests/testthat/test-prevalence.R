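mk_profiles <- function(keys) {
  tibble::tibble(
    birth_id = sprintf("b%03d", seq_along(keys)),
    antibodies = strsplit(keys, ";", fixed = TRUE),
    antibody_key = keys,
    n_antibodies = lengths(strsplit(keys, ";", fixed = TRUE)),
    any_antibody = nzchar(keys),
    prophylaxis_suspected = FALSE,
    has_screening = TRUE
  )
}

mk_pop <- function(n, years = 1984L) {
  tibble::tibble(birth_id = sprintf("b%03d", seq_len(n)),
                 year = rep_len(years, n))
}

test_that("prevalence_rate rounds half away from zero to one decimal", {
  expect_equal(prevalence_rate(1296, 920903), 14.1)
  expect_equal(prevalence_rate(0, 920903), 0.0)
  expect_equal(prevalence_rate(1283, 920903), 13.9)
  expect_error(prevalence_rate(0, 0), class = "rbcscreen_undefined_rate_error")
  expect_equal(round_half_away(0.05, 1), 0.1)
  expect_equal(round_half_away(-0.05, 1), -0.1)
  expect_equal(round_half_away(0.25, 1), 0.3)
})

test_that("tabulation enumerates any, anti-D and non-anti-D strata", {
  prof <- mk_profiles(c("anti-D", "anti-E", ""))
  tab <- tabulate_prevalence(prof, mk_pop(3))
  ov <- tab[tab$period == "overall", ]
  expect_equal(ov$k[ov$stratum == "any antibody"], 2)
  expect_equal(ov$k[ov$stratum == "anti-D"], 1)
  expect_equal(ov$k[ov$stratum == "non-anti-D antibodies"], 1)
  expect_equal(ov$pct_of_ab_positive[ov$stratum == "any antibody"], 100)
})

test_that("a birth with anti-D plus another antibody counts in both rows", {
  prof <- mk_profiles(c("anti-C;anti-D", "anti-D", "anti-E", ""))
  ov <- tabulate_prevalence(prof, mk_pop(4))
  ov <- ov[ov$period == "overall", ]
  k <- function(s) ov$k[ov$stratum == s]
  expect_equal(k("anti-D"), 2)
  expect_equal(k("non-anti-D antibodies"), 2)  # overlap, not a partition
  expect_equal(k("any antibody"), 3)
  # system row bounds its member antibodies
  expect_gte(k("Rh"), max(k("anti-C"), k("anti-D"), k("anti-E")))
})

test_that("period counts partition the overall count for every stratum", {
  reg <- generate_population(noiseless_config(n_mothers = 4000, rng_seed = 31))
  births <- flag_screening(clean_births(reg$births),
                           link_records(clean_births(reg$births),
                                        clean_labs(reg$lab_records)))
  linked <- link_records(births, clean_labs(reg$lab_records))
  prof <- classify_births(births, linked)
  study <- births[births$has_screening, ]
  sp <- prof[match(study$birth_id, prof$birth_id), ]
  tab <- tabulate_prevalence(sp, study)
  sums <- tab |>
    dplyr::filter(period != "overall") |>
    dplyr::group_by(stratum_type, stratum) |>
    dplyr::summarise(k = sum(k), .groups = "drop")
  ov <- tab[tab$period == "overall", c("stratum_type", "stratum", "k")]
  merged <- dplyr::left_join(ov, sums, by = c("stratum_type", "stratum"),
                             suffix = c("_ov", "_sum"))
  expect_equal(merged$k_ov, merged$k_sum)
  # panel split is decided on the unrounded overall rate
  ab <- tab[tab$period == "overall" & tab$stratum_type == "antibody", ]
  expect_identical(ab$panel == "main", ab$k / ab$N >= 1e-4)
})

test_that("tabulation rejects profiles not covering the population", {
  prof <- mk_profiles(c("anti-D", ""))
  expect_error(tabulate_prevalence(prof, mk_pop(3)),
               class = "rbcscreen_consistency_error")
})

test_that("combinations are counted over exact detected sets", {
  prof <- mk_profiles(c("anti-C;anti-D", "anti-C;anti-D",
                        "anti-C;anti-D;anti-E", "anti-E", ""))
  combos <- combination_counts(prof)
  expect_equal(combos$n_births[combos$antibody_key == "anti-C;anti-D"], 2)
  expect_equal(combos$n_births[combos$antibody_key == "anti-C;anti-D;anti-E"], 1)
  # exact-set counts partition the multi-antibody births
  expect_equal(sum(combos$n_births), sum(prof$n_antibodies >= 2))

  subset <- combination_counts(prof, mode = "subset")
  expect_equal(subset$n_births[subset$antibody_key == "anti-C;anti-D"], 3)

  expect_equal(nrow(combination_counts(mk_profiles(c("anti-D", "")))), 0)
})

test_that("combination percentages use all antibody-positive births", {
  keys <- c(rep("anti-C;anti-Cw", 116), rep("anti-D", 8141 - 116))
  prof <- mk_profiles(keys)
  combos <- combination_counts(prof)
  expect_equal(combos$pct_of_ab_positive, 1.4)
})

test_that("characteristics count women once per period but once overall", {
  births <- tibble::tibble(
    birth_id = as.character(1:4),
    mother_id = c("m1", "m1", "m2", "m3"),
    year = c(1984L, 1990L, 1984L, 1984L),
    maternal_age = c(28, 30, 28, 30),
    parity = c(1, 2, 1, 1),
    abo_rhd = c("O+", "O+", "A-", "A+"),
    infant_sex = c("male", "female", "male", "male"),
    country_of_birth = "Sweden"
  )
  tab <- characteristics_table(births)
  val <- function(p, m) tab$value[tab$period == p & tab$measure == m]
  expect_equal(val("1982-1986", "births"), 3)
  expect_equal(val("1982-1986", "women"), 3)
  expect_equal(val("overall", "women"), 3)  # m1 spans two periods
  expect_gt(sum(tab$value[tab$measure == "women" & tab$period != "overall"]),
            val("overall", "women"))
  expect_equal(val("1987-1991", "maternal_age_mean"), 30.0)
  expect_equal(val("overall", "maternal_age_mean"),
               round_half_away(mean(births$maternal_age), 1))
})

test_that("period bins must be contiguous and cover the data", {
  expect_error(period_bins(c(1982, 1990), c(1986, 1996)),
               class = "rbcscreen_config_error")
  prof <- mk_profiles("anti-D")
  expect_error(tabulate_prevalence(prof, mk_pop(1, years = 1971L)),
               class = "rbcscreen_config_error")
})
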