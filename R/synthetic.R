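#' Configuration for the synthetic registry generator
#'
#' Bundles and validates every knob of the synthetic birth-register and
#' laboratory-record generator. Defaults emulate the national screening
#' setting the package targets: a 1982--2002 study window, county-by-county
#' computerization onset producing the characteristic coverage ramp, RhD
#' typing fractions and per-antibody positivity probabilities matching the
#' overall prevalence rates reported for the Swedish cohort, retesting of
#' RhD-negative women at gestational weeks 25 and 35, and a small rate of
#' free-text noise (misspelled mentions and stray antibody-like tokens).
#'
#' @param n_mothers Number of mothers to simulate.
#' @param years Inclusive calendar-year range, length 2.
#' @param counties Data frame with columns `county`, `onset_year`
#'   (computerization onset; `NA` means never computerized) and `weight`
#'   (relative population share). A county whose onset equals the first study
#'   year is treated as computerized before the study started, so none of its
#'   records are date-censored.
#' @param antibody_probs Named numeric vector: per-birth positivity
#'   probability for each canonical antibody name in the catalogue.
#' @param cooccurrence Data frame of co-occurrence rules with columns
#'   `condition` (";"-separated antibody names), `target` and `factor`: given
#'   all condition antibodies present, the target's conditional probability
#'   is `factor` times its marginal probability. The generator compensates
#'   the probability in the complement so the configured marginal rate is
#'   preserved exactly. A rule's target may not be `anti-D` and may not be
#'   used as a condition of a later rule.
#' @param prophylaxis_prob Probability that an RhD-negative pregnancy without
#'   true anti-D immunization carries a prophylaxis-related anti-D annotation
#'   in its laboratory text.
#' @param misspelling_prob Probability that a rendered antibody mention is
#'   corrupted by a typo (recorded in the ground truth).
#' @param noise_prob Probability that a lab record of an antibody-positive
#'   pregnancy receives a stray token resembling an antibody not truly
#'   present (recorded in the ground truth). Stray tokens only occur where
#'   antibody names are typed free-hand, which is on the records of women
#'   who screened positive; the default corresponds to the order of one
#'   stray entry in a thousand such records, matching what a chart review
#'   of a few thousand screening records would surface as a single
#'   misclassified entry.
#' @param retest_weeks Gestational weeks of the RhD-negative retest schedule.
#' @param screen_week,identification_week,prophylaxis_week Gestational weeks
#'   of the first-visit screen, the antibody identification record of
#'   positive pregnancies, and the prophylaxis annotation record.
#' @param coverage_rate Probability that a pregnancy's records are
#'   computerized once the county has passed its onset year.
#' @param abo_probs Named probabilities of maternal ABO/RhD groups.
#' @param country_probs Named probabilities of mother's country-of-birth
#'   categories.
#' @param twin_prob Probability that a delivery is a twin delivery.
#' @param stillbirth_prob,male_prob Per-birth stillbirth and male-infant
#'   probabilities.
#' @param mean_first_age,sd_age Normal distribution (years) of maternal age
#'   at first delivery, truncated to 16--45.
#' @param births_per_mother_rate Poisson rate of deliveries beyond the first.
#' @param rng_seed Integer seed; a fixed seed gives byte-identical output.
#' @param catalogue An `antibody_catalogue`; antibody names in
#'   `antibody_probs` and `cooccurrence` must come from it.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_mothers = 5000,
                             years = c(1982, 2002),
                             counties = default_counties(),
                             antibody_probs = default_antibody_probs(),
                             cooccurrence = default_cooccurrence(),
                             prophylaxis_prob = 0.05,
                             misspelling_prob = 0.01,
                             noise_prob = 0.001,
                             retest_weeks = c(25, 35),
                             screen_week = 9,
                             identification_week = 11,
                             prophylaxis_week = 28,
                             coverage_rate = 0.937,
                             abo_probs = default_abo_probs(),
                             country_probs = default_country_probs(),
                             twin_prob = 0.014,
                             stillbirth_prob = 0.004,
                             male_prob = 0.513,
                             mean_first_age = 27.5,
                             sd_age = 5,
                             births_per_mother_rate = 0.8,
                             rng_seed = 1L,
                             catalogue = default_catalogue()) {
  if (!is.numeric(n_mothers) || length(n_mothers) != 1 || n_mothers < 1) {
    abort("`n_mothers` must be a positive integer", class = "rbcscreen_config_error")
  }
  if (!is.numeric(years) || length(years) != 2 || years[2] < years[1]) {
    abort("`years` must be an inclusive year range c(first, last)",
          class = "rbcscreen_config_error")
  }
  counties <- as_tibble(counties)
  check_columns(counties, c("county", "onset_year", "weight"), "`counties`")
  if (nrow(counties) == 0) {
    abort("`counties` must list at least one county", class = "rbcscreen_config_error")
  }
  onset <- counties$onset_year
  if (any(!is.na(onset) & (onset < years[1] | onset > years[2]))) {
    abort("`counties$onset_year` must lie within `years` or be NA (never)",
          class = "rbcscreen_config_error")
  }
  check_probability(antibody_probs, "antibody_probs")
  if (is.null(names(antibody_probs)) && length(antibody_probs) > 0) {
    abort("`antibody_probs` must be a named vector", class = "rbcscreen_config_error")
  }
  unknown <- setdiff(names(antibody_probs), catalogue$entries$name)
  if (length(unknown) > 0) {
    abort(sprintf("`antibody_probs` names not in catalogue: %s",
                  paste(unknown, collapse = ", ")),
          class = "rbcscreen_config_error")
  }
  for (field in c("prophylaxis_prob", "misspelling_prob", "noise_prob",
                  "coverage_rate", "twin_prob", "stillbirth_prob", "male_prob")) {
    check_probability(get(field), field)
  }
  cooccurrence <- as_tibble(cooccurrence)
  if (nrow(cooccurrence) > 0) {
    check_columns(cooccurrence, c("condition", "target", "factor"), "`cooccurrence`")
    if (anyDuplicated(cooccurrence$target)) {
      abort("`cooccurrence` targets must be unique", class = "rbcscreen_config_error")
    }
    if ("anti-D" %in% cooccurrence$target) {
      abort("`cooccurrence` target may not be anti-D", class = "rbcscreen_config_error")
    }
    conds <- strsplit(cooccurrence$condition, ";", fixed = TRUE)
    for (i in seq_along(conds)) {
      later_targets <- cooccurrence$target[seq_along(conds) > i]
      if (any(conds[[i]] %in% later_targets)) {
        abort("`cooccurrence` rules must be ordered so no condition antibody is the target of a later rule",
              class = "rbcscreen_config_error")
      }
      bad <- setdiff(c(conds[[i]], cooccurrence$target[i]), names(antibody_probs))
      if (length(bad) > 0) {
        abort(sprintf("`cooccurrence` names without configured probability: %s",
                      paste(bad, collapse = ", ")),
              class = "rbcscreen_config_error")
      }
    }
  }
  check_probability(sum(abo_probs), "abo_probs (sum)")
  structure(list(
    n_mothers = as.integer(n_mothers), years = as.integer(years),
    counties = counties, antibody_probs = antibody_probs,
    cooccurrence = cooccurrence, prophylaxis_prob = prophylaxis_prob,
    misspelling_prob = misspelling_prob, noise_prob = noise_prob,
    retest_weeks = retest_weeks, screen_week = screen_week,
    identification_week = identification_week,
    prophylaxis_week = prophylaxis_week, coverage_rate = coverage_rate,
    abo_probs = abo_probs, country_probs = country_probs,
    twin_prob = twin_prob, stillbirth_prob = stillbirth_prob,
    male_prob = male_prob, mean_first_age = mean_first_age, sd_age = sd_age,
    births_per_mother_rate = births_per_mother_rate,
    rng_seed = as.integer(rng_seed), catalogue = catalogue
  ), class = "synthetic_config")
}

#' Default county table for the generator
#'
#' Eight counties whose computerization onsets stagger across the study
#' period: two early adopters computerized from the study start, a large
#' county reaching computerization in 1987, later adopters in 1990--1999, and
#' one county that never delivers computerized data.
#'
#' @return Tibble with columns `county`, `onset_year`, `weight`.
#' @export
default_counties <- function() {
  tibble(
    county = c("C01", "C02", "C03", "C04", "C05", "C06", "C07", "C08"),
    onset_year = c(1982, 1982, 1987, 1990, 1993, 1996, 1999, NA),
    weight = c(0.05, 0.04, 0.22, 0.15, 0.15, 0.15, 0.12, 0.12)
  )
}

#' Default per-birth antibody positivity probabilities
#'
#' Per-10,000 rates of the most common maternal red-cell antibodies in the
#' Swedish 1982--2002 cohort, expressed as per-birth probabilities, plus
#' small probabilities for a handful of rarer specificities.
#'
#' @return Named numeric vector of probabilities.
#' @export
default_antibody_probs <- function() {
  c("anti-D" = 14.1, "anti-Lea" = 13.9, "anti-E" = 13.0, "anti-M" = 8.0,
    "unspecified" = 6.0, "anti-K" = 5.8, "anti-Leb" = 4.7, "anti-C" = 4.5,
    "anti-c" = 4.5, "anti-P1" = 4.5, "anti-Bg" = 2.5, "anti-A1" = 2.4,
    "anti-Fya" = 2.0, "anti-Cw" = 1.9, "anti-Jka" = 1.8, "anti-Lua" = 1.0,
    "anti-S" = 0.6, "anti-Kpa" = 0.5, "anti-N" = 0.3, "anti-e" = 0.3,
    "anti-Jkb" = 0.3, "anti-Wra" = 0.3, "anti-s" = 0.2, "anti-k" = 0.2,
    "anti-Fyb" = 0.2, "anti-Lub" = 0.2) / 1e4
}

#' Default antibody co-occurrence rules
#'
#' Relative-risk style boosts reproducing the most frequent antibody
#' combinations (anti-C with anti-Cw, anti-E with anti-c, the Lewis pair, and
#' anti-D with anti-C/anti-E). Marginal rates are preserved by compensation,
#' see [synthetic_config()].
#'
#' @return Tibble with columns `condition`, `target`, `factor`.
#' @export
default_cooccurrence <- function() {
  tibble(
    condition = c("anti-D", "anti-D", "anti-E", "anti-C", "anti-Lea", "anti-C"),
    target = c("anti-C", "anti-E", "anti-c", "anti-Cw", "anti-Leb", "anti-e"),
    factor = c(202, 44, 195, 147, 154, 1356)
  )
}

#' @rdname default_counties
#' @export
default_abo_probs <- function() {
  c("A+" = 0.385, "B+" = 0.102, "AB+" = 0.046, "O+" = 0.318,
    "A-" = 0.067, "B-" = 0.016, "AB-" = 0.008, "O-" = 0.054,
    "unknown" = 0.004)
}

#' @rdname default_counties
#' @export
default_country_probs <- function() {
  c("Sweden" = 0.836, "Other Nordic" = 0.039, "Other" = 0.124,
    "Unknown" = 0.001)
}

rhd_negative_groups <- c("A-", "B-", "AB-", "O-")

# Free-text boilerplate. Swedish and English interleaved so the matcher is
# exercised against both dialects; none of these templates may contain an
# antibody mention (asserted in the test suite).
.templates <- list(
  negative = c(
    "Negativ antikroppsscreening",
    "Inga irreguljära erytrocytantikroppar påvisade",
    "Ak-screening negativ",
    "Screening negativ, inga antikroppar",
    "BAS-test negativ, blodgruppering klar",
    "Blodgruppering klar, screening utan anmärkning",
    "Antibody screen negative",
    "No irregular antibodies detected",
    "Neg screen"
  ),
  positive_screen = c(
    "Positiv antikroppsscreening, id följer",
    "Antikroppsscreening positiv, se identifiering",
    "Positive antibody screen, identification to follow"
  ),
  id_prefix = c(
    "Irreguljära antikroppar påvisade:",
    "Identifierade antikroppar:",
    "Antikroppsidentifiering:",
    "Antibody identification:",
    "Id:"
  ),
  id_suffix = c("", "", " påvisad", " verifierad")
)

# Vectorised mention renderer: one varied surface form per canonical name.
# Misspelled mentions get their 2nd and 3rd characters swapped, which breaks
# the "anti" stem (or the standalone phrase) so the typo is no longer
# machine-readable -- the false-negative error mode of free-text records.
render_mentions <- function(names, catalogue, misspell = rep(FALSE, length(names))) {
  ent <- catalogue$entries
  i <- match(names, ent$name)
  if (anyNA(i)) {
    abort(sprintf("unknown antibody name%s: %s",
                  if (sum(is.na(i)) > 1) "s" else "",
                  paste(unique(names[is.na(i)]), collapse = ", ")),
          class = "rbcscreen_vocabulary_error")
  }
  n <- length(names)
  if (n == 0) return(character(0))
  forms <- strsplit(ent$surface_forms[i], "|", fixed = TRUE)
  nf <- lengths(forms)
  pick <- floor(runif(n) * nf) + 1L
  surf <- unlist(forms, use.names = FALSE)[cumsum(nf) - nf + pick]
  fixed <- ent$case_fixed[i]
  u <- runif(n)
  surf <- ifelse(!fixed & u < 0.12, toupper(surf),
                 ifelse(!fixed & u >= 0.12 & u < 0.24, tolower(surf), surf))
  standalone <- names == "unspecified"
  pre <- sample(c("anti", "Anti", "ANTI"), n, replace = TRUE,
                prob = c(0.5, 0.3, 0.2))
  sep <- sample(c("-", " "), n, replace = TRUE, prob = c(0.85, 0.15))
  out <- ifelse(standalone, surf, paste0(pre, sep, surf))
  if (any(misspell)) {
    s <- out[misspell]
    out[misspell] <- paste0(substr(s, 1, 1), substr(s, 3, 3),
                            substr(s, 2, 2), substr(s, 4, nchar(s)))
  }
  out
}

sample_prophylaxis_phrase <- function(n, catalogue) {
  phrases <- unlist(strsplit(catalogue$prophylaxis$surface_forms, "|",
                             fixed = TRUE), use.names = FALSE)
  phrases[sample.int(length(phrases), n, replace = TRUE)]
}

#' Render a free-text laboratory result
#'
#' Produces one plausible screening/identification result string containing
#' exactly one surface form per antibody in `antibodies`, with varied case,
#' separator and parenthesisation, surrounded by Swedish or English
#' boilerplate. Uses the current RNG state.
#'
#' @param antibodies Character vector of canonical antibody names (may be
#'   empty, giving a negative-screen text with no mention).
#' @param style Optional list overriding the random variation: elements
#'   `prefix` (e.g. `"ANTI"`), `sep` (`"-"` or `" "`) and `lang`
#'   (`"sv"`/`"en"` boilerplate).
#' @param prophylaxis If `TRUE`, a prophylaxis phrase is appended, as on
#'   records documenting administered anti-D immunoglobulin.
#' @param misspell If `TRUE`, one mention is corrupted by a typo; the
#'   corrupted mention is returned in attribute `"corrupted"`.
#' @param catalogue An `antibody_catalogue`.
#' @return A single string; rendered mention texts in attribute
#'   `"mentions"`.
#' @export
#' @examples
#' set.seed(1)
#' render_lab_text(c("anti-E", "anti-c"))
render_lab_text <- function(antibodies, style = NULL, prophylaxis = FALSE,
                            misspell = FALSE, catalogue = default_catalogue()) {
  stopifnot(is.character(antibodies) || length(antibodies) == 0)
  antibodies <- as.character(antibodies)
  bad <- setdiff(antibodies, catalogue$entries$name)
  if (length(bad) > 0) {
    abort(sprintf("unknown antibody name%s: %s",
                  if (length(bad) > 1) "s" else "", paste(bad, collapse = ", ")),
          class = "rbcscreen_vocabulary_error")
  }
  lang <- style$lang %||% sample(c("sv", "en"), 1, prob = c(0.7, 0.3))
  if (length(antibodies) == 0) {
    base <- if (prophylaxis) "" else sample(.templates$negative, 1)
    ment <- character(0)
  } else {
    mis <- rep(FALSE, length(antibodies))
    if (isTRUE(misspell)) mis[sample.int(length(antibodies), 1)] <- TRUE
    ment <- render_mentions(antibodies, catalogue, mis)
    if (!is.null(style$prefix)) {
      ment <- ifelse(antibodies == "unspecified", ment,
                     stringr::str_replace(ment, "^[AaNnTtIi]{4}[- ]",
                                          paste0(style$prefix, style$sep %||% "-")))
    }
    prefix <- if (lang == "sv") .templates$id_prefix[1] else .templates$id_prefix[4]
    base <- paste0(prefix, " ", paste(ment, collapse = ", "))
    if (isTRUE(misspell)) attr(base, "corrupted") <- ment[mis]
  }
  if (isTRUE(prophylaxis)) {
    phrase <- sample_prophylaxis_phrase(1, catalogue)
    base <- if (nzchar(base)) paste0(base, ", ", phrase) else phrase
  }
  structure(base, mentions = ment, corrupted = attr(base, "corrupted"))
}

#' Generate a synthetic birth register and laboratory record table
#'
#' Simulates mothers, deliveries (with twins), maternal covariates, true
#' antibody status with configurable co-occurrence structure, prophylaxis
#' annotations, county-by-year computerization onset, and free-text
#' laboratory records rendered with notation variants -- together with the
#' ground truth needed to validate every downstream pipeline stage.
#'
#' Records are generated for a pregnancy only when the mother's county has
#' reached its computerization onset by the delivery year and the pregnancy
#' is covered (probability `coverage_rate`); records dated before the onset
#' year are additionally censored, producing the partial-coverage ramp in a
#' county's onset year. Anti-D is only assigned to RhD-negative mothers
#' (scaled so the configured marginal per-birth rate is preserved), and
#' prophylaxis annotations occur only in RhD-negative pregnancies without
#' true anti-D immunization.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `rbc_registry` with elements `births` (raw birth
#'   register), `lab_records` (free-text laboratory records), `truth`
#'   (per-birth ground truth: `birth_id`, `true_antibodies`, `prophylaxis`)
#'   and `truth_mentions` (per-record rendered mentions with `corrupted`,
#'   `noise` and `prophylaxis` flags).
#' @export
#' @examples
#' reg <- generate_population(synthetic_config(n_mothers = 200, rng_seed = 42))
#' reg$births
generate_population <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    abort("`config` must be created by synthetic_config()",
          class = "rbcscreen_config_error")
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$rng_seed)

  n_m <- config$n_mothers
  years <- config$years
  n_years <- years[2] - years[1] + 1
  catalogue <- config$catalogue

  ## -- mothers ------------------------------------------------------------
  mother_id <- sprintf("M%06d", seq_len(n_m))
  cty <- config$counties
  m_county <- cty$county[sample.int(nrow(cty), n_m, replace = TRUE,
                                    prob = cty$weight)]
  m_abo <- names(config$abo_probs)[sample.int(length(config$abo_probs), n_m,
                                              replace = TRUE,
                                              prob = config$abo_probs)]
  m_country <- names(config$country_probs)[
    sample.int(length(config$country_probs), n_m, replace = TRUE,
               prob = config$country_probs)]
  m_first_age <- pmin(pmax(rnorm(n_m, config$mean_first_age, config$sd_age), 16), 45)

  ## -- deliveries ----------------------------------------------------------
  k <- pmin(1L + rpois(n_m, config$births_per_mother_rate), min(6L, n_years))
  di <- rep.int(seq_len(n_m), k)
  nd <- length(di)
  day0 <- as.integer(as.Date(sprintf("%d-01-01", years[1])))
  day1 <- as.integer(as.Date(sprintf("%d-12-31", years[2])))
  span <- day1 - day0 + 1L
  ddate <- day0 + sample.int(span, nd, replace = TRUE) - 1L
  # deliveries of one mother must be spaced beyond the pregnancy window so a
  # record can never be shared between two of her pregnancies by accident
  for (iter in 1:1000) {
    ord <- order(di, ddate)
    clash <- which(diff(ddate[ord]) < 330L & diff(di[ord]) == 0L)
    if (length(clash) == 0) break
    redo <- ord[clash + 1L]
    ddate[redo] <- day0 + sample.int(span, length(redo), replace = TRUE) - 1L
  }
  ord <- order(di, ddate)
  parity <- integer(nd)
  parity[ord] <- sequence(k)
  first_date <- ddate[ord][cumsum(k) - k + 1L]  # one per mother, in order

  d_year <- as.POSIXlt(as.Date(ddate, origin = "1970-01-01"))$year + 1900L
  rhd_neg <- m_abo[di] %in% rhd_negative_groups

  ## -- true antibody status (per delivery) ---------------------------------
  probs <- config$antibody_probs
  ab_names <- names(probs)
  p_neg <- sum(config$abo_probs[rhd_negative_groups])
  ind <- matrix(FALSE, nrow = nd, ncol = length(ab_names),
                dimnames = list(NULL, ab_names))
  for (a in ab_names) {
    if (a == "anti-D") {
      p_cond <- probs[[a]] / p_neg
      if (p_cond > 1) {
        abort("anti-D probability exceeds the RhD-negative fraction",
              class = "rbcscreen_config_error")
      }
      ind[rhd_neg, a] <- runif(sum(rhd_neg)) < p_cond
    } else {
      ind[, a] <- runif(nd) < probs[[a]]
    }
  }
  if (nrow(config$cooccurrence) > 0) {
    for (r in seq_len(nrow(config$cooccurrence))) {
      cond <- strsplit(config$cooccurrence$condition[r], ";", fixed = TRUE)[[1]]
      tgt <- config$cooccurrence$target[r]
      f <- config$cooccurrence$factor[r]
      p_t <- probs[[tgt]]
      if (f * p_t > 1) {
        abort(sprintf("cooccurrence factor for %s gives probability > 1", tgt),
              class = "rbcscreen_config_error")
      }
      on_cond <- rowSums(ind[, cond, drop = FALSE]) == length(cond)
      n_s <- sum(on_cond)
      # complement probability chosen so the realised marginal stays p_t in
      # expectation; in tiny populations a large factor can make this
      # negative, in which case it is clamped (negligible bias, as the
      # boosted stratum is then a handful of births)
      q_else <- max((p_t * nd - n_s * f * p_t) / max(nd - n_s, 1L), 0)
      ind[, tgt] <- FALSE
      ind[on_cond, tgt] <- runif(n_s) < f * p_t
      ind[!on_cond, tgt] <- runif(nd - n_s) < q_else
    }
  }
  hits <- which(ind, arr.ind = TRUE)
  truth_key <- character(nd)
  if (nrow(hits) > 0) {
    sp <- split(ab_names[hits[, 2]], hits[, 1])
    truth_key[as.integer(names(sp))] <-
      vapply(sp, function(s) paste(sort(s), collapse = ";"), character(1))
  }
  positive <- nzchar(truth_key)
  has_anti_d <- if ("anti-D" %in% ab_names) ind[, "anti-D"] else rep(FALSE, nd)
  proph <- rhd_neg & !has_anti_d & runif(nd) < config$prophylaxis_prob

  ## -- births (twins share the delivery) ------------------------------------
  twin <- runif(nd) < config$twin_prob
  reps <- 1L + twin
  b_del <- rep.int(seq_len(nd), reps)
  birth_order <- sequence(reps)
  nb <- length(b_del)
  delivery_date <- as.Date(ddate[b_del], origin = "1970-01-01")
  births <- tibble(
    mother_id = mother_id[di[b_del]],
    delivery_date = delivery_date,
    parity = parity[b_del],
    birth_order = birth_order,
    county = m_county[di[b_del]],
    maternal_age = as.integer(floor(
      m_first_age[di[b_del]] + (ddate[b_del] - first_date[di[b_del]]) / 365.25)),
    abo_rhd = m_abo[di[b_del]],
    country_of_birth = m_country[di[b_del]],
    infant_sex = ifelse(runif(nb) < config$male_prob, "male", "female"),
    stillbirth = runif(nb) < config$stillbirth_prob
  )
  truth <- tibble(
    birth_id = paste(births$mother_id, format(births$delivery_date),
                     births$parity, births$birth_order, sep = "|"),
    mother_id = births$mother_id,
    delivery_date = births$delivery_date,
    true_antibodies = truth_key[b_del],
    prophylaxis = proph[b_del]
  )

  ## -- laboratory records ---------------------------------------------------
  onset <- cty$onset_year[match(m_county, cty$county)]
  d_onset <- onset[di]
  computerized <- !is.na(d_onset) & d_year >= d_onset &
    runif(nd) < config$coverage_rate

  offs_screen <- (40L - config$screen_week) * 7L
  offs_id <- (40L - config$identification_week) * 7L
  offs_proph <- (40L - config$prophylaxis_week) * 7L
  offs_retest <- (40L - config$retest_weeks) * 7L

  idx_screen <- which(computerized)
  idx_retest <- which(computerized & rhd_neg)
  idx_id <- which(computerized & positive)
  idx_proph <- which(computerized & proph)

  rec_del <- c(idx_screen, rep(idx_retest, length(offs_retest)), idx_id, idx_proph)
  rec_type <- c(rep("screen", length(idx_screen)),
                rep("retest", length(idx_retest) * length(offs_retest)),
                rep("identification", length(idx_id)),
                rep("prophylaxis", length(idx_proph)))
  rec_off <- c(rep(offs_screen, length(idx_screen)),
               rep(offs_retest, each = length(idx_retest)),
               rep(offs_id, length(idx_id)),
               rep(offs_proph, length(idx_proph)))
  rec_date <- ddate[rec_del] - rec_off
  # censor records dated before the county's onset year (late adopters only)
  rec_year <- as.POSIXlt(as.Date(rec_date, origin = "1970-1-1"))$year + 1900L
  rec_onset <- d_onset[rec_del]
  keep <- !(rec_onset > years[1] & rec_year < rec_onset)
  rec_del <- rec_del[keep]; rec_type <- rec_type[keep]; rec_date <- rec_date[keep]

  o <- order(rec_del, rec_date)
  rec_del <- rec_del[o]; rec_type <- rec_type[o]; rec_date <- rec_date[o]
  nrec <- length(rec_del)
  record_id <- sprintf("L%08d", seq_len(nrec))

  text <- character(nrec)
  is_screenish <- rec_type %in% c("screen", "retest")
  neg_rows <- which(is_screenish & !positive[rec_del])
  pos_rows <- which(is_screenish & positive[rec_del])
  text[neg_rows] <- sample(.templates$negative, length(neg_rows), replace = TRUE)
  text[pos_rows] <- sample(.templates$positive_screen, length(pos_rows),
                           replace = TRUE)

  gt_mentions <- list()

  id_rows <- which(rec_type == "identification")
  if (length(id_rows) > 0) {
    sets <- strsplit(truth_key[rec_del[id_rows]], ";", fixed = TRUE)
    n_per <- lengths(sets)
    ment_rec <- rep.int(id_rows, n_per)
    ment_name <- unlist(sets, use.names = FALSE)
    mis <- runif(length(ment_name)) < config$misspelling_prob
    ment_text <- render_mentions(ment_name, catalogue, mis)
    joined <- vapply(split(ment_text, ment_rec), paste, character(1),
                     collapse = ", ")
    prefix <- sample(.templates$id_prefix, length(id_rows), replace = TRUE)
    suffix <- sample(.templates$id_suffix, length(id_rows), replace = TRUE)
    text[id_rows] <- paste0(prefix, " ", joined[as.character(id_rows)], suffix)
    gt_mentions$true <- tibble(
      record_id = record_id[ment_rec], name = ment_name,
      corrupted = mis, noise = FALSE, prophylaxis = FALSE
    )
  }

  pr_rows <- which(rec_type == "prophylaxis")
  if (length(pr_rows) > 0) {
    d_ment <- render_mentions(rep("anti-D", length(pr_rows)), catalogue)
    phrase <- sample_prophylaxis_phrase(length(pr_rows), catalogue)
    text[pr_rows] <- paste0(d_ment, ", ", phrase)
    gt_mentions$proph <- tibble(
      record_id = record_id[pr_rows], name = "anti-D",
      corrupted = FALSE, noise = FALSE, prophylaxis = TRUE
    )
  }

  if (config$noise_prob > 0 && nrec > 0) {
    # stray tokens occur where technicians type antibody names free-hand,
    # i.e. on records of pregnancies that screened positive; negative
    # screens are terse template output
    noisy <- which(runif(nrec) < config$noise_prob & positive[rec_del])
    if (length(noisy) > 0) {
      noise_name <- catalogue$entries$name[
        sample.int(nrow(catalogue$entries), length(noisy), replace = TRUE)]
      noise_text <- render_mentions(noise_name, catalogue)
      text[noisy] <- paste0(text[noisy], ", ", noise_text)
      gt_mentions$noise <- tibble(
        record_id = record_id[noisy], name = noise_name,
        corrupted = FALSE, noise = TRUE, prophylaxis = FALSE
      )
    }
  }

  lab_records <- tibble(
    record_id = record_id,
    mother_id = mother_id[di[rec_del]],
    sample_date = as.Date(rec_date, origin = "1970-01-01"),
    county = m_county[di[rec_del]],
    text = text
  )
  truth_mentions <- dplyr::bind_rows(gt_mentions)
  if (nrow(truth_mentions) > 0) {
    truth_mentions <- truth_mentions[order(truth_mentions$record_id), ]
  }

  structure(list(births = births, lab_records = lab_records, truth = truth,
                 truth_mentions = truth_mentions, config = config),
            class = "rbc_registry")
}

#' @export
print.rbc_registry <- function(x, ...) {
  cat(sprintf(
    "<rbc_registry> %d births (%d mothers), %d lab records, %d antibody-positive births\n",
    nrow(x$births), length(unique(x$births$mother_id)),
    nrow(x$lab_records), sum(nzchar(x$truth$true_antibodies))
  ))
  invisible(x)
}
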