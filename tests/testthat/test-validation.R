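test_that("ppv_npv matches a brute-force confusion matrix", {
  expect_equal(ppv_npv(rep(TRUE, 100), rep(TRUE, 100))$ppv, 1.0)
  expect_equal(ppv_npv(rep(TRUE, 10), c(rep(TRUE, 9), FALSE))$ppv, 0.9)
  expect_error(ppv_npv(c(TRUE, FALSE), TRUE),
               class = "rbcscreen_alignment_error")

  set.seed(6)
  for (i in 1:20) {
    pred <- runif(50) < 0.5
    tru <- runif(50) < 0.5
    got <- ppv_npv(pred, tru)
    want <- brute_confusion(pred, tru)
    expect_equal(got[c("tp", "fp", "tn", "fn")],
                 lapply(want, function(x) as.integer(x)),
                 ignore_attr = TRUE)
  }
  # empty denominators are flagged as NA, not errors
  expect_true(is.na(ppv_npv(rep(FALSE, 5), rep(FALSE, 5))$ppv))
})

test_that("term accuracy is the verified fraction to two decimals", {
  expect_equal(term_accuracy(107, 108), 0.99)
  expect_equal(term_accuracy(5, 5), 1.0)
  expect_equal(term_accuracy(0, 5), 0.0)
  expect_true(is.na(term_accuracy(0, 0)))
})

test_that("the rule of three gives (0, 3/n) for zero events only", {
  expect_equal(rule_of_three_ci(0, 100), c(lower = 0, upper = 0.03))
  expect_equal(rule_of_three_ci(0, 300), c(lower = 0, upper = 0.01))
  expect_error(rule_of_three_ci(1, 100), class = "rbcscreen_method_error")
  # the approximation undershoots the exact zero-event upper bound
  exact_upper <- 1 - (0.05 / 2)^(1 / 100)
  expect_equal(unname(clopper_pearson_ci(0, 100)["upper"]), exact_upper,
               tolerance = 1e-10)
  expect_lt(rule_of_three_ci(0, 100)["upper"], exact_upper)
})

test_that("Clopper-Pearson bounds reproduce the printed validation interval", {
  ci <- clopper_pearson_ci(107, 108, 0.95)
  expect_equal(round(ci[["lower"]], 2), 0.95)
  expect_equal(round(ci[["upper"]], 2), 1.00)
  expect_equal(clopper_pearson_ci(10, 10)[["upper"]], 1.0)
  expect_equal(clopper_pearson_ci(0, 10)[["lower"]], 0.0)
  expect_error(clopper_pearson_ci(5, 10, level = 1.5),
               class = "rbcscreen_parameter_error")
})

test_that("Clopper-Pearson equals bisection of the binomial tails", {
  cases <- rbind(c(107, 108), c(0, 10), c(10, 10), c(3, 17), c(50, 200),
                 c(1, 2), c(95, 100))
  for (r in seq_len(nrow(cases))) {
    m <- cases[r, 1]; M <- cases[r, 2]
    expect_equal(clopper_pearson_ci(m, M), cp_bisect(m, M), tolerance = 1e-9,
                 label = sprintf("m=%d M=%d", m, M))
  }
})

test_that("Clopper-Pearson intervals reach nominal coverage in simulation", {
  set.seed(2718)
  for (p in c(0.9, 0.99)) {
    m <- rbinom(1000, 108, p)
    lo <- ifelse(m == 0, 0, qbeta(0.025, m, 108 - m + 1))
    hi <- ifelse(m == 108, 1, qbeta(0.975, m + 1, 108 - m))
    covered <- mean(lo <= p & p <= hi)
    mc_err <- 3 * sqrt(0.95 * 0.05 / 1000)
    expect_gte(covered, 0.95 - mc_err)
  }
})

test_that("validation sampling is stratified, deterministic and guarded", {
  prof <- tibble::tibble(
    birth_id = sprintf("b%03d", 1:300),
    any_antibody = rep(c(TRUE, FALSE), c(120, 180)),
    has_screening = TRUE
  )
  s1 <- sample_validation(prof, 100, 100, seed = 4)
  s2 <- sample_validation(prof, 100, 100, seed = 4)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 200)
  expect_equal(sum(s1$stratum == "positive"), 100)
  expect_true(all(s1$birth_id[s1$stratum == "positive"] %in%
                    prof$birth_id[prof$any_antibody]))
  expect_error(sample_validation(prof, 150, 100, seed = 4),
               class = "rbcscreen_sampling_error")
})

test_that("a noiseless corpus validates perfectly", {
  reg <- generate_population(noiseless_config(n_mothers = 3000, rng_seed = 17))
  births <- clean_births(reg$births)
  linked <- link_records(births, clean_labs(reg$lab_records))
  prof <- classify_births(births, linked)
  rep_ <- validate_extraction(prof, reg$truth, n_pos = 15, n_neg = 50, seed = 2)
  expect_equal(rep_$confusion$ppv, 1)
  expect_equal(rep_$confusion$npv, 1)
  expect_equal(rep_$verified_terms, rep_$detected_terms)
  g <- glance(rep_)
  expect_equal(g$term_accuracy, 1)
  td <- tidy(rep_)
  expect_true(all(td$ci_lower <= td$estimate & td$estimate <= td$ci_upper))
  expect_true("rule_of_three" %in% td$ci_method)
})

test_that("unverified terms in a noisy corpus are exactly the ground-truth noise", {
  cfg <- noiseless_config(n_mothers = 8000, rng_seed = 23)
  cfg$noise_prob <- 0.02  # heavy stray-token injection
  reg <- generate_population(cfg)
  births <- clean_births(reg$births)
  linked <- link_records(births, clean_labs(reg$lab_records))
  prof <- classify_births(births, linked)

  n_pos <- min(sum(prof$any_antibody & prof$has_screening), 100)
  rep_ <- validate_extraction(prof, reg$truth, n_pos = n_pos, n_neg = 100,
                              seed = 5)
  # oracle recount: per sampled positive birth, detected names absent from
  # the true set must all trace to injected noise mentions on its records
  samp_pos <- rep_$sample$birth_id[rep_$sample$stratum == "positive"]
  truth_sets <- strsplit(
    reg$truth$true_antibodies[match(samp_pos, reg$truth$birth_id)],
    ";", fixed = TRUE)
  det_sets <- prof$antibodies[match(samp_pos, prof$birth_id)]
  false_terms <- sum(mapply(function(d, t) sum(!(d %in% t)),
                            det_sets, truth_sets))
  expect_equal(rep_$detected_terms - rep_$verified_terms, false_terms)
  noise_names <- dplyr::inner_join(
    reg$truth_mentions[reg$truth_mentions$noise, ],
    linked[, c("record_id", "birth_id")], by = "record_id")
  for (i in seq_along(samp_pos)) {
    extra <- setdiff(det_sets[[i]], truth_sets[[i]])
    if (length(extra) > 0) {
      expect_true(all(extra %in%
                        noise_names$name[noise_names$birth_id == samp_pos[i]]))
    }
  }
  # and 1 - accuracy equals the false-term share of detected terms
  expect_equal(1 - rep_$verified_terms / rep_$detected_terms,
               false_terms / rep_$detected_terms)
})

test_that("recovery_rate compares detected and true sets exactly", {
  prof <- tibble::tibble(
    birth_id = c("a", "b", "c"),
    antibodies = list(character(0), c("anti-D"), c("anti-C", "anti-E")),
    antibody_key = c("", "anti-D", "anti-C;anti-E"),
    n_antibodies = c(0L, 1L, 2L),
    any_antibody = c(FALSE, TRUE, TRUE),
    prophylaxis_suspected = FALSE,
    has_screening = TRUE
  )
  truth <- tibble::tibble(
    birth_id = c("a", "b", "c"),
    true_antibodies = c("", "anti-D", "anti-E;anti-C")
  )
  expect_equal(recovery_rate(prof, truth), 1)
  truth$true_antibodies[2] <- "anti-K"
  expect_equal(recovery_rate(prof, truth), 2 / 3)
})
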