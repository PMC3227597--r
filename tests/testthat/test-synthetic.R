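test_that("generation is deterministic under a fixed seed", {
  cfg <- synthetic_config(n_mothers = 500, rng_seed = 77)
  a <- generate_population(cfg)
  b <- generate_population(cfg)
  expect_identical(a$births, b$births)
  expect_identical(a$lab_records, b$lab_records)
  expect_identical(a$truth, b$truth)
  expect_identical(a$truth_mentions, b$truth_mentions)
})

test_that("zero antibody probabilities give a fully negative ground truth", {
  probs <- default_antibody_probs() * 0
  cfg <- synthetic_config(n_mothers = 300, antibody_probs = probs,
                          cooccurrence = tibble::tibble(), rng_seed = 5)
  reg <- generate_population(cfg)
  expect_true(all(reg$truth$true_antibodies == ""))
})

test_that("configuration errors name the offending field", {
  expect_error(synthetic_config(misspelling_prob = 1.2),
               "misspelling_prob", class = "rbcscreen_config_error")
  expect_error(synthetic_config(counties = default_counties()[0, ]),
               "counties", class = "rbcscreen_config_error")
  expect_error(synthetic_config(antibody_probs = c("anti-Zeta" = 0.1)),
               "anti-Zeta", class = "rbcscreen_config_error")
  bad_counties <- default_counties()
  bad_counties$onset_year[1] <- 1950
  expect_error(synthetic_config(counties = bad_counties),
               "onset_year", class = "rbcscreen_config_error")
})

test_that("empirical positivity tracks the configured binomial rate", {
  # single antibody at an inflated rate so a moderate population suffices
  p <- 30 / 1e4
  cfg <- synthetic_config(
    n_mothers = 30000, antibody_probs = c("anti-Lea" = p),
    cooccurrence = tibble::tibble(), rng_seed = 11
  )
  reg <- generate_population(cfg)
  n <- nrow(reg$truth)
  phat <- mean(reg$truth$true_antibodies == "anti-Lea")
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(phat - p), 3 * se)
})

test_that("no laboratory record predates its county's computerization onset", {
  reg <- generate_population(synthetic_config(n_mothers = 3000, rng_seed = 13))
  cty <- default_counties()
  labs <- reg$lab_records
  labs$year <- as.integer(format(labs$sample_date, "%Y"))
  labs$onset <- cty$onset_year[match(labs$county, cty$county)]
  expect_false(any(is.na(labs$onset)))  # never-computerized county emits nothing
  late <- labs[labs$onset > 1982, ]
  expect_true(all(late$year >= late$onset))
  # births before onset have no screening at all
  births <- flag_screening(clean_births(reg$births),
                           link_records(clean_births(reg$births),
                                        clean_labs(labs[, 1:5])))
  births$year <- as.integer(format(births$delivery_date, "%Y"))
  births$onset <- cty$onset_year[match(births$county, cty$county)]
  pre <- births[is.na(births$onset) | births$year < births$onset, ]
  expect_false(any(pre$has_screening))
})

test_that("rendered text round-trips through extraction", {
  set.seed(99)
  for (i in 1:1000) {
    txt <- render_lab_text(c("anti-E", "anti-c"))
    expect_setequal(extract_antibodies(txt), c("anti-E", "anti-c"))
  }
})

test_that("render_lab_text applies the prophylaxis and vocabulary rules", {
  set.seed(3)
  txt <- render_lab_text("anti-D", prophylaxis = TRUE)
  expect_true("anti-D" %in% extract_antibodies(txt))
  expect_true(detect_prophylaxis(txt))
  empty <- render_lab_text(character(0))
  expect_identical(extract_antibodies(empty), character(0))
  expect_error(render_lab_text("anti-Nope"), class = "rbcscreen_vocabulary_error")
})

test_that("misspelled mentions are flagged in the ground truth and unreadable", {
  cfg <- noiseless_config(n_mothers = 4000, rng_seed = 21)
  cfg$misspelling_prob <- 1  # corrupt every rendered true mention
  reg <- generate_population(cfg)
  tm <- reg$truth_mentions
  expect_true(all(tm$corrupted[!tm$noise & !tm$prophylaxis]))
  id_texts <- reg$lab_records$text[reg$lab_records$record_id %in% tm$record_id[tm$corrupted]]
  hits <- unlist(lapply(id_texts, extract_antibodies))
  expect_length(hits, 0)
})
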