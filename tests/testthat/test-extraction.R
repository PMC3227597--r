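test_that("extraction handles notation variants and plain negatives", {
  expect_setequal(extract_antibodies("Anti-Lea och anti-Leb påvisade"),
                  c("anti-Lea", "anti-Leb"))
  expect_identical(extract_antibodies("negativ screening"), character(0))
  expect_setequal(extract_antibodies("ANTI E, ANTI C(W)"),
                  c("anti-E", "anti-Cw"))
  # case distinguishes the paired Rh antigens
  expect_identical(extract_antibodies("anti-E påvisad"), "anti-E")
  expect_identical(extract_antibodies("anti-e påvisad"), "anti-e")
  expect_identical(extract_antibodies("anti-c påvisad"), "anti-c")
})

test_that("none of the generator boilerplate templates contains a mention", {
  tpl <- rbcscreen:::.templates
  for (text in c(tpl$negative, tpl$positive_screen, tpl$id_prefix)) {
    expect_identical(extract_antibodies(text), character(0), label = text)
  }
})

test_that("mention spans are 0-based half-open offsets into the text", {
  txt <- "Id: anti-D, anti-Lea"
  m <- extract_mentions(tibble::tibble(record_id = "r1", text = txt))
  m <- m[order(m$start0), ]
  expect_equal(nrow(m), 2)
  expect_identical(substr(txt, m$start0[1] + 1, m$end0[1]), "anti-D")
  expect_identical(substr(txt, m$start0[2] + 1, m$end0[2]), "anti-Lea")
})

test_that("prophylaxis terms are detected as stems", {
  expect_true(detect_prophylaxis("anti-D efter Rh-profylax"))
  expect_true(detect_prophylaxis("anti-D, ej profylax-relaterad anmärkning saknas"))
  expect_false(detect_prophylaxis(""))
  expect_false(detect_prophylaxis("anti-D anti-C"))
})

test_that("classification unions records and applies the anti-D rule", {
  births <- tibble::tibble(birth_id = "b1")
  linked <- tibble::tibble(
    birth_id = "b1", record_id = c("r1", "r2"),
    text = c("anti-E påvisad", "anti-c påvisad")
  )
  prof <- classify_births(births, linked)
  expect_setequal(prof$antibodies[[1]], c("anti-E", "anti-c"))
  expect_true(prof$any_antibody)

  linked2 <- tibble::tibble(
    birth_id = "b1", record_id = c("r1", "r2"),
    text = c("anti-D", "Rh-profylax given")
  )
  prof2 <- classify_births(births, linked2)
  expect_identical(prof2$antibodies[[1]], character(0))
  expect_true(prof2$prophylaxis_suspected)
  expect_false(prof2$any_antibody)

  linked3 <- tibble::tibble(
    birth_id = "b1", record_id = c("r1", "r2"),
    text = c("anti-D", "anti-C")
  )
  prof3 <- classify_births(births, linked3)
  expect_setequal(prof3$antibodies[[1]], c("anti-D", "anti-C"))
})

test_that("anti-D in a detected set implies no prophylaxis suspicion", {
  reg <- generate_population(synthetic_config(n_mothers = 4000, rng_seed = 9))
  births <- clean_births(reg$births)
  linked <- link_records(births, clean_labs(reg$lab_records))
  prof <- classify_births(births, linked)
  has_d <- vapply(prof$antibodies, function(s) "anti-D" %in% s, logical(1))
  expect_false(any(has_d & prof$prophylaxis_suspected))
  # any_antibody is exactly non-emptiness of the detected set
  expect_identical(prof$any_antibody, prof$n_antibodies > 0)
})

test_that("record-level prophylaxis scope keeps anti-D mentioned cleanly elsewhere", {
  births <- tibble::tibble(birth_id = "b1")
  linked <- tibble::tibble(
    birth_id = "b1", record_id = c("r1", "r2"),
    text = c("anti-D påvisad", "anti-D efter Rh-profylax")
  )
  preg <- classify_births(births, linked, prophylaxis_scope = "pregnancy")
  rec <- classify_births(births, linked, prophylaxis_scope = "record")
  expect_identical(preg$antibodies[[1]], character(0))
  expect_identical(rec$antibodies[[1]], "anti-D")
})

test_that("extraction is idempotent and order-independent across records", {
  texts <- c("anti-E, anti-c", "Anti-Lea och anti-Leb", "negativ", "ANTI-K")
  births <- tibble::tibble(birth_id = "b1")
  mk <- function(ord) {
    linked <- tibble::tibble(birth_id = "b1",
                             record_id = paste0("r", seq_along(texts)),
                             text = texts[ord])
    classify_births(births, linked)$antibody_key
  }
  base <- mk(1:4)
  expect_identical(mk(4:1), base)
  expect_identical(mk(c(2, 4, 1, 3)), base)
  # re-extracting an already-extracted set of names changes nothing
  set <- extract_antibodies("anti-E, anti-c")
  expect_identical(extract_antibodies(paste(set, collapse = ", ")), set)
})
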