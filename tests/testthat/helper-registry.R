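# Shared fixtures, built in code.

# A generator configuration with no free-text noise and every county
# computerized from the study start: the noiseless surface on which
# extraction must recover the truth exactly.
noiseless_config <- function(n_mothers = 2000, rng_seed = 101, ...) {
  counties <- default_counties()
  counties$onset_year <- 1982
  synthetic_config(
    n_mothers = n_mothers, counties = counties,
    misspelling_prob = 0, noise_prob = 0,
    rng_seed = rng_seed, ...
  )
}

# Small raw birth table with a known layout for linkage tests.
toy_births <- function() {
  tibble::tibble(
    mother_id = c("m1", "m1", "m2", "m2", "m3"),
    delivery_date = c("1990-05-10", "1993-08-01", "1995-02-28",
                      "1995-02-28", "2000-10-01"),
    parity = c(1, 2, 1, 1, 1),
    birth_order = c(1, 1, 1, 2, 1),
    county = "C01",
    maternal_age = c(25, 28, 30, 30, 33),
    abo_rhd = c("O-", "O-", "A+", "A+", "B+"),
    country_of_birth = "Sweden",
    infant_sex = c("male", "female", "male", "female", "male"),
    stillbirth = FALSE
  )
}

# Independent confusion-matrix computation used as an oracle.
brute_confusion <- function(predicted, truth) {
  tab <- table(factor(predicted, c(FALSE, TRUE)), factor(truth, c(FALSE, TRUE)))
  list(tp = tab["TRUE", "TRUE"], fp = tab["TRUE", "FALSE"],
       tn = tab["FALSE", "FALSE"], fn = tab["FALSE", "TRUE"])
}

# Independent Clopper-Pearson bounds by bisection of binomial tails.
cp_bisect <- function(m, M, level = 0.95) {
  alpha <- 1 - level
  lower <- if (m == 0) 0 else {
    lo <- 0; hi <- 1
    for (i in 1:80) {  # smallest p with P(Bin(M,p) >= m) >= alpha/2
      mid <- (lo + hi) / 2
      if (stats::pbinom(m - 1, M, mid, lower.tail = FALSE) >= alpha / 2) hi <- mid else lo <- mid
    }
    hi
  }
  upper <- if (m == M) 1 else {
    lo <- 0; hi <- 1
    for (i in 1:80) {  # largest p with P(Bin(M,p) <= m) >= alpha/2
      mid <- (lo + hi) / 2
      if (stats::pbinom(m, M, mid) >= alpha / 2) lo <- mid else hi <- mid
    }
    lo
  }
  c(lower = lower, upper = upper)
}
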