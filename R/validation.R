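#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' Inverts the binomial tail probabilities via the beta-quantile
#' representation: the lower bound is the `alpha/2` quantile of
#' `Beta(m, M - m + 1)` (0 when `m = 0`), the upper bound the
#' `1 - alpha/2` quantile of `Beta(m + 1, M - m)` (1 when `m = M`).
#'
#' @param m Number of successes.
#' @param M Number of trials.
#' @param level Confidence level, default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
#' @examples
#' clopper_pearson_ci(107, 108)
clopper_pearson_ci <- function(m, M, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    abort("`level` must be a confidence level in (0, 1)",
          class = "rbcscreen_parameter_error")
  }
  stopifnot(length(m) == 1, length(M) == 1, M > 0, m >= 0, m <= M)
  alpha <- 1 - level
  lower <- if (m == 0) 0 else qbeta(alpha / 2, m, M - m + 1)
  upper <- if (m == M) 1 else qbeta(1 - alpha / 2, m + 1, M - m)
  c(lower = lower, upper = upper)
}

#' Rule-of-three interval for zero observed events
#'
#' With zero events in `n` trials the 95% upper confidence bound for the
#' event probability is approximately `3 / n`; with `n = 100` validated
#' pregnancies and no misclassifications this gives the familiar (0, 3%)
#' interval for the misclassification proportion.
#'
#' @param k Event count; the rule only applies to `k = 0` (otherwise an
#'   error points to [clopper_pearson_ci()]).
#' @param n Number of trials.
#' @return Named numeric vector `c(lower, upper) = c(0, 3/n)`.
#' @export
#' @examples
#' rule_of_three_ci(0, 100)
rule_of_three_ci <- function(k, n) {
  stopifnot(length(k) == 1, length(n) == 1, n > 0)
  if (k != 0) {
    abort("rule of three applies only to zero observed events; use clopper_pearson_ci()",
          class = "rbcscreen_method_error")
  }
  c(lower = 0, upper = 3 / n)
}

#' Positive and negative predictive value
#'
#' Compares predicted any-antibody flags with review-standard flags aligned
#' by pregnancy and returns the confusion counts with PPV = TP / (TP + FP)
#' and NPV = TN / (TN + FN). An undefined ratio (empty denominator) is
#' returned as `NA`.
#'
#' @param predicted,truth Logical vectors of equal length.
#' @return Named list: `tp`, `fp`, `tn`, `fn`, `ppv`, `npv`.
#' @export
#' @examples
#' ppv_npv(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE))
ppv_npv <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    abort("`predicted` and `truth` must be aligned vectors of equal length",
          class = "rbcscreen_alignment_error")
  }
  predicted <- as.logical(predicted); truth <- as.logical(truth)
  tp <- sum(predicted & truth); fp <- sum(predicted & !truth)
  tn <- sum(!predicted & !truth); fn <- sum(!predicted & truth)
  list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_
  )
}

#' Term identification accuracy
#'
#' The fraction of detected specific-antibody terms verified against the
#' review standard, reported to two decimals.
#'
#' @param verified Number of verified terms (`m`).
#' @param detected Number of detected terms (`M`); `0` gives `NA`.
#' @return Accuracy `m / M` rounded to 2 decimals.
#' @export
#' @examples
#' term_accuracy(107, 108)
term_accuracy <- function(verified, detected) {
  stopifnot(verified >= 0, verified <= max(detected, 0))
  if (detected == 0) return(NA_real_)
  round_half_away(verified / detected, 2)
}

#' Draw a chart-review validation sample
#'
#' Simple random sample without replacement of `n_pos` predicted
#' antibody-positive and `n_neg` predicted negative births, deterministic
#' under the seed.
#'
#' @param profiles Antibody profiles from [classify_births()]. Only births
#'   with screening information are eligible.
#' @param n_pos,n_neg Stratum sample sizes.
#' @param seed Integer RNG seed.
#' @return Tibble `birth_id`, `stratum` (`"positive"`/`"negative"`).
#' @export
sample_validation <- function(profiles, n_pos = 100, n_neg = 100, seed = 1L) {
  check_columns(profiles, c("birth_id", "any_antibody", "has_screening"),
                "profile table")
  eligible <- profiles[profiles$has_screening, , drop = FALSE]
  pos <- eligible$birth_id[eligible$any_antibody]
  neg <- eligible$birth_id[!eligible$any_antibody]
  if (length(pos) < n_pos || length(neg) < n_neg) {
    abort(sprintf(
      "insufficient stratum size: %d positive (need %d), %d negative (need %d)",
      length(pos), n_pos, length(neg), n_neg),
      class = "rbcscreen_sampling_error")
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  dplyr::bind_rows(
    tibble(birth_id = sort(sample(pos, n_pos)), stratum = "positive"),
    tibble(birth_id = sort(sample(neg, n_neg)), stratum = "negative")
  )
}

#' Validate extraction against ground truth on a review sample
#'
#' Reproduces the chart-review validation design: a stratified random
#' sample of predicted-positive and predicted-negative pregnancies is
#' compared with the ground truth (standing in for human record review).
#' Computes PPV and NPV at the any-antibody level, term identification
#' accuracy among the sampled positives (a detected term is verified when
#' its antibody is truly present for that birth), and 95% intervals: exact
#' Clopper-Pearson for each proportion and, when no misclassifications are
#' observed, the rule-of-three bound for the misclassification proportion.
#'
#' @param profiles Antibody profiles from [classify_births()].
#' @param truth Ground-truth birth table with `birth_id` and
#'   `true_antibodies` (";"-separated canonical names, empty = negative).
#' @param n_pos,n_neg Stratum sample sizes (default 100 and 100).
#' @param seed RNG seed for the sample draw.
#' @return An object of class `rbc_validation`; see [tidy()] and
#'   [glance()] methods.
#' @export
validate_extraction <- function(profiles, truth, n_pos = 100, n_neg = 100,
                                seed = 1L) {
  check_columns(truth, c("birth_id", "true_antibodies"), "ground truth table")
  samp <- sample_validation(profiles, n_pos, n_neg, seed)
  idx_p <- match(samp$birth_id, profiles$birth_id)
  idx_t <- match(samp$birth_id, truth$birth_id)
  if (anyNA(idx_t)) {
    abort("ground truth does not cover the sampled births",
          class = "rbcscreen_alignment_error")
  }
  predicted <- profiles$any_antibody[idx_p]
  true_sets <- strsplit(truth$true_antibodies[idx_t], ";", fixed = TRUE)
  truly_pos <- lengths(true_sets) > 0
  conf <- ppv_npv(predicted, truly_pos)

  pos_rows <- which(samp$stratum == "positive")
  det_sets <- profiles$antibodies[idx_p[pos_rows]]
  M <- sum(lengths(det_sets))
  m <- sum(unlist(mapply(function(d, t) d %in% t, det_sets,
                         true_sets[pos_rows], SIMPLIFY = FALSE)))
  acc <- term_accuracy(m, M)

  ci_row <- function(metric, est, k, n, method, ci) {
    tibble(metric = metric, estimate = est, successes = k, trials = n,
           ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
           ci_method = method)
  }
  rows <- list()
  if (!is.na(conf$ppv)) {
    n <- conf$tp + conf$fp
    rows$ppv <- ci_row("ppv", conf$ppv, conf$tp, n, "clopper_pearson",
                       clopper_pearson_ci(conf$tp, n))
    if (conf$fp == 0) {
      r3 <- rule_of_three_ci(0, n)
      rows$mis_pos <- ci_row("misclassification_among_predicted_positive",
                             0, 0, n, "rule_of_three", r3)
    }
  }
  if (!is.na(conf$npv)) {
    n <- conf$tn + conf$fn
    rows$npv <- ci_row("npv", conf$npv, conf$tn, n, "clopper_pearson",
                       clopper_pearson_ci(conf$tn, n))
    if (conf$fn == 0) {
      r3 <- rule_of_three_ci(0, n)
      rows$mis_neg <- ci_row("misclassification_among_predicted_negative",
                             0, 0, n, "rule_of_three", r3)
    }
  }
  if (M > 0) {
    rows$acc <- ci_row("term_accuracy", acc, m, M, "clopper_pearson",
                       clopper_pearson_ci(m, M))
  }
  structure(list(
    sample = samp, metrics = dplyr::bind_rows(rows),
    confusion = conf, detected_terms = M, verified_terms = m,
    n_pos = n_pos, n_neg = n_neg, seed = seed
  ), class = "rbc_validation")
}

#' @export
print.rbc_validation <- function(x, ...) {
  cat(sprintf(
    "<rbc_validation> %d + %d sampled pregnancies\nPPV %s, NPV %s; %d/%d detected terms verified (accuracy %s)\n",
    x$n_pos, x$n_neg,
    format(x$confusion$ppv), format(x$confusion$npv),
    x$verified_terms, x$detected_terms,
    format(term_accuracy(x$verified_terms, max(x$detected_terms, 1)))
  ))
  print(x$metrics)
  invisible(x)
}

#' Tidy a validation report
#'
#' @param x An `rbc_validation` object.
#' @param ... Unused.
#' @return Tibble of metrics with point estimates, counts and confidence
#'   intervals.
#' @export
tidy.rbc_validation <- function(x, ...) {
  x$metrics
}

#' One-row summary of a validation report
#'
#' @param x An `rbc_validation` object.
#' @param ... Unused.
#' @return One-row tibble with sample sizes, confusion counts, PPV, NPV and
#'   term accuracy.
#' @export
glance.rbc_validation <- function(x, ...) {
  tibble(
    n_pos = x$n_pos, n_neg = x$n_neg,
    tp = x$confusion$tp, fp = x$confusion$fp,
    tn = x$confusion$tn, fn = x$confusion$fn,
    ppv = x$confusion$ppv, npv = x$confusion$npv,
    detected_terms = x$detected_terms, verified_terms = x$verified_terms,
    term_accuracy = term_accuracy(x$verified_terms,
                                  max(x$detected_terms, 0))
  )
}

#' Fraction of births whose detected set equals the ground truth
#'
#' Convenience metric for round-trip experiments: the proportion of births
#' (by default those with screening information) whose detected antibody
#' set matches the true set exactly.
#'
#' @param profiles Antibody profiles from [classify_births()].
#' @param truth Ground-truth table with `birth_id`, `true_antibodies`.
#' @param screened_only Restrict to births with linked screening records.
#' @return A fraction in \[0, 1\].
#' @export
recovery_rate <- function(profiles, truth, screened_only = TRUE) {
  check_columns(truth, c("birth_id", "true_antibodies"), "ground truth table")
  p <- profiles
  if (screened_only) p <- p[p$has_screening, , drop = FALSE]
  idx <- match(p$birth_id, truth$birth_id)
  if (anyNA(idx)) {
    abort("ground truth does not cover the profiled births",
          class = "rbcscreen_alignment_error")
  }
  truth_key <- vapply(strsplit(truth$true_antibodies[idx], ";", fixed = TRUE),
                      function(s) paste(sort(s), collapse = ";"), character(1))
  mean(p$antibody_key == truth_key)
}
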