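---
title: "Constructing a maternal RBC antibody screening database: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing a maternal RBC antibody screening database}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbcscreen)
```

## The problem

Maternal red blood cell (RBC) alloantibodies — anti-D foremost, but also
anti-c, anti-K, anti-E and dozens of rarer specificities — can cause
hemolytic disease of the fetus and newborn. Because non-anti-D antibodies
occur at rates of a few per 10,000 pregnancies, studying their distribution
and consequences requires population-scale data spanning decades. Routine
prenatal screening produces exactly that data, but in an awkward shape:
identification results are stored as free text by regional laboratories,
each with its own notation habits, and laboratories computerized their
records in different years, so the fraction of births with usable
electronic results varies strongly by region and calendar time.

`rbcscreen` turns these two sources — a birth register and a table of dated
free-text laboratory results — into an analysis-ready cohort with per-birth
antibody profiles, quality-controlled denominators, stratified prevalence
tables, and a validation report. Since the real registers cannot be
distributed, the package includes a synthetic registry generator whose
ground truth makes every stage verifiable.

## Pipeline model and assumptions

**Unit of analysis.** The individual infant born (live or still), uniquely
identified by (mother's study number, delivery date, parity, birth order).
Twins share the mother's laboratory records but count as separate births in
all denominators.

**Pregnancy window.** A laboratory record belongs to a birth when the
mother matches and the sample date lies in
`[delivery − 270 days, delivery + 14 days]`, both ends inclusive. "Nine
months" is implemented as exactly 270 days: calendar-month arithmetic is
ambiguous (month lengths vary), while a fixed day count is deterministic
and auditable. Both window lengths are configurable. A record falling in
the overlap of two pregnancies of one mother attaches to both; we do not
invent an assignment rule the data cannot support, and the duplication is
visible in the linked table.

**Positivity rule.** A birth is positive for antibody *a* if *a* is
mentioned in at least one linked record. Text only reaches the
identification stage after a positive non-specific screen, so the source
texts are confirmatory; negated mentions are therefore not modelled (a
documented limitation, see below). Anti-D is special: anti-D
immunoglobulin given as RhD prophylaxis is detectable in maternal plasma,
so an anti-D mention only counts as immunization when *no* prophylaxis term
occurs. By default this suppression is pregnancy-level (any prophylaxis
term in any linked record suppresses anti-D for that birth), matching the
operational reading of "no search terms indicating prophylaxis were
found"; `prophylaxis_scope = "record"` switches to record-level suppression
for sensitivity analysis.

**Coverage and inclusion.** For each county × year the coverage is the
fraction of births with at least one linked record. The study population is
restricted to county-years with *sustained* coverage at or above a
threshold τ (default 0.80, comparison `≥`): the earliest year from which
coverage stays at or above τ through the study end. "Sustained" means a
single sub-threshold year restarts the clock — this reproduces the
behaviour where a large county with data from the study start only enters
several years later, and where a region that never reaches stable coverage
is excluded entirely. Prevalence denominators are the births in included
county-years *with* screening information; births there without screening
count toward coverage only.

**Prevalence.** Rates are `10⁴·k/N` rounded half away from zero to one
decimal; percentages of antibody-positive births use the count of births
with any antibody as denominator. "Non-anti-D antibodies" means at least
one detected antibody other than anti-D — a birth carrying anti-D *plus*
another antibody counts in both the anti-D and the non-anti-D rows. The
overlap convention follows from the published marginal counts, where the
anti-D and non-anti-D counts sum to more than the any-antibody count;
treating them as a partition would be arithmetically inconsistent.
Combination tables count *exact* detected sets by default (so the counts
partition the multi-antibody births); subset counting is available via
`combination_counts(mode = "subset")` since the alternative reading cannot
be ruled out. The main/rare table split (≥ 1 vs < 1 per 10,000) is decided
on the unrounded overall rate.

**Validation.** The chart-review design is reproduced in code: simple
random samples of predicted-positive and predicted-negative pregnancies
(default 100 + 100), reviewed against ground truth. PPV, NPV and term
accuracy are binomial proportions; intervals are exact Clopper–Pearson (by
beta-quantile inversion of the binomial tails, cross-checked in the test
suite against independent bisection), and when zero errors are observed
the rule-of-three bound 3/n for the misclassification proportion is
reported alongside — the report labels each method explicitly because
"based on a binomial distribution" admits both readings.

## The pattern catalogue

The bundled catalogue (`inst/extdata/antibody_patterns.csv`) is a
**constructed** resource: 64 specific antibodies across the Rh (9), Kell
(7), Duffy (3), Kidd (3), MNS (8), Lewis (3), Lutheran (2), P (2) and
Other (27) groups, an "unspecified antibodies" entry tabulated like a
specific antibody, and a prophylaxis term list (Swedish and English stems
plus a brand name). It was assembled from standard blood-group nomenclature
rather than copied from any laboratory system, and users can supply their
own file with the same columns.

Patterns are restricted to a portable regex subset — literals, character
classes, optional tokens, alternation, inline case-insensitivity groups —
so any mainstream engine reproduces the matches. Three design decisions
matter:

* **Case-paired antigens.** For C/c, E/e, S/s, K/k and I/i, letter case is
  the *only* feature separating two different antibodies, so the antigen
  letter is matched case-sensitively while everything else ("anti", the
  separators, multi-letter antigen names, parenthesised subscripts) is
  case-insensitive. `"ANTI E, ANTI C(W)"` resolves to anti-E and anti-Cw;
  `"anti-e"` resolves to anti-e. The generator never case-folds the paired
  letters, mirroring laboratory practice where the case of these letters is
  semantically load-bearing.
* **Word-boundary guards.** A match flanked by a letter or digit is
  discarded in code: the `antik` inside Swedish "antikroppar" must not fire
  anti-k, and anti-C must not fire inside "anti-Coa". Guards live in the
  matcher, not in the patterns, keeping the patterns portable.
* **Longest-match precedence.** When two entries match overlapping spans,
  a match strictly contained in a longer match of another entry is dropped
  — anti-C gives way to anti-Cw in `"ANTI C(W)"` where the boundary guard
  alone cannot decide (the parenthesis is not a word character). The test
  suite exhaustively renders every surface variant of every entry and
  asserts it maps back to exactly its own canonical name.

Prophylaxis terms are deliberately matched as stems without boundary
guards, so "profylax" also fires in "profylax-relaterad" and
"prophylaxis"; the term list is configuration, and results should be
reported together with the list used.

## What the synthetic generator emulates

`generate_population()` simulates mothers (county, ABO/RhD group,
country of birth, age at first delivery ~ N(27.5, 5²) years truncated to
16–45), their deliveries (one plus a Poisson(0.8) number, at least 330 days
apart so pregnancy windows of one mother never overlap; 1.4% twin
deliveries), true antibody status, and the laboratory paper trail:

* a first-visit screen at gestational week 9, retests at weeks 25 and 35
  for RhD-negative women, an identification record (week 11) for
  antibody-positive pregnancies, and a prophylaxis annotation record
  (week 28) for RhD-negative pregnancies without true anti-D;
* per-antibody positivity probabilities defaulting to the overall per-10⁴
  rates observed in the Swedish 1982–2002 cohort (anti-D 14.1, anti-Lea
  13.9, anti-E 13.0, …, plus small rates for a handful of rare
  specificities, ~93.7/10⁴ summed);
* anti-D assigned only to RhD-negative mothers, with probability scaled by
  the RhD-negative fraction so the configured marginal per-birth rate is
  exact;
* co-occurrence rules (`condition → target, factor`) reproducing the most
  frequent antibody combinations; the complement probability is
  compensated so each target's marginal rate is preserved exactly (clamped
  at zero in tiny populations where exact compensation is infeasible);
* county-by-year computerization: a pregnancy's records are computerized
  with probability `coverage_rate` (default 0.937, the aggregate coverage
  of the included region in the source cohort) once the county's onset
  year is reached, and records dated before the onset year are censored.
  This yields the characteristic pattern in which a county's onset year is
  a partial-coverage ramp (most first-visit samples predate the onset) and
  the sustained-80% rule admits the county the following year; a county
  whose onset equals the first study year is treated as computerized
  before the study began, and a county with onset `NA` never contributes
  records;
* free text rendered with notation variants (case, hyphen/space
  separators, `Lea` vs `Le(a)`, Swedish and English boilerplate), a typo
  channel (probability 0.01 per rendered mention; the corrupted mention no
  longer machine-matches — the false-negative error mode), and a stray
  token channel (probability 0.001 per record of an antibody-positive
  pregnancy; an antibody name not truly present — the false-positive error
  mode). Strays are confined to positive pregnancies because free-typed
  antibody text only exists after a positive screen; negative screens are
  template output. Both channels are recorded in the ground truth, giving
  validation an unambiguous oracle. The two default rates correspond to
  the error structure a review of a few thousand records would surface as
  roughly one corrupted term in a hundred and one stray entry overall.

**What it does not emulate:** assay-technology eras and their changing
sensitivity (the real 1980s–90s transitions from saline IAT through LISS
and gel cards shifted detection rates, visibly for Lewis antibodies);
antibody titers; negated mentions; transfusion and donation histories;
between-laboratory dialect differences beyond the implemented variants;
true secular trends in immunization (per-antibody probabilities are
time-constant). Passing round-trip tests on this corpus therefore
demonstrates that the extraction machinery is correct for the modelled
notation space — not that any fixed pattern set generalizes to an unseen
laboratory's text.

## Numerical choices and degenerate inputs

* Rounding of published-style rates and percentages is half away from
  zero (`round_half_away()`), not banker's rounding, matching how the
  printed tables were produced.
* Dates are parsed strictly as ISO-8601; malformed or missing dates are
  rejected to a per-reason log, mirroring the exclusion of laboratories
  with systematically missing dates. Cleaning is idempotent.
* Clopper–Pearson bounds use the beta-quantile representation with the
  conventional closures L = 0 at m = 0 and U = 1 at m = M;
  `rule_of_three_ci()` refuses k ≠ 0 and points to the exact interval.
* Zero-birth county-years have undefined coverage; the pipeline completes
  the county × year grid and the sustained rule treats such years as
  vacuously satisfying the threshold (no birth's coverage can fall short).
  Genuinely non-contiguous coverage input still raises a data error.
* `ppv_npv()` returns `NA` for empty denominators rather than failing, and
  flags them; `term_accuracy(0 terms)` is `NA`.
* Determinism: every stochastic step (generation, validation sampling) is
  seeded; a fixed configuration and seed give byte-identical CSV outputs,
  asserted in the test suite.

## Problem sizes used in the checks

The bundled verification runs were sized to exercise the claims at
meaningful scale: the noiseless round-trip corpus uses ~11,000 births
(6,000 mothers), parameter recovery uses a single ~530,000-birth registry
checked against configured rates at 3 binomial standard errors, and the
acceptance script pools three independent ~530,000-birth registries
(~1.6 million births) so reported rates carry a Monte-Carlo standard error
of about 0.45 per 10,000. The interval-coverage simulation uses 1,000
replicates at p ∈ {0.9, 0.99} with 108 trials.

## Known limitations

* The pattern catalogue is a reconstruction from standard nomenclature,
  not a copy of any production laboratory system; term-level results on
  real data would need a site-specific catalogue review.
* Negation is not handled; applying the extractor to non-confirmatory text
  (e.g. screening comments that mention antibodies being absent) would
  inflate positives.
* A lowercase rendering of anti-Cw ("anti-cw") would fire anti-c; the
  generator never emits it because the C is case-load-bearing, but foreign
  text might.
* Prevalence inference (trend models, confidence bands per rate) is out of
  scope; the package produces the counts and rates that such analyses
  would consume.
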