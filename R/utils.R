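#' Round half away from zero
#'
#' Commercial rounding as used in printed prevalence tables: ties are rounded
#' away from zero, so `round_half_away(0.05, 1)` is `0.1`, unlike base
#' [round()] which rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded to `digits` decimals.
#' @export
#' @examples
#' round_half_away(c(0.05, 0.15, -0.05), 1)
round_half_away <- function(x, digits = 0) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1)
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Strict ISO-8601 date parsing: anything not YYYY-MM-DD becomes NA.
parse_iso_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  ok <- !is.na(x) & stringr::str_detect(x, "^\\d{4}-\\d{2}-\\d{2}$")
  out <- rep(as.Date(NA), length(x))
  out[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  out
}

# Error if `data` is missing any of `cols`; `what` names the table in messages.
check_columns <- function(data, cols, what = "input") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column%s: %s",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ), class = "rbcscreen_schema_error")
  }
  invisible(data)
}

check_probability <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must contain probabilities in [0, 1]", field),
          class = "rbcscreen_config_error")
  }
  invisible(x)
}

# Collapse a list of antibody-name character vectors into stable ";" keys,
# sorted so that set comparison is a plain string comparison.
antibody_set_key <- function(sets) {
  vapply(sets, function(s) paste(sort(s), collapse = ";"), character(1))
}
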