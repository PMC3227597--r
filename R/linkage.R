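#' Clean a raw birth-register table
#'
#' Validates the four-part identity key (mother's study number, delivery
#' date, parity, birth order) that uniquely identifies each infant born.
#' Rows with a missing or blank key field, an unparseable delivery date, or
#' a duplicated full key are removed; the counts per rejection reason are
#' attached as the `"rejection_log"` attribute (see [rejection_log()]).
#' Dates are parsed strictly as ISO-8601 (`YYYY-MM-DD`).
#'
#' Cleaning is idempotent: cleaning an already-clean table returns it
#' unchanged with an empty log.
#'
#' @param data Raw birth table with at least `mother_id`, `delivery_date`,
#'   `parity`, `birth_order`.
#' @return A tibble of valid births with a `birth_id` key column prepended,
#'   `delivery_date` as `Date`, and attribute `"rejection_log"`.
#' @export
clean_births <- function(data) {
  check_columns(data, c("mother_id", "delivery_date", "parity", "birth_order"),
                "birth table")
  data <- as_tibble(data)
  n0 <- nrow(data)
  data$delivery_date <- parse_iso_date(data$delivery_date)

  bad_id <- is.na(data$mother_id) | !nzchar(trimws(as.character(data$mother_id)))
  bad_date <- !bad_id & is.na(data$delivery_date)
  bad_key <- !bad_id & !bad_date &
    (is.na(data$parity) | data$parity < 1 | is.na(data$birth_order) |
       data$birth_order < 1)
  keep <- !(bad_id | bad_date | bad_key)
  out <- data[keep, , drop = FALSE]

  key <- paste(out$mother_id, format(out$delivery_date), out$parity,
               out$birth_order, sep = "|")
  dup <- duplicated(key)
  log <- tibble(
    reason = c("invalid_id", "invalid_date", "invalid_key", "duplicate_key"),
    n = c(sum(bad_id), sum(bad_date), sum(bad_key), sum(dup))
  )
  log <- log[log$n > 0, , drop = FALSE]
  out <- out[!dup, , drop = FALSE]
  out <- dplyr::bind_cols(tibble(birth_id = key[!dup]), out)
  stopifnot(nrow(out) + sum(log$n) == n0)
  attr(out, "rejection_log") <- log
  out
}

#' Clean a raw laboratory record table
#'
#' Removes records with a missing mother identifier or a missing/unparseable
#' sample date (mirroring the exclusion of laboratories with systematically
#' missing dates), logging counts per reason. Assigns a `record_id` if the
#' table has none.
#'
#' @param data Raw lab table with at least `mother_id`, `sample_date`,
#'   `text`.
#' @return Tibble of valid lab records with attribute `"rejection_log"`.
#' @export
clean_labs <- function(data) {
  check_columns(data, c("mother_id", "sample_date", "text"), "lab record table")
  data <- as_tibble(data)
  data$sample_date <- parse_iso_date(data$sample_date)
  if (!"record_id" %in% names(data)) {
    data$record_id <- sprintf("L%08d", seq_len(nrow(data)))
  }
  bad_id <- is.na(data$mother_id) | !nzchar(trimws(as.character(data$mother_id)))
  bad_date <- !bad_id & is.na(data$sample_date)
  log <- tibble(
    reason = c("invalid_id", "missing_date"),
    n = c(sum(bad_id), sum(bad_date))
  )
  log <- log[log$n > 0, , drop = FALSE]
  out <- data[!(bad_id | bad_date), , drop = FALSE]
  attr(out, "rejection_log") <- log
  out
}

#' Rejection log of a cleaned table
#'
#' @param data Output of [clean_births()] or [clean_labs()].
#' @return Tibble with columns `reason` and `n` (empty if nothing was
#'   rejected).
#' @export
rejection_log <- function(data) {
  attr(data, "rejection_log") %||% tibble(reason = character(), n = integer())
}

#' Pregnancy time window around a delivery date
#'
#' The window runs from nine months (taken as exactly 270 days) before to
#' two weeks (14 days) after the delivery date, inclusive at both ends:
#' laboratory samples drawn in this window belong to the pregnancy.
#'
#' @param delivery_date A `Date` vector (or ISO-8601 strings).
#' @param before,after Window extent in days before/after delivery.
#' @return A tibble with columns `delivery_date`, `start`, `end`.
#' @export
#' @examples
#' pregnancy_window(as.Date("2000-10-01"))
pregnancy_window <- function(delivery_date, before = 270, after = 14) {
  delivery_date <- parse_iso_date(delivery_date)
  if (anyNA(delivery_date)) {
    abort("`delivery_date` contains invalid dates", class = "rbcscreen_date_error")
  }
  tibble(
    delivery_date = delivery_date,
    start = delivery_date - before,
    end = delivery_date + after
  )
}

#' Link laboratory records to births within the pregnancy window
#'
#' Attaches a lab record to a birth when the mother matches and the sample
#' date falls inside the pregnancy window (inclusive). A record may attach
#' to more than one birth: twins share all maternal records, and records in
#' the overlap of two closely spaced pregnancies of the same mother attach
#' to both (such duplications are visible in the output and can be audited).
#'
#' @param births Cleaned birth table from [clean_births()].
#' @param labs Cleaned lab table from [clean_labs()].
#' @param before,after Window extent in days, see [pregnancy_window()].
#' @return A tibble with one row per (birth, record) pair: `birth_id`,
#'   `mother_id`, `delivery_date`, `record_id`, `sample_date`, `text`, plus
#'   any further lab columns.
#' @export
link_records <- function(births, labs, before = 270, after = 14) {
  check_columns(births, c("birth_id", "mother_id", "delivery_date"), "birth table")
  check_columns(labs, c("record_id", "mother_id", "sample_date", "text"),
                "lab record table")
  b <- births[, c("birth_id", "mother_id", "delivery_date")]
  joined <- dplyr::inner_join(b, labs, by = "mother_id",
                              relationship = "many-to-many")
  dplyr::filter(
    joined,
    .data$sample_date >= .data$delivery_date - before,
    .data$sample_date <= .data$delivery_date + after
  )
}

#' Flag births having valid screening information
#'
#' @param births Cleaned birth table.
#' @param linked Output of [link_records()].
#' @return `births` with a logical `has_screening` column added.
#' @export
flag_screening <- function(births, linked) {
  check_columns(births, "birth_id", "birth table")
  births$has_screening <- births$birth_id %in% unique(linked$birth_id)
  births
}
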