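#' Extract antibody mentions from free-text laboratory results
#'
#' Runs every catalogue pattern over the text and returns the canonical
#' antibody names with at least one surviving match. Two safeguards prevent
#' substring false positives between related antibody names (for example
#' anti-C inside "anti-Cw", or anti-K inside "anti-Kp(a)"):
#'
#' * a word-boundary guard discards a match that is directly flanked by a
#'   letter or digit, and
#' * longest-match precedence discards a match lying strictly inside a longer
#'   match of a different catalogue entry.
#'
#' @param text A single free-text laboratory result string.
#' @param catalogue An `antibody_catalogue` from [compile_catalogue()].
#' @return Character vector of canonical antibody names (sorted), empty if
#'   nothing matches.
#' @export
#' @examples
#' extract_antibodies("Anti-Lea och anti-Leb påvisade")
#' extract_antibodies("negativ screening")
extract_antibodies <- function(text, catalogue = default_catalogue()) {
  stopifnot(is.character(text), length(text) == 1)
  m <- match_texts(text, catalogue)
  sort(unique(m$name))
}

#' Locate antibody mentions in a table of free-text records
#'
#' Data-frame-first companion to [extract_antibodies()]: matches every
#' catalogue pattern against a text column and returns one row per surviving
#' mention with 0-based half-open span offsets. Matching is performed once
#' per unique text string, so heavily templated corpora are cheap.
#'
#' @param data A data frame of laboratory records.
#' @param catalogue An `antibody_catalogue`.
#' @param text_col Name of the column holding the free text.
#' @return A tibble with the identifying columns of `data` (all columns
#'   except `text_col`), plus `name`, `start0`, `end0` per mention.
#' @export
extract_mentions <- function(data, catalogue = default_catalogue(),
                             text_col = "text") {
  check_columns(data, text_col, "lab record table")
  texts <- data[[text_col]]
  ut <- unique(texts)
  m <- match_texts(ut, catalogue)
  idx <- match(texts, ut)
  # expand per-unique-text matches back onto the record rows
  hits <- split(seq_len(nrow(m)), m$text_id)
  row_hits <- hits[as.character(idx)]
  n_per_row <- lengths(row_hits)
  out_rows <- rep.int(seq_len(nrow(data)), n_per_row)
  mrows <- unlist(row_hits, use.names = FALSE)
  keep_cols <- setdiff(names(data), text_col)
  res <- data[out_rows, keep_cols, drop = FALSE]
  res$name <- m$name[mrows]
  res$start0 <- m$start[mrows] - 1L
  res$end0 <- m$end[mrows]
  as_tibble(res)
}

#' Detect prophylaxis-related wording
#'
#' Returns `TRUE` for each text containing at least one prophylaxis search
#' term from the catalogue. Terms are matched as stems without boundary
#' guards, so "profylax" also fires inside "profylax-relaterad" and
#' "profylaxis". Passively administered anti-D immunoglobulin shows up in
#' screening free text; records carrying these terms must not be counted as
#' anti-D immunization.
#'
#' @param text Character vector of free-text results.
#' @param catalogue An `antibody_catalogue` with a non-empty prophylaxis term
#'   list.
#' @return Logical vector, one element per text.
#' @export
#' @examples
#' detect_prophylaxis("anti-D efter Rh-profylax")
detect_prophylaxis <- function(text, catalogue = default_catalogue()) {
  stopifnot(is.character(text))
  if (nrow(catalogue$prophylaxis) == 0) {
    abort("catalogue has no prophylaxis terms", class = "rbcscreen_catalogue_error")
  }
  out <- rep(FALSE, length(text))
  for (p in catalogue$prophylaxis$pattern) {
    out <- out | stringi::stri_detect_regex(text, p)
  }
  out
}

#' Classify births into antibody profiles
#'
#' Builds one antibody profile per birth from its linked laboratory records.
#' A birth is antibody-positive for an antibody if the antibody is mentioned
#' in at least one linked record. Anti-D is only retained when the positive
#' finding is not suspected to come from RhD prophylaxis: with
#' `prophylaxis_scope = "pregnancy"` (default) any prophylaxis term in any
#' linked record suppresses anti-D for that birth; with `"record"` anti-D
#' survives if at least one record mentions it without a prophylaxis term.
#'
#' @param births A cleaned birth table with a `birth_id` column (see
#'   [clean_births()]). Births without linked records receive an empty
#'   profile.
#' @param linked Output of [link_records()]: one row per (birth, lab record)
#'   pair with columns `birth_id`, `record_id`, `text`.
#' @param catalogue An `antibody_catalogue`.
#' @param prophylaxis_scope `"pregnancy"` or `"record"`.
#' @return A tibble with one row per birth: `birth_id`, `antibodies`
#'   (list-column of canonical names), `antibody_key` (";"-collapsed sorted
#'   names), `n_antibodies`, `any_antibody`, `prophylaxis_suspected`,
#'   `has_screening`. The per-mention table (birth, record, canonical name,
#'   0-based half-open span) is attached as attribute `"mentions"`, see
#'   [mentions()].
#' @export
classify_births <- function(births, linked, catalogue = default_catalogue(),
                            prophylaxis_scope = c("pregnancy", "record")) {
  prophylaxis_scope <- match.arg(prophylaxis_scope)
  check_columns(births, "birth_id", "birth table")
  check_columns(linked, c("birth_id", "record_id", "text"), "linked record table")

  ut <- unique(linked$text)
  m <- match_texts(ut, catalogue)
  proph_ut <- detect_prophylaxis(ut, catalogue)
  tidx <- match(linked$text, ut)

  mention_tbl <- {
    hits <- split(seq_len(nrow(m)), m$text_id)
    row_hits <- hits[as.character(tidx)]
    n_per_row <- lengths(row_hits)
    rows <- rep.int(seq_len(nrow(linked)), n_per_row)
    mrows <- unlist(row_hits, use.names = FALSE)
    tibble(
      birth_id = linked$birth_id[rows],
      record_id = linked$record_id[rows],
      name = m$name[mrows],
      start0 = m$start[mrows] - 1L,
      end0 = m$end[mrows]
    )
  }
  rec_proph <- tibble(
    birth_id = linked$birth_id,
    record_id = linked$record_id,
    prophylaxis = proph_ut[tidx]
  )

  proph_by_birth <- rec_proph |>
    dplyr::group_by(.data$birth_id) |>
    dplyr::summarise(prophylaxis_suspected = any(.data$prophylaxis),
                     .groups = "drop")

  if (prophylaxis_scope == "pregnancy") {
    sets <- mention_tbl |>
      dplyr::distinct(.data$birth_id, .data$name) |>
      dplyr::left_join(proph_by_birth, by = "birth_id") |>
      dplyr::filter(!(.data$name == "anti-D" & .data$prophylaxis_suspected))
  } else {
    # record scope: anti-D kept if some record mentions it cleanly
    d_clean <- mention_tbl |>
      dplyr::filter(.data$name == "anti-D") |>
      dplyr::left_join(rec_proph, by = c("birth_id", "record_id")) |>
      dplyr::group_by(.data$birth_id) |>
      dplyr::summarise(keep_d = any(!.data$prophylaxis), .groups = "drop")
    sets <- mention_tbl |>
      dplyr::distinct(.data$birth_id, .data$name) |>
      dplyr::left_join(d_clean, by = "birth_id") |>
      dplyr::filter(!(.data$name == "anti-D" & !(.data$keep_d %||% FALSE)))
  }

  set_by_birth <- sets |>
    dplyr::group_by(.data$birth_id) |>
    dplyr::summarise(antibody_key = paste(sort(.data$name), collapse = ";"),
                     .groups = "drop")

  profiles <- tibble(birth_id = births$birth_id) |>
    dplyr::left_join(set_by_birth, by = "birth_id") |>
    dplyr::left_join(proph_by_birth, by = "birth_id") |>
    dplyr::mutate(
      antibody_key = dplyr::coalesce(.data$antibody_key, ""),
      prophylaxis_suspected = dplyr::coalesce(.data$prophylaxis_suspected, FALSE),
      has_screening = .data$birth_id %in% linked$birth_id
    )
  ab_list <- rep(list(character(0)), nrow(profiles))
  pos <- which(nzchar(profiles$antibody_key))
  ab_list[pos] <- strsplit(profiles$antibody_key[pos], ";", fixed = TRUE)
  profiles$antibodies <- ab_list
  profiles$n_antibodies <- lengths(ab_list)
  profiles$any_antibody <- profiles$n_antibodies > 0
  profiles <- profiles[, c("birth_id", "antibodies", "antibody_key",
                           "n_antibodies", "any_antibody",
                           "prophylaxis_suspected", "has_screening")]
  attr(profiles, "mentions") <- mention_tbl
  profiles
}

#' Per-mention table of a classified cohort
#'
#' @param profiles Output of [classify_births()].
#' @return Tibble of mentions (birth, record, canonical name, span offsets).
#' @export
mentions <- function(profiles) {
  attr(profiles, "mentions")
}

# Core matcher over a character vector of texts. Returns a tibble
# (text_id, name, start, end) with 1-based inclusive spans after applying
# the boundary guard and longest-match containment precedence.
match_texts <- function(texts, catalogue) {
  entries <- catalogue$entries
  empty <- tibble(text_id = integer(), name = character(),
                  start = integer(), end = integer())
  if (length(texts) == 0 || nrow(entries) == 0) return(empty)

  pieces <- vector("list", nrow(entries))
  for (i in seq_len(nrow(entries))) {
    loc <- stringi::stri_locate_all_regex(texts, entries$pattern[i],
                                          omit_no_match = TRUE)
    ns <- vapply(loc, nrow, integer(1))
    if (sum(ns) == 0) next
    mat <- do.call(rbind, loc)
    pieces[[i]] <- tibble(
      text_id = rep.int(seq_along(texts), ns),
      name = entries$name[i],
      start = as.integer(mat[, 1]),
      end = as.integer(mat[, 2])
    )
  }
  m <- dplyr::bind_rows(pieces)
  if (nrow(m) == 0) return(empty)

  # word-boundary guard: a mention flanked by a letter/digit is a fragment of
  # a longer token (e.g. the "antik" of "antikroppar") and is discarded
  wordish <- "[A-Za-z0-9ÅÄÖåäö]"
  before <- stringi::stri_sub(texts[m$text_id], m$start - 1L, length = 1)
  after <- stringi::stri_sub(texts[m$text_id], m$end + 1L, length = 1)
  keep <- !(m$start > 1L & stringi::stri_detect_regex(before, wordish)) &
    !stringi::stri_detect_regex(after, wordish)
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0) return(empty)

  # longest-match precedence: drop a match strictly contained in a longer
  # match of another entry (anti-C inside "anti-Cw" when anti-Cw also fires)
  multi <- m$text_id %in% m$text_id[duplicated(m$text_id)]
  if (any(multi)) {
    drop <- rep(FALSE, nrow(m))
    for (tid in unique(m$text_id[multi])) {
      rows <- which(m$text_id == tid)
      s <- m$start[rows]; e <- m$end[rows]; nm <- m$name[rows]
      len <- e - s
      for (a in seq_along(rows)) {
        contained <- s <= s[a] & e >= e[a] & len > len[a] & nm != nm[a]
        if (any(contained)) drop[rows[a]] <- TRUE
      }
    }
    m <- m[!drop, , drop = FALSE]
  }
  m
}
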