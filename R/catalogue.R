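#' Compile an antibody pattern catalogue
#'
#' Reads a delimited pattern specification (columns `name`, `system`,
#' `pattern`, and optionally `surface_forms`, `case_fixed`) and compiles it
#' into a catalogue used by the extraction functions. Rows whose `system` is
#' the reserved label `"prophylaxis"` form the prophylaxis term list used by
#' [detect_prophylaxis()]; all other rows are antibody entries. The entry
#' named `"unspecified"` matches free-text reports of unspecified irregular
#' antibodies and is tabulated like a specific antibody.
#'
#' Patterns are written in a portable regular-expression subset (literals,
#' character classes, alternation, optional tokens, inline case-insensitivity
#' groups) so that any mainstream engine reproduces the matches. Case-paired
#' single-letter antigens (C/c, E/e, S/s, K/k, I/i) keep their antigen letter
#' case-sensitive because letter case is the only feature distinguishing the
#' two antibodies; everything else matches case-insensitively.
#'
#' @param path Path to the pattern specification file (CSV). Defaults to the
#'   catalogue bundled with the package, which covers 64 specific antibodies
#'   across the Rh, Kell, Duffy, Kidd, MNS, Lewis, Lutheran, P and Other
#'   groups.
#' @return An object of class `antibody_catalogue`: a list with `entries`
#'   (tibble of antibody entries), `prophylaxis` (tibble of prophylaxis
#'   terms) and `systems` (antibody to blood-group-system lookup).
#' @export
#' @examples
#' cat <- compile_catalogue()
#' nrow(cat$entries)
compile_catalogue <- function(path = NULL) {
  path <- path %||% system.file("extdata", "antibody_patterns.csv",
                                package = "rbcscreen")
  if (!file.exists(path)) {
    abort(sprintf("pattern specification file not found: %s", path),
          class = "rbcscreen_catalogue_error")
  }
  spec <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  check_columns(spec, c("name", "system", "pattern"), "pattern specification")
  if (!"surface_forms" %in% names(spec)) spec$surface_forms <- spec$name
  if (!"case_fixed" %in% names(spec)) spec$case_fixed <- FALSE
  spec$case_fixed <- as.logical(spec$case_fixed)

  prophylaxis <- dplyr::filter(spec, .data$system == "prophylaxis")
  entries <- dplyr::filter(spec, .data$system != "prophylaxis")

  dup <- entries$name[duplicated(entries$name)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate canonical antibody name%s: %s",
                  if (length(dup) > 1) "s" else "",
                  paste(unique(dup), collapse = ", ")),
          class = "rbcscreen_catalogue_error")
  }

  for (tbl in list(entries, prophylaxis)) {
    for (i in seq_len(nrow(tbl))) {
      ok <- tryCatch({
        stringi::stri_detect_regex("probe", tbl$pattern[i])
        TRUE
      }, error = function(e) FALSE)
      if (!ok) {
        abort(sprintf("entry '%s' has a malformed pattern: %s",
                      tbl$name[i], tbl$pattern[i]),
              class = "rbcscreen_catalogue_error")
      }
    }
  }

  structure(
    list(
      entries = entries,
      prophylaxis = prophylaxis,
      systems = setNames(entries$system, entries$name)
    ),
    class = "antibody_catalogue"
  )
}

#' @export
print.antibody_catalogue <- function(x, ...) {
  n_spec <- sum(x$entries$name != "unspecified")
  cat(sprintf(
    "<antibody_catalogue> %d specific antibodies (%d entries), %d prophylaxis terms\n",
    n_spec, nrow(x$entries), nrow(x$prophylaxis)
  ))
  cat("systems:", paste(unique(x$entries$system), collapse = ", "), "\n")
  invisible(x)
}

#' Bundled default catalogue
#'
#' Returns the catalogue compiled from the pattern file shipped with the
#' package, memoised per session.
#'
#' @return An `antibody_catalogue` object.
#' @export
default_catalogue <- function() {
  if (is.null(.catalogue_cache$catalogue)) {
    .catalogue_cache$catalogue <- compile_catalogue()
  }
  .catalogue_cache$catalogue
}

.catalogue_cache <- new.env(parent = emptyenv())
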