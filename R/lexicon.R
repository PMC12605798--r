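# Drug-name lexicon: canonical TNFi categories and free-text name matching.

#' Canonical TNFi categories
#'
#' The closed six-category set used throughout the package: the five TNFi
#' generics, with infliximab split into biooriginator and biosimilar
#' products. Biosimilar infliximab is a distinct category because switching
#' between the originator and a biosimilar counts as a treatment switch.
#'
#' @return Character vector of the six canonical category names.
#' @export
tnfi_canonicals <- function() {
  c(
    "adalimumab", "etanercept", "certolizumab", "golimumab",
    "infliximab-biooriginator", "infliximab-biosimilar"
  )
}

#' Reason-for-switching categories
#'
#' The closed seven-value taxonomy for why a TNFi was stopped:
#' adverse event, drug resistance (documented anti-drug antibodies),
#' insurance/cost, lack of efficacy, patient preference, other, and
#' `na` (no reason documented).
#'
#' @return Character vector of the seven reason categories.
#' @export
reason_categories <- function() {
  c(
    "adverse_event", "drug_resistance", "insurance_cost",
    "lack_of_efficacy", "patient_preference", "other", "na"
  )
}

valid_name_kinds <- c("generic", "brand", "biosimilar")

#' Load a drug-name lexicon
#'
#' Reads a comma-separated lexicon with header `pattern,canonical,name_kind`.
#' Each `pattern` is matched case-insensitively as a substring of raw
#' medication strings; `canonical` must be one of [tnfi_canonicals()];
#' `name_kind` is one of generic, brand, biosimilar. Patterns must be unique
#' after case-folding.
#'
#' @param path Path to a lexicon CSV. Defaults to the bundled lexicon.
#' @return A tibble with columns `pattern`, `canonical`, `name_kind`.
#' @export
load_lexicon <- function(path = default_lexicon_path()) {
  if (!file.exists(path)) {
    stop("lexicon file does not exist: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  required <- c("pattern", "canonical", "name_kind")
  if (!all(required %in% names(raw))) {
    stop(
      "lexicon must have columns pattern, canonical, name_kind; got: ",
      paste(names(raw), collapse = ", "),
      call. = FALSE
    )
  }
  lex <- tibble::as_tibble(raw[required])
  if (nrow(lex) == 0) {
    warning("lexicon file is empty: ", path, call. = FALSE)
    return(lex)
  }
  bad_field <- which(!nzchar(lex$pattern) | is.na(lex$pattern) |
    is.na(lex$canonical) | is.na(lex$name_kind))
  if (length(bad_field) > 0) {
    stop(
      "malformed lexicon row(s) at line(s) ",
      paste(bad_field + 1L, collapse = ", "),
      " (1 header line): empty or missing fields",
      call. = FALSE
    )
  }
  bad_canon <- which(!lex$canonical %in% tnfi_canonicals())
  if (length(bad_canon) > 0) {
    stop(
      "lexicon row(s) at line(s) ", paste(bad_canon + 1L, collapse = ", "),
      ": canonical not in the six-category set: ",
      paste(unique(lex$canonical[bad_canon]), collapse = ", "),
      call. = FALSE
    )
  }
  bad_kind <- which(!lex$name_kind %in% valid_name_kinds)
  if (length(bad_kind) > 0) {
    stop(
      "lexicon row(s) at line(s) ", paste(bad_kind + 1L, collapse = ", "),
      ": name_kind must be one of ", paste(valid_name_kinds, collapse = ", "),
      call. = FALSE
    )
  }
  folded <- tolower(lex$pattern)
  if (anyDuplicated(folded)) {
    dups <- unique(folded[duplicated(folded)])
    stop(
      "duplicate lexicon pattern(s) after case-folding: ",
      paste(dups, collapse = ", "),
      call. = FALSE
    )
  }
  lex$pattern <- folded
  lex
}

#' @rdname load_lexicon
#' @export
default_lexicon_path <- function() {
  system.file("extdata", "tnfi_lexicon.csv", package = "tnfiswitch", mustWork = TRUE)
}

lexicon_cache <- new.env(parent = emptyenv())

#' Bundled default lexicon
#'
#' The shipped lexicon covers the six canonical categories with generic
#' names, the major US brand names, and the suffixed infliximab biosimilar
#' names. It is replaceable data, not method: supply your own file to
#' [load_lexicon()] to extend coverage.
#'
#' @return A tibble as returned by [load_lexicon()].
#' @export
default_lexicon <- function() {
  if (is.null(lexicon_cache$default)) {
    lexicon_cache$default <- load_lexicon(default_lexicon_path())
  }
  lexicon_cache$default
}

#' Normalize free-text medication names to canonical TNFi categories
#'
#' A raw string maps to the canonical category of the longest lexicon
#' pattern that occurs in it as a case-insensitive substring; dose, route
#' and form tokens are ignored implicitly by substring matching. The
#' longest-pattern rule makes biosimilar-specific patterns
#' (e.g. "infliximab-dyyb") beat the bare originator generic "infliximab".
#'
#' @param raw Character vector of free-text medication names.
#' @param lexicon A lexicon tibble from [load_lexicon()].
#' @return Character vector of canonical categories, `NA` where no pattern
#'   matches.
#' @examples
#' normalize_drug_name("adalimumab 40 mg/0.8 mL syringe")
#' normalize_drug_name("lisinopril 10mg tablet")
#' @export
normalize_drug_name <- function(raw, lexicon = default_lexicon()) {
  stopifnot(is.character(raw))
  if (length(raw) == 0) {
    return(character(0))
  }
  if (nrow(lexicon) == 0) {
    return(rep(NA_character_, length(raw)))
  }
  # longest pattern first; alphabetical within a length for determinism
  ord <- order(-nchar(lexicon$pattern), lexicon$pattern)
  patterns <- lexicon$pattern[ord]
  canons <- lexicon$canonical[ord]
  folded <- tolower(raw)
  out <- rep(NA_character_, length(raw))
  todo <- !is.na(folded)
  for (i in seq_along(patterns)) {
    if (!any(todo)) break
    hit <- todo & grepl(patterns[i], folded, fixed = TRUE)
    out[hit] <- canons[i]
    todo <- todo & !hit
  }
  out
}
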