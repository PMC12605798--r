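# Zero-shot prompt registry, output parsing into the fixed JSON schema,
# and deterministic extractor backends.

prompt_variants_all <- c(
  "default", "drugs_provided", "reasons_provided", "all_values_provided"
)

drug_value_list <- paste0(
  ' "Adalimumab", "Etanercept", "Certolizumab", "Golimumab",',
  ' "Infliximab-biooriginator", "Infliximab-biosimilar",'
)

reason_value_list <- paste0(
  ' "Adverse event", "Drug resistance", "Insurance/Cost",',
  '"Lack of efficacy","Patient preference","Other",'
)

prompt_body <- function(variant) {
  drugs <- variant %in% c("drugs_provided", "all_values_provided")
  reasons <- variant %in% c("reasons_provided", "all_values_provided")
  paste0(
    "Task: Tumor necrosis factor inhibitors (TNFis) are biologic drugs ",
    "targeting TNF proteins. Using the clinical note provided, extract the ",
    "following information into this JSON format: ",
    '{"new_TNFi":"What new TNFi was prescribed or started?',
    if (drugs) drug_value_list else "",
    ' If the patient is not starting a new TNFi, write "NA"",',
    '"last_TNFi":"What was the last TNFi the patient used?',
    if (drugs) drug_value_list else "",
    ' If none, write "NA"",',
    '"Reason for Switching":"Which best describes why the last TNFi was ',
    "stopped or planned to be stopped?",
    if (reasons) reason_value_list else "",
    ' "NA"",',
    '"full_reason_last_TNFi_stopped":"Provide a description for why the ',
    'last TNFi was stopped or planned to be stopped?"}'
  )
}

#' Render a zero-shot extraction prompt
#'
#' Four prompt variants share one instruction body and JSON output schema
#' (keys `new_TNFi`, `last_TNFi`, `Reason for Switching`,
#' `full_reason_last_TNFi_stopped`) and differ only in which closed value
#' lists they enumerate: `default` enumerates none, `drugs_provided` the
#' six canonical TNFi categories, `reasons_provided` the seven switching
#' reasons, and `all_values_provided` both. The clinical note is appended
#' after the instruction block, followed by the answer cue. An optional
#' backend tag wrapper decorates the prompt with model-specific template
#' tags without altering the body.
#'
#' @param variant One of `default`, `drugs_provided`, `reasons_provided`,
#'   `all_values_provided`.
#' @param note_text The clinical note (non-empty).
#' @param backend_tag Optional list with `prefix` and/or `suffix` strings.
#' @return The prompt as a single string.
#' @export
render_prompt <- function(variant, note_text, backend_tag = NULL) {
  if (!is.character(variant) || length(variant) != 1 ||
    !variant %in% prompt_variants_all) {
    stop(
      "unknown prompt variant; must be one of: ",
      paste(prompt_variants_all, collapse = ", "),
      call. = FALSE
    )
  }
  if (!is.character(note_text) || length(note_text) != 1 || !nzchar(note_text)) {
    stop("note_text must be a non-empty string", call. = FALSE)
  }
  body <- paste0(
    prompt_body(variant),
    "\n\nClinical note:\n", note_text, "\n\nAnswer:"
  )
  if (!is.null(backend_tag)) {
    body <- paste0(
      if (!is.null(backend_tag$prefix)) backend_tag$prefix else "",
      body,
      if (!is.null(backend_tag$suffix)) backend_tag$suffix else ""
    )
  }
  body
}

#' @rdname render_prompt
#' @export
prompt_variants <- function() prompt_variants_all

# -- output parsing ----------------------------------------------------------

fold_key <- function(x) gsub("[^a-z0-9]", "", tolower(x))

reason_lookup <- c(
  adverseevent = "adverse_event",
  adverseevents = "adverse_event",
  drugresistance = "drug_resistance",
  insurancecost = "insurance_cost",
  insurance = "insurance_cost",
  cost = "insurance_cost",
  lackofefficacy = "lack_of_efficacy",
  patientpreference = "patient_preference",
  other = "other",
  na = "na",
  unknown = "na",
  none = "na"
)

normalize_reason_value <- function(x) {
  if (is.null(x) || length(x) == 0 || all(is.na(x))) {
    return("na")
  }
  key <- fold_key(as.character(x)[1])
  if (!nzchar(key)) {
    return("na")
  }
  if (key %in% names(reason_lookup)) {
    return(unname(reason_lookup[[key]]))
  }
  # free text that is not one of the seven categories: keep as other
  "other"
}

normalize_drug_value <- function(x, lexicon) {
  if (is.null(x) || length(x) == 0 || all(is.na(x))) {
    return("na")
  }
  v <- as.character(x)[1]
  if (!nzchar(v) || fold_key(v) %in% c("na", "none", "unknown")) {
    return("na")
  }
  canon <- normalize_drug_name(v, lexicon)
  if (is.na(canon)) "na" else canon
}

# locate balanced {...} candidates outside of strings; returns substrings
balanced_json_candidates <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  out <- character(0)
  depth <- 0L
  start <- NA_integer_
  in_str <- FALSE
  esc <- FALSE
  for (i in seq_len(n)) {
    ch <- chars[i]
    if (in_str) {
      if (esc) {
        esc <- FALSE
      } else if (ch == "\\") {
        esc <- TRUE
      } else if (ch == '"') {
        in_str <- FALSE
      }
      next
    }
    if (ch == '"' && depth > 0L) {
      in_str <- TRUE
    } else if (ch == "{") {
      if (depth == 0L) start <- i
      depth <- depth + 1L
    } else if (ch == "}") {
      if (depth > 0L) {
        depth <- depth - 1L
        if (depth == 0L) {
          out <- c(out, substr(text, start, i))
        }
      }
    }
  }
  out
}

#' Parse extractor output into an extraction record
#'
#' Locates the first balanced JSON object in the backend's response
#' (stripping code fences and surrounding prose), maps its keys onto the
#' fixed schema, normalizes drug answers through the lexicon and reason
#' answers onto the seven-category taxonomy (case, whitespace and
#' punctuation folded). Missing keys become `na`; free-text reasons that
#' match no category become `other` with the text preserved in
#' `full_reason`. The parser never raises: an unparseable response yields
#' a record with `parse_ok = FALSE` and all categorical fields `na`.
#'
#' @param raw_text Full backend response.
#' @param lexicon Drug-name lexicon for normalizing drug answers.
#' @param note_id Optional note id to stamp on the record.
#' @param backend_id Optional backend id to stamp on the record.
#' @return One-row tibble: `note_id`, `new_tnfi`, `last_tnfi`, `reason`,
#'   `full_reason`, `parse_ok`, `backend_id`.
#' @export
parse_extraction_output <- function(raw_text, lexicon = default_lexicon(),
                                    note_id = NA_character_,
                                    backend_id = NA_character_) {
  failed <- tibble::tibble(
    note_id = note_id, new_tnfi = "na", last_tnfi = "na", reason = "na",
    full_reason = NA_character_, parse_ok = FALSE, backend_id = backend_id
  )
  if (!is.character(raw_text) || length(raw_text) != 1 || is.na(raw_text)) {
    return(failed)
  }
  text <- gsub("```[a-zA-Z]*", "", raw_text)
  parsed <- NULL
  for (cand in balanced_json_candidates(text)) {
    obj <- tryCatch(
      jsonlite::fromJSON(cand, simplifyVector = TRUE),
      error = function(e) NULL
    )
    if (is.list(obj) && !is.null(names(obj))) {
      parsed <- obj
      break
    }
  }
  if (is.null(parsed)) {
    return(failed)
  }
  keys <- fold_key(names(parsed))
  pick <- function(aliases) {
    idx <- which(keys %in% aliases)
    if (length(idx) == 0) NULL else parsed[[idx[1]]]
  }
  new_raw <- pick(c("newtnfi", "newtnf"))
  last_raw <- pick(c("lasttnfi", "lasttnf", "previoustnfi"))
  reason_raw <- pick(c("reasonforswitching", "reason"))
  full_raw <- pick(c("fullreasonlasttnfistopped", "fullreason"))
  full_reason <- if (is.null(full_raw) || length(full_raw) == 0) {
    NA_character_
  } else {
    as.character(full_raw)[1]
  }
  tibble::tibble(
    note_id = note_id,
    new_tnfi = normalize_drug_value(new_raw, lexicon),
    last_tnfi = normalize_drug_value(last_raw, lexicon),
    reason = normalize_reason_value(reason_raw),
    full_reason = full_reason,
    parse_ok = TRUE,
    backend_id = backend_id
  )
}

# -- backends ----------------------------------------------------------------

note_from_prompt <- function(prompt) {
  m <- regmatches(
    prompt,
    regexpr("Clinical note:\n.*\n\nAnswer:", prompt)
  )
  if (length(m) == 0) {
    return(prompt)
  }
  sub("\n\nAnswer:$", "", sub("^Clinical note:\n", "", m))
}

# rule-based field recovery keyed to the synthetic note template library
extract_note_fields <- function(note_text, lexicon = default_lexicon()) {
  last <- "na"
  new <- "na"
  reason <- "na"
  full_reason <- NA_character_
  # lazy matches: raw spellings may carry dose strings with embedded periods
  m <- regmatches(
    note_text,
    regexec("Plan: discontinue ([^\n]+?) and start ([^\n]+)\\.", note_text)
  )[[1]]
  if (length(m) == 3) {
    last <- normalize_drug_value(m[2], lexicon)
    new <- normalize_drug_value(m[3], lexicon)
  } else {
    m <- regmatches(
      note_text,
      regexec("Plan: continue ([^\n]+)\\.", note_text)
    )[[1]]
    if (length(m) == 2) {
      last <- normalize_drug_value(m[2], lexicon)
    }
  }
  bank <- reason_phrase_bank()
  for (cat in names(bank)) {
    hit <- bank[[cat]][vapply(
      bank[[cat]], function(p) grepl(p, note_text, fixed = TRUE), logical(1)
    )]
    if (length(hit) > 0) {
      reason <- cat
      full_reason <- hit[[1]]
      break
    }
  }
  list(last_tnfi = last, new_tnfi = new, reason = reason, full_reason = full_reason)
}

fields_to_json <- function(f) {
  display_drug <- function(x) if (identical(x, "na")) "NA" else x
  display_reason <- c(
    adverse_event = "Adverse event", drug_resistance = "Drug resistance",
    insurance_cost = "Insurance/Cost", lack_of_efficacy = "Lack of efficacy",
    patient_preference = "Patient preference", other = "Other", na = "NA"
  )
  jsonlite::toJSON(
    list(
      new_TNFi = display_drug(f$new_tnfi),
      last_TNFi = display_drug(f$last_tnfi),
      `Reason for Switching` = unname(display_reason[[f$reason]]),
      full_reason_last_TNFi_stopped = if (is.na(f$full_reason)) "NA" else f$full_reason
    ),
    auto_unbox = TRUE
  )
}

new_backend <- function(id, fun) {
  calls <- new.env(parent = emptyenv())
  calls$n <- 0L
  structure(
    list(
      id = id,
      fun = function(prompt) {
        calls$n <- calls$n + 1L
        fun(prompt)
      },
      calls = calls
    ),
    class = "tnfi_backend"
  )
}

#' @export
print.tnfi_backend <- function(x, ...) {
  cat("<tnfi_backend>", x$id, "- calls so far:", x$calls$n, "\n")
  invisible(x)
}

#' Deterministic reference extractor backend
#'
#' A rule-based stand-in extractor co-designed with the synthetic note
#' template library: on noise-free generated notes it recovers the planted
#' stopped drug, started drug and reason exactly, and returns `na` for the
#' reason on notes that do not verbalize one. It implements the same
#' backend contract as any external model adapter (a function from prompt
#' text to raw response text), emitting a schema-conformant JSON object.
#'
#' @param lexicon Drug-name lexicon.
#' @return A backend object usable with [run_extraction()].
#' @export
reference_backend <- function(lexicon = default_lexicon()) {
  new_backend("reference", function(prompt) {
    f <- extract_note_fields(note_from_prompt(prompt), lexicon)
    as.character(fields_to_json(f))
  })
}

#' @rdname reference_backend
#' @param note_text A clinical note (not a rendered prompt).
#' @return For `reference_extractor`: a one-row extraction record tibble.
#' @export
reference_extractor <- function(note_text, lexicon = default_lexicon()) {
  f <- extract_note_fields(note_text, lexicon)
  tibble::tibble(
    note_id = NA_character_,
    new_tnfi = f$new_tnfi,
    last_tnfi = f$last_tnfi,
    reason = f$reason,
    full_reason = f$full_reason,
    parse_ok = TRUE,
    backend_id = "reference"
  )
}

# deterministic 31-adic string hash into [0, 2^31 - 2]
string_hash <- function(x) {
  ints <- utf8ToInt(x)
  h <- 0
  m <- 2147483647
  for (v in ints) h <- (h * 31 + v) %% m
  as.integer(h)
}

with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

corrupt_value <- function(truth, pool, rate) {
  if (stats::runif(1) < rate) sample(pool, 1) else truth
}

#' Noisy extractor backend
#'
#' Wraps the reference rules and, independently per field with the given
#' probability, replaces the recovered value by a uniform draw over the
#' field's substantive value set (the six canonical drugs, or the six
#' non-`na` reasons). The draw may collide with the truth, so the expected
#' per-field accuracy on notes whose true value is substantive is
#' `1 - rate + rate/6`. Corruption is seeded per note (derived
#' deterministically from the backend seed and the note text), so records
#' are reproducible regardless of evaluation order.
#'
#' @param error_rates Named list/vector of corruption probabilities for
#'   `new_tnfi`, `last_tnfi`, `reason` (each in \[0, 1\]; missing fields
#'   default to 0).
#' @param seed Integer backend seed.
#' @param id Backend id string.
#' @param lexicon Drug-name lexicon.
#' @return A backend object usable with [run_extraction()].
#' @export
noisy_backend <- function(error_rates = list(), seed = 1L,
                          id = NULL, lexicon = default_lexicon()) {
  rates <- list(new_tnfi = 0, last_tnfi = 0, reason = 0)
  for (nm in names(error_rates)) {
    if (!nm %in% names(rates)) {
      stop("unknown field in error_rates: ", nm, call. = FALSE)
    }
    r <- as.numeric(error_rates[[nm]])
    if (is.na(r) || r < 0 || r > 1) {
      stop("error rate for ", nm, " must be in [0, 1]", call. = FALSE)
    }
    rates[[nm]] <- r
  }
  if (is.null(id)) {
    id <- sprintf(
      "noisy-%s-s%d",
      paste(sprintf("%.2f", unlist(rates)), collapse = "-"), seed
    )
  }
  substantive_reasons <- setdiff(reason_categories(), "na")
  new_backend(id, function(prompt) {
    note_text <- note_from_prompt(prompt)
    f <- extract_note_fields(note_text, lexicon)
    note_seed <- (string_hash(note_text) + seed * 7919) %% 2147483647
    f <- with_local_seed(note_seed, {
      f$new_tnfi <- corrupt_value(f$new_tnfi, tnfi_canonicals(), rates$new_tnfi)
      f$last_tnfi <- corrupt_value(f$last_tnfi, tnfi_canonicals(), rates$last_tnfi)
      f$reason <- corrupt_value(f$reason, substantive_reasons, rates$reason)
      f
    })
    as.character(fields_to_json(f))
  })
}

#' Run an extractor backend over a set of notes
#'
#' Renders the prompt, calls the backend once per note, parses responses
#' into extraction records, and (optionally) caches raw responses on disk
#' keyed by backend id, prompt variant and a prompt digest, so a rerun
#' with a warm cache makes no backend calls and returns bit-identical
#' records. A backend failure on one note degrades to a flagged record
#' (`parse_ok = FALSE`); the pipeline continues.
#'
#' @param notes Notes tibble with `note_id` and `text`.
#' @param backend A backend from [reference_backend()], [noisy_backend()],
#'   or any object with fields `id` and `fun(prompt) -> text`.
#' @param variant Prompt variant (see [render_prompt()]).
#' @param cache_dir Optional directory for the response cache.
#' @param lexicon Drug-name lexicon.
#' @return Tibble of extraction records, one row per note.
#' @export
run_extraction <- function(notes, backend, variant = "reasons_provided",
                           cache_dir = NULL, lexicon = default_lexicon()) {
  stopifnot(all(c("note_id", "text") %in% names(notes)))
  if (nrow(notes) == 0) {
    stop("notes must be non-empty", call. = FALSE)
  }
  if (!is.null(cache_dir) && !dir.exists(cache_dir)) {
    dir.create(cache_dir, recursive = TRUE)
  }
  n_failed <- 0L
  records <- vector("list", nrow(notes))
  for (i in seq_len(nrow(notes))) {
    prompt <- render_prompt(variant, notes$text[i])
    raw <- NULL
    cache_file <- NULL
    if (!is.null(cache_dir)) {
      key <- prompt_digest(prompt)
      cache_file <- file.path(
        cache_dir, sprintf("%s_%s_%s.txt", backend$id, variant, key)
      )
      if (file.exists(cache_file)) {
        raw <- readChar(cache_file, file.info(cache_file)$size, useBytes = TRUE)
      }
    }
    if (is.null(raw)) {
      raw <- tryCatch(backend$fun(prompt), error = function(e) NA_character_)
      if (!is.na(raw) && !is.null(cache_file)) {
        writeChar(raw, cache_file, eos = NULL, useBytes = TRUE)
      }
    }
    if (is.na(raw)) n_failed <- n_failed + 1L
    records[[i]] <- parse_extraction_output(
      raw,
      lexicon = lexicon, note_id = notes$note_id[i], backend_id = backend$id
    )
  }
  out <- dplyr::bind_rows(records)
  attr(out, "n_failed") <- n_failed
  out
}

prompt_digest <- function(prompt) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeChar(prompt, tf, eos = NULL, useBytes = TRUE)
  unname(tools::md5sum(tf))
}
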