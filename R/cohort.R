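# Cohort construction: attrition flow, switch detection, follow-up
# classification and demographic tabulation.

attrition_entry <- function(stage, n_in, n_removed) {
  tibble::tibble(
    stage = stage,
    n_in = as.integer(n_in),
    n_removed = as.integer(n_removed),
    n_out = as.integer(n_in - n_removed)
  )
}

check_orders <- function(orders, need_canonical = FALSE) {
  required <- c("patient_id", "encounter_id", "order_date", "raw_name")
  if (need_canonical) required <- c(required, "canonical")
  missing <- setdiff(required, names(orders))
  if (length(missing) > 0) {
    stop("orders table missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (!inherits(orders$order_date, "Date")) {
    stop("orders$order_date must be a Date (whole calendar days)", call. = FALSE)
  }
  if (need_canonical) {
    bad <- !is.na(orders$canonical) & !orders$canonical %in% tnfi_canonicals()
    if (any(bad)) {
      stop(
        "orders$canonical contains values outside the six-category set: ",
        paste(unique(orders$canonical[bad]), collapse = ", "),
        call. = FALSE
      )
    }
  }
  invisible(orders)
}

#' Remove duplicate medication orders
#'
#' A duplicate is a repeated (patient, order date, canonical drug) triple;
#' dose and modality differences are ignored because canonicalization has
#' already discarded them. The first row in a deterministic ordering
#' (by patient, date, canonical, encounter, raw name) is retained, so the
#' result is invariant to input row order.
#'
#' @param orders Orders tibble with a `canonical` column.
#' @return A list with `orders` (deduplicated) and `attrition` (one-row log).
#' @export
deduplicate_orders <- function(orders) {
  check_orders(orders, need_canonical = TRUE)
  n_in <- nrow(orders)
  out <- dplyr::arrange(
    orders,
    .data$patient_id, .data$order_date, .data$canonical,
    .data$encounter_id, .data$raw_name
  )
  out <- dplyr::distinct(out, .data$patient_id, .data$order_date,
    .data$canonical,
    .keep_all = TRUE
  )
  list(
    orders = out,
    attrition = attrition_entry("duplicate orders removed", n_in, n_in - nrow(out))
  )
}

#' Drop encounters where multiple distinct TNFi were ordered the same day
#'
#' All orders from any (patient, order date) bearing two or more distinct
#' canonical categories are removed: a same-day pair of different TNFi is
#' ambiguous and is never counted as a switch.
#'
#' @param orders Deduplicated orders tibble with `canonical`.
#' @return A list with `orders` and `attrition`.
#' @export
drop_multi_tnfi_encounters <- function(orders) {
  check_orders(orders, need_canonical = TRUE)
  n_in <- nrow(orders)
  out <- dplyr::group_by(orders, .data$patient_id, .data$order_date)
  out <- dplyr::filter(out, dplyr::n_distinct(.data$canonical) == 1L)
  out <- dplyr::ungroup(out)
  list(
    orders = out,
    attrition = attrition_entry(
      "multi-TNFi same-date encounters removed", n_in, n_in - nrow(out)
    )
  )
}

#' Attach the last clinical note to each encounter
#'
#' Encounters with several notes keep only the note with the maximum
#' timestamp (the most complete version); timestamp ties are broken by the
#' lexicographically largest note id for determinism. Orders whose
#' encounter has no note are dropped and counted.
#'
#' @param orders Orders tibble.
#' @param notes Notes tibble with `note_id`, `encounter_id`, `timestamp`,
#'   `text`.
#' @return A list with `orders` (note-bearing only), `note_map` (tibble
#'   `encounter_id`, `note_id`), and `attrition`.
#' @export
attach_last_note <- function(orders, notes) {
  check_orders(orders)
  required <- c("note_id", "encounter_id", "timestamp", "text")
  missing <- setdiff(required, names(notes))
  if (length(missing) > 0) {
    stop("notes table missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  n_in <- nrow(orders)
  note_map <- dplyr::arrange(notes, .data$encounter_id, .data$timestamp, .data$note_id)
  note_map <- dplyr::slice_tail(
    dplyr::group_by(note_map, .data$encounter_id),
    n = 1L
  )
  note_map <- dplyr::ungroup(note_map)[, c("encounter_id", "note_id")]
  out <- orders[orders$encounter_id %in% note_map$encounter_id, , drop = FALSE]
  list(
    orders = out,
    note_map = note_map,
    attrition = attrition_entry(
      "orders without associated clinical notes removed", n_in, n_in - nrow(out)
    )
  )
}

#' Detect TNFi switches on one patient's timeline
#'
#' A switch is a change in canonical TNFi between two consecutive
#' TNFi-order encounters. The timeline must be deduplicated, carry one
#' canonical per date, and be sorted ascending by date; ordinals are
#' assigned 1, 2, ... in date order. Biooriginator-to-biosimilar
#' infliximab transitions (either direction) are switches because the two
#' are distinct canonical categories.
#'
#' @param timeline Tibble for one patient with `patient_id`, `order_date`,
#'   `canonical` and optionally `note_id` (note attached to each encounter).
#' @return Tibble of switch events: `patient_id`, `ordinal`, `from_drug`,
#'   `to_drug`, `from_date`, `to_date`, `note_id` (destination encounter's
#'   note, `NA` if none supplied).
#' @export
detect_switches <- function(timeline) {
  stopifnot(all(c("patient_id", "order_date", "canonical") %in% names(timeline)))
  if (length(unique(timeline$patient_id)) > 1) {
    stop("detect_switches expects a single patient's timeline", call. = FALSE)
  }
  if (is.unsorted(timeline$order_date, strictly = FALSE)) {
    stop("timeline must be sorted ascending by order_date", call. = FALSE)
  }
  if (anyDuplicated(timeline$order_date)) {
    stop(
      "timeline has multiple orders on one date; deduplicate and drop ",
      "multi-TNFi encounters first",
      call. = FALSE
    )
  }
  n <- nrow(timeline)
  empty <- tibble::tibble(
    patient_id = character(0), ordinal = integer(0),
    from_drug = character(0), to_drug = character(0),
    from_date = as.Date(character(0)), to_date = as.Date(character(0)),
    note_id = character(0)
  )
  if (n < 2) {
    return(empty)
  }
  change <- which(timeline$canonical[-1] != timeline$canonical[-n]) + 1L
  if (length(change) == 0) {
    return(empty)
  }
  note_id <- if ("note_id" %in% names(timeline)) {
    as.character(timeline$note_id[change])
  } else {
    rep(NA_character_, length(change))
  }
  tibble::tibble(
    patient_id = timeline$patient_id[change],
    ordinal = seq_along(change),
    from_drug = timeline$canonical[change - 1L],
    to_drug = timeline$canonical[change],
    from_date = timeline$order_date[change - 1L],
    to_date = timeline$order_date[change],
    note_id = note_id
  )
}

#' Classify a patient's follow-up status
#'
#' Patients with at least one switch are `switcher`. A non-switcher is
#' `no_switch_followed` when some encounter occurs at least `horizon_days`
#' after the patient's last TNFi order (so absence of a switch is
#' interpretable), otherwise `lost_to_followup`. Follow-up years run from
#' the first TNFi order to the last encounter.
#'
#' @param patient_orders Surviving TNFi orders for one patient (with
#'   `order_date`).
#' @param patient_encounters Encounters for the same patient (with
#'   `encounter_date`, a Date).
#' @param n_switches Number of detected switches for the patient.
#' @param horizon_days Follow-up horizon; 183 days is six months.
#' @return One-row tibble: `patient_id`, `status`, `n_switches`,
#'   `followup_years`.
#' @export
classify_followup <- function(patient_orders, patient_encounters, n_switches,
                              horizon_days = 183L) {
  stopifnot(nrow(patient_orders) >= 1)
  pid <- patient_orders$patient_id[1]
  last_order <- max(patient_orders$order_date)
  first_order <- min(patient_orders$order_date)
  enc_dates <- patient_encounters$encounter_date
  last_touch <- if (length(enc_dates) > 0) max(max(enc_dates), last_order) else last_order
  status <- if (n_switches >= 1) {
    "switcher"
  } else if (length(enc_dates) > 0 &&
    any(as.numeric(enc_dates - last_order) >= horizon_days)) {
    "no_switch_followed"
  } else {
    "lost_to_followup"
  }
  tibble::tibble(
    patient_id = pid,
    status = status,
    n_switches = as.integer(n_switches),
    followup_years = as.numeric(last_touch - first_order) / 365.25
  )
}

#' Build the TNFi cohort
#'
#' Runs the full attrition flow in order: normalize drug names (dropping
#' non-TNFi orders), drop patients without demographic data, deduplicate,
#' drop orders without clinical notes, drop multi-TNFi same-date
#' encounters, attach the last note per encounter, detect switches per
#' patient, and classify follow-up. The attrition log chains exactly:
#' each stage's output count is the next stage's input count.
#'
#' @param orders Orders tibble: `patient_id`, `encounter_id`, `order_date`
#'   (Date), `raw_name`.
#' @param encounters Encounters tibble: `patient_id`, `encounter_id`,
#'   `encounter_date` (Date).
#' @param notes Notes tibble: `note_id`, `encounter_id`, `timestamp`, `text`.
#' @param demographics Demographics tibble with `patient_id`; patients
#'   absent from it are excluded.
#' @param lexicon Drug-name lexicon.
#' @param horizon_days Follow-up horizon in days.
#' @return An object of class `tnfi_cohort`: a list with `orders` (final
#'   analysis orders with `canonical` and `note_id`), `note_map`,
#'   `switches`, `statuses`, `attrition`, `encounters`.
#' @export
build_cohort <- function(orders, encounters, notes, demographics,
                         lexicon = default_lexicon(), horizon_days = 183L) {
  check_orders(orders)
  stopifnot(all(c("patient_id", "encounter_id", "encounter_date") %in% names(encounters)))
  if (!"patient_id" %in% names(demographics)) {
    stop("demographics table must have a patient_id column", call. = FALSE)
  }
  log <- list()

  # 1. normalize raw names; orders not matching any TNFi pattern are dropped
  n_in <- nrow(orders)
  orders$canonical <- normalize_drug_name(orders$raw_name, lexicon)
  orders <- orders[!is.na(orders$canonical), , drop = FALSE]
  log$normalize <- attrition_entry("non-TNFi orders removed", n_in, n_in - nrow(orders))

  # 2. patients without demographics
  n_in <- nrow(orders)
  excluded_pids <- setdiff(unique(orders$patient_id), demographics$patient_id)
  orders <- orders[orders$patient_id %in% demographics$patient_id, , drop = FALSE]
  log$demographics <- attrition_entry(
    "orders from patients without demographics removed", n_in, n_in - nrow(orders)
  )

  # 3. duplicates
  step <- deduplicate_orders(orders)
  orders <- step$orders
  log$dedup <- step$attrition

  # 4. orders without notes
  n_in <- nrow(orders)
  noted <- unique(notes$encounter_id)
  orders <- orders[orders$encounter_id %in% noted, , drop = FALSE]
  log$notes <- attrition_entry(
    "orders without associated clinical notes removed", n_in, n_in - nrow(orders)
  )

  # 5. multi-TNFi same-date encounters
  step <- drop_multi_tnfi_encounters(orders)
  orders <- step$orders
  log$multi <- step$attrition

  # 6. last note per surviving encounter (no rows removed: stage 4 already
  # dropped note-less orders)
  step <- attach_last_note(orders, notes)
  orders <- step$orders
  note_map <- step$note_map
  orders <- dplyr::left_join(orders, note_map, by = "encounter_id")
  orders <- dplyr::arrange(orders, .data$patient_id, .data$order_date)

  # 7. switches per patient
  empty_switches <- tibble::tibble(
    patient_id = character(0), ordinal = integer(0),
    from_drug = character(0), to_drug = character(0),
    from_date = as.Date(character(0)), to_date = as.Date(character(0)),
    note_id = character(0)
  )
  empty_statuses <- tibble::tibble(
    patient_id = character(0), status = character(0),
    n_switches = integer(0), followup_years = numeric(0)
  )
  switches <- if (nrow(orders) == 0) empty_switches else dplyr::group_modify(
    dplyr::group_by(orders, .data$patient_id),
    function(df, key) {
      tl <- tibble::tibble(
        patient_id = key$patient_id,
        order_date = df$order_date,
        canonical = df$canonical,
        note_id = df$note_id
      )
      ev <- detect_switches(tl)
      ev$patient_id <- NULL
      ev
    }
  )
  switches <- dplyr::ungroup(switches)

  # 8. follow-up classification
  n_sw <- table(switches$patient_id)
  statuses <- if (nrow(orders) == 0) empty_statuses else dplyr::group_modify(
    dplyr::group_by(orders, .data$patient_id),
    function(df, key) {
      pid <- key$patient_id
      st <- classify_followup(
        tibble::tibble(patient_id = pid, order_date = df$order_date),
        encounters[encounters$patient_id == pid, , drop = FALSE],
        n_switches = if (pid %in% names(n_sw)) as.integer(n_sw[[pid]]) else 0L,
        horizon_days = horizon_days
      )
      st$patient_id <- NULL
      st
    }
  )
  statuses <- dplyr::ungroup(statuses)
  if (length(excluded_pids) > 0) {
    statuses <- dplyr::bind_rows(
      statuses,
      tibble::tibble(
        patient_id = excluded_pids,
        status = "excluded_no_demographics",
        n_switches = 0L,
        followup_years = NA_real_
      )
    )
  }

  attrition <- dplyr::bind_rows(log)
  if (!all(attrition$n_out == attrition$n_in - attrition$n_removed) ||
    (nrow(attrition) > 1 &&
      !all(attrition$n_in[-1] == attrition$n_out[-nrow(attrition)]))) {
    stop("internal error: attrition log does not chain", call. = FALSE)
  }

  structure(
    list(
      orders = orders,
      note_map = note_map,
      switches = switches,
      statuses = statuses,
      attrition = attrition,
      encounters = encounters,
      horizon_days = horizon_days
    ),
    class = "tnfi_cohort"
  )
}

#' @export
print.tnfi_cohort <- function(x, ...) {
  cat("<tnfi_cohort>\n")
  cat("  orders:   ", nrow(x$orders), "\n")
  cat("  patients: ", sum(x$statuses$status != "excluded_no_demographics"), "\n")
  cat("  switches: ", nrow(x$switches), "\n")
  st <- table(x$statuses$status)
  for (nm in names(st)) cat(sprintf("  %-22s %d\n", nm, st[[nm]]))
  invisible(x)
}

#' Summarize cohort status proportions
#'
#' Counts and percentages of switchers, non-switchers with follow-up, and
#' patients lost to follow-up, over all classified patients (patients
#' excluded for missing demographics are not part of the denominator).
#'
#' @param statuses Tibble with `status` (from [build_cohort()] or
#'   constructed directly).
#' @return Tibble `status`, `n`, `pct` (percent of classified patients).
#' @export
cohort_status_summary <- function(statuses) {
  keep <- statuses$status %in% c("switcher", "no_switch_followed", "lost_to_followup")
  st <- factor(statuses$status[keep],
    levels = c("switcher", "no_switch_followed", "lost_to_followup")
  )
  n <- as.integer(table(st))
  tibble::tibble(
    status = levels(st),
    n = n,
    pct = 100 * n / sum(n)
  )
}
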