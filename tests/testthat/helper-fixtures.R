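# Small in-code fixtures shared across test files.

make_orders <- function(patient_id, dates, raw_names,
                        encounter_ids = sprintf("E%s-%02d", patient_id, seq_along(dates))) {
  tibble::tibble(
    patient_id = patient_id,
    encounter_id = encounter_ids,
    order_date = as.Date(dates),
    raw_name = raw_names
  )
}

make_notes <- function(encounter_ids,
                       note_ids = sprintf("N%02d", seq_along(encounter_ids)),
                       timestamps = as.POSIXct("2020-01-01 12:00:00", tz = "UTC") +
                         seq_along(encounter_ids),
                       texts = rep("note text", length(encounter_ids))) {
  tibble::tibble(
    note_id = note_ids,
    encounter_id = encounter_ids,
    timestamp = timestamps,
    text = texts
  )
}

make_records <- function(note_ids, new_tnfi, last_tnfi, reason,
                         backend_id = "test") {
  tibble::tibble(
    note_id = note_ids,
    new_tnfi = new_tnfi,
    last_tnfi = last_tnfi,
    reason = reason,
    full_reason = NA_character_,
    parse_ok = TRUE,
    backend_id = backend_id
  )
}

# a small fully in-memory patient timeline for cohort tests
tiny_timeline <- function(drugs, patient_id = "P1",
                          start = as.Date("2020-01-01"), gap = 60) {
  tibble::tibble(
    patient_id = patient_id,
    order_date = start + gap * (seq_along(drugs) - 1),
    canonical = drugs
  )
}

random_categories <- function(n, pool) {
  pool[sample.int(length(pool), n, replace = TRUE)]
}
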