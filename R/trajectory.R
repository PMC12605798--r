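# Trajectory summaries: per-patient drug sequences, Sankey flow tables,
# and reason distributions by switch ordinal.

#' Per-patient ordered drug sequences
#'
#' Each patient's sequence is their first canonical drug followed by the
#' destination drug of each switch in ordinal order, so its length is
#' 1 + number of switches.
#'
#' @param cohort A `tnfi_cohort` from [build_cohort()].
#' @return Tibble `patient_id`, `sequence` (list-column of character
#'   vectors).
#' @export
build_sequences <- function(cohort) {
  stopifnot(inherits(cohort, "tnfi_cohort"))
  orders <- dplyr::arrange(cohort$orders, .data$patient_id, .data$order_date)
  first <- dplyr::slice_head(dplyr::group_by(orders, .data$patient_id), n = 1L)
  first <- dplyr::ungroup(first)[, c("patient_id", "canonical")]
  sw <- dplyr::arrange(cohort$switches, .data$patient_id, .data$ordinal)
  seqs <- lapply(seq_len(nrow(first)), function(i) {
    pid <- first$patient_id[i]
    c(first$canonical[i], sw$to_drug[sw$patient_id == pid])
  })
  tibble::tibble(patient_id = first$patient_id, sequence = seqs)
}

#' Sankey-style flow table of switching trajectories
#'
#' Counts stage-by-stage transitions between canonical drugs up to
#' `max_depth` stages. A patient whose sequence ends at stage k flows from
#' their stage-k drug to the terminal node `"no further switch"`. Flow is
#' conserved: at every stage, outflows from a node equal its inflow, and
#' total stage-1 inflow equals the cohort size.
#'
#' @param sequences Output of [build_sequences()].
#' @param max_depth Number of transition stages (a pooled tail beyond it
#'   is not expanded).
#' @return Tibble `stage`, `source`, `target`, `n`.
#' @export
sankey_flow_table <- function(sequences, max_depth = 3L) {
  stopifnot(all(c("patient_id", "sequence") %in% names(sequences)))
  rows <- list()
  for (k in seq_len(max_depth)) {
    src <- character(0)
    tgt <- character(0)
    for (s in sequences$sequence) {
      if (length(s) < k) next
      src <- c(src, s[k])
      tgt <- c(tgt, if (length(s) >= k + 1) s[k + 1] else "no further switch")
    }
    if (length(src) == 0) next
    tab <- as.data.frame(table(source = src, target = tgt),
      stringsAsFactors = FALSE
    )
    tab <- tab[tab$Freq > 0, , drop = FALSE]
    if (nrow(tab) > 0) {
      rows[[k]] <- tibble::tibble(
        stage = k, source = tab$source, target = tab$target,
        n = as.integer(tab$Freq)
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(
      stage = integer(0), source = character(0),
      target = character(0), n = integer(0)
    ))
  }
  dplyr::bind_rows(rows)
}

#' Reason distribution by switch ordinal band
#'
#' Joins extraction records to switch events by note id, maps switch
#' ordinals to the bands first / second / third-plus, and reports the
#' proportion of each reason per band. Records whose reason is `na` (no
#' reason documented) are excluded by default, mirroring reporting of
#' reason shares only among notes with an extractable reason; the
#' denominator per band (`band_n`) is always reported explicitly.
#'
#' @param switches Switch-event tibble (with `ordinal`, `note_id`).
#' @param records Extraction records (with `note_id`, `reason`).
#' @param include_na Include `na` as a category in the proportions.
#' @return Tibble `band`, `reason`, `n`, `proportion`, `band_n`. Bands
#'   with zero records are absent.
#' @export
reason_by_switch_ordinal <- function(switches, records, include_na = FALSE) {
  stopifnot(
    all(c("ordinal", "note_id") %in% names(switches)),
    all(c("note_id", "reason") %in% names(records))
  )
  df <- dplyr::inner_join(
    switches[, c("ordinal", "note_id")],
    records[, c("note_id", "reason")],
    by = "note_id"
  )
  if (!include_na) df <- df[df$reason != "na", , drop = FALSE]
  if (nrow(df) == 0) {
    return(tibble::tibble(
      band = character(0), reason = character(0), n = integer(0),
      proportion = numeric(0), band_n = integer(0)
    ))
  }
  df$band <- ifelse(df$ordinal == 1, "first",
    ifelse(df$ordinal == 2, "second", "third_plus")
  )
  cats <- if (include_na) reason_categories() else setdiff(reason_categories(), "na")
  out <- list()
  for (b in intersect(c("first", "second", "third_plus"), unique(df$band))) {
    sub <- df$reason[df$band == b]
    counts <- table(factor(sub, levels = cats))
    out[[b]] <- tibble::tibble(
      band = b, reason = cats, n = as.integer(counts),
      proportion = as.integer(counts) / length(sub),
      band_n = length(sub)
    )
  }
  dplyr::bind_rows(out)
}

#' Write trajectory summaries to disk
#'
#' Emits the flow table and reason-by-ordinal table as both delimited text
#' and JSON.
#'
#' @param flow_table Output of [sankey_flow_table()].
#' @param reasons Output of [reason_by_switch_ordinal()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_trajectory_report <- function(flow_table, reasons, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    flow_csv = file.path(dir, "sankey_flows.csv"),
    flow_json = file.path(dir, "sankey_flows.json"),
    reasons_csv = file.path(dir, "reason_by_ordinal.csv"),
    reasons_json = file.path(dir, "reason_by_ordinal.json")
  )
  utils::write.csv(flow_table, paths["flow_csv"], row.names = FALSE)
  jsonlite::write_json(flow_table, paths["flow_json"], digits = NA)
  utils::write.csv(reasons, paths["reasons_csv"], row.names = FALSE)
  jsonlite::write_json(reasons, paths["reasons_json"], digits = NA)
  invisible(paths)
}
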