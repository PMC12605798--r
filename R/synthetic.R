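# Seeded synthetic-EHR generator with planted ground truth. Emits the
# exact tables the cohort module consumes (orders, encounters, notes,
# demographics) plus truth and gold labels, so the full pipeline is
# testable offline.

#' Reason phrase bank for synthetic notes
#'
#' At least three paraphrases per substantive reason category, including
#' an anti-drug-antibody phrasing for drug resistance. The reference
#' extractor and these phrases are co-designed: each phrase maps back to
#' exactly one category and no phrase appears in distractor sentences.
#'
#' @return Named list of character vectors, one per substantive reason.
#' @export
reason_phrase_bank <- function() {
  list(
    adverse_event = c(
      "a severe injection-site reaction",
      "recurrent infections attributed to the drug",
      "a drug-induced rash with intolerable side effects"
    ),
    drug_resistance = c(
      "documented anti-drug antibodies on testing",
      "high titers of anti-drug antibodies",
      "neutralizing anti-drug antibodies with undetectable trough levels"
    ),
    insurance_cost = c(
      "loss of insurance coverage for this agent",
      "prohibitive out-of-pocket cost",
      "a formulary change with denied prior authorization"
    ),
    lack_of_efficacy = c(
      "persistent disease activity despite therapy",
      "inadequate clinical response after dose optimization",
      "ongoing flares indicating loss of response"
    ),
    patient_preference = c(
      "the patient's preference for a different injection schedule",
      "patient request to change therapy",
      "the patient's wish to avoid infusions"
    ),
    other = c(
      "planned surgery requiring a treatment change",
      "pregnancy planning considerations",
      "relocation and a change of care setting"
    )
  )
}

dose_suffixes <- c(
  "", " 40 mg/0.8 mL syringe", " 50 mg/mL injection",
  " 100 mg intravenous solution", " prefilled pen"
)

distractor_block <- function() {
  paste0(
    sprintf(
      "Follow-up visit. Vitals: BP %d/%d, HR %d.",
      sample(100:140, 1), sample(60:90, 1), sample(55:95, 1)
    ), "\n",
    sprintf(
      "Labs: CRP %.1f mg/L, ESR %d mm/h.",
      stats::runif(1, 0.5, 30), sample(2:60, 1)
    ), "\n",
    "Other medications: lisinopril 10 mg daily, vitamin D."
  )
}

#' Generate one synthetic clinical note
#'
#' Switch notes embed the stopped and started drug (in whatever raw
#' spelling the caller supplies) and, when a reason is documented, one
#' phrase from the matching reason bank; maintenance notes mention the
#' current drug without causal language. Distractor sentences (vitals,
#' labs, an unrelated medication) are always present. Uses the current
#' RNG stream for distractor values and phrase choice.
#'
#' @param kind `"switch"` or `"maintenance"`.
#' @param from_raw,to_raw Raw spellings of the stopped/started drug
#'   (switch notes).
#' @param current_raw Raw spelling of the continued drug (maintenance
#'   notes).
#' @param reason_category A substantive reason category, or `NULL` for a
#'   reason-free note.
#' @return Note text (single string).
#' @export
generate_note <- function(kind = c("switch", "maintenance"),
                          from_raw = NULL, to_raw = NULL, current_raw = NULL,
                          reason_category = NULL) {
  kind <- match.arg(kind)
  body <- distractor_block()
  if (kind == "switch") {
    stopifnot(!is.null(from_raw), !is.null(to_raw))
    body <- paste0(
      body, "\n",
      sprintf("Plan: discontinue %s and start %s.", from_raw, to_raw)
    )
    if (!is.null(reason_category)) {
      bank <- reason_phrase_bank()
      if (!reason_category %in% names(bank)) {
        stop("unknown reason category: ", reason_category, call. = FALSE)
      }
      phrase <- sample(bank[[reason_category]], 1)
      body <- paste0(body, "\n", sprintf("The switch is prompted by %s.", phrase))
    }
  } else {
    stopifnot(!is.null(current_raw))
    body <- paste0(body, "\n", sprintf("Plan: continue %s.", current_raw))
  }
  body
}

default_generator_defaults <- function() {
  list(
    first_drug_dist = c(
      "adalimumab" = 0.409, "infliximab-biooriginator" = 0.263,
      "etanercept" = 0.241, "certolizumab" = 0.033,
      "infliximab-biosimilar" = 0.031, "golimumab" = 0.023
    ),
    p_switcher = 0.1825,
    switch_count_dist = c("1" = 0.701, "2" = 0.198, "3" = 0.05325, "4" = 0.01775),
    reason_dist = c(
      lack_of_efficacy = 0.569, adverse_event = 0.135, insurance_cost = 0.108,
      patient_preference = 0.082, drug_resistance = 0.053, other = 0.053
    ),
    p_reason_documented = 0.41,
    p_duplicate_order = 0.27,
    p_multi_tnfi_encounter = 0.034,
    p_missing_note = 0.087,
    p_lost_to_followup = 0.206,
    p_missing_demographics = 0.001,
    encounter_gap_min = 14L,
    encounter_gap_shape = 2,
    encounter_gap_scale = 45,
    extra_encounters_mean = 6,
    age_mean = 39.9,
    age_sd = 19.0,
    sex_dist = c(Female = 0.571, Male = 0.429),
    race_dist = c(
      "White" = 0.602, "Hispanic" = 0.139, "Other" = 0.109, "Asian" = 0.070,
      "Black or African American" = 0.048, "Multi-Race/Ethnicity" = 0.024,
      "Southwest Asian and North African" = 0.008
    ),
    p_missing_race = 0.047,
    diagnosis_dist = c(
      "Unspecified" = 0.572, "Inflammatory Bowel Disease" = 0.154,
      "Multiple" = 0.074, "Rheumatoid Arthritis" = 0.057,
      "Psoriasis" = 0.034, "Juvenile Idiopathic Arthritis" = 0.031,
      "SA" = 0.023, "Hidradenitis" = 0.017, "Psoriatic arthritis" = 0.017,
      "Other" = 0.013, "Uveitis" = 0.006
    ),
    start_date_min = as.Date("2012-01-01"),
    start_date_max = as.Date("2021-12-31")
  )
}

#' Construct a validated synthetic-generator configuration
#'
#' Defaults anchor the generated cohort's shape to published desk-scale
#' proportions: first-drug shares, the 18.25% switcher fraction, the
#' switch-count distribution among switchers (70.1% / 19.8% / 7.1% for
#' one / two / three-plus, with the three-plus tail split 3:1 between
#' three and four switches), reason shares led by lack of efficacy
#' (56.9%), a 41% rate of reason documentation in switch notes, a 20.6%
#' loss-to-follow-up rate, and order-level corruption rates for
#' duplicates, multi-TNFi same-date encounters and missing notes.
#' Categorical distributions are renormalized to sum to one and all
#' probabilities are validated; invalid fields are reported together.
#'
#' @param n_patients Number of patients to generate.
#' @param seed Integer seed; all randomness flows from it.
#' @param ... Overrides for any default field (see
#'   `tnfiswitch:::default_generator_defaults`).
#' @return A list of class `tnfi_generator_config`.
#' @export
generator_config <- function(n_patients = 500L, seed = 1L, ...) {
  cfg <- default_generator_defaults()
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0) {
    stop(
      "unknown generator config field(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  cfg[names(overrides)] <- overrides
  cfg$n_patients <- as.integer(n_patients)
  cfg$seed <- as.integer(seed)

  bad <- character(0)
  if (is.na(cfg$n_patients) || cfg$n_patients < 1) bad <- c(bad, "n_patients")
  if (is.na(cfg$seed)) bad <- c(bad, "seed")
  probs <- c(
    "p_switcher", "p_reason_documented", "p_duplicate_order",
    "p_multi_tnfi_encounter", "p_missing_note", "p_lost_to_followup",
    "p_missing_demographics", "p_missing_race"
  )
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      bad <- c(bad, p)
    }
  }
  dists <- c(
    "first_drug_dist", "switch_count_dist", "reason_dist", "sex_dist",
    "race_dist", "diagnosis_dist"
  )
  for (d in dists) {
    v <- cfg[[d]]
    if (!is.numeric(v) || is.null(names(v)) || any(is.na(v)) || any(v < 0) ||
      sum(v) <= 0) {
      bad <- c(bad, d)
    } else {
      cfg[[d]] <- v / sum(v)
    }
  }
  if (!is.numeric(cfg$encounter_gap_min) || cfg$encounter_gap_min < 3) {
    bad <- c(bad, "encounter_gap_min")
  }
  if (length(bad) > 0) {
    stop(
      "invalid generator config field(s): ", paste(unique(bad), collapse = ", "),
      call. = FALSE
    )
  }
  structure(cfg, class = "tnfi_generator_config")
}

spelling_pools <- function(lexicon) {
  # category labels are valid lexicon patterns (idempotent normalization)
  # but are not spellings an EHR order would carry
  keep <- lexicon$pattern != lexicon$canonical |
    !grepl("bio", lexicon$canonical, fixed = TRUE)
  split(lexicon$pattern[keep], lexicon$canonical[keep])
}

#' Generate a synthetic TNFi cohort with planted ground truth
#'
#' Draws per-patient multi-year TNFi order timelines: a follow-up status
#' (switcher / followed non-switcher / lost to follow-up), a planted
#' switch count and drug sequence, encounter dates with gamma-distributed
#' gaps, raw drug spellings sampled from the lexicon's synonym pools, and
#' one clinical note per core encounter (a switch note at each switch
#' destination, verbalizing the reason with probability
#' `p_reason_documented`). Corruptions are injected at configured rates as
#' extra rows the pipeline provably removes — exact duplicate orders,
#' multi-TNFi encounters on new dates strictly between core encounters,
#' and note-less same-drug orders — so ground truth is preserved under
#' cohort construction. Fully reproducible from the config seed.
#'
#' @param config A `tnfi_generator_config` from [generator_config()].
#' @return List with tibbles `orders`, `encounters`, `notes`,
#'   `demographics`, `gold` (note-level labels for all switch notes), and
#'   `truth` (a list with `switches`, `patients`, and planted corruption
#'   counts).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "tnfi_generator_config"))
  lex <- default_lexicon()
  pools <- spelling_pools(lex)
  canonicals <- tnfi_canonicals()
  p_lost_cond <- if (config$p_switcher < 1) {
    min(1, config$p_lost_to_followup / (1 - config$p_switcher))
  } else {
    0
  }
  start_span <- as.integer(config$start_date_max - config$start_date_min)

  with_local_seed(config$seed, {
    orders_l <- list()
    enc_l <- list()
    notes_l <- list()
    demo_l <- list()
    truth_sw_l <- list()
    truth_pat_l <- list()
    n_dup <- 0L
    n_multi_orders <- 0L
    n_noteless <- 0L

    for (i in seq_len(config$n_patients)) {
      pid <- sprintf("P%05d", i)
      is_switcher <- stats::runif(1) < config$p_switcher
      status <- if (is_switcher) {
        "switcher"
      } else if (stats::runif(1) < p_lost_cond) {
        "lost_to_followup"
      } else {
        "no_switch_followed"
      }
      n_sw <- if (is_switcher) {
        as.integer(sample(
          names(config$switch_count_dist), 1,
          prob = config$switch_count_dist
        ))
      } else {
        0L
      }
      n_core <- n_sw + 1L + stats::rpois(1, config$extra_encounters_mean)

      # planted drug sequence over core encounters
      sw_gaps <- if (n_sw > 0) sort(sample(n_core - 1L, n_sw)) else integer(0)
      drugs <- character(n_core)
      drugs[1] <- sample(names(config$first_drug_dist), 1,
        prob = config$first_drug_dist
      )
      cur <- drugs[1]
      for (k in seq_len(n_core - 1L)) {
        if (k %in% sw_gaps) cur <- sample(setdiff(canonicals, cur), 1)
        drugs[k + 1L] <- cur
      }

      gaps <- config$encounter_gap_min +
        round(stats::rgamma(
          max(n_core - 1L, 0), config$encounter_gap_shape,
          scale = config$encounter_gap_scale
        ))
      dates <- config$start_date_min + sample.int(start_span + 1L, 1) - 1L +
        cumsum(c(0, gaps))
      enc_counter <- 0L
      next_eid <- function() {
        enc_counter <<- enc_counter + 1L
        sprintf("E%s-%03d", pid, enc_counter)
      }
      core_eids <- vapply(seq_len(n_core), function(j) next_eid(), character(1))

      spell <- function(canon) {
        paste0(sample(pools[[canon]], 1), sample(dose_suffixes, 1))
      }
      core_raw <- vapply(drugs, spell, character(1), USE.NAMES = FALSE)

      orders_l[[length(orders_l) + 1]] <- data.frame(
        patient_id = pid, encounter_id = core_eids, order_date = dates,
        raw_name = core_raw, stringsAsFactors = FALSE
      )
      enc_l[[length(enc_l) + 1]] <- data.frame(
        patient_id = pid, encounter_id = core_eids, encounter_date = dates,
        stringsAsFactors = FALSE
      )

      # notes: one per core encounter; switch destinations get switch notes
      dest_idx <- sw_gaps + 1L
      reason <- character(0)
      documented <- logical(0)
      if (n_sw > 0) {
        reason <- sample(names(config$reason_dist), n_sw,
          replace = TRUE, prob = config$reason_dist
        )
        documented <- stats::runif(n_sw) < config$p_reason_documented
      }
      note_ids <- sprintf("N%s-%03d", pid, seq_len(n_core))
      texts <- character(n_core)
      for (j in seq_len(n_core)) {
        s <- match(j, dest_idx)
        texts[j] <- if (!is.na(s)) {
          generate_note(
            "switch",
            from_raw = spell(drugs[j - 1L]), to_raw = spell(drugs[j]),
            reason_category = if (documented[s]) reason[s] else NULL
          )
        } else {
          generate_note("maintenance", current_raw = spell(drugs[j]))
        }
      }
      notes_l[[length(notes_l) + 1]] <- data.frame(
        note_id = note_ids, encounter_id = core_eids,
        timestamp = as.POSIXct(dates, tz = "UTC") +
          sample(8 * 3600:(17 * 3600), n_core, replace = TRUE) %% (12 * 3600),
        text = texts, stringsAsFactors = FALSE
      )

      if (n_sw > 0) {
        truth_sw_l[[length(truth_sw_l) + 1]] <- data.frame(
          patient_id = pid, ordinal = seq_len(n_sw),
          from_drug = drugs[dest_idx - 1L], to_drug = drugs[dest_idx],
          from_date = dates[dest_idx - 1L], to_date = dates[dest_idx],
          reason = reason, reason_documented = documented,
          note_id = note_ids[dest_idx], stringsAsFactors = FALSE
        )
      }

      # corruption: exact duplicate orders (removed by deduplication)
      dup <- which(stats::runif(n_core) < config$p_duplicate_order)
      if (length(dup) > 0) {
        n_dup <- n_dup + length(dup)
        orders_l[[length(orders_l) + 1]] <- data.frame(
          patient_id = pid, encounter_id = core_eids[dup],
          order_date = dates[dup],
          raw_name = vapply(drugs[dup], spell, character(1), USE.NAMES = FALSE),
          stringsAsFactors = FALSE
        )
      }

      # corruption: multi-TNFi encounters and note-less orders on new dates
      # strictly between core encounters, where their removal restores the
      # planted timeline
      if (n_core >= 2) {
        for (g in seq_len(n_core - 1L)) {
          span <- as.integer(dates[g + 1L] - dates[g])
          if (span < 3) next
          used_offsets <- integer(0)
          if (stats::runif(1) < config$p_multi_tnfi_encounter) {
            off <- sample(seq_len(span - 1L), 1)
            used_offsets <- off
            mdate <- dates[g] + off
            meid <- next_eid()
            mdrugs <- sample(canonicals, 2)
            n_multi_orders <- n_multi_orders + 2L
            orders_l[[length(orders_l) + 1]] <- data.frame(
              patient_id = pid, encounter_id = meid, order_date = mdate,
              raw_name = vapply(mdrugs, spell, character(1), USE.NAMES = FALSE),
              stringsAsFactors = FALSE
            )
            enc_l[[length(enc_l) + 1]] <- data.frame(
              patient_id = pid, encounter_id = meid, encounter_date = mdate,
              stringsAsFactors = FALSE
            )
            notes_l[[length(notes_l) + 1]] <- data.frame(
              note_id = sprintf("N%s-X%03d", pid, enc_counter),
              encounter_id = meid,
              timestamp = as.POSIXct(mdate, tz = "UTC") + 10 * 3600,
              text = generate_note("maintenance", current_raw = spell(mdrugs[1])),
              stringsAsFactors = FALSE
            )
          }
          free <- setdiff(seq_len(span - 1L), used_offsets)
          if (length(free) > 0 && stats::runif(1) < config$p_missing_note) {
            off <- if (length(free) == 1) free else sample(free, 1)
            ndate <- dates[g] + off
            neid <- next_eid()
            n_noteless <- n_noteless + 1L
            orders_l[[length(orders_l) + 1]] <- data.frame(
              patient_id = pid, encounter_id = neid, order_date = ndate,
              raw_name = spell(drugs[g]), stringsAsFactors = FALSE
            )
            enc_l[[length(enc_l) + 1]] <- data.frame(
              patient_id = pid, encounter_id = neid, encounter_date = ndate,
              stringsAsFactors = FALSE
            )
          }
        }
      }

      # follow-up encounters (drug-free): late for followed patients, early
      # for patients lost to follow-up
      last_core <- dates[n_core]
      if (status != "lost_to_followup") {
        feid <- next_eid()
        fdate <- last_core + 183L + stats::rpois(1, 30)
        enc_l[[length(enc_l) + 1]] <- data.frame(
          patient_id = pid, encounter_id = feid, encounter_date = fdate,
          stringsAsFactors = FALSE
        )
      } else {
        feid <- next_eid()
        fdate <- last_core + sample(14:120, 1)
        enc_l[[length(enc_l) + 1]] <- data.frame(
          patient_id = pid, encounter_id = feid, encounter_date = fdate,
          stringsAsFactors = FALSE
        )
      }

      has_demo <- stats::runif(1) >= config$p_missing_demographics
      if (has_demo) {
        race <- if (stats::runif(1) < config$p_missing_race) {
          NA_character_
        } else {
          sample(names(config$race_dist), 1, prob = config$race_dist)
        }
        demo_l[[length(demo_l) + 1]] <- data.frame(
          patient_id = pid,
          age = max(1, min(95, round(stats::rnorm(1, config$age_mean, config$age_sd)))),
          sex = sample(names(config$sex_dist), 1, prob = config$sex_dist),
          race = race,
          diagnosis = sample(names(config$diagnosis_dist), 1,
            prob = config$diagnosis_dist
          ),
          stringsAsFactors = FALSE
        )
      }
      truth_pat_l[[length(truth_pat_l) + 1]] <- data.frame(
        patient_id = pid, status = if (has_demo) status else "excluded_no_demographics",
        n_switches = n_sw, first_drug = drugs[1], has_demographics = has_demo,
        stringsAsFactors = FALSE
      )
    }

    orders <- tibble::as_tibble(dplyr::bind_rows(orders_l))
    encounters <- tibble::as_tibble(dplyr::bind_rows(enc_l))
    notes <- tibble::as_tibble(dplyr::bind_rows(notes_l))
    demographics <- tibble::as_tibble(dplyr::bind_rows(demo_l))
    truth_switches <- if (length(truth_sw_l) > 0) {
      tibble::as_tibble(dplyr::bind_rows(truth_sw_l))
    } else {
      tibble::tibble(
        patient_id = character(0), ordinal = integer(0),
        from_drug = character(0), to_drug = character(0),
        from_date = as.Date(character(0)), to_date = as.Date(character(0)),
        reason = character(0), reason_documented = logical(0),
        note_id = character(0)
      )
    }
    truth_patients <- tibble::as_tibble(dplyr::bind_rows(truth_pat_l))
    gold <- tibble::tibble(
      note_id = truth_switches$note_id,
      last_tnfi = truth_switches$from_drug,
      new_tnfi = truth_switches$to_drug,
      reason = ifelse(truth_switches$reason_documented, truth_switches$reason, "na")
    )
    list(
      orders = orders,
      encounters = encounters,
      notes = notes,
      demographics = demographics,
      gold = gold,
      truth = list(
        switches = truth_switches,
        patients = truth_patients,
        n_planted_duplicates = n_dup,
        n_planted_multi_orders = n_multi_orders,
        n_planted_noteless = n_noteless
      )
    )
  })
}

#' Write a generated cohort to disk
#'
#' Emits the four input tables as CSV (ISO-8601 dates) and the ground
#' truth and gold labels as JSON-lines.
#'
#' @param sim Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_synthetic_cohort <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    orders = file.path(dir, "orders.csv"),
    encounters = file.path(dir, "encounters.csv"),
    notes = file.path(dir, "notes.csv"),
    demographics = file.path(dir, "demographics.csv"),
    gold = file.path(dir, "gold_labels.jsonl"),
    truth = file.path(dir, "truth_switches.jsonl")
  )
  utils::write.csv(sim$orders, paths["orders"], row.names = FALSE)
  utils::write.csv(sim$encounters, paths["encounters"], row.names = FALSE)
  utils::write.csv(sim$notes, paths["notes"], row.names = FALSE)
  utils::write.csv(sim$demographics, paths["demographics"], row.names = FALSE)
  writeLines(
    vapply(seq_len(nrow(sim$gold)), function(i) {
      as.character(jsonlite::toJSON(as.list(sim$gold[i, ]), auto_unbox = TRUE))
    }, character(1)),
    paths["gold"]
  )
  tsw <- sim$truth$switches
  tsw$from_date <- as.character(tsw$from_date)
  tsw$to_date <- as.character(tsw$to_date)
  writeLines(
    vapply(seq_len(nrow(tsw)), function(i) {
      as.character(jsonlite::toJSON(as.list(tsw[i, ]), auto_unbox = TRUE))
    }, character(1)),
    paths["truth"]
  )
  invisible(paths)
}
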