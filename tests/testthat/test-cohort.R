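canon3 <- c("adalimumab", "etanercept", "infliximab-biooriginator")

test_that("deduplication keeps one order per patient-date-drug and is order-invariant", {
  orders <- make_orders("P1", c("2020-01-01", "2020-01-01", "2020-03-01"),
    rep("humira", 3),
    encounter_ids = c("E1", "E1", "E2")
  )
  orders$canonical <- "adalimumab"
  out <- deduplicate_orders(orders)
  expect_equal(nrow(out$orders), 2)
  expect_equal(out$attrition$n_removed, 1L)
  expect_equal(out$attrition$n_out, out$attrition$n_in - out$attrition$n_removed)

  # same patient/date, different drugs: not duplicates
  two <- make_orders("P1", c("2020-01-01", "2020-01-01"), c("humira", "enbrel"),
    encounter_ids = c("E1", "E1")
  )
  two$canonical <- c("adalimumab", "etanercept")
  expect_equal(nrow(deduplicate_orders(two)$orders), 2)

  # permutation property on random tables
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(5:25, 1)
    tab <- tibble::tibble(
      patient_id = sample(c("P1", "P2"), n, replace = TRUE),
      encounter_id = sprintf("E%d", sample(1:6, n, replace = TRUE)),
      order_date = as.Date("2020-01-01") + sample(0:3, n, replace = TRUE),
      raw_name = "x",
      canonical = random_categories(n, canon3)
    )
    a <- deduplicate_orders(tab)$orders
    b <- deduplicate_orders(tab[sample.int(n), ])$orders
    expect_identical(a, b)
    expect_equal(
      nrow(a),
      nrow(unique(tab[c("patient_id", "order_date", "canonical")]))
    )
  }
})

test_that("multi-TNFi same-date encounters are removed entirely", {
  orders <- make_orders("P1", rep("2020-01-01", 2), c("humira", "enbrel"),
    encounter_ids = c("E1", "E1")
  )
  orders$canonical <- c("adalimumab", "etanercept")
  out <- drop_multi_tnfi_encounters(orders)
  expect_equal(nrow(out$orders), 0)
  expect_equal(out$attrition$n_removed, 2L)

  solo <- make_orders("P1", c("2020-01-01", "2020-02-01"), c("humira", "humira"))
  solo$canonical <- "adalimumab"
  expect_equal(drop_multi_tnfi_encounters(solo)$orders, solo)

  # property: output has exactly one distinct canonical per patient-date
  set.seed(12)
  for (rep in 1:10) {
    n <- sample(10:40, 1)
    tab <- tibble::tibble(
      patient_id = sample(c("P1", "P2", "P3"), n, replace = TRUE),
      encounter_id = sprintf("E%d", seq_len(n)),
      order_date = as.Date("2020-01-01") + sample(0:4, n, replace = TRUE),
      raw_name = "x",
      canonical = random_categories(n, canon3)
    )
    kept <- drop_multi_tnfi_encounters(tab)$orders
    brute <- split(tab$canonical, paste(tab$patient_id, tab$order_date))
    expected_keys <- names(brute)[vapply(brute, function(v) length(unique(v)) == 1, logical(1))]
    expect_setequal(unique(paste(kept$patient_id, kept$order_date)), expected_keys)
  }
})

test_that("last note per encounter is selected, ties broken by note id", {
  orders <- make_orders("P1", c("2020-01-01", "2020-02-01"), rep("humira", 2),
    encounter_ids = c("E1", "E2")
  )
  notes <- make_notes(
    c("E1", "E1", "E2", "E2"),
    note_ids = c("N1", "N2", "N3", "N4"),
    timestamps = as.POSIXct(
      c(
        "2020-01-01 09:00", "2020-01-01 17:00",
        "2020-02-01 10:00", "2020-02-01 10:00"
      ),
      tz = "UTC"
    )
  )
  out <- attach_last_note(orders, notes)
  map <- setNames(out$note_map$note_id, out$note_map$encounter_id)
  expect_equal(unname(map["E1"]), "N2") # max timestamp
  expect_equal(unname(map["E2"]), "N4") # tie -> lexicographic max note id
  expect_equal(out$attrition$n_removed, 0L)

  # encounter with no note is dropped and counted
  out2 <- attach_last_note(orders, notes[notes$encounter_id == "E1", ])
  expect_equal(nrow(out2$orders), 1)
  expect_equal(out2$attrition$n_removed, 1L)
})

test_that("switch detection emits adjacent-unequal transitions with ordinals", {
  expect_equal(nrow(detect_switches(tiny_timeline(rep("adalimumab", 3)))), 0)

  tl <- tiny_timeline(c("adalimumab", "etanercept", "adalimumab"))
  ev <- detect_switches(tl)
  expect_equal(ev$ordinal, 1:2)
  expect_equal(ev$from_drug, c("adalimumab", "etanercept"))
  expect_equal(ev$to_drug, c("etanercept", "adalimumab"))
  expect_true(all(ev$from_date < ev$to_date))

  # biooriginator <-> biosimilar infliximab is a switch
  ev2 <- detect_switches(
    tiny_timeline(c("infliximab-biooriginator", "infliximab-biosimilar"))
  )
  expect_equal(nrow(ev2), 1)

  unsorted <- tiny_timeline(c("adalimumab", "etanercept"))
  unsorted <- unsorted[2:1, ]
  expect_error(detect_switches(unsorted), "sorted")
  same_day <- tiny_timeline(c("adalimumab", "etanercept"), gap = 0)
  expect_error(detect_switches(same_day), "multiple orders")
})

test_that("switch count equals the brute-force oracle over all length<=5 sequences of 3 drugs", {
  for (len in 1:5) {
    grid <- do.call(expand.grid, c(
      rep(list(canon3), len),
      stringsAsFactors = FALSE
    ))
    for (r in seq_len(nrow(grid))) {
      s <- unlist(grid[r, ], use.names = FALSE)
      ev <- detect_switches(tiny_timeline(s))
      expect_equal(nrow(ev), oracle_switch_count(s))
      if (nrow(ev) > 0) expect_equal(ev$ordinal, seq_len(nrow(ev)))
    }
  }
})

test_that("follow-up classification honors the 183-day horizon for non-switchers", {
  po <- tibble::tibble(patient_id = "P1", order_date = as.Date("2020-01-01"))
  enc_late <- tibble::tibble(
    patient_id = "P1", encounter_id = "E9",
    encounter_date = as.Date("2020-01-01") + 200
  )
  enc_early <- tibble::tibble(
    patient_id = "P1", encounter_id = "E9",
    encounter_date = as.Date("2020-01-01") + 30
  )
  expect_equal(classify_followup(po, enc_late, 0)$status, "no_switch_followed")
  expect_equal(classify_followup(po, enc_early, 0)$status, "lost_to_followup")
  # switchers are classified before the follow-up rule
  expect_equal(classify_followup(po, enc_early, 2)$status, "switcher")
  expect_equal(
    classify_followup(po, enc_late, 0)$followup_years, 200 / 365.25
  )
})

test_that("build_cohort recovers planted switches and chains its attrition log", {
  sim <- generate_cohort(generator_config(n_patients = 150, seed = 7))
  co <- build_cohort(sim$orders, sim$encounters, sim$notes, sim$demographics)

  att <- co$attrition
  expect_equal(att$n_out, att$n_in - att$n_removed)
  expect_equal(att$n_in[-1], att$n_out[-nrow(att)])

  truth <- sim$truth$switches
  truth <- truth[truth$patient_id %in% sim$demographics$patient_id, ]
  got <- dplyr::arrange(co$switches, patient_id, ordinal)
  truth <- dplyr::arrange(truth, patient_id, ordinal)
  cols <- c("patient_id", "ordinal", "from_drug", "to_drug", "from_date", "to_date", "note_id")
  expect_equal(as.data.frame(got[cols]), as.data.frame(truth[cols]))

  # statuses match the generator's plan; partition is exhaustive and disjoint
  st <- dplyr::inner_join(co$statuses, sim$truth$patients,
    by = "patient_id", suffix = c("", "_truth")
  )
  expect_equal(st$status, st$status_truth)
  expect_equal(sum(st$n_switches), nrow(truth))
  expect_true(all(
    (st$status == "switcher") == (st$n_switches >= 1) |
      st$status == "excluded_no_demographics"
  ))
  expect_true(all(st$n_switches[st$status == "lost_to_followup"] == 0))

  # deduplication removed exactly the planted duplicates
  expect_equal(
    att$n_removed[att$stage == "duplicate orders removed"],
    {
      # duplicates planted for the excluded patient are removed earlier
      pre <- sim$orders[sim$orders$patient_id %in% sim$demographics$patient_id, ]
      pre$canonical <- normalize_drug_name(pre$raw_name)
      nrow(pre) - nrow(unique(pre[c("patient_id", "order_date", "canonical")]))
    }
  )

  # determinism: rebuilt cohort is identical
  co2 <- build_cohort(sim$orders, sim$encounters, sim$notes, sim$demographics)
  expect_identical(co$switches, co2$switches)
  expect_identical(co$attrition, co2$attrition)
})

test_that("build_cohort on empty input yields an empty cohort with a zero attrition log", {
  empty_orders <- tibble::tibble(
    patient_id = character(0), encounter_id = character(0),
    order_date = as.Date(character(0)), raw_name = character(0)
  )
  empty_enc <- tibble::tibble(
    patient_id = character(0), encounter_id = character(0),
    encounter_date = as.Date(character(0))
  )
  empty_notes <- make_notes(character(0), note_ids = character(0),
    timestamps = as.POSIXct(character(0), tz = "UTC"), texts = character(0)
  )
  co <- build_cohort(
    empty_orders, empty_enc, empty_notes,
    tibble::tibble(patient_id = character(0))
  )
  expect_equal(nrow(co$switches), 0)
  expect_equal(nrow(co$statuses), 0)
  expect_true(all(co$attrition$n_in == 0) && all(co$attrition$n_removed == 0))
})

test_that("cohort status proportions are percentages of classified patients", {
  statuses <- tibble::tibble(status = c(
    rep("switcher", 3), rep("no_switch_followed", 5), rep("lost_to_followup", 2)
  ))
  s <- cohort_status_summary(statuses)
  expect_equal(s$n, c(3L, 5L, 2L))
  expect_equal(s$pct, c(30, 50, 20))
})
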