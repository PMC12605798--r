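test_that("silver labels mirror the structured switch orders", {
  switches <- tibble::tibble(
    note_id = c("n1", "n2"),
    from_drug = c("etanercept", "adalimumab"),
    to_drug = c("adalimumab", "golimumab")
  )
  lab <- derive_silver_labels(switches)
  expect_equal(lab$last_tnfi, c("etanercept", "adalimumab"))
  expect_equal(lab$new_tnfi, c("adalimumab", "golimumab"))

  none <- switches[0, ]
  expect_equal(nrow(derive_silver_labels(none)), 0)

  dup <- switches
  dup$note_id <- "n1"
  expect_error(derive_silver_labels(dup), "multiple switch events")
})

test_that("validation/test split is patient-level, seeded, disjoint and exhaustive", {
  patients <- sprintf("P%03d", 1:100)
  note_ids <- sprintf("note%03d", 1:300)
  patient_ids <- rep(patients, each = 3)
  sp <- split_validation_test(note_ids, patient_ids, fraction = 0.05, seed = 42)
  val_patients <- unique(patient_ids[note_ids %in% sp$validation])
  expect_equal(length(val_patients), 5)
  # no patient straddles the split
  expect_length(intersect(
    val_patients, unique(patient_ids[note_ids %in% sp$test])
  ), 0)
  expect_setequal(c(sp$validation, sp$test), note_ids)
  sp2 <- split_validation_test(note_ids, patient_ids, fraction = 0.05, seed = 42)
  expect_identical(sp, sp2)
  expect_false(identical(
    sp,
    split_validation_test(note_ids, patient_ids, fraction = 0.05, seed = 43)
  ))
  expect_error(
    split_validation_test("n1", "P1", fraction = 0.05, seed = 1),
    "validation"
  )

  set.seed(17)
  for (rep in 1:10) {
    n_pat <- sample(30:80, 1)
    pids <- rep(sprintf("q%02d", seq_len(n_pat)), sample(1:3, n_pat, replace = TRUE))
    nids <- sprintf("m%03d", seq_along(pids))
    s <- split_validation_test(nids, pids, fraction = 0.2, seed = rep)
    expect_length(intersect(s$validation, s$test), 0)
    expect_setequal(c(s$validation, s$test), nids)
  }
})

test_that("micro-F1 pools TP/FP/FN across substantive classes", {
  labels <- tibble::tibble(note_id = c("n1", "n2", "n3"), reason = c("A", "B", "C"))
  recs <- make_records(c("n1", "n2", "n3"),
    new_tnfi = "na", last_tnfi = "na",
    reason = c("A", "B", "B")
  )
  res <- micro_f1(recs, labels, "reason", "all_values")
  expect_equal(res$micro_f1, 2 / 3) # TP=2, FP=1, FN=1
  expect_equal(res$n_evaluated, 3L)

  perfect <- micro_f1(
    make_records(labels$note_id, "na", "na", labels$reason),
    labels, "reason", "all_values"
  )
  expect_equal(perfect$micro_f1, 1)
})

test_that("na predictions miss recall; null-dropping excludes self-reported na notes", {
  labels <- tibble::tibble(note_id = c("n1", "n2"), reason = c("A", "na"))
  recs <- make_records(c("n1", "n2"), "na", "na", reason = c("na", "na"))
  all_vals <- micro_f1(recs, labels, "reason", "all_values")
  expect_equal(all_vals$micro_f1, 0) # TP=0, FN=1
  dropped <- micro_f1(recs, labels, "reason", "null_dropped")
  expect_true(is.na(dropped$micro_f1))
  expect_equal(dropped$n_evaluated, 0L)
})

test_that("null-dropping is governed by the record's own reason field for drug scores", {
  labels <- tibble::tibble(
    note_id = c("n1", "n2"),
    last_tnfi = c("etanercept", "adalimumab")
  )
  recs <- make_records(c("n1", "n2"),
    new_tnfi = "na",
    last_tnfi = c("etanercept", "golimumab"),
    reason = c("lack_of_efficacy", "na")
  )
  all_vals <- micro_f1(recs, labels, "last_tnfi", "all_values")
  dropped <- micro_f1(recs, labels, "last_tnfi", "null_dropped")
  expect_equal(all_vals$n_evaluated, 2L)
  expect_equal(dropped$n_evaluated, 1L) # n2 self-filtered
  expect_equal(dropped$micro_f1, 1)
  expect_lte(dropped$n_evaluated, all_vals$n_evaluated)
})

test_that("pairwise win/loss/tie rates have the stated identities", {
  correct <- cbind(A = rep(TRUE, 10), B = rep(FALSE, 10))
  m <- pairwise_win_rates(correct)
  ab <- m$pairs[m$pairs$model_a == "A" & m$pairs$model_b == "B", ]
  expect_equal(ab$win, 1)
  expect_equal(ab$tie, 0)

  twin <- cbind(A = c(TRUE, FALSE, TRUE), B = c(TRUE, FALSE, TRUE))
  m2 <- pairwise_win_rates(twin)
  p <- m2$pairs[m2$pairs$model_a == "A", ]
  expect_equal(p$win, 0)
  expect_equal(p$loss, 0)
  expect_equal(p$tie, 1)
})

test_that("win/loss/tie identities and antisymmetry hold on random vectors", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(10:50, 1)
    correct <- cbind(
      A = sample(c(TRUE, FALSE), n, TRUE),
      B = sample(c(TRUE, FALSE), n, TRUE),
      C = sample(c(TRUE, FALSE), n, TRUE)
    )
    m <- pairwise_win_rates(correct)
    expect_equal(m$pairs$win + m$pairs$loss + m$pairs$tie, rep(1, nrow(m$pairs)),
      tolerance = 1e-12
    )
    for (r in seq_len(nrow(m$pairs))) {
      rev <- m$pairs[
        m$pairs$model_a == m$pairs$model_b[r] &
          m$pairs$model_b == m$pairs$model_a[r],
      ]
      expect_equal(m$pairs$win[r], rev$loss)
      expect_equal(m$pairs$tie[r], rev$tie)
    }
    # oracle equivalence by brute-force double loop
    for (pair in list(c("A", "B"), c("B", "C"), c("C", "A"))) {
      o <- oracle_pair_rates(correct[, pair[1]], correct[, pair[2]])
      row <- m$pairs[m$pairs$model_a == pair[1] & m$pairs$model_b == pair[2], ]
      expect_equal(c(row$win, row$loss, row$tie), unname(o))
    }
  }
})

test_that("win-minus-loss versus a baseline is zero for the baseline and signed correctly", {
  correct <- cbind(
    base = c(TRUE, FALSE, FALSE, TRUE),
    better = c(TRUE, TRUE, FALSE, TRUE),
    same = c(TRUE, FALSE, FALSE, TRUE)
  )
  m <- pairwise_win_rates(correct)
  wml <- win_minus_loss_vs_baseline(m, "base")
  expect_equal(wml$win_minus_loss[wml$model == "base"], 0)
  expect_equal(wml$win_minus_loss[wml$model == "same"], 0)
  expect_gt(wml$win_minus_loss[wml$model == "better"], 0)
  expect_error(win_minus_loss_vs_baseline(m, "nope"), "baseline")
})

test_that("concordance is 100% with SD 0 against itself and matches the oracle", {
  recs <- make_records(c("n1", "n2", "n3"),
    new_tnfi = c("adalimumab", "na", "etanercept"),
    last_tnfi = c("etanercept", "adalimumab", "na"),
    reason = c("lack_of_efficacy", "na", "other")
  )
  self <- concordance(recs, recs)
  expect_equal(self$mean, 100)
  expect_equal(self$sd, 0)

  other <- recs
  other$reason <- c("adverse_event", "other", "na") # total disagreement, one field
  mixed <- concordance(recs, other)
  expect_lt(mixed$mean, 100)
  expect_gt(mixed$sd, 0)

  set.seed(9)
  cats <- c(tnfi_canonicals(), "na")
  for (rep in 1:10) {
    n <- sample(5:30, 1)
    a <- make_records(sprintf("n%02d", 1:n),
      random_categories(n, cats), random_categories(n, cats),
      random_categories(n, reason_categories())
    )
    b <- make_records(sprintf("n%02d", 1:n),
      random_categories(n, cats), random_categories(n, cats),
      random_categories(n, reason_categories())
    )
    got <- concordance(a, b)
    oracle <- oracle_concordance(a, b, c("new_tnfi", "last_tnfi", "reason"))
    expect_equal(got$mean, oracle$mean)
    expect_equal(got$sd, oracle$sd)
  }

  disjoint <- make_records("zz", "na", "na", "na")
  expect_error(concordance(recs, disjoint), "same")
})

test_that("micro-F1 matches the brute-force oracle on random instances", {
  set.seed(31)
  cats <- c("A", "B", "C", "na")
  for (rep in 1:50) {
    n <- sample(3:50, 1)
    ids <- sprintf("n%03d", 1:n)
    labels <- tibble::tibble(note_id = ids, reason = random_categories(n, cats))
    recs <- make_records(ids, "na", "na", random_categories(n, cats))
    got <- micro_f1(recs, labels, "reason", "all_values")
    expect_equal(got$micro_f1, oracle_micro_f1(labels$reason, recs$reason))
  }
})

test_that("the evaluation suite ranks a noiseless backend above noisy ones", {
  sim <- generate_cohort(generator_config(n_patients = 200, seed = 41))
  co <- build_cohort(sim$orders, sim$encounters, sim$notes, sim$demographics)
  silver <- derive_silver_labels(co$switches)
  notes <- sim$notes[sim$notes$note_id %in% silver$note_id, ]
  backends <- list(
    reference = reference_backend(),
    mid = noisy_backend(list(new_tnfi = .3, last_tnfi = .3, reason = .3),
      seed = 2, id = "mid"
    )
  )
  records <- lapply(backends, function(b) run_extraction(notes, b))
  report <- evaluate_suite(records,
    silver = silver, gold = sim$gold,
    baseline_id = "reference"
  )
  mw <- report$win_matrix$mean_win
  expect_gt(
    mw$mean_win_rate[mw$model == "reference"],
    mw$mean_win_rate[mw$model == "mid"]
  )
  ref_rows <- report$eval_results[report$eval_results$backend_id == "reference", ]
  expect_true(all(ref_rows$micro_f1 == 1))
  expect_equal(report$concordance$reference$mean, 100)
  expect_lt(report$concordance$mid$mean, 100)
  expect_error(evaluate_suite(list()), "non-empty")

  # report bundle round-trips to disk
  dir <- withr::local_tempdir()
  paths <- write_eval_report(report, dir)
  expect_true(all(file.exists(paths)))
  loaded <- jsonlite::read_json(paths[["json"]])
  expect_equal(loaded$baseline_id, "reference")
})
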