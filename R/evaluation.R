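# Evaluation framework: silver/gold labels, micro-F1 under null policies,
# pairwise win/loss/tie rates, and concordance.

#' Derive silver-standard labels from switch events
#'
#' For the note attached to each switch's destination encounter, the
#' structured orders themselves provide proxy truth for the drug fields:
#' `last_tnfi` is the switch's source drug and `new_tnfi` its destination
#' drug. Reasons are never silver-labeled (structured orders carry no
#' rationale), so silver label sets have drug fields only.
#'
#' @param switches Switch-event tibble from [build_cohort()] (columns
#'   `note_id`, `from_drug`, `to_drug`).
#' @return Tibble `note_id`, `last_tnfi`, `new_tnfi`.
#' @export
derive_silver_labels <- function(switches) {
  stopifnot(all(c("note_id", "from_drug", "to_drug") %in% names(switches)))
  labeled <- switches[!is.na(switches$note_id), , drop = FALSE]
  if (anyDuplicated(labeled$note_id)) {
    stop(
      "a note is linked to multiple switch events; cohort invariants violated",
      call. = FALSE
    )
  }
  tibble::tibble(
    note_id = labeled$note_id,
    last_tnfi = labeled$from_drug,
    new_tnfi = labeled$to_drug
  )
}

#' Patient-level validation/test split
#'
#' Seeded uniform partition of notes at the patient level (all of a
#' patient's notes land on one side, avoiding leakage).
#' `round(fraction * n_patients)` patients form the validation side.
#'
#' @param note_ids Character vector of note ids.
#' @param patient_ids Parallel vector of owning patient ids.
#' @param fraction Validation fraction (0 < fraction < 1).
#' @param seed Integer seed.
#' @return List with `validation` and `test` note-id vectors (disjoint,
#'   exhaustive).
#' @export
split_validation_test <- function(note_ids, patient_ids, fraction = 0.05,
                                  seed = 1L) {
  stopifnot(length(note_ids) == length(patient_ids))
  if (!(fraction > 0 && fraction < 1)) {
    stop("fraction must be strictly between 0 and 1", call. = FALSE)
  }
  patients <- sort(unique(as.character(patient_ids)))
  n_val <- round(fraction * length(patients))
  if (n_val < 1) {
    stop(
      "too few patients (", length(patients), ") for a non-empty validation ",
      "side at fraction ", fraction,
      call. = FALSE
    )
  }
  val_patients <- with_local_seed(seed, sample(patients, n_val))
  val <- note_ids[patient_ids %in% val_patients]
  list(validation = val, test = setdiff(note_ids, val))
}

#' Micro-averaged F1 for one extraction field
#'
#' Scores predictions against a label set by pooling true positives, false
#' positives and false negatives across the substantive (non-`na`) classes:
#' a prediction of `na` is the absence of a positive prediction (it earns
#' no credit and costs recall when the label is substantive), and an `na`
#' label means there is nothing to find (a substantive prediction there is
#' a false positive). Under the `null_dropped` policy, notes whose record
#' reports reason `na` — the evaluated backend's own judgement that the
#' note contains no switching information — are excluded before scoring.
#'
#' @param records Extraction records (one backend).
#' @param labels Label tibble with `note_id` and the field column; the
#'   labeled notes define the evaluation set.
#' @param field One of `new_tnfi`, `last_tnfi`, `reason`.
#' @param null_policy `"all_values"` or `"null_dropped"`.
#' @return One-row tibble: `backend_id`, `field`, `null_policy`,
#'   `micro_f1`, `n_evaluated`. `micro_f1` is `NA` when nothing is
#'   evaluable.
#' @export
micro_f1 <- function(records, labels, field,
                     null_policy = c("all_values", "null_dropped")) {
  null_policy <- match.arg(null_policy)
  if (!field %in% names(labels)) {
    stop("field '", field, "' is not labeled in this label set", call. = FALSE)
  }
  stopifnot(field %in% names(records))
  rec_cols <- unique(c("note_id", field, "reason"))
  df <- dplyr::inner_join(
    labels[, c("note_id", field)],
    records[, rec_cols],
    by = "note_id", suffix = c("_gold", "_pred")
  )
  gold <- df[[paste0(field, "_gold")]]
  pred <- df[[paste0(field, "_pred")]]
  # the evaluated backend's own na-reason outputs govern null-dropping
  self_reason <- if (field == "reason") df$reason_pred else df$reason
  backend_id <- if (nrow(records) > 0) records$backend_id[1] else NA_character_
  if (null_policy == "null_dropped") {
    keep <- self_reason != "na"
    gold <- gold[keep]
    pred <- pred[keep]
  }
  n_eval <- length(gold)
  if (n_eval == 0) {
    return(tibble::tibble(
      backend_id = backend_id, field = field, null_policy = null_policy,
      micro_f1 = NA_real_, n_evaluated = 0L
    ))
  }
  gold_pos <- gold != "na"
  pred_pos <- pred != "na"
  tp <- sum(gold_pos & pred_pos & gold == pred)
  fp <- sum(pred_pos & (!gold_pos | gold != pred))
  fn <- sum(gold_pos & (!pred_pos | gold != pred))
  f1 <- if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  tibble::tibble(
    backend_id = backend_id, field = field, null_policy = null_policy,
    micro_f1 = f1, n_evaluated = as.integer(n_eval)
  )
}

pop_sd <- function(x) {
  # population SD (n divisor), matching small reported spreads
  if (length(x) == 0) {
    return(NA_real_)
  }
  sqrt(mean((x - mean(x))^2))
}

#' Pairwise win/loss/tie rates across extractor backends
#'
#' For each ordered model pair (A, B): the win rate is the fraction of
#' items where A is correct and B is not, the loss rate the reverse, and a
#' tie is both-correct or both-incorrect, so win + loss + tie = 1 and the
#' matrix is antisymmetric under pair reversal. Each model's mean win rate
#' averages its win rate over all opponents, with the population SD across
#' opponents.
#'
#' @param correct Logical matrix (items x models) of per-item correctness,
#'   with model names as column names; all models judged on the same items
#'   in the same order.
#' @return Object of class `win_rate_matrix`: list with `pairs` (tibble
#'   `model_a`, `model_b`, `win`, `loss`, `tie`), `mean_win` (tibble
#'   `model`, `mean_win_rate`, `sd_win_rate`, `mean_tie_rate`,
#'   `sd_tie_rate`), and `models`.
#' @export
pairwise_win_rates <- function(correct) {
  if (is.data.frame(correct)) correct <- as.matrix(correct)
  stopifnot(is.matrix(correct), is.logical(correct))
  models <- colnames(correct)
  if (is.null(models) || length(models) < 2) {
    stop("need a named logical matrix with at least 2 model columns",
      call. = FALSE
    )
  }
  if (anyNA(correct)) {
    stop("correctness matrix must not contain NA", call. = FALSE)
  }
  grid <- expand.grid(
    model_a = models, model_b = models,
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
  )
  grid <- grid[grid$model_a != grid$model_b, , drop = FALSE]
  win <- mapply(function(a, b) mean(correct[, a] & !correct[, b]),
    grid$model_a, grid$model_b
  )
  loss <- mapply(function(a, b) mean(!correct[, a] & correct[, b]),
    grid$model_a, grid$model_b
  )
  pairs <- tibble::tibble(
    model_a = grid$model_a, model_b = grid$model_b,
    win = unname(win), loss = unname(loss), tie = 1 - unname(win) - unname(loss)
  )
  mean_win <- dplyr::bind_rows(lapply(models, function(m) {
    mine <- pairs[pairs$model_a == m, , drop = FALSE]
    tibble::tibble(
      model = m,
      mean_win_rate = mean(mine$win),
      sd_win_rate = pop_sd(mine$win),
      mean_tie_rate = mean(mine$tie),
      sd_tie_rate = pop_sd(mine$tie)
    )
  }))
  structure(
    list(pairs = pairs, mean_win = mean_win, models = models),
    class = "win_rate_matrix"
  )
}

#' @export
print.win_rate_matrix <- function(x, ...) {
  cat("<win_rate_matrix>", length(x$models), "models\n")
  print(x$mean_win)
  invisible(x)
}

#' Win-minus-loss rates against a designated baseline
#'
#' For each model M other than the baseline, `win(M, baseline) -
#' loss(M, baseline)`; positive values mean M is correct more often than
#' the baseline on items where they disagree. The baseline's own value is 0.
#'
#' @param matrix A `win_rate_matrix` from [pairwise_win_rates()].
#' @param baseline_id Model id of the baseline.
#' @return Tibble `model`, `win_minus_loss`.
#' @export
win_minus_loss_vs_baseline <- function(matrix, baseline_id) {
  stopifnot(inherits(matrix, "win_rate_matrix"))
  if (!baseline_id %in% matrix$models) {
    stop("unknown baseline: ", baseline_id, call. = FALSE)
  }
  rows <- lapply(matrix$models, function(m) {
    if (m == baseline_id) {
      return(tibble::tibble(model = m, win_minus_loss = 0))
    }
    p <- matrix$pairs[
      matrix$pairs$model_a == m & matrix$pairs$model_b == baseline_id, ,
      drop = FALSE
    ]
    tibble::tibble(model = m, win_minus_loss = p$win - p$loss)
  })
  dplyr::bind_rows(rows)
}

#' Concordance between two backends
#'
#' Per field, the fraction of notes on which the two backends emit equal
#' normalized values (`na` agreeing with `na` counts as agreement),
#' irrespective of any truth; plus the mean and population SD across
#' fields.
#'
#' @param records_a,records_b Extraction record tibbles covering the same
#'   notes.
#' @param fields Fields to compare.
#' @return List with `per_field` (tibble `field`, `rate`), `mean`
#'   (percent), `sd` (percent), `n_notes`.
#' @export
concordance <- function(records_a, records_b,
                        fields = c("new_tnfi", "last_tnfi", "reason")) {
  if (!setequal(records_a$note_id, records_b$note_id) ||
    length(records_a$note_id) == 0) {
    stop("record sets must cover the same non-empty set of notes", call. = FALSE)
  }
  df <- dplyr::inner_join(
    records_a[, c("note_id", fields)],
    records_b[, c("note_id", fields)],
    by = "note_id", suffix = c("_a", "_b")
  )
  rates <- vapply(fields, function(f) {
    mean(df[[paste0(f, "_a")]] == df[[paste0(f, "_b")]])
  }, numeric(1))
  list(
    per_field = tibble::tibble(field = fields, rate = unname(rates)),
    mean = 100 * mean(rates),
    sd = 100 * pop_sd(rates),
    n_notes = nrow(df)
  )
}

#' Full evaluation suite over several backends
#'
#' Computes, for every backend: micro-F1 against silver labels (drug
#' fields) and gold labels (all labeled fields) under both null policies;
#' a pairwise win/loss/tie matrix with mean win rates (correctness judged
#' per note-field against gold labels where available, silver drug labels
#' otherwise, pooled across fields); win-minus-loss versus the baseline;
#' and each backend's concordance with the baseline. The truth source per
#' note-field is recorded in the report.
#'
#' @param records_list Named list of extraction record tibbles (names are
#'   backend ids); all must cover a common set of notes.
#' @param silver Silver label tibble ([derive_silver_labels()]), or `NULL`.
#' @param gold Gold label tibble (`note_id`, `last_tnfi`, `new_tnfi`,
#'   `reason`), or `NULL`.
#' @param baseline_id Backend id used as the comparison baseline.
#' @return Object of class `tnfi_eval_report`: list with `eval_results`,
#'   `win_matrix`, `win_minus_loss`, `concordance`, `truth_source`,
#'   `baseline_id`.
#' @export
evaluate_suite <- function(records_list, silver = NULL, gold = NULL,
                           baseline_id = names(records_list)[1]) {
  if (!is.list(records_list) || length(records_list) == 0 ||
    is.null(names(records_list)) || any(!nzchar(names(records_list)))) {
    stop("records_list must be a non-empty named list", call. = FALSE)
  }
  if (is.null(silver) && is.null(gold)) {
    stop("at least one of silver or gold labels is required", call. = FALSE)
  }
  if (!baseline_id %in% names(records_list)) {
    stop("baseline_id must name an element of records_list", call. = FALSE)
  }
  common <- Reduce(intersect, lapply(records_list, function(r) r$note_id))
  if (length(common) == 0) {
    stop("backends share no notes", call. = FALSE)
  }
  records_list <- lapply(records_list, function(r) {
    r <- r[r$note_id %in% common, , drop = FALSE]
    r[order(r$note_id), , drop = FALSE]
  })

  eval_results <- list()
  for (bid in names(records_list)) {
    recs <- records_list[[bid]]
    for (policy in c("all_values", "null_dropped")) {
      if (!is.null(silver)) {
        for (f in intersect(c("last_tnfi", "new_tnfi"), names(silver))) {
          row <- micro_f1(recs, silver, f, policy)
          row$label_source <- "silver"
          eval_results[[length(eval_results) + 1]] <- row
        }
      }
      if (!is.null(gold)) {
        for (f in intersect(c("last_tnfi", "new_tnfi", "reason"), names(gold))) {
          row <- micro_f1(recs, gold, f, policy)
          row$label_source <- "gold"
          eval_results[[length(eval_results) + 1]] <- row
        }
      }
    }
  }
  eval_results <- dplyr::bind_rows(eval_results)

  # truth per note-field: gold where labeled, else silver drug labels
  truth <- list()
  for (f in c("last_tnfi", "new_tnfi", "reason")) {
    src <- NULL
    if (!is.null(gold) && f %in% names(gold)) {
      src <- tibble::tibble(
        note_id = gold$note_id, field = f, truth = gold[[f]], source = "gold"
      )
    } else if (!is.null(silver) && f %in% names(silver)) {
      src <- tibble::tibble(
        note_id = silver$note_id, field = f, truth = silver[[f]], source = "silver"
      )
    }
    if (!is.null(src)) truth[[f]] <- src[src$note_id %in% common, , drop = FALSE]
  }
  truth <- dplyr::bind_rows(truth)
  if (nrow(truth) == 0) {
    stop("no labeled note-fields overlap the shared note set", call. = FALSE)
  }
  correct <- vapply(names(records_list), function(bid) {
    recs <- records_list[[bid]]
    vapply(seq_len(nrow(truth)), function(i) {
      pred <- recs[[truth$field[i]]][match(truth$note_id[i], recs$note_id)]
      identical(pred, truth$truth[i])
    }, logical(1))
  }, logical(nrow(truth)))
  win_matrix <- if (length(records_list) >= 2) {
    pairwise_win_rates(correct)
  } else {
    NULL
  }
  wml <- if (!is.null(win_matrix)) {
    win_minus_loss_vs_baseline(win_matrix, baseline_id)
  } else {
    NULL
  }
  conc <- lapply(names(records_list), function(bid) {
    concordance(records_list[[bid]], records_list[[baseline_id]])
  })
  names(conc) <- names(records_list)

  structure(
    list(
      eval_results = eval_results,
      win_matrix = win_matrix,
      win_minus_loss = wml,
      concordance = conc,
      truth_source = truth[, c("note_id", "field", "source")],
      baseline_id = baseline_id
    ),
    class = "tnfi_eval_report"
  )
}

#' @export
print.tnfi_eval_report <- function(x, ...) {
  cat("<tnfi_eval_report> baseline:", x$baseline_id, "\n")
  print(x$eval_results)
  if (!is.null(x$win_matrix)) print(x$win_matrix$mean_win)
  invisible(x)
}

#' Write an evaluation report bundle to disk
#'
#' Emits a machine-readable JSON bundle and a delimited summary of the
#' micro-F1 results.
#'
#' @param report A `tnfi_eval_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_eval_report <- function(report, dir) {
  stopifnot(inherits(report, "tnfi_eval_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  json_path <- file.path(dir, "eval_report.json")
  csv_path <- file.path(dir, "eval_results.csv")
  payload <- list(
    baseline_id = report$baseline_id,
    eval_results = report$eval_results,
    win_pairs = if (!is.null(report$win_matrix)) report$win_matrix$pairs,
    mean_win = if (!is.null(report$win_matrix)) report$win_matrix$mean_win,
    win_minus_loss = report$win_minus_loss,
    concordance = lapply(report$concordance, function(cc) {
      list(per_field = cc$per_field, mean = cc$mean, sd = cc$sd, n_notes = cc$n_notes)
    })
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.csv(report$eval_results, csv_path, row.names = FALSE)
  invisible(c(json = json_path, csv = csv_path))
}
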