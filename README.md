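# tnfiswitch

Tools for profiling **switching between tumor necrosis factor inhibitors
(TNFi)** in longitudinal electronic health record (EHR) data, and for
evaluating structured extraction of *why* patients switched from the
clinical notes that accompany their medication orders.

TNFi (adalimumab, etanercept, certolizumab, golimumab, infliximab and its
biosimilars) are biologic therapies for autoimmune disease. Patients
frequently move between agents in the class — because of lost efficacy,
anti-drug antibodies, adverse events, cost, or preference — but the reason
is usually recorded only in free-text notes, not in structured orders.
`tnfiswitch` is aimed at pharmacoepidemiologists and clinical-NLP
researchers who want to (a) build switch trajectories from order tables
with a reproducible attrition flow, and (b) benchmark note-level extractors
(for example LLM backends) for the stopped drug, started drug, and
switching reason, without access to protected patient data: a seeded
synthetic-EHR generator with planted ground truth stands in for the real
thing.

## What it computes

* **Cohort construction** — free-text drug names are normalized to six
  canonical categories (five generics, with infliximab split into
  biooriginator and biosimilar); orders are deduplicated on
  (patient, date, drug); same-date multi-TNFi encounters are excluded;
  each encounter keeps its last clinical note; a *switch* is a change in
  canonical TNFi between two consecutive TNFi-order encounters; patients
  without an encounter ≥ 183 days after their last order (and no switch)
  are lost to follow-up. Every stage is logged in an attrition table with
  the invariant `out = in − removed`.
* **Micro-F1 under two null policies** — predictions are scored against
  silver labels (drug fields read off the structured orders) or gold
  annotations, pooling counts over the substantive classes:

  `microF1 = 2·TP / (2·TP + FP + FN)`

  A prediction of `na` is the absence of a positive prediction. Under
  `all_values` every labeled note counts; under `null_dropped`, notes the
  evaluated backend itself judged reason-free (`reason = na`) are excluded
  first.
* **Pairwise win rates** — for models A and B, `win(A,B)` is the fraction
  of items A gets right while B does not; both-right or both-wrong is a
  tie, so `win + loss + tie = 1`. Mean win rate averages over opponents;
  `win − loss` against a designated baseline summarizes head-to-head
  superiority.
* **Concordance** — the fraction of notes on which two backends emit
  identical normalized values, per field, with mean and SD across fields.
* **Trajectories** — per-patient drug sequences, Sankey-style flow tables
  with exact flow conservation, and reason distributions by switch ordinal
  (first, second, third-plus).

## Worked example

```r
library(tnfiswitch)

sim    <- generate_cohort(generator_config(n_patients = 500, seed = 42))
cohort <- build_cohort(sim$orders, sim$encounters, sim$notes, sim$demographics)
cohort_status_summary(cohort$statuses)
#> # A tibble: 3 × 3
#>   status                 n   pct
#> 1 switcher              87  17.5
#> 2 no_switch_followed   305  61.2
#> 3 lost_to_followup     106  21.3
```

17.5% of classified patients switched TNFi at least once, 61.2% stayed on
one agent with adequate follow-up, and 21.3% were lost to follow-up —
tracking the generator's configured rates. Now benchmark a perfect
rule-based extractor against a deliberately degraded one on the switch
notes:

```r
silver  <- derive_silver_labels(cohort$switches)
notes   <- sim$notes[sim$notes$note_id %in% silver$note_id, ]
records <- list(
  reference = run_extraction(notes, reference_backend()),
  degraded  = run_extraction(notes, noisy_backend(
    list(new_tnfi = 0.3, last_tnfi = 0.3, reason = 0.3), seed = 7, id = "degraded"))
)
report <- evaluate_suite(records, silver = silver,
                         gold = sim$gold[sim$gold$note_id %in% silver$note_id, ],
                         baseline_id = "reference")

subset(as.data.frame(report$eval_results),
       label_source == "gold" & null_policy == "all_values")
#>    backend_id     field null_policy  micro_f1 n_evaluated label_source
#> 3   reference last_tnfi  all_values 1.0000000         124         gold
#> 4   reference  new_tnfi  all_values 1.0000000         124         gold
#> 5   reference    reason  all_values 1.0000000         124         gold
#> 13   degraded last_tnfi  all_values 0.7419355         124         gold
#> 14   degraded  new_tnfi  all_values 0.7096774         124         gold
#> 15   degraded    reason  all_values 0.6500000         124         gold

report$win_matrix$mean_win
#> # A tibble: 2 × 5
#>   model     mean_win_rate sd_win_rate mean_tie_rate sd_tie_rate
#> 1 reference         0.269           0         0.731           0
#> 2 degraded          0               0         0.731           0
```

The reference backend recovers every planted field (micro-F1 = 1.0 on all
124 gold-labeled switch notes); corrupting each field with probability 0.3
drops micro-F1 to 0.65–0.74, gives the reference a 26.9% win rate over the
degraded model (the degraded model never beats it, so its win rate is 0),
and leaves the two backends concordant on 73.1% of values (SD 1.5% across
fields).

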