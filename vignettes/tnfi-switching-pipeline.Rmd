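---
title: "Modeling TNFi switching trajectories and evaluating note-based reason extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling TNFi switching trajectories and evaluating note-based reason extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its own methods: the cohort
model and its assumptions, the extraction and evaluation machinery, the
synthetic-data generator that stands in for protected EHR data, and the
design decisions taken where more than one reasonable choice existed.

## The cohort model

The unit of analysis is a patient's timeline of TNFi medication orders.
Six canonical drug categories are used throughout: adalimumab,
etanercept, certolizumab, golimumab, and infliximab split into
biooriginator and biosimilar products. The split matters because a move
from originator infliximab to a biosimilar (or back) is a genuine
treatment switch — often insurance-driven — and the two are therefore
distinct categories, while dose and formulation changes within a category
are deliberately invisible: `normalize_drug_name()` matches lexicon
patterns as case-insensitive substrings of the raw order string, so
`"HUMIRA 40 mg/0.8 mL syringe"` and `"adalimumab prefilled pen"` both map
to adalimumab. The longest matching pattern wins, which is what lets the
suffixed biosimilar names (`infliximab-dyyb`, `inflectra`, ...) beat the
bare substring `infliximab` they contain. The bundled lexicon is
replaceable data, not method: any file with columns
`pattern,canonical,name_kind` can be supplied, subject to the closed
six-category set and pattern uniqueness after case-folding.

`build_cohort()` runs a fixed attrition flow: normalize names (dropping
non-TNFi orders), drop patients absent from the demographics table,
deduplicate, drop orders whose encounter has no clinical note, drop
same-date multi-TNFi encounters, attach the last note per encounter,
detect switches, classify follow-up. Each stage logs
`(in, removed, out)` and the log must chain exactly — `out` of one stage
is `in` of the next — which turns bookkeeping bugs into hard failures
rather than silently shifted denominators.

Several definitional choices deserve justification:

* **A duplicate is a repeated (patient, order date, canonical drug)
  triple.** Since canonicalization already discards dose and modality,
  two same-day orders of the same drug carry no additional signal.
  The retained row is chosen by a full deterministic sort, so
  deduplication is invariant to input row order.
* **A switch is a change in canonical drug between two *consecutive
  TNFi-order encounters*.** Encounters without TNFi orders may fall in
  between; they do not interrupt the medication timeline. Same-date
  orders of two different TNFi are excluded outright (never counted as a
  switch) because their ordering is undefined.
* **Follow-up horizon: 183 days**, the nearest whole-day count to half of
  365.25. A non-switching patient with no encounter at least 183 days
  after their *last* TNFi order is lost to follow-up: one cannot tell
  whether they stayed on the drug or switched elsewhere. The rule applies
  only to non-switchers — an observed switch is evidence enough,
  regardless of what happened afterwards — and is anchored at the last
  order because that is the point after which continuation becomes
  unobservable. Switch status is therefore assigned before the follow-up
  classification, never the other way around.
* **Note-timestamp ties** are broken by the lexicographically largest
  note id. Any fixed rule would do; this one needs no extra state.

## The demographic table

`tabulate_demographics()` produces a stratified (no-switch / switch /
total) summary. Continuous variables are reported as mean and SD over
non-missing values; categorical variables as counts with percentages of
the non-missing stratum, the convention of standard table-one tooling.
Number-of-switches bands {0, 1, 2, >2} are the one deliberate exception:
their percentages are taken against the *full* stratum size, with
patients whose band is indeterminate surfacing in the missing count
rather than inflating a band — the bands define the strata, so their
shares should partition the stratum itself. Diagnosis categories with
fewer than `min_cell = 10` switchers are pooled into "Other", a
de-identification-style small-cell rule. Group comparisons use Pearson
chi-square tests without continuity correction for categorical variables
and Welch two-sided t-tests for continuous ones; degenerate inputs
(zero-variance strata, single-category tables) are reported as
not-applicable instead of erroring.

## Extraction: prompts, parsing, backends

The extraction contract is a fixed JSON schema with four keys —
`new_TNFi`, `last_TNFi`, `Reason for Switching`,
`full_reason_last_TNFi_stopped` — and a closed seven-value reason
taxonomy: adverse event, drug resistance (defined by documented anti-drug
antibodies), insurance/cost, lack of efficacy, patient preference, other,
and `na` for "no reason documented". Four zero-shot prompt variants share
one instruction body and differ only in which closed value lists they
enumerate (none, the six drug categories, the seven reasons, or both).
The clinical note is appended after the instruction block; an optional
backend tag wrapper adds model-specific template markers without touching
the body.

`parse_extraction_output()` is total: it scans the response for the first
balanced JSON object (string-aware, fence-stripping), folds key names,
routes drug answers through the lexicon and reason answers through a
punctuation-insensitive lookup, and degrades every failure mode to a
flagged record rather than an exception. Two normalization decisions are
the package's own, since upstream behavior for malformed output is
undefined anywhere else: free-text reasons that match no category become
`other` (with the text preserved), because `na` is reserved for the
positive assertion that no reason is documented; and unrecognizable drug
answers become `na` rather than guesses.

Backends implement one function, prompt text in, response text out.
Two deterministic backends ship with the package:

* `reference_backend()` — rule-based extraction co-designed with the
  synthetic note templates (below). On noise-free generated notes it is
  exact by construction, which is what makes end-to-end pipeline tests
  meaningful: any deviation from perfect recovery is a pipeline defect,
  not extractor noise.
* `noisy_backend(error_rates, seed)` — wraps the reference rules and,
  independently per field with the configured probability, replaces the
  value with a uniform draw over the field's six substantive values (the
  six drugs, or the six non-`na` reasons). The draw may collide with the
  truth, so expected accuracy on a note whose true value is substantive
  is `1 − e + e/6`: at `e = 0.3`, 0.75. This collision model was chosen
  over draw-from-the-others because it mimics a model that guesses over
  the label space rather than one that is adversarially wrong, and it
  makes accuracy analytically predictable for parameter-recovery tests.
  Corruption seeds are derived per note from the backend seed and the
  note text, so records do not depend on evaluation order.

`run_extraction()` caches raw responses keyed by backend, variant and a
prompt digest; a warm rerun is call-free and bit-identical. Caching is
not an optimization nicety — it is what makes extraction with expensive
or flaky external backends resumable and idempotent. External chat-API
adapters can implement the same contract but are intentionally outside
the test surface; everything here is validated with the deterministic
backends.

## Evaluation

Silver labels come from the structured orders themselves: for the note
attached to a switch's destination encounter, the stopped and started
drug are known without any annotation. Reasons have no silver source.
Gold labels are human-annotation-shaped files with all three fields.

Micro-F1 pools TP/FP/FN across the substantive classes. `na` is not a
class: predicting it earns nothing and costs recall when the label is
substantive; a substantive prediction against an `na` label is a false
positive. The `null_dropped` policy removes notes that the *evaluated
backend itself* marked reason-free before scoring — self-filtering, which
mirrors how note-level extraction scores are reported once
apparently-information-free notes are excluded, and which is why the
policy can either raise or lower a score (no monotonicity is asserted,
only that it never evaluates more notes).

Pairwise win rates, win-minus-loss against a baseline, and concordance
are defined in the README; two conventions matter. Correctness for win
rates is judged per note-field against gold labels where a field is
gold-labeled and silver labels otherwise, and the truth source per
note-field is recorded in the report — making the different comparison
modes (against structured data, against annotation, against a baseline
model's outputs) explicit rather than implicit. Spread statistics (SD of
win rate across opponents, SD of concordance across fields) use the
population (n-divisor) form, since the opponents or fields at hand are
the entire population of interest, not a sample. The validation/test
split is done at the patient level so that no patient's notes straddle
the split.

## The synthetic-data generator

`generate_cohort()` emulates the statistical structure the analysis
assumes, not clinical prose. Its defaults are the study conditions:

| parameter | default | anchor |
|---|---|---|
| first-drug shares | .409 / .263 / .241 / .033 / .031 / .023 | first documented TNFi distribution |
| switcher fraction | 0.1825 | share of patients with a documented switch |
| switches per switcher | 70.1% one, 19.8% two, 7.1% three-plus | switch-count bands |
| reason shares | .569 / .135 / .108 / .082, remainder split | documented-reason distribution |
| reason documented | 0.41 | share of switch notes verbalizing a reason |
| lost to follow-up | 0.206 | cohort attrition share |
| duplicate orders | 0.27 | duplicate share of raw orders |
| multi-TNFi encounters | 0.034 | share of same-date multi-TNFi orders |
| missing notes | 0.087 | share of orders without notes |

The three-plus tail is split 3:1 between three and four switches, and the
loss-to-follow-up marginal is converted to a conditional rate among
non-switchers; both are unconstrained by the anchors and were fixed once
at plausible values. Patient status is drawn directly at the patient
level (a Bernoulli switcher draw, then a conditional lost-to-follow-up
draw) rather than emerging from a per-encounter switch hazard, because
every anchored quantity is a patient-level proportion; the per-encounter
formulation would add a latent parameter with nothing to pin it down.
Encounter gaps are `14 + Gamma(shape 2, scale 45)` days (median gap
roughly ten weeks, matching injection/infusion schedules), and each
patient receives `n_switches + 1 + Poisson(6)` order encounters, so
timelines span multiple years at desk scale.

Corruptions are injected as *extra rows whose removal provably restores
the planted timeline*: duplicates repeat a core (patient, date, drug)
triple; multi-TNFi encounters appear on new dates strictly between core
encounters and carry two distinct drugs (the whole encounter is dropped);
note-less orders carry the same drug as the preceding core encounter (so
even if retained they could not create a switch) and are dropped at the
note stage. This is what makes exact end-to-end recovery a fair
invariant: the pipeline must undo precisely the planted damage, no more,
no less. Follow-up status is realized through the encounter schedule — a
drug-free encounter at last order + 183+ days for followed patients, only
early encounters for lost ones.

Notes are template-based: distractor sentences (vitals, labs, an
unrelated medication) plus a single plan sentence, with switch notes
stating the stopped and started drug in randomly chosen spellings and,
with probability `p_reason_documented`, a reason phrase drawn from a bank
of at least three paraphrases per category (drug resistance always
phrased via anti-drug antibodies). The reference extractor's rules are
written against exactly this template grammar. The co-design is a
feature, not a confession: the acceptance surface is the pipeline and the
metrics, and an exact oracle is only possible when generator and
reference extractor agree on the note language. What passing tests
consequently do **not** show is robustness to real clinical prose —
negation, hedging, history-vs-plan confusion, OCR noise — or anything
about any particular LLM's extraction quality. They show that the
cohort logic, the metrics, and the evaluation harness are correct, so
that when a real backend is plugged in, its scores measure the backend
and not the plumbing.

## Numerical and degenerate-input choices

All randomness flows from a single integer seed per generator or backend;
internal RNG use saves and restores the caller's `.Random.seed`, so
library calls never perturb user scripts. Dates are whole calendar days;
follow-up years use the 365.25-day year. Rate identities
(`win + loss + tie = 1`) hold exactly, not to tolerance, because ties are
computed as the complement. Empty inputs return empty, correctly-typed
results (empty cohort with a zero attrition log, empty flow table, empty
label set); undefined statistics (micro-F1 with nothing evaluable, tests
on zero-variance strata) are reported as not-applicable values rather
than raised as errors, since both arise routinely in small strata.

Desk-scale problem sizes were chosen once for the test suite: exhaustive
switch-detection checks enumerate all 363 drug sequences of length ≤ 5
over three categories; metric-oracle equivalence runs 200 random
instances of ≤ 50 notes; end-to-end recovery and parameter recovery use
2000-patient and 2000-note cohorts, where three binomial standard errors
separate configured rates from estimation noise comfortably.

## Known limitations

The generator does not model dose changes, discontinuation without
replacement, non-TNFi therapies, disease-specific switching patterns, or
informative missingness; the drug-name lexicon ships a core synonym set
rather than an exhaustive registry-derived list (it is user-replaceable);
and the evaluation framework deliberately omits significance testing and
bootstrap intervals for score differences. Notes are English-language
templates; nothing here addresses de-identification.
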