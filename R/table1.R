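# Stratified demographic tabulation (switch vs no-switch) and the
# accompanying between-group tests.

switcher_flag <- function(patients) {
  if ("status" %in% names(patients)) {
    keep <- patients$status %in% c("switcher", "no_switch_followed")
    patients <- patients[keep, , drop = FALSE]
    flag <- patients$status == "switcher"
  } else if ("n_switches" %in% names(patients)) {
    flag <- !is.na(patients$n_switches) & patients$n_switches >= 1
  } else {
    stop("patients table needs a status or n_switches column", call. = FALSE)
  }
  list(patients = patients, switch = flag)
}

switch_bands <- function(n_switches) {
  cut(n_switches,
    breaks = c(-0.5, 0.5, 1.5, 2.5, Inf),
    labels = c("0", "1", "2", ">2")
  )
}

summarise_continuous <- function(variable, x, switch) {
  strata <- list(total = rep(TRUE, length(x)), no_switch = !switch, switch = switch)
  dplyr::bind_rows(lapply(names(strata), function(s) {
    v <- x[strata[[s]]]
    tibble::tibble(
      variable = variable, level = NA_character_, stratum = s,
      n = sum(!is.na(v)), pct = NA_real_,
      mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE),
      n_missing = sum(is.na(v))
    )
  }))
}

summarise_categorical <- function(variable, x, switch, denom = c("nonmissing", "stratum")) {
  denom <- match.arg(denom)
  x <- as.character(x)
  levels_seen <- unique(x[!is.na(x)])
  # order by descending total count for a Table-1-like layout
  levels_seen <- names(sort(table(factor(x, levels = levels_seen)), decreasing = TRUE))
  if (variable == "n_switches_band") levels_seen <- intersect(c("0", "1", "2", ">2"), levels_seen)
  strata <- list(total = rep(TRUE, length(x)), no_switch = !switch, switch = switch)
  dplyr::bind_rows(lapply(names(strata), function(s) {
    v <- x[strata[[s]]]
    d <- if (denom == "stratum") length(v) else sum(!is.na(v))
    counts <- table(factor(v, levels = levels_seen))
    tibble::tibble(
      variable = variable, level = levels_seen, stratum = s,
      n = as.integer(counts),
      pct = if (d > 0) 100 * as.integer(counts) / d else NA_real_,
      mean = NA_real_, sd = NA_real_,
      n_missing = sum(is.na(v))
    )
  }))
}

#' Tabulate cohort demographics stratified by switch status
#'
#' Produces a Table-1-style long summary with strata `total`, `no_switch`
#' and `switch`. Patients lost to follow-up (or excluded) are not part of
#' the table when a `status` column is present. Continuous variables
#' (`age`, `followup_years`) are reported as mean and SD over non-missing
#' values; categorical variables (`sex`, `race`, `first_tnfi`,
#' `diagnosis`) as counts and percentages of the non-missing stratum.
#' Number-of-switches bands \{0, 1, 2, >2\} are reported against the full
#' stratum size, so patients with an indeterminate switch count appear in
#' `n_missing` without inflating any band. Diagnosis categories with fewer
#' than `min_cell` switchers are consolidated into `"Other"`.
#'
#' @param patients Patient-level tibble; recognized columns: `status` or
#'   `n_switches` (defining the strata), `age`, `followup_years`, `sex`,
#'   `race`, `first_tnfi`, `diagnosis`. Only columns present are tabulated.
#' @param min_cell Minimum switcher count for a diagnosis category to stand
#'   alone (small-cell consolidation threshold).
#' @return Long tibble: `variable`, `level`, `stratum`, `n`, `pct`,
#'   `mean`, `sd`, `n_missing`.
#' @export
tabulate_demographics <- function(patients, min_cell = 10L) {
  sw <- switcher_flag(patients)
  patients <- sw$patients
  switch <- sw$switch
  out <- list()
  if ("age" %in% names(patients)) {
    out$age <- summarise_continuous("age", patients$age, switch)
  }
  if ("followup_years" %in% names(patients)) {
    out$fy <- summarise_continuous("followup_years", patients$followup_years, switch)
  }
  for (v in c("sex", "race", "first_tnfi")) {
    if (v %in% names(patients)) {
      out[[v]] <- summarise_categorical(v, patients[[v]], switch)
    }
  }
  if ("diagnosis" %in% names(patients)) {
    dx <- as.character(patients$diagnosis)
    counts_sw <- table(dx[switch & !is.na(dx)])
    small <- names(counts_sw)[counts_sw < min_cell]
    # categories absent among switchers are small cells too
    absent <- setdiff(unique(dx[!is.na(dx)]), names(counts_sw))
    small <- setdiff(union(small, absent), "Other")
    dx[dx %in% small] <- "Other"
    out$diagnosis <- summarise_categorical("diagnosis", dx, switch)
  }
  if ("n_switches" %in% names(patients)) {
    out$bands <- summarise_categorical(
      "n_switches_band", switch_bands(patients$n_switches), switch,
      denom = "stratum"
    )
  }
  if (length(out) == 0) {
    stop("no recognized demographic columns to tabulate", call. = FALSE)
  }
  dplyr::bind_rows(out)
}

#' Between-group tests for the demographic table
#'
#' Pearson chi-square tests (without continuity correction) on the
#' switch-status-by-category contingency table for categorical variables,
#' and Welch two-sided two-sample t-tests for continuous variables. A
#' stratum with zero variance (or too few observations) for a continuous
#' variable yields a not-applicable row rather than an error.
#'
#' @param patients Patient-level tibble as for [tabulate_demographics()].
#' @param continuous Names of continuous columns to test.
#' @param categorical Names of categorical columns to test.
#' @return Tibble: `variable`, `test`, `statistic`, `p_value`, `note`.
#' @export
group_comparison_tests <- function(patients,
                                   continuous = intersect(
                                     c("age", "followup_years"), names(patients)
                                   ),
                                   categorical = intersect(
                                     c("sex", "race", "first_tnfi", "diagnosis"),
                                     names(patients)
                                   )) {
  sw <- switcher_flag(patients)
  patients <- sw$patients
  switch <- sw$switch
  if (sum(switch) == 0 || sum(!switch) == 0) {
    stop("both strata must be non-empty for group comparisons", call. = FALSE)
  }
  rows <- list()
  for (v in continuous) {
    x <- patients[[v]]
    a <- x[switch & !is.na(x)]
    b <- x[!switch & !is.na(x)]
    if (length(a) < 2 || length(b) < 2 ||
      (stats::var(a) == 0 && stats::var(b) == 0)) {
      rows[[v]] <- tibble::tibble(
        variable = v, test = "t", statistic = NA_real_, p_value = NA_real_,
        note = "not applicable (degenerate stratum)"
      )
    } else {
      tt <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
      rows[[v]] <- tibble::tibble(
        variable = v, test = "t",
        statistic = unname(tt$statistic), p_value = tt$p.value, note = NA_character_
      )
    }
  }
  for (v in categorical) {
    x <- as.character(patients[[v]])
    ok <- !is.na(x)
    tab <- table(ifelse(switch[ok], "switch", "no_switch"), x[ok])
    if (ncol(tab) < 2 || nrow(tab) < 2) {
      rows[[v]] <- tibble::tibble(
        variable = v, test = "chisq", statistic = NA_real_, p_value = NA_real_,
        note = "not applicable (single category)"
      )
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      rows[[v]] <- tibble::tibble(
        variable = v, test = "chisq",
        statistic = unname(ct$statistic), p_value = ct$p.value, note = NA_character_
      )
    }
  }
  dplyr::bind_rows(rows)
}
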