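# Independent brute-force recounts used as oracles for the evaluation
# metrics. These deliberately share no code with the package: plain loops
# over notes and model pairs.

oracle_micro_f1 <- function(gold, pred) {
  tp <- 0L
  fp <- 0L
  fn <- 0L
  for (i in seq_along(gold)) {
    g <- gold[i]
    p <- pred[i]
    if (p != "na") {
      if (g == p) tp <- tp + 1L else fp <- fp + 1L
    }
    if (g != "na" && g != p) fn <- fn + 1L
  }
  if (2 * tp + fp + fn == 0) {
    return(NA_real_)
  }
  2 * tp / (2 * tp + fp + fn)
}

oracle_pair_rates <- function(correct_a, correct_b) {
  win <- 0L
  loss <- 0L
  tie <- 0L
  for (i in seq_along(correct_a)) {
    if (correct_a[i] && !correct_b[i]) {
      win <- win + 1L
    } else if (!correct_a[i] && correct_b[i]) {
      loss <- loss + 1L
    } else {
      tie <- tie + 1L
    }
  }
  n <- length(correct_a)
  c(win = win / n, loss = loss / n, tie = tie / n)
}

oracle_concordance <- function(records_a, records_b, fields) {
  rates <- numeric(0)
  for (f in fields) {
    agree <- 0L
    for (i in seq_len(nrow(records_a))) {
      j <- which(records_b$note_id == records_a$note_id[i])
      if (identical(records_a[[f]][i], records_b[[f]][j])) agree <- agree + 1L
    }
    rates <- c(rates, agree / nrow(records_a))
  }
  m <- mean(rates)
  list(mean = 100 * m, sd = 100 * sqrt(mean((rates - m)^2)))
}

# adjacent-unequal-pair count: the definitional switch-count oracle
oracle_switch_count <- function(drug_seq) {
  n <- 0L
  for (i in seq_along(drug_seq)[-1]) {
    if (drug_seq[i] != drug_seq[i - 1]) n <- n + 1L
  }
  n
}
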