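# independent reference implementations used as oracles: one exam at a
# time, plain loops, no shared code with the vectorized engine

naive_top_fraction <- function(cohort, rate) {
  n <- nrow(cohort)
  k <- floor(rate * n + 0.5)
  remaining <- seq_len(n)
  chosen <- character(0)
  while (length(chosen) < min(k, n)) {
    best <- remaining[1]
    for (i in remaining) {
      if (cohort$ai_raw[i] > cohort$ai_raw[best] ||
          (cohort$ai_raw[i] == cohort$ai_raw[best] &&
           cohort$exam_id[i] < cohort$exam_id[best])) {
        best <- i
      }
    }
    chosen <- c(chosen, cohort$exam_id[best])
    remaining <- remaining[remaining != best]
  }
  chosen
}

naive_evaluate <- function(cohort, spec) {
  n <- nrow(cohort)
  n_consensus <- 0L; n_recall <- 0L; n_sdc <- 0L; n_ic <- 0L
  if (spec$mode %in% c("AI_AS_READER", "AI_STANDALONE")) {
    ai_set <- if (!is.null(spec$score_cutoff)) {
      cohort$exam_id[cohort$ai_score >= spec$score_cutoff]
    } else {
      naive_top_fraction(cohort, spec$rate)
    }
  }
  for (i in seq_len(n)) {
    pos1 <- cohort$r1_score[i] >= 2
    pos2 <- cohort$r2_score[i] >= 2
    if (spec$mode == "TRIAGE") {
      reading <- NA
      for (b in seq_len(nrow(spec$bands))) {
        if (cohort$ai_raw[i] > spec$bands$lower[b] &&
            cohort$ai_raw[i] <= spec$bands$upper[b]) {
          reading <- spec$bands$reading[b]
        }
      }
      selected <- if (reading == "DOUBLE") pos1 || pos2
        else if (reading == "SINGLE_R1") pos1 else FALSE
      recalled <- selected && cohort$recall[i]
    } else if (spec$mode == "AI_AS_READER") {
      selected <- pos1 || (cohort$exam_id[i] %in% ai_set)
      recalled <- selected && cohort$recall[i]
    } else {
      selected <- cohort$exam_id[i] %in% ai_set
      recalled <- selected
    }
    if (selected) n_consensus <- n_consensus + 1L
    if (recalled) n_recall <- n_recall + 1L
    if (recalled && cohort$outcome[i] == "SDC") n_sdc <- n_sdc + 1L
    if (selected && cohort$outcome[i] == "IC") n_ic <- n_ic + 1L
  }
  list(
    n_consensus = if (spec$mode == "AI_STANDALONE") NA_integer_ else n_consensus,
    n_recall = n_recall, n_sdc = n_sdc, n_ic_selected = n_ic
  )
}

expect_matches_oracle <- function(cohort, spec) {
  got <- evaluate_scenario(cohort, spec)
  want <- naive_evaluate(cohort, spec)
  expect_identical(
    list(n_consensus = as.integer(got$n_consensus),
         n_recall = as.integer(got$n_recall),
         n_sdc = as.integer(got$n_sdc),
         n_ic_selected = as.integer(got$n_ic_selected)),
    want,
    label = sprintf("engine counts for %s", spec$name)
  )
}
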