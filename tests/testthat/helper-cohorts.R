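# fixtures built in code: a 10-exam hand-enumerable cohort and a
# generator of random valid cohorts for property tests

hand_cohort <- function() {
  as_cohort(data.frame(
    exam_id = sprintf("E%02d", 1:10),
    woman_id = sprintf("W%02d", c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5)),
    ai_raw = c(2.1, 4.9, 5.6, 6.2, 7.0, 9.4, 3.3, 8.8, 5.1, 1.2),
    ai_score = c(3L, 5L, 6L, 7L, 7L, 10L, 4L, 9L, 6L, 2L),
    r1_score = c(1L, 2L, 1L, 3L, 1L, 4L, 1L, 1L, 2L, 1L),
    r2_score = c(1L, 1L, 1L, 1L, 2L, 5L, 2L, 1L, 2L, 1L),
    consensus = c(FALSE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE),
    recall = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    outcome = c("NEGATIVE", "NEGATIVE", "NEGATIVE", "IC", "NEGATIVE", "SDC",
                "NEGATIVE", "NEGATIVE", "NEGATIVE", "NEGATIVE"),
    stringsAsFactors = FALSE
  ))
}

# six-row cohort with one SDC (recalled) and one IC (not recalled),
# written as CSV text for read_cohort tests
six_row_csv <- function(path) {
  writeLines(c(
    "exam_id,woman_id,ai_raw,ai_score,r1_score,r2_score,consensus,recall,outcome",
    "A1,W1,1.500000,2,1,1,0,0,NEGATIVE",
    "A2,W1,9.200000,10,4,3,1,1,SDC",
    "A3,W2,6.700000,7,2,1,1,0,IC",
    "A4,W2,3.100000,4,1,1,0,0,NEGATIVE",
    "A5,W3,5.000000,5,1,2,1,1,NEGATIVE",
    "A6,W3,8.000000,8,1,1,0,0,NEGATIVE"
  ), path)
  path
}

# random valid cohort; 1-decimal ai_raw creates score ties on purpose
random_cohort <- function(n, seed) {
  set.seed(seed)
  ai_raw <- round(stats::runif(n, 0.05, 10), 1)
  ai_raw[ai_raw <= 0] <- 0.1
  r1 <- sample(1:5, n, TRUE, prob = c(0.80, 0.10, 0.05, 0.03, 0.02))
  r2 <- sample(1:5, n, TRUE, prob = c(0.80, 0.10, 0.05, 0.03, 0.02))
  consensus <- r1 >= 2 | r2 >= 2
  recall <- consensus & stats::runif(n) < 0.5
  outcome <- rep("NEGATIVE", n)
  recalled <- which(recall)
  if (length(recalled)) {
    n_sdc <- min(length(recalled), stats::rbinom(1, 3, 0.5))
    if (n_sdc > 0) outcome[sample(recalled, n_sdc)] <- "SDC"
  }
  free <- which(outcome == "NEGATIVE" & !recall)
  if (length(free)) {
    n_ic <- min(length(free), stats::rbinom(1, 3, 0.4))
    if (n_ic > 0) outcome[sample(free, n_ic)] <- "IC"
  }
  as_cohort(data.frame(
    exam_id = sprintf("R%04d", seq_len(n)),
    woman_id = sprintf("W%04d", ceiling(seq_len(n) / 2)),
    ai_raw = ai_raw, ai_score = as.integer(ceiling(ai_raw)),
    r1_score = r1, r2_score = r2,
    consensus = consensus, recall = recall, outcome = outcome,
    stringsAsFactors = FALSE
  ))
}
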