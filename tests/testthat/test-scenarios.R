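test_that("the built-in catalog encodes the 11 published scenarios", {
  cat11 <- scenario_catalog()
  expect_length(cat11, 11L)
  expect_named(cat11, paste0("S", 1:11))

  expect_equal(cat11$S1$mode, "AI_AS_READER")
  expect_equal(cat11$S1$rate, 0.058)
  expect_equal(cat11$S2$score_cutoff, 10L)

  expect_equal(cat11$S3$bands$upper, c(5, 10))
  expect_equal(cat11$S3$bands$reading, c("NEGATIVE", "DOUBLE"))
  expect_equal(cat11$S9$bands$upper, c(5, 7.5, 10))
  expect_equal(cat11$S9$bands$reading, c("NEGATIVE", "SINGLE_R1", "DOUBLE"))
  expect_equal(cat11$S10$bands$reading, c("NEGATIVE", "DOUBLE", "SINGLE_R1"))

  expect_equal(cat11$S11$mode, "AI_STANDALONE")
  expect_equal(cat11$S11$rate, 0.032)

  # malformed band sets are rejected
  expect_error(
    triage_scenario("bad", data.frame(
      lower = c(0, 4), upper = c(5, 10),
      reading = c("NEGATIVE", "DOUBLE"))),
    "partition"
  )
  expect_error(
    triage_scenario("bad", data.frame(lower = 0, upper = 9, reading = "DOUBLE")),
    "partition"
  )
})

test_that("top-fraction selection rounds half-up and breaks ties by exam_id", {
  co <- random_cohort(100, 1)
  co$ai_raw <- round(seq(0.1, 9.99, length.out = 100), 3)  # distinct scores
  co$ai_score <- as.integer(ceiling(co$ai_raw))
  sel <- select_top_fraction(co, 0.058)
  expect_length(sel, 6L)  # round(5.8) = 6
  expect_setequal(sel, co$exam_id[order(-co$ai_raw)][1:6])

  expect_setequal(select_top_fraction(co, 1), co$exam_id)

  tied <- co
  tied$ai_raw <- rep(5.5, 100)
  tied$ai_score <- rep(6L, 100)
  s1 <- select_top_fraction(tied, 0.5)
  expect_identical(s1, sort(tied$exam_id)[1:50])
  expect_identical(s1, select_top_fraction(tied, 0.5))

  expect_length(select_top_fraction(as_cohort(mammotriage:::empty_cohort_df()), 0.5), 0L)
})

test_that("scenario evaluation reproduces hand-enumerated counterfactuals", {
  co <- hand_cohort()
  cat11 <- scenario_catalog()

  # a single all-double band is standard double reading
  all_double <- triage_scenario("identity",
    data.frame(lower = 0, upper = 10, reading = "DOUBLE"))
  res <- evaluate_scenario(co, all_double)
  expect_equal(res$n_consensus, sum(co$consensus))
  expect_equal(res$n_recall, sum(co$recall))
  expect_equal(res$n_sdc, sum(co$outcome == "SDC"))

  # a single negative band reads nobody and finds nothing
  none <- triage_scenario("none",
    data.frame(lower = 0, upper = 10, reading = "NEGATIVE"))
  res0 <- evaluate_scenario(co, none)
  expect_equal(res0$n_consensus, 0L)
  expect_equal(res0$n_recall, 0L)
  expect_equal(res0$n_sdc, 0L)
  expect_equal(res0$n_ic_selected, 0L)

  # S3 on the hand fixture: consensus-selected are E04 (6.2, r1=3),
  # E05 (7.0, r2=2), E06 (9.4, SDC, recalled) and E09 (5.1, both 2);
  # of those only E05 and E06 were actually recalled; the IC exam E04
  # is consensus-selected
  s3 <- evaluate_scenario(co, cat11$S3)
  expect_equal(s3$n_consensus, 4L)
  expect_equal(s3$n_recall, 2L)
  expect_equal(s3$n_sdc, 1L)
  expect_equal(s3$n_ic_selected, 1L)
  expect_equal(s3$reader_fractions, c(r1 = 0.6, r2 = 0.6))

  # S7 adds the low-band single reading: E02 (4.9, r1=2) joins consensus
  s7 <- evaluate_scenario(co, cat11$S7)
  expect_equal(s7$n_consensus, 5L)
  expect_equal(s7$n_recall, 2L)

  # standalone AI at rate 0.3 takes the top 3 raw scores E06, E08, E05
  s11 <- evaluate_scenario(co, ai_standalone_scenario("top3", 0.3))
  expect_true(is.na(s11$n_consensus))
  expect_equal(s11$n_recall, 3L)
  expect_equal(s11$n_sdc, 1L)
  expect_equal(s11$n_ic_selected, 0L)
})

test_that("volume reduction matches band arithmetic, nominal and empirical", {
  cat11 <- scenario_catalog()
  expect_equal(volume_reduction(cat11$S3), 50)
  expect_equal(volume_reduction(cat11$S5), 90)
  expect_equal(volume_reduction(cat11$S9), 62.5)
  expect_equal(volume_reduction(cat11$S11), 100)
  all_double <- triage_scenario("identity",
    data.frame(lower = 0, upper = 10, reading = "DOUBLE"))
  expect_equal(volume_reduction(all_double), 0)

  # empirical fractions come from the cohort at hand: 6 of 10 exams of
  # the hand fixture lie above raw score 5
  co <- hand_cohort()
  expect_equal(volume_reduction(cat11$S3, co), 100 * (1 - (0.6 + 0.6) / 2))
  expect_equal(volume_reduction(cat11$S6, co), 100 * (1 - 0.6 / 2))
  expect_equal(volume_reduction(cat11$S1, co), 50)
})

test_that("engine agrees with the per-exam enumeration oracle", {
  cat11 <- scenario_catalog()
  for (seed in 1:100) {
    co <- random_cohort(40, seed)
    spec <- cat11[[(seed %% 11) + 1L]]
    expect_matches_oracle(co, spec)
  }
  # and on the hand fixture for every scenario
  co <- hand_cohort()
  for (spec in cat11) expect_matches_oracle(co, spec)
})

test_that("counts are monotone under band enlargement and reading upgrades", {
  count_vec <- function(res) c(res$n_consensus, res$n_recall, res$n_sdc,
                               res$n_ic_selected)
  for (seed in 1:40) {
    co <- random_cohort(80, seed + 500)
    a <- sort(stats::runif(2, 1, 9))
    narrow <- triage_scenario("narrow", data.frame(
      lower = c(0, a[2]), upper = c(a[2], 10),
      reading = c("NEGATIVE", "DOUBLE")))
    wide <- triage_scenario("wide", data.frame(
      lower = c(0, a[1]), upper = c(a[1], 10),
      reading = c("NEGATIVE", "DOUBLE")))
    expect_true(all(count_vec(evaluate_scenario(co, wide)) >=
                    count_vec(evaluate_scenario(co, narrow))))

    # NEGATIVE -> SINGLE_R1 -> DOUBLE never lowers any count
    neg <- triage_scenario("neg", data.frame(
      lower = c(0, a[1]), upper = c(a[1], 10),
      reading = c("NEGATIVE", "DOUBLE")))
    single <- triage_scenario("single", data.frame(
      lower = c(0, a[1]), upper = c(a[1], 10),
      reading = c("SINGLE_R1", "DOUBLE")))
    dbl <- triage_scenario("dbl", data.frame(
      lower = c(0, a[1]), upper = c(a[1], 10),
      reading = c("DOUBLE", "DOUBLE")))
    expect_true(all(count_vec(evaluate_scenario(co, single)) >=
                    count_vec(evaluate_scenario(co, neg))))
    expect_true(all(count_vec(evaluate_scenario(co, dbl)) >=
                    count_vec(evaluate_scenario(co, single))))
  }
})

test_that("scenario recalls are conserved subsets of actual recalls", {
  cat11 <- scenario_catalog()
  for (seed in 1:30) {
    co <- random_cohort(60, seed + 900)
    actual_recalls <- co$exam_id[co$recall]
    for (spec in cat11[c("S1", "S3", "S7", "S9")]) {
      ind <- mammotriage:::scenario_indicators(co, spec)
      expect_true(all(co$exam_id[ind$recalled] %in% actual_recalls))
      res <- evaluate_scenario(co, spec)
      # detected plus missed screen-detected cancers sum to the total
      missed <- sum(co$outcome == "SDC" & !ind$recalled)
      expect_equal(res$n_sdc + missed, res$n_sdc_total)
      expect_lte(res$n_recall, res$n_consensus)
      expect_lte(res$n_sdc, res$n_recall)
    }
  }
})
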