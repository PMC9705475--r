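test_that("logit-transformed CI matches the closed form", {
  # frozen oracle values for tp=10, fn=90: L = ln(1/9),
  # SE = sqrt(1/10 + 1/90) = 1/3, evaluated independently
  est <- sensitivity_logit_ci(10, 90)
  expect_equal(est$point, 0.1)
  expect_equal(est$ci_low, 0.05465311, tolerance = 1e-6)
  expect_equal(est$ci_high, 0.17596857, tolerance = 1e-6)
  expect_false(est$degenerate)

  # tp = fn gives an interval symmetric about one half
  est2 <- sensitivity_logit_ci(50, 50)
  expect_equal(est2$point, 0.5)
  expect_equal(est2$ci_low + est2$ci_high, 1, tolerance = 1e-12)
  expect_equal(est2$ci_low, 0.40323767, tolerance = 1e-6)

  # strict ordering for nondegenerate counts
  for (tp in c(1, 5, 100)) {
    for (fn in c(1, 7, 300)) {
      e <- sensitivity_logit_ci(tp, fn)
      expect_true(e$ci_low < e$point && e$point < e$ci_high)
      expect_true(e$ci_low >= 0 && e$ci_high <= 1)
    }
  }

  # zero cells fall back to a flagged continuity-corrected interval
  d0 <- sensitivity_logit_ci(0, 20)
  expect_true(d0$degenerate)
  expect_equal(d0$point, 0)
  expect_gt(d0$ci_high, 0)
  d1 <- sensitivity_logit_ci(20, 0)
  expect_true(d1$degenerate)
  expect_equal(d1$point, 1)
  expect_lt(d1$ci_low, 1)
  expect_error(sensitivity_logit_ci(0, 0))
})

test_that("scenario sensitivity uses the two true-positive definitions", {
  # a scenario identical to double reading reduces to the baseline
  full <- scenario_result("full", 1000, 90, 40, 10, 0,
                          n_sdc_total = 10, n_ic_total = 4)
  expect_equal(unclass(scenario_sensitivity(full, "A"))[c("tp", "fn", "point")],
               unclass(sensitivity_logit_ci(10, 4))[c("tp", "fn", "point")])

  # standalone AI with study-like counts: tp = 555,
  # fn = (752 - 555) + 205 = 402
  s11 <- scenario_result("S11", 122969, NA, 3896, 555, 44,
                         n_sdc_total = 752, n_ic_total = 205)
  a <- scenario_sensitivity(s11, "A")
  expect_equal(a$tp, 555)
  expect_equal(a$fn, 402)
  expect_equal(a$point, 555 / 957)
  b <- scenario_sensitivity(s11, "B")
  expect_equal(b$tp, 555 + 44)
  expect_equal(b$fn, 197 + 161)

  # variant B never falls below variant A
  for (seed in 1:25) {
    set.seed(seed)
    tot_sdc <- sample(5:30, 1)
    tot_ic <- sample(2:15, 1)
    nsdc <- sample(0:tot_sdc, 1)
    nic <- sample(0:tot_ic, 1)
    res <- scenario_result("r", 5000, NA, max(nsdc, 1), nsdc, nic,
                           n_sdc_total = tot_sdc, n_ic_total = tot_ic)
    expect_gte(scenario_sensitivity(res, "B")$point,
               scenario_sensitivity(res, "A")$point)
  }
})

test_that("potential rates transfer selected interval cancers and conserve totals", {
  res <- scenario_result("x", 100000, 9000, 3000, 600, 50,
                         n_sdc_total = 640, n_ic_total = 170)
  pr <- potential_rates(res)
  expect_equal(pr$potential_sdc$per1000, 1000 * 650 / 100000)
  expect_equal(pr$potential_ic$per1000, 1000 * 120 / 100000)
  # conservation: the sum never depends on how many ICs transfer
  expect_equal(pr$potential_sdc$per1000 + pr$potential_ic$per1000,
               1000 * (600 + 170) / 100000)
  expect_true(pr$potential_sdc$ci_low < pr$potential_sdc$per1000)
  expect_true(pr$potential_sdc$ci_high > pr$potential_sdc$per1000)

  # no transfer: potential equals plain rates
  res0 <- scenario_result("y", 100000, 9000, 3000, 600, 0,
                          n_sdc_total = 640, n_ic_total = 170)
  pr0 <- potential_rates(res0)
  expect_equal(pr0$potential_sdc$per1000, 6)
  expect_equal(pr0$potential_ic$per1000, 1.7)

  expect_error(potential_rates(scenario_result("z", 0, 0, 0, 0, 0, 0, 0)),
               "empty")
})

test_that("design effect grows with within-woman duplication and widens CIs", {
  set.seed(99)
  # independent exams: design effect near 1
  ev <- stats::runif(4000) < 0.05
  cl <- seq_len(4000)
  expect_equal(design_effect(ev, cl), 1, tolerance = 0.15)
  # both exams of each woman share the event: strong clustering
  ev2 <- rep(stats::runif(2000) < 0.05, each = 2)
  cl2 <- rep(seq_len(2000), each = 2)
  expect_gt(design_effect(ev2, cl2), 1.5)

  res <- scenario_result("x", 4000, 400, 150, 24, 3,
                         n_sdc_total = 26, n_ic_total = 8)
  plain <- potential_rates(res)
  wide <- potential_rates(res, deff = 2)
  expect_lt(wide$potential_sdc$ci_low, plain$potential_sdc$ci_low)
  expect_gt(wide$potential_sdc$ci_high, plain$potential_sdc$ci_high)
})

test_that("rate and sensitivity reports cover baseline plus every scenario", {
  co <- generate_cohort(cohort_params(n_exams = 8000, seed = 21))
  rep11 <- rates_report(co)
  expect_s3_class(rep11, "rates_report")
  expect_equal(nrow(rep11), 12L)
  expect_equal(rep11$scenario[1], "double_reading")
  # the standalone-AI row has no consensus entry and full volume reduction
  s11row <- rep11[rep11$scenario == "S11", ]
  expect_true(is.na(s11row$n_consensus))
  expect_equal(s11row$volume_reduction_pct, 100)
  expect_equal(format(rep11)$consensus[rep11$scenario == "S11"], "-")
  # conservation holds on every row
  expect_equal(rep11$potential_sdc_per1000 + rep11$potential_ic_per1000,
               (rep11$n_sdc + sum(co$outcome == "IC")) / nrow(co) * 1000)

  # empty scenario list: baseline row only
  expect_equal(nrow(rates_report(co, specs = list())), 1L)

  sens <- sensitivity_report(co)
  expect_equal(nrow(sens), 1L + 2L * 11L)
  ab <- merge(sens[sens$variant == "A", c("scenario", "sensitivity")],
              sens[sens$variant == "B", c("scenario", "sensitivity")],
              by = "scenario")
  expect_true(all(ab$sensitivity.y >= ab$sensitivity.x))

  # cluster adjustment can only widen the potential-rate intervals
  repc <- rates_report(co, cluster_adjust = TRUE)
  expect_true(all(repc$potential_sdc_hi >= rep11$potential_sdc_hi - 1e-9))
  expect_true(all(repc$potential_sdc_lo <= rep11$potential_sdc_lo + 1e-9))
})
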