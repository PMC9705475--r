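#' Sensitivity with a logit-transformed confidence interval
#'
#' Point estimate `tp / (tp + fn)` with confidence bounds computed on
#' the log-odds scale: `L = ln(tp/fn)`, `SE = sqrt(1/tp + 1/fn)`, and
#' bounds `plogis(L -/+ z * SE)` with `z` the standard-normal quantile
#' for the level. When `tp` or `fn` is zero the log odds are undefined;
#' a continuity fallback adds 0.5 to both counts for the interval (the
#' point estimate keeps the raw counts) and the estimate is flagged
#' `degenerate`.
#'
#' @param tp true-positive count.
#' @param fn false-negative count.
#' @param level confidence level (default 0.95).
#' @return an object of class `sensitivity_estimate` with fields `tp`,
#'   `fn`, `point`, `ci_low`, `ci_high`, `level`, `degenerate` (and
#'   `variant` when produced by [scenario_sensitivity()]).
#' @examples
#' est <- sensitivity_logit_ci(752, 205)
#' round_half_up(100 * c(est$point, est$ci_low, est$ci_high), 1)
#' @export
sensitivity_logit_ci <- function(tp, fn, level = 0.95) {
  stopifnot(tp >= 0, fn >= 0, tp + fn > 0, is_prob(level), level > 0, level < 1)
  degenerate <- tp == 0 || fn == 0
  tp_c <- if (degenerate) tp + 0.5 else tp
  fn_c <- if (degenerate) fn + 0.5 else fn
  L <- log(tp_c / fn_c)
  se <- sqrt(1 / tp_c + 1 / fn_c)
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- stats::plogis(L + c(-1, 1) * z * se)
  structure(list(
    tp = tp, fn = fn, point = tp / (tp + fn),
    ci_low = ci[1L], ci_high = ci[2L],
    level = level, degenerate = degenerate, variant = NA_character_
  ), class = "sensitivity_estimate")
}

#' Scenario sensitivity under two true-positive definitions
#'
#' Variant A counts only the scenario's screen-detected cancers as true
#' positives; screen-detected cancers missed by the scenario and all
#' interval cancers are false negatives. Variant B additionally credits
#' interval cancers whose prior exam the scenario selected for
#' consensus (or recall, standalone AI) as true positives, leaving only
#' unselected interval cancers (and missed screen-detected cancers) as
#' false negatives:
#' \itemize{
#'   \item A: `tp = n_sdc`,
#'     `fn = (n_sdc_total - n_sdc) + n_ic_total`;
#'   \item B: `tp = n_sdc + n_ic_selected`,
#'     `fn = (n_sdc_total - n_sdc) + (n_ic_total - n_ic_selected)`.
#' }
#' Variant B is never below variant A.
#'
#' @param result a [scenario_result()].
#' @param variant `"A"` or `"B"`.
#' @param level confidence level (default 0.95).
#' @return a `sensitivity_estimate`, see [sensitivity_logit_ci()].
#' @export
scenario_sensitivity <- function(result, variant = c("A", "B"), level = 0.95) {
  stopifnot(inherits(result, "scenario_result"))
  variant <- match.arg(variant)
  if (variant == "A") {
    tp <- result$n_sdc
    fn <- (result$n_sdc_total - result$n_sdc) + result$n_ic_total
  } else {
    tp <- result$n_sdc + result$n_ic_selected
    fn <- (result$n_sdc_total - result$n_sdc) +
      (result$n_ic_total - result$n_ic_selected)
  }
  est <- sensitivity_logit_ci(tp, fn, level)
  est$variant <- variant
  est
}

#' @export
print.sensitivity_estimate <- function(x, ...) {
  cat(sprintf(
    "sensitivity %.1f%% (%d%% CI: %.1f-%.1f%%) [tp=%s fn=%s]%s%s\n",
    round_half_up(100 * x$point, 1), round(100 * x$level),
    round_half_up(100 * x$ci_low, 1), round_half_up(100 * x$ci_high, 1),
    format(x$tp), format(x$fn),
    if (!is.na(x$variant)) sprintf(" variant %s", x$variant) else "",
    if (x$degenerate) " (degenerate: continuity-corrected interval)" else ""
  ))
  invisible(x)
}

# Wilson score interval for a binomial proportion; deff > 1 inflates z
# by sqrt(deff) (design-effect cluster adjustment)
wilson_ci <- function(x, n, level = 0.95, deff = 1) {
  stopifnot(x >= 0, n > 0, x <= n, deff >= 1)
  p <- x / n
  z <- stats::qnorm(1 - (1 - level) / 2) * sqrt(deff)
  den <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(low = max(center - hw, 0), high = min(center + hw, 1))
}

#' Design effect of within-woman clustering for a binary event
#'
#' Ratio of the cluster-robust variance of the event proportion to the
#' simple-random-sampling binomial variance, computed from per-woman
#' event and exam counts: `DEFF = [K/(K-1) * sum_k (x_k - n_k p)^2 / N^2]
#' / [p(1-p)/N]` over clusters `k`. Used (optionally) to widen
#' potential-rate confidence intervals for repeated screening rounds of
#' the same woman.
#'
#' @param event logical vector, one entry per examination.
#' @param cluster cluster (woman) identifier per examination.
#' @return design effect, floored at 1.
#' @export
design_effect <- function(event, cluster) {
  stopifnot(length(event) == length(cluster))
  n <- length(event)
  p <- mean(event)
  if (p == 0 || p == 1) return(1)
  xk <- tapply(as.numeric(event), cluster, sum)
  nk <- tapply(rep(1, n), cluster, sum)
  k <- length(xk)
  if (k < 2L) return(1)
  v_clust <- (k / (k - 1)) * sum((xk - nk * p)^2) / n^2
  v_srs <- p * (1 - p) / n
  max(v_clust / v_srs, 1)
}

#' Potential cancer-detection rates of a scenario
#'
#' Recomputes the screen-detected and interval cancer rates under the
#' optimistic assumption that every interval cancer whose prior exam
#' the scenario selected for consensus would have been detected at
#' screening:
#' `potential SDC per 1000 = (n_sdc + n_ic_selected) / n * 1000` and
#' `potential IC per 1000 = (n_ic_total - n_ic_selected) / n * 1000`.
#' Their sum is always `(n_sdc + n_ic_total) / n * 1000`, independent of
#' how many interval cancers transfer. Confidence intervals use the
#' Wilson score method, optionally widened by a design effect for
#' within-woman clustering.
#'
#' @param result a [scenario_result()].
#' @param level confidence level (default 0.95).
#' @param deff design effect(s) for the interval width: a single number
#'   or `c(sdc = , ic = )` (default 1 = unadjusted; see
#'   [design_effect()]).
#' @return list with `potential_sdc` and `potential_ic`, each
#'   `list(per1000, ci_low, ci_high)` on the per-1000 scale, plus
#'   `deff`.
#' @export
potential_rates <- function(result, level = 0.95, deff = 1) {
  stopifnot(inherits(result, "scenario_result"))
  if (result$n == 0L) abort("%s: rates undefined for an empty cohort", result$name)
  if (length(deff) == 1L) deff <- c(sdc = deff, ic = deff)
  x_sdc <- result$n_sdc + result$n_ic_selected
  x_ic <- result$n_ic_total - result$n_ic_selected
  ci_sdc <- wilson_ci(x_sdc, result$n, level, deff[["sdc"]])
  ci_ic <- wilson_ci(x_ic, result$n, level, deff[["ic"]])
  list(
    potential_sdc = list(per1000 = 1000 * x_sdc / result$n,
                         ci_low = 1000 * ci_sdc[["low"]],
                         ci_high = 1000 * ci_sdc[["high"]]),
    potential_ic = list(per1000 = 1000 * x_ic / result$n,
                        ci_low = 1000 * ci_ic[["low"]],
                        ci_high = 1000 * ci_ic[["high"]]),
    deff = deff
  )
}

#' Per-scenario rate report
#'
#' One row per scenario plus a leading baseline row for actual
#' independent double reading: consensus and recall percentages,
#' screen-detected cancer and selected-interval-cancer rates, potential
#' rates with confidence intervals, and the nominal volume reduction.
#' All columns are unrounded; `format()`/`print()` render them at the
#' reporting precision (one decimal for percentages and per-1000 rates,
#' half-up; integer volume reduction).
#'
#' Note: AI-as-reader scenarios assume every consensus selection made
#' by the AI alone would have been recalled by the consensus meeting,
#' which may overestimate their screen-detected cancer rate.
#'
#' @param cohort a validated `screening_cohort`.
#' @param specs list of `scenario_spec` objects (default the built-in
#'   [scenario_catalog()]); may be empty for the baseline row only.
#' @param level confidence level for the potential-rate intervals.
#' @param cluster_adjust if TRUE, widen the potential-rate intervals by
#'   the per-scenario [design_effect()] of within-woman clustering
#'   (default FALSE: unadjusted Wilson intervals).
#' @return a data frame of class `rates_report`.
#' @export
rates_report <- function(cohort, specs = scenario_catalog(), level = 0.95,
                         cluster_adjust = FALSE) {
  base <- cohort_rates(cohort)
  n <- base$n

  baseline_res <- scenario_result(
    name = "double_reading", n = n,
    n_consensus = base$n_consensus, n_recall = base$n_recall,
    n_sdc = base$n_sdc, n_ic_selected = 0L,
    n_sdc_total = base$n_sdc, n_ic_total = base$n_ic,
    reader_fractions = c(r1 = 1, r2 = 1)
  )

  row_for <- function(res, vol, deff) {
    pr <- potential_rates(res, level = level, deff = deff)
    data.frame(
      scenario = res$name,
      n_consensus = if (is.na(res$n_consensus)) NA_integer_ else as.integer(res$n_consensus),
      consensus_pct = if (is.na(res$n_consensus)) NA_real_ else 100 * res$n_consensus / n,
      n_recall = as.integer(res$n_recall),
      recall_pct = 100 * res$n_recall / n,
      n_sdc = as.integer(res$n_sdc),
      sdc_per1000 = 1000 * res$n_sdc / n,
      n_ic_selected = as.integer(res$n_ic_selected),
      ic_selected_per1000 = 1000 * res$n_ic_selected / n,
      potential_sdc_per1000 = pr$potential_sdc$per1000,
      potential_sdc_lo = pr$potential_sdc$ci_low,
      potential_sdc_hi = pr$potential_sdc$ci_high,
      potential_ic_per1000 = pr$potential_ic$per1000,
      potential_ic_lo = pr$potential_ic$ci_low,
      potential_ic_hi = pr$potential_ic$ci_high,
      volume_reduction_pct = vol,
      stringsAsFactors = FALSE
    )
  }

  deff_for <- function(ind) {
    if (!cluster_adjust) return(1)
    pot_sdc_event <- ind$sdc_detected | ind$ic_selected
    pot_ic_event <- (cohort$outcome == "IC") & !ind$ic_selected
    c(sdc = design_effect(pot_sdc_event, cohort$woman_id),
      ic = design_effect(pot_ic_event, cohort$woman_id))
  }

  baseline_ind <- list(sdc_detected = cohort$outcome == "SDC",
                       ic_selected = rep(FALSE, n))
  rows <- list(row_for(baseline_res, 0, deff_for(baseline_ind)))
  for (spec in specs) {
    ind <- scenario_indicators(cohort, spec)
    res <- evaluate_scenario(cohort, spec)
    rows[[length(rows) + 1L]] <- row_for(res, volume_reduction(spec), deff_for(ind))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "level") <- level
  attr(out, "cluster_adjust") <- cluster_adjust
  class(out) <- c("rates_report", "data.frame")
  out
}

#' @export
format.rates_report <- function(x, ...) {
  fmt1 <- function(v) ifelse(is.na(v), "-", sprintf("%.1f", round_half_up(v, 1)))
  data.frame(
    scenario = x$scenario,
    consensus = ifelse(is.na(x$n_consensus), "-",
                       sprintf("%d (%s%%)", x$n_consensus, fmt1(x$consensus_pct))),
    recall = sprintf("%d (%s%%)", x$n_recall, fmt1(x$recall_pct)),
    sdc = sprintf("%d (%s)", x$n_sdc, fmt1(x$sdc_per1000)),
    ic_selected = sprintf("%d (%s)", x$n_ic_selected, fmt1(x$ic_selected_per1000)),
    potential_sdc = sprintf("%s (%s-%s)", fmt1(x$potential_sdc_per1000),
                            fmt1(x$potential_sdc_lo), fmt1(x$potential_sdc_hi)),
    potential_ic = sprintf("%s (%s-%s)", fmt1(x$potential_ic_per1000),
                           fmt1(x$potential_ic_lo), fmt1(x$potential_ic_hi)),
    volume_reduction = sprintf("%d", as.integer(round_half_up(x$volume_reduction_pct))),
    stringsAsFactors = FALSE
  )
}

#' @export
print.rates_report <- function(x, ...) {
  cat(sprintf("Scenario rate report (level %.2f%s)\n", attr(x, "level"),
              if (isTRUE(attr(x, "cluster_adjust"))) ", cluster-adjusted CIs" else ""))
  print.data.frame(format(x), row.names = FALSE)
  invisible(x)
}

#' Per-scenario sensitivity table (both variants)
#'
#' Sensitivity with logit-transformed confidence intervals for every
#' scenario under both true-positive definitions (see
#' [scenario_sensitivity()]), plus the double-reading baseline
#' (screen-detected cancers true positive, interval cancers false
#' negative) — the numeric content of the usual scenario-sensitivity
#' forest plot.
#'
#' @inheritParams rates_report
#' @return data frame with columns `scenario`, `variant`, `tp`, `fn`,
#'   `sensitivity`, `ci_low`, `ci_high` (proportions, unrounded), and
#'   `volume_reduction_pct`.
#' @export
sensitivity_report <- function(cohort, specs = scenario_catalog(), level = 0.95) {
  base <- cohort_rates(cohort)
  est0 <- sensitivity_logit_ci(base$n_sdc, base$n_ic, level)
  rows <- list(data.frame(
    scenario = "double_reading", variant = "baseline",
    tp = base$n_sdc, fn = base$n_ic,
    sensitivity = est0$point, ci_low = est0$ci_low, ci_high = est0$ci_high,
    volume_reduction_pct = 0, stringsAsFactors = FALSE
  ))
  for (spec in specs) {
    res <- evaluate_scenario(cohort, spec)
    for (v in c("A", "B")) {
      est <- scenario_sensitivity(res, v, level)
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = res$name, variant = v,
        tp = est$tp, fn = est$fn,
        sensitivity = est$point, ci_low = est$ci_low, ci_high = est$ci_high,
        volume_reduction_pct = volume_reduction(spec),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
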