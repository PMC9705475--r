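#' @title Reading scenarios
#'
#' @description
#' A reading scenario says how the AI score and the two radiologists
#' (R1, R2) are combined in screen-reading. Three modes exist:
#' \describe{
#'   \item{TRIAGE}{the raw AI score partitions (0, 10] into bands, each
#'     read by nobody (`NEGATIVE`), by the first reader only
#'     (`SINGLE_R1`), or by both readers (`DOUBLE`).}
#'   \item{AI_AS_READER}{R1 reads everything; the AI replaces the second
#'     reader and flags either a fixed fraction of exams with the
#'     highest raw scores or a whole top decile.}
#'   \item{AI_STANDALONE}{the AI alone selects a fixed fraction of exams
#'     for recall; no radiologist reads.}
#' }
#' Band intervals are half-open upper-closed on the raw score, so the
#' decile label "1-5" is (0, 5], "6-10" is (5, 10], and a split at 7.5
#' gives (5, 7.5] and (7.5, 10] — consistent with
#' `ai_score == ceiling(ai_raw)`.
#' @name reading_scenarios
NULL

READING_MODES <- c("NEGATIVE", "SINGLE_R1", "DOUBLE")

#' Define a triage scenario
#'
#' @param name scenario identifier.
#' @param bands data frame with columns `lower`, `upper` (numeric) and
#'   `reading` (one of NEGATIVE, SINGLE_R1, DOUBLE); the intervals
#'   `(lower, upper]` must partition (0, 10] contiguously in order.
#' @param description optional human-readable label.
#' @return a `scenario_spec` with mode `"TRIAGE"`.
#' @export
triage_scenario <- function(name, bands, description = NULL) {
  bands <- as.data.frame(bands)
  stopifnot(all(c("lower", "upper", "reading") %in% names(bands)))
  bands <- bands[order(bands$lower), , drop = FALSE]
  rownames(bands) <- NULL
  if (!all(bands$reading %in% READING_MODES)) {
    abort("scenario %s: reading modes must be one of %s",
          name, paste(READING_MODES, collapse = ", "))
  }
  nb <- nrow(bands)
  if (nb == 0L || bands$lower[1L] != 0 || bands$upper[nb] != 10 ||
      any(bands$upper <= bands$lower) ||
      (nb > 1L && any(abs(bands$lower[-1L] - bands$upper[-nb]) > 1e-12))) {
    abort("scenario %s: bands must partition (0, 10] contiguously without overlap", name)
  }
  structure(list(name = name, mode = "TRIAGE", bands = bands,
                 description = description %||% name),
            class = "scenario_spec")
}

#' Define an AI-as-second-reader scenario
#'
#' R1 reads all examinations; the AI flags exams for consensus either as
#' the top `rate` fraction by raw score or as a whole decile cutoff.
#' Exactly one of `rate` and `score_cutoff` must be given.
#'
#' @param name scenario identifier.
#' @param rate fraction of exams the AI flags, selected as the
#'   highest-ranked by `ai_raw` (e.g. 0.058).
#' @param score_cutoff integer decile; the AI flags all exams with
#'   `ai_score >= score_cutoff` (e.g. 10).
#' @param description optional label.
#' @return a `scenario_spec` with mode `"AI_AS_READER"`.
#' @export
ai_reader_scenario <- function(name, rate = NULL, score_cutoff = NULL,
                               description = NULL) {
  if (is.null(rate) == is.null(score_cutoff)) {
    abort("scenario %s: give exactly one of rate or score_cutoff", name)
  }
  if (!is.null(rate) && !(is_prob(rate) && rate > 0)) {
    abort("scenario %s: rate must be in (0, 1]", name)
  }
  if (!is.null(score_cutoff) && !(score_cutoff %in% 1:10)) {
    abort("scenario %s: score_cutoff must be a decile 1..10", name)
  }
  structure(list(name = name, mode = "AI_AS_READER", rate = rate,
                 score_cutoff = score_cutoff, description = description %||% name),
            class = "scenario_spec")
}

#' Define a standalone-AI recall scenario
#'
#' The AI alone selects the top `rate` fraction of exams (by raw score)
#' to be recalled; no radiologist reads and there is no consensus stage.
#'
#' @param name scenario identifier.
#' @param rate recall selection fraction in (0, 1] (e.g. 0.032).
#' @param description optional label.
#' @return a `scenario_spec` with mode `"AI_STANDALONE"`.
#' @export
ai_standalone_scenario <- function(name, rate, description = NULL) {
  if (!(is_prob(rate) && rate > 0)) abort("scenario %s: rate must be in (0, 1]", name)
  structure(list(name = name, mode = "AI_STANDALONE", rate = rate,
                 description = description %||% name),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec> %s [%s] %s\n", x$name, x$mode, x$description))
  if (x$mode == "TRIAGE") {
    for (i in seq_len(nrow(x$bands))) {
      cat(sprintf("  (%g, %g]: %s\n", x$bands$lower[i], x$bands$upper[i],
                  x$bands$reading[i]))
    }
  } else if (!is.null(x$rate)) {
    cat(sprintf("  AI selection rate: %.3f\n", x$rate))
  } else {
    cat(sprintf("  AI selects AI score >= %d\n", x$score_cutoff))
  }
  invisible(x)
}

bands_df <- function(lower, upper, reading) {
  data.frame(lower = lower, upper = upper, reading = reading,
             stringsAsFactors = FALSE)
}

#' The built-in catalog of 11 reading scenarios
#'
#' The eleven published combinations of AI and radiologists, in order:
#' \itemize{
#'   \item S1 — AI as one of two readers, AI flags the top 5.8% of exams
#'     (the average per-reader positive-interpretation rate).
#'   \item S2 — AI as one of two readers, AI flags AI score 10.
#'   \item S3 — scores 1-5 negative, 6-10 double read.
#'   \item S4 — scores 1-7 negative, 8-10 double read.
#'   \item S5 — scores 1-9 negative, 10 double read.
#'   \item S6 — scores 1-5 negative, 6-10 single read (R1).
#'   \item S7 — scores 1-5 single read (R1), 6-10 double read.
#'   \item S8 — scores 1-7 single read (R1), 8-10 double read.
#'   \item S9 — scores 1-5 negative, 6-7.5 single read, 7.6-10 double read.
#'   \item S10 — scores 1-5 negative, 6-7.5 double read, 7.6-10 single read.
#'   \item S11 — standalone AI recalls the top 3.2% (the double-reading
#'     recall rate).
#' }
#'
#' @return named list of 11 `scenario_spec` objects, `S1` .. `S11`.
#' @export
scenario_catalog <- function() {
  list(
    S1 = ai_reader_scenario("S1", rate = 0.058,
      description = "AI and R1 select 5.8% each for consensus"),
    S2 = ai_reader_scenario("S2", score_cutoff = 10L,
      description = "AI selects AI score 10, R1 selects 5.8%"),
    S3 = triage_scenario("S3",
      bands_df(c(0, 5), c(5, 10), c("NEGATIVE", "DOUBLE")),
      "AI score 1-5: negative; 6-10: R1+R2"),
    S4 = triage_scenario("S4",
      bands_df(c(0, 7), c(7, 10), c("NEGATIVE", "DOUBLE")),
      "AI score 1-7: negative; 8-10: R1+R2"),
    S5 = triage_scenario("S5",
      bands_df(c(0, 9), c(9, 10), c("NEGATIVE", "DOUBLE")),
      "AI score 1-9: negative; 10: R1+R2"),
    S6 = triage_scenario("S6",
      bands_df(c(0, 5), c(5, 10), c("NEGATIVE", "SINGLE_R1")),
      "AI score 1-5: negative; 6-10: R1"),
    S7 = triage_scenario("S7",
      bands_df(c(0, 5), c(5, 10), c("SINGLE_R1", "DOUBLE")),
      "AI score 1-5: R1; 6-10: R1+R2"),
    S8 = triage_scenario("S8",
      bands_df(c(0, 7), c(7, 10), c("SINGLE_R1", "DOUBLE")),
      "AI score 1-7: R1; 8-10: R1+R2"),
    S9 = triage_scenario("S9",
      bands_df(c(0, 5, 7.5), c(5, 7.5, 10), c("NEGATIVE", "SINGLE_R1", "DOUBLE")),
      "AI score 1-5: negative; 6-7.5: R1; 7.6-10: R1+R2"),
    S10 = triage_scenario("S10",
      bands_df(c(0, 5, 7.5), c(5, 7.5, 10), c("NEGATIVE", "DOUBLE", "SINGLE_R1")),
      "AI score 1-5: negative; 6-7.5: R1+R2; 7.6-10: R1"),
    S11 = ai_standalone_scenario("S11", rate = 0.032,
      description = "AI selects 3.2% of exams to be recalled")
  )
}

#' Select the top fraction of exams by raw AI score
#'
#' Returns the `round(rate * n)` exam identifiers with the highest
#' `ai_raw` (half-up rounding of the count). Ties in `ai_raw` are
#' broken deterministically by ascending `exam_id`.
#'
#' @param cohort a `screening_cohort`.
#' @param rate selection fraction in (0, 1].
#' @return character vector of selected `exam_id`s (empty for an empty
#'   cohort).
#' @export
select_top_fraction <- function(cohort, rate) {
  stopifnot(is_prob(rate), rate > 0)
  n <- nrow(cohort)
  if (n == 0L) return(character())
  k <- as.integer(round_half_up(rate * n))
  ord <- order(-cohort$ai_raw, cohort$exam_id)
  cohort$exam_id[ord[seq_len(min(k, n))]]
}

# per-exam counterfactual indicator vectors for one scenario; the
# single source of truth used by evaluate_scenario() and the
# cluster-adjusted CIs in rates_report()
scenario_indicators <- function(cohort, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  n <- nrow(cohort)
  r1p <- cohort$r1_score >= 2L
  r2p <- cohort$r2_score >= 2L
  if (spec$mode == "TRIAGE") {
    idx <- cut(cohort$ai_raw, breaks = c(0, spec$bands$upper), labels = FALSE,
               right = TRUE)
    if (anyNA(idx)) abort("scenario %s: bands do not cover all ai_raw values", spec$name)
    reading <- spec$bands$reading[idx]
    selected <- (reading == "DOUBLE" & (r1p | r2p)) |
      (reading == "SINGLE_R1" & r1p)
    recalled <- selected & cohort$recall
    r1_frac <- mean(reading != "NEGATIVE")
    r2_frac <- mean(reading == "DOUBLE")
    has_consensus <- TRUE
  } else if (spec$mode == "AI_AS_READER") {
    ai_sel <- if (!is.null(spec$score_cutoff)) {
      cohort$ai_score >= spec$score_cutoff
    } else {
      cohort$exam_id %in% select_top_fraction(cohort, spec$rate)
    }
    selected <- r1p | ai_sel
    recalled <- selected & cohort$recall
    r1_frac <- 1
    r2_frac <- 0
    has_consensus <- TRUE
  } else { # AI_STANDALONE
    selected <- cohort$exam_id %in% select_top_fraction(cohort, spec$rate)
    recalled <- selected
    r1_frac <- 0
    r2_frac <- 0
    has_consensus <- FALSE
  }
  list(
    selected = selected,
    recalled = recalled,
    sdc_detected = recalled & cohort$outcome == "SDC",
    ic_selected = selected & cohort$outcome == "IC",
    reader_fractions = c(r1 = r1_frac, r2 = r2_frac),
    has_consensus = has_consensus
  )
}

#' Construct a scenario result from counts
#'
#' Counterfactual counts for one scenario. Usually produced by
#' [evaluate_scenario()]; the constructor is exported so that results
#' can also be built directly from published count tables.
#'
#' @param name scenario identifier.
#' @param n cohort size.
#' @param n_consensus exams selected for consensus (NA for standalone
#'   AI, which has no consensus stage).
#' @param n_recall counterfactual recalls.
#' @param n_sdc screen-detected cancers among the counterfactual
#'   recalls.
#' @param n_ic_selected interval cancers whose prior exam was selected
#'   for consensus (or for recall, standalone AI).
#' @param n_sdc_total,n_ic_total cohort totals for reference.
#' @param reader_fractions named numeric `c(r1 = , r2 = )`: fraction of
#'   exams each radiologist reads under the scenario.
#' @return an object of class `scenario_result`.
#' @export
scenario_result <- function(name, n, n_consensus, n_recall, n_sdc,
                            n_ic_selected, n_sdc_total, n_ic_total,
                            reader_fractions = c(r1 = NA_real_, r2 = NA_real_)) {
  stopifnot(n >= 0, n_sdc >= 0, n_ic_selected >= 0,
            n_sdc <= n_sdc_total, n_ic_selected <= n_ic_total)
  if (!is.na(n_recall) && n_sdc > n_recall) abort("%s: n_sdc exceeds n_recall", name)
  if (!is.na(n_consensus) && !is.na(n_recall) && n_recall > n_consensus) {
    abort("%s: n_recall exceeds n_consensus", name)
  }
  structure(list(
    name = name, n = as.integer(n),
    n_consensus = n_consensus, n_recall = n_recall, n_sdc = n_sdc,
    n_ic_selected = n_ic_selected,
    n_sdc_total = n_sdc_total, n_ic_total = n_ic_total,
    reader_fractions = reader_fractions
  ), class = "scenario_result")
}

#' Evaluate a reading scenario on a cohort
#'
#' Applies the counterfactual semantics of retrospective scenario
#' evaluation: an exam is consensus-selected according to the scenario's
#' reading allocation and the readers' recorded scores; scenario recalls
#' are the consensus-selected exams that were actually recalled in the
#' real double-reading setting (for standalone AI, the AI selection
#' itself is the recall set); screen-detected cancers are counted among
#' the scenario recalls; interval cancers are counted among the
#' consensus-selected exams (these are the ones with the greatest
#' potential to be detected at screening had the AI score been
#' available).
#'
#' @param cohort a validated `screening_cohort`.
#' @param spec a `scenario_spec`.
#' @return a [scenario_result()].
#' @export
evaluate_scenario <- function(cohort, spec) {
  ind <- scenario_indicators(cohort, spec)
  scenario_result(
    name = spec$name, n = nrow(cohort),
    n_consensus = if (ind$has_consensus) sum(ind$selected) else NA_integer_,
    n_recall = sum(ind$recalled),
    n_sdc = sum(ind$sdc_detected),
    n_ic_selected = sum(ind$ic_selected),
    n_sdc_total = sum(cohort$outcome == "SDC"),
    n_ic_total = sum(cohort$outcome == "IC"),
    reader_fractions = ind$reader_fractions
  )
}

#' Screen-reading volume reduction of a scenario
#'
#' The percentage reduction in human screen-readings relative to the
#' two-readings-per-exam baseline:
#' `100 * (1 - (fraction_R1 + fraction_R2) / 2)`. AI readings never
#' count as human workload. With `cohort = NULL` (nominal mode) triage
#' band fractions are taken from exact decile widths — each decile holds
#' 10% of exams, so a band's fraction is its width divided by 10 and the
#' 7.5 split gives 25%; with a cohort, fractions are empirical.
#'
#' @param spec a `scenario_spec`.
#' @param cohort optional `screening_cohort` for empirical fractions.
#' @return unrounded percentage in `[0, 100]` (e.g. 62.5; published
#'   tables round half-up to integers).
#' @export
volume_reduction <- function(spec, cohort = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (!is.null(cohort)) {
    fr <- scenario_indicators(cohort, spec)$reader_fractions
  } else if (spec$mode == "TRIAGE") {
    w <- (spec$bands$upper - spec$bands$lower) / 10
    fr <- c(r1 = sum(w[spec$bands$reading != "NEGATIVE"]),
            r2 = sum(w[spec$bands$reading == "DOUBLE"]))
  } else if (spec$mode == "AI_AS_READER") {
    fr <- c(r1 = 1, r2 = 0)
  } else {
    fr <- c(r1 = 0, r2 = 0)
  }
  100 * (1 - (fr[["r1"]] + fr[["r2"]]) / 2)
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %s (n = %d)\n", x$name, x$n))
  cat(sprintf("  consensus %s, recall %s, SDC %d/%d, IC selected %d/%d\n",
              if (is.na(x$n_consensus)) "-" else x$n_consensus,
              x$n_recall, x$n_sdc, x$n_sdc_total,
              x$n_ic_selected, x$n_ic_total))
  invisible(x)
}
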