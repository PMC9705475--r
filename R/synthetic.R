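#' @title Synthetic screening cohorts
#'
#' @description
#' Generates synthetic cohorts whose marginal structure matches a large
#' population-based double-reading screening program: roughly 123,000
#' examinations from about 48,000 women (2-3 rounds each), about 10% of
#' exams per AI decile, a per-reader positive-interpretation rate of
#' 5.8%, consensus 8.8%, recall 3.2%, 6.1 screen-detected and 1.7
#' interval cancers per 1000 examinations, with cancers concentrated at
#' high AI scores. All reader-model parameters are calibrated in closed
#' form from those targets; see [calibrate_params()].
#' @name synthetic_cohort
NULL

# default decile distribution of screen-detected cancers: band totals
# 17 (deciles 1-5), 16 (6-7), 66 (8-9), 653 (decile 10) out of 752,
# spread uniformly within each band
DEFAULT_SCORE_DIST_SDC <- c(rep(17 / 5, 5), rep(8, 2), rep(33, 2), 653) / 752

# interval cancers: monotone increasing suspicion, less extreme than SDC
DEFAULT_SCORE_DIST_IC <- c(3, 4, 5, 6, 7, 8, 10, 12, 15, 30) / 100

DEFAULT_TARGETS <- list(
  reader_positive_rate = 0.058,
  consensus_rate = 0.088,
  recall_rate = 0.032,
  sdc_single_reader_fraction = 0.23
)

#' Generative parameters for a synthetic screening cohort
#'
#' Bundles the prevalences, AI-score distributions and reader-model
#' parameters that drive [generate_cohort()]. Reader-model parameters
#' left `NULL` are filled by [calibrate_params()] against `targets`
#' (defaults: per-reader positive rate 5.8%, consensus 8.8%, recall
#' 3.2%, and 23% of screen-detected cancers positive by only one
#' reader).
#'
#' @param n_exams target number of examinations (default 122969).
#' @param prop_three_exams probability a woman contributes three (vs
#'   two) screening rounds; the default 0.5685 makes the expected woman
#'   count for the default `n_exams` about 47,877.
#' @param sdc_rate,ic_rate per-exam prevalence of screen-detected and
#'   interval cancer (defaults 0.00611 and 0.00167).
#' @param score_dist_negative,score_dist_sdc,score_dist_ic probability
#'   vectors over AI deciles 1..10 for each outcome class. Defaults:
#'   uniform for non-cancer exams; screen-detected cancers heavily
#'   concentrated in decile 10; interval cancers intermediate.
#' @param reader_positive_rate probability a reader scores 2+ on a
#'   non-cancer exam (calibrated if `NULL`).
#' @param reader_sensitivity probability a reader scores 2+ on a
#'   screen-detected cancer (calibrated if `NULL`).
#' @param reader_correlation phi correlation between the two readers'
#'   positivity on the same non-cancer exam, realised by a mixture
#'   construction (calibrated if `NULL`).
#' @param recall_given_consensus_negative probability a
#'   consensus-discussed non-cancer exam is recalled (calibrated if
#'   `NULL`).
#' @param ic_recall_rate probability a consensus-discussed
#'   interval-cancer prior exam is recalled as a false positive
#'   (default 0: interval cancers follow a screening-negative exam).
#' @param positive_score_dist distribution of interpretation scores
#'   2..5 given a positive reader (default c(0.5, 0.25, 0.15, 0.1));
#'   only the 2+ threshold matters downstream.
#' @param seed master random seed (integer).
#' @param targets named list of calibration targets, see
#'   [calibrate_params()].
#' @return an object of class `cohort_params`.
#' @export
cohort_params <- function(n_exams = 122969L,
                          prop_three_exams = 0.5685,
                          sdc_rate = 0.00611,
                          ic_rate = 0.00167,
                          score_dist_negative = rep(0.1, 10),
                          score_dist_sdc = DEFAULT_SCORE_DIST_SDC,
                          score_dist_ic = DEFAULT_SCORE_DIST_IC,
                          reader_positive_rate = NULL,
                          reader_sensitivity = NULL,
                          reader_correlation = NULL,
                          recall_given_consensus_negative = NULL,
                          ic_recall_rate = 0,
                          positive_score_dist = c(0.5, 0.25, 0.15, 0.1),
                          seed = 1L,
                          targets = DEFAULT_TARGETS) {
  stopifnot(n_exams >= 0, is_prob(prop_three_exams), is_prob(sdc_rate),
            is_prob(ic_rate), is_prob(ic_recall_rate))
  if (sdc_rate + ic_rate >= 1) abort("sdc_rate + ic_rate must be < 1")
  check_prob_vector(score_dist_negative, "score_dist_negative")
  check_prob_vector(score_dist_sdc, "score_dist_sdc")
  check_prob_vector(score_dist_ic, "score_dist_ic")
  check_prob_vector(positive_score_dist, "positive_score_dist", len = 4L)

  params <- structure(list(
    n_exams = as.integer(n_exams),
    prop_three_exams = prop_three_exams,
    sdc_rate = sdc_rate, ic_rate = ic_rate,
    score_dist_negative = score_dist_negative,
    score_dist_sdc = score_dist_sdc,
    score_dist_ic = score_dist_ic,
    reader_positive_rate = reader_positive_rate,
    reader_sensitivity = reader_sensitivity,
    reader_correlation = reader_correlation,
    recall_given_consensus_negative = recall_given_consensus_negative,
    ic_recall_rate = ic_recall_rate,
    positive_score_dist = positive_score_dist,
    seed = as.integer(seed)
  ), class = "cohort_params")

  needs_cal <- is.null(reader_positive_rate) || is.null(reader_sensitivity) ||
    is.null(reader_correlation) || is.null(recall_given_consensus_negative)
  if (needs_cal) params <- calibrate_params(targets, params)
  for (fld in c("reader_positive_rate", "reader_sensitivity",
                "reader_correlation", "recall_given_consensus_negative")) {
    if (!is_prob(params[[fld]])) abort("%s must be a probability in [0,1]", fld)
  }
  params
}

#' Calibrate reader-model parameters to marginal targets
#'
#' Inverts the generative reader model in closed form so that a large
#' generated cohort reproduces the target marginals. With `d` the
#' screen-detected cancer prevalence, `i` the interval-cancer
#' prevalence, and `f` the target fraction of screen-detected cancers
#' positive by only one reader:
#' \itemize{
#'   \item reader sensitivity `s = (2 - 2f) / (2 - f)` (each reader
#'     Bernoulli(`s`) conditioned on at least one positive);
#'   \item non-cancer per-reader rate `p` solves
#'     `d / (2 - s) + (1 - d) p = reader target`;
#'   \item non-cancer consensus (union) probability
#'     `u = (consensus target - d) / (1 - d)`; the mixture correlation
#'     is `m = (2p - u - p^2) / (p - p^2)`, which requires
#'     `p <= u <= 2p - p^2` — a consensus target above the union bound
#'     `2p` (or below the single-reader rate) is infeasible;
#'   \item recall-given-consensus probability
#'     `q = (recall target - d) / ((1 - d - i) u)`.
#' }
#' Deterministic: no random draws are involved.
#'
#' @param targets named list with any of `reader_positive_rate`,
#'   `consensus_rate`, `recall_rate`, `sdc_single_reader_fraction`;
#'   missing entries default to the study-like values (0.058, 0.088,
#'   0.032, 0.23).
#' @param base a `cohort_params` object supplying prevalences and all
#'   non-calibrated fields.
#' @return `base` with the four reader-model parameters filled in.
#' @seealso [expected_rates()] for the forward closed forms.
#' @export
calibrate_params <- function(targets = DEFAULT_TARGETS, base = NULL) {
  if (is.null(base)) {
    base <- cohort_params(reader_positive_rate = 0, reader_sensitivity = 0,
                          reader_correlation = 0,
                          recall_given_consensus_negative = 0)
  }
  tg <- utils::modifyList(DEFAULT_TARGETS, as.list(targets))
  d <- base$sdc_rate
  i <- base$ic_rate
  f <- tg$sdc_single_reader_fraction
  if (!is_prob(f) || f >= 1) abort("sdc_single_reader_fraction must be in [0, 1)")
  s <- (2 - 2 * f) / (2 - f)
  marg_sdc <- if (d > 0) 1 / (2 - s) else 0

  p <- (tg$reader_positive_rate - d * marg_sdc) / (1 - d)
  if (!is_prob(p)) {
    abort("infeasible reader_positive_rate target %.4f given sdc_rate %.5f",
          tg$reader_positive_rate, d)
  }
  u <- (tg$consensus_rate - d) / (1 - d)
  if (u < p - 1e-12) {
    abort(paste0("infeasible consensus target %.4f: non-cancer consensus ",
                 "probability %.4f is below the single-reader rate %.4f"),
          tg$consensus_rate, u, p)
  }
  if (u > 2 * p - p^2 + 1e-12) {
    abort(paste0("infeasible consensus target %.4f: non-cancer consensus ",
                 "probability %.4f exceeds the independence union bound %.4f ",
                 "(would require negative reader correlation)"),
          tg$consensus_rate, u, 2 * p - p^2)
  }
  m <- if (p > 0 && p < 1) (2 * p - u - p^2) / (p - p^2) else 0
  m <- min(max(m, 0), 1)

  q <- if (u > 0) (tg$recall_rate - d) / ((1 - d - i) * u) else 0
  if (!is_prob(q)) {
    abort("infeasible recall target %.4f given sdc_rate %.5f and consensus target %.4f",
          tg$recall_rate, d, tg$consensus_rate)
  }
  base$reader_positive_rate <- p
  base$reader_sensitivity <- s
  base$reader_correlation <- m
  base$recall_given_consensus_negative <- q
  base
}

#' Expected marginal rates implied by cohort parameters
#'
#' The forward closed forms of the generative model: the population
#' values of the per-reader positive rate, consensus rate, recall rate
#' and cancer rates that [generate_cohort()] targets in expectation.
#' `calibrate_params(expected_rates(p), p)` is a fixed point.
#'
#' @param params a `cohort_params` object.
#' @return named list with `reader_positive_rate`, `consensus_rate`,
#'   `recall_rate`, `sdc_rate`, `ic_rate`,
#'   `sdc_single_reader_fraction`.
#' @export
expected_rates <- function(params) {
  d <- params$sdc_rate
  i <- params$ic_rate
  s <- params$reader_sensitivity
  p <- params$reader_positive_rate
  m <- params$reader_correlation
  q <- params$recall_given_consensus_negative
  marg_sdc <- if (d > 0) 1 / (2 - s) else 0
  p11 <- m * p + (1 - m) * p^2      # both readers positive, non-cancer exam
  u <- 2 * p - p11                  # at least one positive, non-cancer exam
  list(
    reader_positive_rate = d * marg_sdc + (1 - d) * p,
    consensus_rate = d + (1 - d) * u,
    recall_rate = d + (1 - d - i) * u * q + i * u * params$ic_recall_rate,
    sdc_rate = d,
    ic_rate = i,
    sdc_single_reader_fraction = if (s > 0) 2 * s * (1 - s) / (1 - (1 - s)^2) else NA_real_
  )
}

#' Generate a synthetic screening cohort
#'
#' Draws a full cohort from the generative model described in
#' [cohort_params()]: women are allocated 2-3 screening rounds; each
#' exam draws an outcome (screen-detected cancer, interval cancer,
#' negative), an AI decile from the outcome's score distribution and a
#' raw AI score uniform within the decile's interval; the two readers'
#' positivity is a correlated Bernoulli pair (mixture construction) on
#' non-cancer exams and an at-least-one-positive-conditioned pair on
#' screen-detected cancers; consensus follows the 2+ rule; recall is
#' forced for screen-detected cancers and drawn for consensus-discussed
#' negatives. One master seed spawns independent sub-streams per
#' generation stage, so the same `cohort_params` always yields a
#' byte-identical cohort file.
#'
#' @param params a `cohort_params` object.
#' @return a validated `screening_cohort` with `params$n_exams` rows.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  n <- params$n_exams
  if (n == 0L) return(as_cohort(empty_cohort_df()))

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(params$seed)
  stage_seed <- sample.int(2147483646L, 7L)

  # stage 1: women and exams per woman (draw generously, trim to n)
  set.seed(stage_seed[1L])
  n_women_max <- ceiling(n / 2) + 10L
  rounds <- 2L + stats::rbinom(n_women_max, 1L, params$prop_three_exams)
  cum <- cumsum(rounds)
  n_women <- which(cum >= n)[1L]
  rounds <- rounds[seq_len(n_women)]
  rounds[n_women] <- rounds[n_women] - (cum[n_women] - n)
  woman_id <- rep(sprintf("W%06d", seq_len(n_women)), times = rounds)
  exam_id <- sprintf("E%07d", seq_len(n))

  # stage 2: outcome
  set.seed(stage_seed[2L])
  outcome <- sample(OUTCOME_LEVELS[c(2L, 3L, 1L)], n, replace = TRUE,
                    prob = c(params$sdc_rate, params$ic_rate,
                             1 - params$sdc_rate - params$ic_rate))
  is_sdc <- outcome == "SDC"
  is_ic <- outcome == "IC"

  # stage 3: AI decile conditional on outcome
  set.seed(stage_seed[3L])
  decile <- integer(n)
  decile[!is_sdc & !is_ic] <- sample.int(10L, sum(!is_sdc & !is_ic), replace = TRUE,
                                         prob = params$score_dist_negative)
  if (any(is_sdc)) decile[is_sdc] <- sample.int(10L, sum(is_sdc), replace = TRUE,
                                                prob = params$score_dist_sdc)
  if (any(is_ic)) decile[is_ic] <- sample.int(10L, sum(is_ic), replace = TRUE,
                                              prob = params$score_dist_ic)

  # stage 4: raw score uniform within the decile interval (d-1, d] on a
  # micro-unit (1e-6) grid, so the CSV representation is bit-exact
  set.seed(stage_seed[4L])
  micro <- sample.int(1000000L, n, replace = TRUE) - 1L
  ai_raw <- (decile * 1000000L - micro) / 1e6

  # stage 5: reader positivity pair
  set.seed(stage_seed[5L])
  r1_pos <- logical(n)
  r2_pos <- logical(n)
  nc <- which(!is_sdc)                       # non-cancer reader model (incl. IC)
  if (length(nc)) {
    p <- params$reader_positive_rate
    m <- params$reader_correlation
    shared <- stats::runif(length(nc)) < m
    common <- stats::runif(length(nc)) < p
    ind1 <- stats::runif(length(nc)) < p
    ind2 <- stats::runif(length(nc)) < p
    r1_pos[nc] <- ifelse(shared, common, ind1)
    r2_pos[nc] <- ifelse(shared, common, ind2)
  }
  sdc_idx <- which(is_sdc)                   # conditioned on >= 1 positive
  if (length(sdc_idx)) {
    s <- params$reader_sensitivity
    cell <- sample.int(3L, length(sdc_idx), replace = TRUE,
                       prob = c(s^2, s * (1 - s), s * (1 - s)))
    r1_pos[sdc_idx] <- cell != 3L
    r2_pos[sdc_idx] <- cell != 2L
  }

  # stage 6: interpretation scores (positive -> 2..5, negative -> 1)
  set.seed(stage_seed[6L])
  r1_score <- rep(1L, n)
  r2_score <- rep(1L, n)
  r1_score[r1_pos] <- sample(2:5, sum(r1_pos), replace = TRUE,
                             prob = params$positive_score_dist)
  r2_score[r2_pos] <- sample(2:5, sum(r2_pos), replace = TRUE,
                             prob = params$positive_score_dist)

  consensus <- r1_pos | r2_pos

  # stage 7: recall
  set.seed(stage_seed[7L])
  recall <- logical(n)
  recall[is_sdc] <- TRUE
  neg_cons <- which(!is_sdc & !is_ic & consensus)
  recall[neg_cons] <- stats::runif(length(neg_cons)) <
    params$recall_given_consensus_negative
  ic_cons <- which(is_ic & consensus)
  if (length(ic_cons) && params$ic_recall_rate > 0) {
    recall[ic_cons] <- stats::runif(length(ic_cons)) < params$ic_recall_rate
  }

  as_cohort(data.frame(
    exam_id = exam_id, woman_id = woman_id,
    ai_raw = ai_raw, ai_score = decile,
    r1_score = r1_score, r2_score = r2_score,
    consensus = consensus, recall = recall,
    outcome = outcome, stringsAsFactors = FALSE
  ))
}

#' @export
print.cohort_params <- function(x, ...) {
  cat(sprintf("<cohort_params> n_exams=%d seed=%d\n", x$n_exams, x$seed))
  cat(sprintf("  sdc_rate=%.5f ic_rate=%.5f\n", x$sdc_rate, x$ic_rate))
  cat(sprintf(
    "  reader: positive_rate=%.4f sensitivity=%.4f correlation=%.4f recall|consensus=%.4f\n",
    x$reader_positive_rate, x$reader_sensitivity,
    x$reader_correlation, x$recall_given_consensus_negative
  ))
  invisible(x)
}
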