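#' @title Screening cohort data model
#'
#' @description
#' A screening cohort is one row per mammographic screening examination,
#' carrying the AI suspicion score, both radiologists' interpretation
#' scores, the consensus and recall flags from the real double-reading
#' setting, and the cancer outcome. It is the unit of all counterfactual
#' accounting in this package.
#'
#' Columns (the canonical CSV schema):
#' \describe{
#'   \item{exam_id}{opaque unique examination identifier (character).}
#'   \item{woman_id}{opaque identifier shared across a woman's screening
#'     rounds (character).}
#'   \item{ai_raw}{continuous AI suspicion score on the half-open
#'     interval (0, 10].}
#'   \item{ai_score}{integer decile score 1-10; always
#'     `ceiling(ai_raw)`, so decile d covers ai_raw in (d-1, d].}
#'   \item{r1_score, r2_score}{per-reader interpretation scores 1-5
#'     (1 negative for malignancy ... 5 high suspicion).}
#'   \item{consensus}{logical; TRUE iff the exam was discussed at the
#'     consensus meeting, which by program rule happens exactly when at
#'     least one reader scores 2 or higher.}
#'   \item{recall}{logical; TRUE iff the woman was recalled for further
#'     assessment. Recall implies consensus.}
#'   \item{outcome}{one of `"NEGATIVE"`, `"SDC"` (screen-detected
#'     cancer, which by definition follows a recall) or `"IC"` (the exam
#'     is the screening examination prior to an interval cancer).}
#' }
#' @name screening_cohort
NULL

COHORT_COLUMNS <- c(
  "exam_id", "woman_id", "ai_raw", "ai_score",
  "r1_score", "r2_score", "consensus", "recall", "outcome"
)
OUTCOME_LEVELS <- c("NEGATIVE", "SDC", "IC")

#' Construct a screening cohort from a data frame
#'
#' Coerces a data frame with the canonical columns (see
#' [screening_cohort]) to a validated `screening_cohort` object.
#'
#' @param df data frame with the columns listed under [screening_cohort].
#'   `consensus` and `recall` may be logical or 0/1.
#' @param strict if TRUE (default) any invariant violation aborts with a
#'   message naming the offending exams; if FALSE violating rows are
#'   dropped and counted in the `"dropped"` attribute of the result.
#' @return a `screening_cohort` (a data frame subclass).
#' @seealso [validate_cohort()], [read_cohort()]
#' @export
as_cohort <- function(df, strict = TRUE) {
  missing_cols <- setdiff(COHORT_COLUMNS, names(df))
  if (length(missing_cols)) {
    abort("missing required column(s): %s", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[COHORT_COLUMNS]
  df$exam_id <- as.character(df$exam_id)
  df$woman_id <- as.character(df$woman_id)
  for (col in c("ai_raw")) df[[col]] <- as.numeric(df[[col]])
  for (col in c("ai_score", "r1_score", "r2_score")) df[[col]] <- as.integer(df[[col]])
  for (col in c("consensus", "recall")) {
    v <- df[[col]]
    if (!is.logical(v)) v <- as.integer(v) > 0L
    df[[col]] <- v
  }
  df$outcome <- as.character(df$outcome)
  rownames(df) <- NULL

  cohort <- structure(df, class = c("screening_cohort", "data.frame"))
  viol <- validate_cohort(cohort)
  if (nrow(viol)) {
    if (strict) {
      abort(
        "cohort invariant violation(s):\n%s",
        paste(sprintf("  [%s] exam_id=%s", viol$rule, viol$exam_id), collapse = "\n")
      )
    }
    keep <- !(cohort$exam_id %in% viol$exam_id)
    dropped <- sum(!keep)
    cohort <- structure(df[keep, , drop = FALSE], class = c("screening_cohort", "data.frame"))
    rownames(cohort) <- NULL
    attr(cohort, "dropped") <- dropped
    message(sprintf("as_cohort: dropped %d invalid row(s)", dropped))
  }
  cohort
}

#' Validate a screening cohort
#'
#' Checks every examination against the cohort invariants: score ranges,
#' the decile rule `ai_score == ceiling(ai_raw)`, the consensus rule
#' (discussed iff a reader scored 2+), recall implying consensus,
#' screen-detected cancer implying recall, unique exam identifiers, and
#' legal outcome labels.
#'
#' @param cohort a `screening_cohort` or data frame with the canonical
#'   columns.
#' @return data frame with columns `exam_id` and `rule`, one row per
#'   violated invariant; zero rows iff the cohort is valid.
#' @export
validate_cohort <- function(cohort) {
  viol <- list()
  add <- function(mask, rule) {
    mask[is.na(mask)] <- TRUE
    if (any(mask)) {
      viol[[length(viol) + 1L]] <<- data.frame(
        exam_id = cohort$exam_id[mask], rule = rule,
        stringsAsFactors = FALSE
      )
    }
  }
  if (nrow(cohort) == 0L) {
    return(data.frame(exam_id = character(), rule = character(), stringsAsFactors = FALSE))
  }
  add(duplicated(cohort$exam_id) | duplicated(cohort$exam_id, fromLast = TRUE),
      "duplicate_exam_id")
  add(!(cohort$ai_raw > 0 & cohort$ai_raw <= 10), "ai_raw_range")
  add(!(cohort$ai_score %in% 1:10), "ai_score_range")
  add(cohort$ai_score != ceiling(cohort$ai_raw), "score_not_ceiling")
  add(!(cohort$r1_score %in% 1:5), "r1_score_range")
  add(!(cohort$r2_score %in% 1:5), "r2_score_range")
  add(!(cohort$outcome %in% OUTCOME_LEVELS), "outcome_value")
  add(cohort$consensus != (cohort$r1_score >= 2L | cohort$r2_score >= 2L),
      "consensus_rule")
  add(cohort$recall & !cohort$consensus, "recall_requires_consensus")
  add(cohort$outcome == "SDC" & !cohort$recall, "sdc_requires_recall")
  if (!length(viol)) {
    return(data.frame(exam_id = character(), rule = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, viol)
  rownames(out) <- NULL
  out
}

#' Read a screening cohort from CSV
#'
#' Reads the canonical comma-separated cohort format (header required,
#' booleans encoded 0/1, outcome values NEGATIVE/SDC/IC) and validates
#' it.
#'
#' @param path path to a CSV file.
#' @param strict if TRUE (default) abort on any invariant violation or
#'   unparsable row; if FALSE drop offending rows with a message and
#'   record the count in the `"dropped"` attribute.
#' @return a validated `screening_cohort`.
#' @export
read_cohort <- function(path, strict = TRUE) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = TRUE)
  missing_cols <- setdiff(COHORT_COLUMNS, names(raw))
  if (length(missing_cols)) {
    abort("cohort file %s: missing required column(s): %s",
          path, paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0L) {
    return(as_cohort(empty_cohort_df()))
  }
  if (anyDuplicated(raw$exam_id)) {
    dup <- unique(raw$exam_id[duplicated(raw$exam_id)])
    abort("cohort file %s: duplicate exam_id(s): %s",
          path, paste(utils::head(dup, 5L), collapse = ", "))
  }
  num_cols <- c("ai_raw", "ai_score", "r1_score", "r2_score", "consensus", "recall")
  parsed <- lapply(raw[num_cols], function(v) suppressWarnings(as.numeric(v)))
  bad_row <- Reduce(`|`, lapply(parsed, is.na))
  if (any(bad_row)) {
    if (strict) {
      abort("cohort file %s: unparsable numeric value(s) in row(s) for exam_id: %s",
            path, paste(utils::head(raw$exam_id[bad_row], 5L), collapse = ", "))
    }
    raw <- raw[!bad_row, , drop = FALSE]
    parsed <- lapply(parsed, function(v) v[!bad_row])
    message(sprintf("read_cohort: dropped %d unparsable row(s)", sum(bad_row)))
  }
  df <- data.frame(
    exam_id = raw$exam_id, woman_id = raw$woman_id,
    ai_raw = parsed$ai_raw, ai_score = as.integer(parsed$ai_score),
    r1_score = as.integer(parsed$r1_score), r2_score = as.integer(parsed$r2_score),
    consensus = parsed$consensus > 0, recall = parsed$recall > 0,
    outcome = raw$outcome, stringsAsFactors = FALSE
  )
  out <- as_cohort(df, strict = strict)
  if (!strict) {
    attr(out, "dropped") <- sum(bad_row) + (attr(out, "dropped") %||% 0L)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_cohort_df <- function() {
  data.frame(
    exam_id = character(), woman_id = character(),
    ai_raw = numeric(), ai_score = integer(),
    r1_score = integer(), r2_score = integer(),
    consensus = logical(), recall = logical(),
    outcome = character(), stringsAsFactors = FALSE
  )
}

#' Write a screening cohort to CSV
#'
#' Writes the canonical cohort CSV: comma-separated, UTF-8, header row,
#' booleans as 0/1, `ai_raw` with six decimal places so that
#' `read_cohort(write_cohort(c))` round-trips bit-exactly for cohorts
#' produced by [generate_cohort()].
#'
#' @param cohort a `screening_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "screening_cohort") || is.data.frame(cohort))
  out <- data.frame(
    exam_id = cohort$exam_id, woman_id = cohort$woman_id,
    ai_raw = sprintf("%.6f", cohort$ai_raw),
    ai_score = cohort$ai_score,
    r1_score = cohort$r1_score, r2_score = cohort$r2_score,
    consensus = as.integer(cohort$consensus),
    recall = as.integer(cohort$recall),
    outcome = cohort$outcome, stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Baseline screening performance of a cohort
#'
#' The reference quantities of standard independent double reading:
#' consensus and recall percentages, screen-detected and interval cancer
#' rates per 1000 examinations, and the per-reader positive
#' (score 2+) rates. Pure functions of the cohort table.
#'
#' @param cohort a `screening_cohort`.
#' @return a list with counts (`n`, `n_women`, `n_consensus`, `n_recall`,
#'   `n_sdc`, `n_ic`) and rates (`consensus_pct`, `recall_pct`,
#'   `sdc_per1000`, `ic_per1000`, `r1_positive_rate`,
#'   `r2_positive_rate`, `reader_positive_rate`), unrounded.
#' @export
cohort_rates <- function(cohort) {
  n <- nrow(cohort)
  if (n == 0L) abort("cohort is empty; baseline rates undefined")
  list(
    n = n,
    n_women = length(unique(cohort$woman_id)),
    n_consensus = sum(cohort$consensus),
    n_recall = sum(cohort$recall),
    n_sdc = sum(cohort$outcome == "SDC"),
    n_ic = sum(cohort$outcome == "IC"),
    consensus_pct = 100 * mean(cohort$consensus),
    recall_pct = 100 * mean(cohort$recall),
    sdc_per1000 = 1000 * mean(cohort$outcome == "SDC"),
    ic_per1000 = 1000 * mean(cohort$outcome == "IC"),
    r1_positive_rate = mean(cohort$r1_score >= 2L),
    r2_positive_rate = mean(cohort$r2_score >= 2L),
    reader_positive_rate = mean(c(cohort$r1_score >= 2L, cohort$r2_score >= 2L))
  )
}

#' @export
print.screening_cohort <- function(x, ...) {
  cat(sprintf(
    "<screening_cohort> %d examinations from %d women\n",
    nrow(x), length(unique(x$woman_id))
  ))
  if (nrow(x)) {
    r <- cohort_rates(x)
    cat(sprintf(
      "  consensus %.1f%%, recall %.1f%%, SDC %.1f/1000, IC %.1f/1000\n",
      r$consensus_pct, r$recall_pct, r$sdc_per1000, r$ic_per1000
    ))
  }
  invisible(x)
}
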