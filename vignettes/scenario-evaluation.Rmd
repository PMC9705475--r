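---
title: "Counterfactual reading scenarios in mammographic screening: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counterfactual reading scenarios in mammographic screening: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammotriage)
```

## The setting and the counterfactual model

In biennial population screening with independent double reading, two
radiologists each score an examination 1–5; a score of 2 or higher by
either sends the exam to a consensus meeting, which decides on recall.
Screen-detected cancer (SDC) is cancer diagnosed after a recall;
interval cancer (IC) surfaces within 24 months of a negative screen (or
6–24 months after a false positive), so its screening examination is a
missed opportunity. An AI system scores each exam on deciles 1–10
(about 10% of exams per decile) with a continuous raw score underneath;
`mammotriage` fixes the raw scale to (0, 10] with
`ai_score = ceiling(ai_raw)`, so decile *d* is the interval (d−1, d]
and a split at 7.5 is well defined. The raw scale is a package
convention — vendors do not publish one — and only band membership ever
matters.

A *reading scenario* reallocates who reads what, and is replayed
against the recorded scores and outcomes of a completed double-reading
cohort:

* **Triage** (`triage_scenario()`): raw-score bands are read by nobody,
  by R1 only, or by both readers. An exam enters the scenario's
  consensus pool if its band's reader(s) scored it 2+ (for single
  reading, R1 alone decides).
* **AI as second reader** (`ai_reader_scenario()`): R1 reads
  everything; the AI flags the top fraction of raw scores or a whole
  top decile; the consensus pool is the union.
* **Standalone AI** (`ai_standalone_scenario()`): the AI selects a
  fixed fraction directly for recall; no human reads.

The counterfactual accounting is deliberately conservative about what
retrospective data can support: scenario recalls are the
consensus-selected exams that were *actually* recalled under double
reading, and scenario SDC are verified cancers among those recalls —
the engine never invents recalls that did not happen (for standalone
AI, the selection itself is the recall set, so some selected cases were
not recalled in reality). Interval cancers are counted when the
scenario *selects their prior exam for consensus*: these are the cases
with the greatest potential to be converted to screen-detected if the
AI score were available at consensus. One caveat is asymmetric:
AI-as-reader scenarios put exams into consensus that no radiologist
flagged, and crediting their recalled cancers may overestimate
detection; this caveat is surfaced in the report documentation, not
"corrected", because no retrospective correction exists.

Two sensitivity definitions bracket a prospective expectation: variant
A counts only scenario SDC as true positives (missed SDC and all IC are
false negatives); variant B also credits selected IC as true positives.
B ≥ A always. Confidence intervals for sensitivity use the
logit-transformed formula — L = ln(tp/fn), SE = sqrt(1/tp + 1/fn),
bounds logit⁻¹(L ∓ z·SE) — which reproduces the reference double-reading
value 78.6% (75.9–81.1) from (tp, fn) = (752, 205) exactly at one
decimal. When a cell is zero the log odds are undefined; the interval
falls back to adding 0.5 to both counts and the estimate is flagged
`degenerate` rather than dropped.

*Potential rates* move every selected IC into the scenario's SDC pool:
potential SDC/1000 = (n_sdc + n_ic_selected)/n × 1000, potential
IC/1000 = (n_ic_total − n_ic_selected)/n × 1000. Their sum is
(n_sdc + n_ic_total)/n × 1000 regardless of how many transfer, which
the tests assert as a conservation law. Interval estimates use the
Wilson score method; published analyses adjust these intervals for
repeated rounds of the same woman without stating a method, so the
package default is the plain Wilson interval (which matches the
published baseline intervals at printed precision) and a design-effect
adjustment by `woman_id` (`design_effect()`, z inflated by √DEFF) is
available behind `cluster_adjust = TRUE`, clearly labelled in output.
Neither option claims to be "the" original adjustment.

*Volume reduction* is 100 × (1 − (f_R1 + f_R2)/2) against the
two-readings-per-exam baseline; AI readings are never human workload.
Nominal values use exact decile widths (each decile 10%, the 7.5 split
25%), giving the analytic column 50, 50, 50, 70, 90, 75, 25, 35, 62.5,
62.5, 100 for the built-in catalog `S1`–`S11`; reported tables round
half-up (62.5 → 63). Half-up rounding (`round_half_up()`) is used for
*all* reported values because it reproduces every published baseline
figure; `base::round()`'s banker's rounding does not.

## Tunable parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `sdc_rate`, `ic_rate` | cancer prevalence per exam | 0.00611, 0.00167 | reference program rates (6.1 and 1.7 per 1000) |
| `reader_positive_rate` target | per-reader score-2+ rate | 0.058 | reference per-reader positive rate |
| `consensus_rate` target | union of the two readers | 0.088 | reference consensus load |
| `recall_rate` target | recalls per exam | 0.032 | reference recall rate |
| `sdc_single_reader_fraction` | SDC flagged by exactly one reader | 0.23 | reported single-reader detection share |
| `score_dist_sdc` | SDC decile distribution | 17/16/66/653 of 752 across bands 1–5 / 6–7 / 8–9 / 10, uniform within band | recoverable from the published per-band SDC counts |
| `score_dist_ic` | IC decile distribution | monotone, 30% in decile 10 | plausible intermediate concentration; no published per-band IC-by-score table exists without also fixing the IC×reader joint |
| `score_dist_negative` | non-cancer deciles | uniform 0.1 | the AI system targets equal deciles |
| `prop_three_exams` | women with 3 (vs 2) rounds | 0.5685 | yields ≈ 47,877 women for 122,969 exams |
| `ic_recall_rate` | false-positive recall of IC priors | 0 | ICs follow screening-negative exams by default |

## Calibration closed forms

Reader behaviour is the only genuinely latent part of the model, and it
is calibrated analytically (`calibrate_params()`, no optimisation), with
d = `sdc_rate`, i = `ic_rate`, f = single-reader fraction:

* SDC reads: each reader Bernoulli(s) conditioned on at least one
  positive (SDC is defined via recall, so a positive reader is forced).
  P(exactly one | ≥1) = 2(1−s)/(2−s) = f gives s = (2−2f)/(2−f) ≈ 0.870,
  and a per-reader marginal of 1/(2−s) on SDC exams.
* Non-cancer reads: a mixture pair — with probability m both readers
  share one Bernoulli(p) draw, otherwise independent — whose phi
  correlation is exactly m. The 5.8% marginal fixes
  p = (0.058 − d/(2−s))/(1−d) ≈ 0.0529; the 8.8% consensus target fixes
  the union u = (0.088 − d)/(1−d) ≈ 0.0824 and hence
  m = (2p − u − p²)/(p − p²) ≈ 0.41. Feasibility demands
  p ≤ u ≤ 2p − p²: under independence the union would be
  1 − (1 − 0.058)² ≈ 0.113, so the observed 8.8% forces positive
  reader correlation, and a consensus target above the union bound is
  rejected with the violated bound named.
* Recall: consensus-discussed non-cancer exams are recalled with
  q = (0.032 − d)/((1 − d − i)·u) ≈ 0.32.

`expected_rates()` is the forward map; calibration is its exact inverse,
and the fixed-point property is tested. Generation uses one master seed
that spawns per-stage sub-streams (women, outcomes, deciles, raw
scores, reader pairs, scores, recall), so adding a stage cannot perturb
earlier draws and identical parameters give byte-identical cohort
files. Raw scores are drawn on a 10⁻⁶ grid so the CSV round-trip is
bit-exact.

## What the generator does and does not emulate

It reproduces, at full size within three binomial standard errors: the
five marginal targets above, ≈10% of exams per decile, 2–3 exams per
woman, and cancers concentrated at high AI scores (so the qualitative
scenario ordering — detection falls as the double-read band narrows —
emerges). It deliberately does **not** reproduce three joints the
source text does not constrain:

* non-cancer reader positivity is independent of the AI score, so
  synthetic triage scenarios shed more consensus and recall volume than
  the study's (in reality, readers and AI flag the same exams);
* interval-cancer priors use the non-cancer reader model, so far fewer
  synthetic ICs are consensus-selected than in the study, where readers
  showed elevated (sub-recall) suspicion on missed cancers;
* raw scores are uniform within a decile, so top-fraction selections
  (AI as reader at 5.8%, standalone at 3.2%) capture fewer cancers than
  in reality, where cancers concentrate at the top of decile 10.

Passing tests on synthetic data therefore validate the *accounting
machinery and calibration*, not study-level scenario counts; every
published quantity that is a pure function of printed counts is instead
recomputed exactly from those counts in the test suite.

## Numerical and design choices

* Band intervals are upper-closed on the raw score; decile labels
  "1–5" = (0, 5], "6–7.5" = (5, 7.5], "7.6–10" = (7.5, 10].
* Top-fraction selection takes k = round(rate × n) exams (half-up) by
  descending raw score with deterministic `exam_id` tie-break.
* The decile-cutoff variant of AI-as-reader is primary for "AI selects
  score 10" (its empirical size ≈ 10% of exams); a 10%-top-fraction
  reading would differ only through within-decile ties.
* Strict validation is the default for file reads; lenient mode drops
  violating rows but counts them, because silent dropping hides
  calibration errors.
* Scenario results carry raw counts; all rounding happens at the
  reporting edge (`format()`), so conservation identities hold exactly.
* Problem sizes in the shipped analysis: the full 122,969-exam cohort
  for the drivers and the marginal-recovery test; 40–80-exam random
  cohorts (1000 replicates) for the engine-vs-enumeration oracle and
  property suites — small enough to enumerate by hand, numerous enough
  to exercise ties, empty selections and degenerate outcomes.

## Known limitations

Beyond the generator joints above: the package models neither reader
behaviour change when AI scores are visible (explicitly a prospective
question), nor consensus-meeting dynamics, nor per-breast or per-view
scores (reader scores are per exam), nor costs. The cluster adjustment
is a design-effect approximation, not a replication of any specific
published adjustment.
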