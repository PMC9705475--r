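#!/usr/bin/env Rscript
# Step 2: evaluate the 11 reading scenarios on the simulated cohort.
#
# Reads scratch/cohort.csv (from analysis/01_simulate.R), runs the
# counterfactual scenario engine for the full catalog, and writes the
# per-scenario rate table (consensus, recall, SDC, selected IC,
# potential rates with Wilson CIs, nominal volume reduction) and the
# two-variant sensitivity table with logit-transformed CIs.
#
# Usage: Rscript analysis/02_evaluate.R [--cohort <path>] [--cluster]

suppressPackageStartupMessages(library(mammotriage))

args <- commandArgs(trailingOnly = TRUE)
arg_val <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) && i < length(args)) args[i + 1L] else default
}
cohort_path <- arg_val("--cohort", "scratch/cohort.csv")
cluster <- "--cluster" %in% args

if (!file.exists(cohort_path)) {
  stop("cohort file not found: ", cohort_path,
       " (run analysis/01_simulate.R first)", call. = FALSE)
}
cohort <- read_cohort(cohort_path, strict = TRUE)
print(cohort)

dir.create("results", showWarnings = FALSE)
catalog <- scenario_catalog()

message("evaluating ", length(catalog), " scenarios on ", nrow(cohort), " exams")
for (spec in catalog) {
  res <- evaluate_scenario(cohort, spec)
  message(sprintf(
    "  %-4s consensus=%s recall=%d sdc=%d/%d ic_selected=%d/%d",
    res$name, if (is.na(res$n_consensus)) "-" else res$n_consensus,
    res$n_recall, res$n_sdc, res$n_sdc_total,
    res$n_ic_selected, res$n_ic_total
  ))
}

rates <- rates_report(cohort, catalog, cluster_adjust = cluster)
write.csv(as.data.frame(rates), "results/scenario_rates.csv", row.names = FALSE)

sens <- sensitivity_report(cohort, catalog)
write.csv(sens, "results/scenario_sensitivity.csv", row.names = FALSE)

if (requireNamespace("jsonlite", quietly = TRUE)) {
  jsonlite::write_json(
    list(rates = as.data.frame(rates), sensitivity = sens),
    "results/scenario_report.json", digits = NA, dataframe = "rows"
  )
}

cat("\n")
print(rates)
cat("\nTables written to results/scenario_rates.csv and results/scenario_sensitivity.csv\n")
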