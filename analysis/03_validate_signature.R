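#!/usr/bin/env Rscript

# Validate the frozen signature on the independent, platform-distorted
# cohort: no refitting, no renormalization - scores depend only on
# within-sample orderings, so the platform change is irrelevant by
# construction.

suppressPackageStartupMessages(library(irgpair))

sig <- read_signature("results/build/signature.tsv")
report <- jsonlite::read_json("results/build/report.json", simplifyVector = TRUE)
expr <- read_expression("results/data/validation_expression.tsv")
clin <- read_clinical("results/data/validation_clinical.tsv", time_unit = "years")

val <- run_validate(sig, report$cutoff, expr, clin)

dir.create("results/validation", recursive = TRUE, showWarnings = FALSE)
write.table(val$profile, "results/validation/risk_profile.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
km_tab <- rbind(
  data.frame(group = "high", time = val$km_high$time, survival = val$km_high$survival),
  data.frame(group = "low", time = val$km_low$time, survival = val$km_low$survival)
)
write.table(km_tab, "results/validation/km_curves.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(cutoff = report$cutoff, n_high = val$n_high, n_low = val$n_low,
       logrank_chisq = val$logrank_chisq, logrank_p = val$logrank_p),
  "results/validation/report.json", auto_unbox = TRUE, digits = NA
)

message("validation groups: ", val$n_high, " high / ", val$n_low, " low risk")
message("validation log-rank p: ", signif(val$logrank_p, 3))
message("artifacts in results/validation/")
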