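#!/usr/bin/env Rscript
# Stage 1: generate the default synthetic cohort — 140 subjects in five
# groups (Control 41, SSc 19, IPAH 30, SSc-PAH 42, SSc-PH-ILD 8), 20000
# probes with six planted correlated modules — and write it to disk in
# series-matrix form together with the clinical table and the ground truth.

library(edsig)

seed <- 7
out <- "results/cohort"

cfg <- cohort_config()
print(cfg)
co <- generate_cohort(cfg, seed = seed)
files <- write_cohort(co, out)

cat("\nCohort written to", out, "\n")
print(co$expr)
cat("Planted module sizes:\n")
print(table(co$truth$module_membership$module))
cat("\nSubjects with catheterization data:",
    sum(!is.na(co$clinical$days_cath_to_draw)), "\n")
cat("Within the 120-day window:",
    length(window_filter(co$clinical)), "\n")
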