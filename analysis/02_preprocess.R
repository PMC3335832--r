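#!/usr/bin/env Rscript
# Stage 2: preprocessing — per-sample median scaling to 256, log2
# transform, and the detection filter (detection p < 0.01 in at least one
# sample, gene symbol available). Writes the filtered log2 matrix.

library(edsig)

co <- read_cohort("results/cohort")
cat("Raw:", nrow(co$expr$values), "probes x", ncol(co$expr$values),
    "samples\n")

lx <- log2_transform(median_scale(co$expr))
cat("Per-sample median log2 after scaling (all probes):",
    round(median(apply(lx$values, 2, median)), 3), "\n")
prep <- preprocess_cohort(co$expr)
cat("After detection + symbol filter:", nrow(prep$values), "probes\n")

dir.create("results/preprocess", showWarnings = FALSE, recursive = TRUE)
write_series_matrix(prep, "results/preprocess/filtered_log2.tsv")
cat("Filtered matrix written to results/preprocess/filtered_log2.tsv\n")
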