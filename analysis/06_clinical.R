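#!/usr/bin/env Rscript
# Stage 6: clinical association. Correlates the EDS surrogate biomarker
# with hemodynamic severity within IPAH (coupled by construction) and
# SSc-PAH (decoupled), restricted to subjects catheterized within 120 days
# of blood draw; summarizes surrogate expression per group with 84%
# confidence intervals; stratifies by cardiac index at 2.2 L/min/m^2.

library(edsig)

co <- read_cohort("results/cohort")
prep <- preprocess_cohort(co$expr)
dir.create("results/clinical", showWarnings = FALSE, recursive = TRUE)

surro <- read.delim("results/discover/eds_surrogates.tsv")
probe <- surro$probe_id[1]
cat(sprintf("Surrogate biomarker: %s (%s), r = %.3f vs EDS centroid\n\n",
            surro$symbol[1], probe, surro$r[1]))

tabs <- list()
for (g in c("IPAH", "SSc-PAH")) {
  res <- biomarker_hemodynamics(prep, probe, co$clinical, group = g)
  tabs[[g]] <- res
  cat(sprintf("%s (n = %d in window):\n", g, res$n[1]))
  print(res, digits = 3)
  cat("\n")
}
write.table(do.call(rbind, tabs), "results/clinical/correlations.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Surrogate expression by group (mean and 84% CI):\n")
ci <- do.call(rbind, lapply(split(prep$values[probe, ],
                                  prep$samples$group), group_ci84))
ci <- cbind(group = rownames(ci), ci)
print(ci, digits = 3, row.names = FALSE)
write.table(ci, "results/clinical/group_ci84.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

strata <- dichotomize_ci(co$clinical)
cat("\nCardiac-index strata (cut 2.2 L/min/m^2):\n")
print(table(strata, useNA = "ifany"))
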