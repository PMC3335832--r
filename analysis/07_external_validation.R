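#!/usr/bin/env Rscript
# Stage 7: external validation. An independently seeded cohort plays the
# role of an external PBMC dataset: the discovered EDS gene list is embedded
# in a background of 550 random gene sets and scored with the simple
# difference metric for each disease-vs-control contrast, reporting the
# signature's PAGE z and its rank among all sets.

library(edsig)

eds_genes <- read_gmt("results/discover/signatures.gmt")$sets[[1]]
sig_coll <- read_gmt("results/discover/signatures.gmt")
# take the EDS-like signature: the one carrying the surrogate biomarker
surro <- read.delim("results/discover/eds_surrogates.tsv")
eds_name <- NULL
for (nm in names(sig_coll$sets)) {
  if (toupper(surro$symbol[1]) %in% sig_coll$sets[[nm]]) eds_name <- nm
}
eds_genes <- sig_coll$sets[[eds_name]]
cat(sprintf("Query signature: %s (%d genes)\n", eds_name, length(eds_genes)))

external <- generate_cohort(cohort_config(), seed = 1234)
prep <- preprocess_cohort(external$expr)
set.seed(99)
background <- random_gene_sets(unique(na.omit(prep$probes$symbol)), 550,
                               size_range = c(10, 200))

dir.create("results/external", showWarnings = FALSE, recursive = TRUE)
rows <- list()
for (g in c("SSc-PH-ILD", "IPAH", "SSc-PAH", "SSc")) {
  res <- score_signature_in_dataset(prep, g, "Control", eds_genes,
                                    background, signature_name = "EDS_QUERY")
  rows[[g]] <- cbind(contrast = sprintf("%s_vs_Control", g), res$signature)
  cat(sprintf("%-12s vs Control: Z = %7.2f, rank %d of %d sets\n",
              g, res$signature$Z, res$signature$rank, res$signature$n_sets))
}
out <- do.call(rbind, rows)
write.table(out, "results/external/eds_scores.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
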