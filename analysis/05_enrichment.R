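#!/usr/bin/env Rscript
# Stage 5: parametric gene-set enrichment. Scores the discovered signatures
# plus a random background collection with the z-ratio metric for each
# disease-vs-control contrast (the pathway-table view) and computes the
# per-sample landscape with group-averaged PAGE z-scores.

library(edsig)

co <- read_cohort("results/cohort")
prep <- preprocess_cohort(co$expr)
dir.create("results/enrich", showWarnings = FALSE, recursive = TRUE)

gene_z <- collapse_to_genes(zscore_within_sample(prep), by = prep)
sig_coll <- read_gmt("results/discover/signatures.gmt",
                     source = "discovered signatures")
set.seed(7)
background <- random_gene_sets(rownames(gene_z), 550, size_range = c(10, 200))
coll <- merge_collections(background, sig_coll)

for (g in c("IPAH", "SSc-PAH", "SSc", "SSc-PH-ILD")) {
  sA <- prep$samples$sample_id[prep$samples$group == g]
  sB <- prep$samples$sample_id[prep$samples$group == "Control"]
  tab <- score_collection(zratio_metric(gene_z, sA, sB), coll)
  nm <- sprintf("%s_vs_Control", g)
  write.table(tab, file.path("results/enrich", paste0(nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  top <- head(tab[tab$significant, ], 4)
  cat(sprintf("%-22s %d/%d sets significant at p <= 0.01; top: %s\n",
              nm, sum(tab$significant), nrow(tab),
              paste(sprintf("%s (Z = %.1f)", top$set, top$Z),
                    collapse = ", ")))
}

ls <- sample_landscape(gene_z, coll, groups = prep$samples$group)
cat("\nGroup-averaged landscape z for the discovered signatures:\n")
print(round(ls$group_mean[names(sig_coll$sets), ], 2))
write.table(data.frame(set = rownames(ls$group_mean), ls$group_mean,
                       check.names = FALSE),
            "results/enrich/landscape_group_mean.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
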