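#!/usr/bin/env Rscript
# Stage 3: detection-gated three-criterion differential expression
# (Welch p <= 0.01, BH FDR <= 0.1 over gated probes, geometric fold change
# >= 1.5) for each disease group versus controls, followed by the Venn
# partitioning of the significant gene lists by direction.

library(edsig)

co <- read_cohort("results/cohort")
prep <- preprocess_cohort(co$expr)
dir.create("results/de", showWarnings = FALSE, recursive = TRUE)

contrasts <- list(c("IPAH", "Control"), c("SSc-PAH", "Control"),
                  c("SSc", "Control"))
up <- list(); down <- list()
for (ct in contrasts) {
  res <- call_de(prep, ct[1], ct[2])
  nm <- sprintf("%s_vs_%s", ct[1], ct[2])
  write.table(res, file.path("results/de", paste0(nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%-22s tested %5d probes, significant %4d (%d genes up, %d down)\n",
              nm, sum(res$tested), sum(res$significant),
              length(significant_genes(res, "up")),
              length(significant_genes(res, "down"))))
  up[[ct[1]]] <- significant_genes(res, "up")
  down[[ct[1]]] <- significant_genes(res, "down")
}

for (dir_label in c("up", "down")) {
  parts <- venn_partition(if (dir_label == "up") up else down)
  cat(sprintf("\nVenn regions (%s-regulated genes):\n", dir_label))
  print(lengths(parts))
  venn_df <- data.frame(region = names(parts), n = lengths(parts),
                        genes = vapply(parts, paste, character(1),
                                       collapse = ","))
  write.table(venn_df,
              file.path("results/de", paste0("venn_", dir_label, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
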