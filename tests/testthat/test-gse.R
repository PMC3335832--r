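page_oracle <- function(values, genes) {
  # independent closed-form evaluation on the raw named vector
  hit <- intersect(genes, names(values))
  mu <- mean(values)
  delta <- sqrt(mean((values - mu)^2))
  Sm <- mean(values[hit])
  (Sm - mu) * sqrt(length(hit)) / delta
}

toy_gene_z <- function(n_genes = 50, n_samp = 12, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samp), n_genes, n_samp,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samp))))
  m
}

test_that("z-ratio metric is standardized and flags degenerate contrasts", {
  m <- toy_gene_z()
  met <- zratio_metric(m, colnames(m)[1:6], colnames(m)[7:12])
  expect_equal(mean(met$values), 0, tolerance = 1e-12)
  expect_equal(edsig:::sd_pop(met$values), 1, tolerance = 1e-12)
  expect_warning(deg <- zratio_metric(m, colnames(m)[1:6], colnames(m)[1:6]),
                 "degenerate")
  expect_true(all(deg$values == 0))
})

test_that("difference metric is a plain mean difference, shift-invariant", {
  m <- toy_gene_z()
  A <- colnames(m)[1:6]; B <- colnames(m)[7:12]
  met <- difference_metric(m, A, B)
  expect_equal(unname(met$values["G001"]),
               mean(m["G001", A]) - mean(m["G001", B]))
  expect_true(all(difference_metric(m, A, A)$values == 0))
  expect_equal(difference_metric(m + 5, A, B)$values, met$values,
               tolerance = 1e-12)
  m2 <- m; m2["G002", A] <- m2["G002", A] + 1
  expect_equal(unname(difference_metric(m2, A, B)$values["G002"]),
               unname(met$values["G002"]) + 1, tolerance = 1e-12)
})

test_that("page_score matches its closed form and handles edge sets", {
  vals <- (1:100 - mean(1:100)) / edsig:::sd_pop(as.numeric(1:100))
  names(vals) <- sprintf("G%03d", 1:100)
  met <- edsig:::metric_vector(vals, "custom", "toy")
  s <- page_score(met, names(vals)[91:100])
  expect_equal(s$Z, page_oracle(vals, names(vals)[91:100]), tolerance = 1e-12)
  whole <- page_score(met, names(vals))
  expect_equal(whole$Z, 0, tolerance = 1e-12)
  expect_equal(whole$p, 1, tolerance = 1e-12)
  tiny <- page_score(met, names(vals)[1:3])
  expect_false(tiny$reported)
  set.seed(12)
  for (i in 1:50) {
    v <- rnorm(sample(50:500, 1))
    names(v) <- sprintf("g%04d", seq_along(v))
    genes <- sample(names(v), sample(10:40, 1))
    s <- page_score(edsig:::metric_vector(v, "custom", "x"), genes)
    expect_equal(s$Z, page_oracle(v, genes), tolerance = 1e-12)
  }
})

test_that("PAGE null calibration holds on i.i.d. normal metrics", {
  set.seed(99)
  vals <- rnorm(4000)
  names(vals) <- sprintf("g%04d", seq_along(vals))
  met <- edsig:::metric_vector(vals, "custom", "null")
  p <- replicate(500, page_score(met, sample(names(vals), 20))$p)
  expect_lt(abs(mean(p < 0.01) - 0.01), 0.01)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("collection scoring preserves sign and ignores listing order", {
  co <- small_cohort(seed = 51)
  prep <- preprocess_cohort(co$expr)
  gene_z <- collapse_to_genes(zscore_within_sample(prep), by = prep)
  coll <- gene_set_collection(list(
    IR_DR = module_genes(co, "IR_DR"),
    IR_UR = module_genes(co, "IR_UR")))
  for (g in c("IPAH", "SSc-PAH", "SSc")) {
    sA <- prep$samples$sample_id[prep$samples$group == g]
    sB <- prep$samples$sample_id[prep$samples$group == "Control"]
    tab <- score_collection(zratio_metric(gene_z, sA, sB), coll)
    expect_lt(tab$Z[tab$set == "IR_DR"], 0)  # down in every disease group
    expect_gt(tab$Z[tab$set == "IR_UR"], 0)
  }
  sA <- prep$samples$sample_id[prep$samples$group == "IPAH"]
  sB <- prep$samples$sample_id[prep$samples$group == "Control"]
  met <- zratio_metric(gene_z, sA, sB)
  coll_rev <- gene_set_collection(rev(list(
    IR_DR = module_genes(co, "IR_DR"),
    IR_UR = module_genes(co, "IR_UR"))))
  t1 <- score_collection(met, coll)
  t2 <- score_collection(met, coll_rev)
  expect_equal(t1[order(t1$set), c("Z", "p")],
               t2[order(t2$set), c("Z", "p")], ignore_attr = TRUE)
  empty <- gene_set_collection(stats::setNames(list(), character(0)))
  expect_equal(nrow(score_collection(met, empty)), 0)
})

test_that("Z is antisymmetric under swapping the contrast groups", {
  co <- small_cohort(seed = 53)
  prep <- preprocess_cohort(co$expr)
  gene_z <- collapse_to_genes(zscore_within_sample(prep), by = prep)
  gene_l <- collapse_to_genes(prep)
  eds <- module_genes(co, "EDS")
  sA <- prep$samples$sample_id[prep$samples$group == "IPAH"]
  sB <- prep$samples$sample_id[prep$samples$group == "Control"]
  for (metric_fn in list(zratio_metric, difference_metric)) {
    mat <- if (identical(metric_fn, zratio_metric)) gene_z else gene_l
    zf <- page_score(metric_fn(mat, sA, sB), eds)$Z
    zr <- page_score(metric_fn(mat, sB, sA), eds)$Z
    expect_equal(zf, -zr, tolerance = 1e-10)
  }
})

test_that("landscape scores columns exactly as single-sample PAGE calls", {
  m <- toy_gene_z(n_genes = 80, n_samp = 8, seed = 5)
  coll <- gene_set_collection(list(S1 = rownames(m)[1:15],
                                   S2 = rownames(m)[40:60]))
  ls <- sample_landscape(m, coll, row_normalize = FALSE)
  for (j in c(1, 5)) {
    met <- edsig:::metric_vector(m[, j], "per_sample_z", colnames(m)[j])
    expect_equal(ls$Z["S1", j], page_score(met, rownames(m)[1:15])$Z,
                 tolerance = 1e-12)
  }
  # an all-zero sample profile scores zero for every set
  m0 <- m; m0[, 3] <- 0
  ls0 <- sample_landscape(m0, coll, row_normalize = FALSE)
  expect_true(all(ls0$Z[, 3] == 0))
})

test_that("EDS landscape is highest in PH groups, lowest in controls", {
  co <- small_cohort(seed = 57)
  prep <- preprocess_cohort(co$expr)
  gene_z <- collapse_to_genes(zscore_within_sample(prep), by = prep)
  coll <- gene_set_collection(list(EDS = module_genes(co, "EDS")))
  ls <- sample_landscape(gene_z, coll, groups = prep$samples$group)
  gm <- ls$group_mean["EDS", ]
  expect_gt(min(gm[c("IPAH", "SSc-PAH", "SSc-PH-ILD")]),
            max(gm[c("Control", "SSc")]))
})

test_that("signature Z is normal under label permutation", {
  co <- small_cohort(seed = 59)
  prep <- preprocess_cohort(co$expr)
  gene_z <- collapse_to_genes(zscore_within_sample(prep), by = prep)
  eds <- module_genes(co, "EDS")
  ids <- prep$samples$sample_id
  set.seed(101)
  zs <- replicate(300, {
    perm <- sample(ids)
    met <- zratio_metric(gene_z, perm[1:15], perm[16:35])
    page_score(met, eds)$Z
  })
  expect_gt(stats::ks.test(zs, "pnorm", mean(zs), sd(zs))$p.value, 0.01)
})

test_that("an external dataset with the planted signature ranks it on top", {
  co <- generate_cohort(small_config(), seed = 61)  # plays the external cohort
  prep <- preprocess_cohort(co$expr)
  set.seed(7)
  background <- random_gene_sets(
    unique(stats::na.omit(prep$probes$symbol)), 120, size_range = c(10, 80))
  res <- score_signature_in_dataset(prep, "IPAH", "Control",
                                    module_genes(co, "EDS"), background,
                                    signature_name = "EDS_QUERY")
  expect_true(res$signature$reported)
  expect_lte(res$signature$rank, ceiling(0.01 * res$signature$n_sets) + 1)
  expect_gt(res$signature$Z, 0)
  # genes absent from the universe -> unreported
  res2 <- score_signature_in_dataset(prep, "IPAH", "Control",
                                     sprintf("ZZZ%02d", 1:30), background)
  expect_false(res2$signature$reported)
})
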