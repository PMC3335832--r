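test_that("detection gate counts detected samples in the higher group", {
  exprA <- rep(10, 10); exprB <- rep(5, 8)
  detA8 <- c(rep(0.001, 8), rep(0.5, 2))   # 8/10 = 80%: boundary passes
  detA7 <- c(rep(0.001, 7), rep(0.5, 3))   # 7/10 fails
  detB <- rep(0.9, 8)
  expect_true(detection_gate(exprA, exprB, detA8, detB))
  expect_false(detection_gate(exprA, exprB, detA7, detB))
  # lower-mean group's detection is irrelevant
  expect_true(detection_gate(exprA, exprB, rep(0.001, 10), rep(0.99, 8)))
  # exact tie: either group passing suffices
  expect_true(detection_gate(rep(5, 4), rep(5, 4), rep(0.5, 4),
                             rep(0.001, 4)))
})

test_that("gate is monotone in the detection threshold", {
  set.seed(4)
  for (i in 1:20) {
    exprA <- rnorm(10, 6); exprB <- rnorm(10, 5)
    detA <- runif(10); detB <- runif(10)
    gates <- vapply(c(0.001, 0.01, 0.05, 0.2),
                    function(dp) detection_gate(exprA, exprB, detA, detB,
                                                detect_p = dp), logical(1))
    expect_true(all(diff(as.integer(gates)) >= 0))
  }
})

test_that("welch_t matches stats::t.test", {
  set.seed(7)
  for (i in 1:50) {
    a <- rnorm(sample(3:12, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1))
    w <- welch_t(a, b)
    ref <- t.test(a, b)
    expect_equal(w$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(w$df, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(w$p, ref$p.value, tolerance = 1e-12)
    sw <- welch_t(b, a)  # antisymmetry
    expect_equal(sw$t, -w$t, tolerance = 1e-12)
    expect_equal(sw$p, w$p, tolerance = 1e-12)
  }
  expect_equal(welch_t(c(1, 1, 1), c(1, 1, 1)), list(t = 0, df = NA_real_,
                                                     p = 1))
  expect_error(welch_t(c(1, 1), c(2, 2)), "constant")
})

test_that("row-wise Welch agrees with the scalar version", {
  set.seed(11)
  mat <- matrix(rnorm(200), 20, 10,
                dimnames = list(paste0("p", 1:20), paste0("s", 1:10)))
  rw <- edsig:::row_welch(mat, 1:4, 5:10)
  for (i in 1:20) {
    w <- welch_t(mat[i, 1:4], mat[i, 5:10])
    expect_equal(rw$t[i], w$t, tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(rw$p[i], w$p, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

brute_bh <- function(p) {
  m <- length(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(seq_len(m), function(j) {
      if (p[j] >= p[i]) m * p[j] / rank(p, ties.method = "max")[j] else Inf
    }, numeric(1))
    q[i] <- min(min(cand), 1)
  }
  q
}

test_that("bh_fdr reproduces the step-up procedure", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  set.seed(2)
  for (i in 1:25) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    q <- bh_fdr(p)
    expect_equal(q, brute_bh(p), tolerance = 1e-12)
    expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone in p
  }
})

test_that("geometric fold change is the log2 mean-difference ratio", {
  expect_equal(geometric_fold_change(c(4, 6), c(3, 5)), 2)
  expect_equal(geometric_fold_change(c(4, 6), c(4, 6)), 1)
  expect_equal(geometric_fold_change(c(8.585), c(8)), 2^0.585)
  expect_equal(2^0.585, 1.5, tolerance = 1e-3)
})

test_that("call_de flags planted probes and respects all three criteria", {
  co <- generate_cohort(power_config(n_probes = 1500), seed = 6)
  prep <- preprocess_cohort(co$expr)
  res <- call_de(prep, "IPAH", "Control")
  planted <- intersect(module_probes(co, "DEMOD"), res$probe_id)
  hit <- res$significant[match(planted, res$probe_id)]
  expect_gte(mean(hit), 0.9)
  expect_true(all(res$tested[res$significant]))
  sig <- res[res$significant, ]
  expect_true(all(sig$p <= 0.01 & sig$q <= 0.1 &
                    (sig$fold_change >= 1.5 | sig$fold_change <= 1 / 1.5)))
  expect_true(all(res$fold_change > 0))
  expect_error(call_de(prep, "IPAH", "nope"), "2 samples")
})

test_that("a probe failing only the fold-change criterion stays tested", {
  set.seed(5)
  n <- 60
  v <- rbind(shift = c(rnorm(n, 8.3, 0.05), rnorm(n, 8, 0.05)),
             null = rnorm(2 * n, 8, 0.05))
  colnames(v) <- paste0("s", seq_len(2 * n))
  det <- matrix(0.001, 2, 2 * n, dimnames = dimnames(v))
  x <- expr_set(v, detection_p = det,
                probes = data.frame(probe_id = rownames(v),
                                    symbol = c("A", "B")),
                samples = data.frame(sample_id = colnames(v),
                                     group = rep(c("g1", "g2"), each = n)),
                scale = "log2")
  res <- call_de(x, "g1", "g2")
  row <- res[res$probe_id == "shift", ]
  expect_true(row$tested)
  expect_lt(row$p, 0.01)           # criterion (i) passes
  expect_lt(row$fold_change, 1.5)  # criterion (iii) fails: 2^0.3 < 1.5
  expect_false(row$significant)
})

test_that("venn partition splits lists into disjoint regions", {
  out <- venn_partition(list(l1 = c("a", "b"), l2 = c("b", "c")))
  expect_equal(out$l1, "a")
  expect_equal(out$l2, "c")
  expect_equal(out$`l1&l2`, "b")
  same <- venn_partition(list(x = c("g1", "g2"), y = c("g1", "g2"),
                              z = c("g1", "g2")))
  expect_equal(same$`x&y&z`, c("g1", "g2"))
  expect_equal(sum(lengths(same)), 2)
  # region sizes always sum to the union
  set.seed(3)
  lists <- lapply(1:3, function(i) sample(letters, 10))
  names(lists) <- c("A", "B", "C")
  parts <- venn_partition(lists)
  expect_equal(sum(lengths(parts)), length(unique(unlist(lists))))
})

test_that("shared planted modules land in the Venn intersection", {
  co <- small_cohort(seed = 19)
  prep <- preprocess_cohort(co$expr)
  up <- list(
    IPAH = significant_genes(call_de(prep, "IPAH", "Control"), "up"),
    SScPAH = significant_genes(call_de(prep, "SSc-PAH", "Control"), "up"),
    SSc = significant_genes(call_de(prep, "SSc", "Control"), "up"))
  parts <- venn_partition(up)
  ir <- module_genes(co, "IR_UR")  # planted up in all three disease groups
  shared <- parts$`IPAH&SScPAH&SSc`
  expect_gt(length(intersect(shared, ir)) / length(ir), 0.8)
})
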