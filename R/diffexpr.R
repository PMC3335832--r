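# Three-criterion differential expression with a detection gate:
# (i) two-sided Welch t p <= 0.01, (ii) Benjamini-Hochberg FDR q <= 0.1
# computed over gated probes only, (iii) geometric-mean fold change >= 1.5
# (or <= 1/1.5). A probe is tested only if, in the group with the higher mean
# expression, at least 80% of samples have detection p < 0.01.

#' Detection gate for one probe
#'
#' A probe is eligible for testing when, in the group with the larger mean
#' log2 expression, the proportion of samples with detection p below
#' `detect_p` is at least `fraction`. When group means tie exactly, the gate
#' passes if either group meets the detection requirement.
#'
#' @param exprA,exprB log2 expression values per group.
#' @param detA,detB detection p-values per group.
#' @param detect_p detection p-value threshold.
#' @param fraction required detected fraction in the higher group.
#' @return logical flag.
#' @export
detection_gate <- function(exprA, exprB, detA, detB,
                           detect_p = 0.01, fraction = 0.8) {
  stopifnot(length(exprA) == length(detA), length(exprB) == length(detB),
            length(exprA) > 0, length(exprB) > 0)
  fracA <- mean(detA < detect_p)
  fracB <- mean(detB < detect_p)
  mA <- mean(exprA); mB <- mean(exprB)
  if (mA > mB) fracA >= fraction
  else if (mB > mA) fracB >= fraction
  else fracA >= fraction || fracB >= fraction
}

#' Welch's unequal-variance t-test
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list with `t`, `df` (Welch-Satterthwaite) and two-sided `p`.
#'   Two constant groups with equal means return `t = 0, p = 1` by
#'   convention; two constant groups with different means are an error.
#' @export
welch_t <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = NA_real_, p = 1))
    stopf("both groups constant with different means: variance undefined")
  }
  sa <- va / length(a); sb <- vb / length(b)
  t <- (mean(a) - mean(b)) / sqrt(sa + sb)
  df <- (sa + sb)^2 / (sa^2 / (length(a) - 1) + sb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Vectorized Welch over matrix rows (columns split into two groups).
row_welch <- function(mat, idxA, idxB) {
  nA <- length(idxA); nB <- length(idxB)
  A <- mat[, idxA, drop = FALSE]; B <- mat[, idxB, drop = FALSE]
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- rowSums((A - mA)^2) / (nA - 1)
  vB <- rowSums((B - mB)^2) / (nB - 1)
  sa <- vA / nA; sb <- vB / nB
  se2 <- sa + sb
  t <- (mA - mB) / sqrt(se2)
  df <- se2^2 / (sa^2 / (nA - 1) + sb^2 / (nB - 1))
  p <- 2 * stats::pt(-abs(t), df)
  both_const <- vA == 0 & vB == 0
  if (any(both_const)) {
    eq <- both_const & (mA == mB)
    t[eq] <- 0; p[eq] <- 1; df[eq] <- NA_real_
    bad <- both_const & (mA != mB)
    t[bad] <- NA_real_; p[bad] <- NA_real_; df[bad] <- NA_real_
  }
  list(mean_A = mA, mean_B = mB, t = t, df = df, p = p)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjusted p-values, `q_i = min_{p_j >= p_i} m * p_j / rank_j`
#' clipped to 1. Computed only over the p-values supplied (the caller
#' restricts to gated probes).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values in input order.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Fold change as a ratio of geometric means
#'
#' With log2 inputs, the geometric-mean ratio is `2^(mean(a) - mean(b))`.
#'
#' @param a,b log2 expression values per group.
#' @return positive fold change of A over B.
#' @export
geometric_fold_change <- function(a, b) 2^(mean(a) - mean(b))

#' Call differential expression between two groups
#'
#' Applies the detection gate, Welch tests on gated probes, BH FDR over the
#' gated tests only (the gate shrinks the testing universe before the FDR
#' step), and the geometric fold-change criterion.
#'
#' @param x an [expr_set()] on the log2 scale with detection p-values.
#' @param groupA,groupB group labels in `x$samples$group`. Direction and fold
#'   change are A relative to B.
#' @param detect_p,detect_fraction detection-gate parameters.
#' @param p_max,q_max,fc_min significance thresholds for criteria (i)-(iii).
#' @return data.frame of class `de_result`: probe, symbol, group means, fold
#'   change, t, df, p, q, `tested` and `significant` flags, direction.
#' @export
call_de <- function(x, groupA, groupB, detect_p = 0.01,
                    detect_fraction = 0.8, p_max = 0.01, q_max = 0.1,
                    fc_min = 1.5) {
  stopifnot(inherits(x, "expr_set"))
  if (x$scale != "log2") stopf("call_de expects a log2-scale expr_set")
  if (is.null(x$detection_p)) stopf("detection p-values required")
  idxA <- which(x$samples$group == groupA)
  idxB <- which(x$samples$group == groupB)
  if (length(idxA) < 2 || length(idxB) < 2) {
    stopf("each group needs >= 2 samples")
  }

  detA <- x$detection_p[, idxA, drop = FALSE] < detect_p
  detB <- x$detection_p[, idxB, drop = FALSE] < detect_p
  fracA <- rowMeans(detA); fracB <- rowMeans(detB)
  mA0 <- rowMeans(x$values[, idxA, drop = FALSE])
  mB0 <- rowMeans(x$values[, idxB, drop = FALSE])
  tested <- ifelse(mA0 > mB0, fracA >= detect_fraction,
                   ifelse(mB0 > mA0, fracB >= detect_fraction,
                          fracA >= detect_fraction | fracB >= detect_fraction))

  res <- data.frame(probe_id = rownames(x$values),
                    symbol = x$probes$symbol,
                    mean_A = mA0, mean_B = mB0,
                    fold_change = 2^(mA0 - mB0),
                    t = NA_real_, df = NA_real_, p = NA_real_, q = NA_real_,
                    tested = tested, significant = FALSE,
                    direction = ifelse(mA0 >= mB0, "up", "down"),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL

  if (any(tested)) {
    w <- row_welch(x$values[tested, , drop = FALSE], idxA, idxB)
    res$t[tested] <- w$t
    res$df[tested] <- w$df
    res$p[tested] <- w$p
    res$q[tested] <- bh_fdr(w$p)
    res$significant <- res$tested & !is.na(res$p) &
      res$p <= p_max & res$q <= q_max &
      (res$fold_change >= fc_min | res$fold_change <= 1 / fc_min)
  }
  attr(res, "contrast") <- c(groupA = groupA, groupB = groupB)
  class(res) <- c("de_result", "data.frame")
  res
}

#' Collapse a DE result to significant unique gene symbols
#'
#' A gene is significant if any of its probes is; symbols are deduplicated.
#'
#' @param res a `de_result` from [call_de()].
#' @param direction `"up"`, `"down"` or `"both"`.
#' @return character vector of gene symbols.
#' @export
significant_genes <- function(res, direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  keep <- res$significant & !is.na(res$symbol)
  if (direction != "both") keep <- keep & res$direction == direction
  sort(unique(res$symbol[keep]))
}

#' Partition gene lists into Venn regions
#'
#' Splits the union of the lists into the `2^k - 1` disjoint membership
#' regions. Region names join member list names with `&`.
#'
#' @param lists named list of >= 2 character vectors.
#' @return named list: region -> sorted gene vector (regions may be empty).
#' @export
venn_partition <- function(lists) {
  stopifnot(is.list(lists), length(lists) >= 2, !is.null(names(lists)))
  lists <- lapply(lists, unique)
  universe <- sort(unique(unlist(lists)))
  k <- length(lists)
  member <- vapply(lists, function(l) universe %in% l, logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1)
  out <- list()
  for (mask in seq_len(2^k - 1)) {
    bits <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1)))
    region <- paste(names(lists)[bits], collapse = "&")
    sel <- apply(member, 1, function(r) identical(unname(r), bits))
    out[[region]] <- universe[sel]
  }
  out
}
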