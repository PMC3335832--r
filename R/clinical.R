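# Clinical association: hemodynamic window filtering, Pearson correlation
# with the customary t-test on (r, n), group summaries with 84% confidence
# intervals, cardiac-index dichotomization, and ddCt relative quantification.

#' Subjects with hemodynamics inside the catheterization window
#'
#' @param clinical data.frame with `sample_id` and `days_cath_to_draw`.
#' @param max_days window half-width in days (120 = the conventional
#'   four-month reading).
#' @return character vector of sample ids with `0 <= days <= max_days`.
#' @export
window_filter <- function(clinical, max_days = 120) {
  stopifnot(is.data.frame(clinical),
            all(c("sample_id", "days_cath_to_draw") %in% names(clinical)))
  d <- clinical$days_cath_to_draw
  clinical$sample_id[!is.na(d) & d >= 0 & d <= max_days]
}

#' Pearson product-moment correlation
#'
#' @param x,y equal-length numeric vectors, `n >= 3`, both nonconstant;
#'   pairs with missing values are dropped.
#' @return the correlation coefficient r.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stopf("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stopf("constant input")
  stats::cor(x, y)
}

#' t-test of a correlation coefficient
#'
#' The customary test of `rho = 0` from (r, n):
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` with `n - 2` degrees of freedom,
#' two-sided.
#'
#' @param r Pearson correlation, `|r| <= 1`.
#' @param n number of pairs, `n >= 3`.
#' @return data.frame: r, n, t, df, p, exact_fit. `|r| = 1` yields `p = 0`
#'   with `exact_fit = TRUE`.
#' @export
correlation_test <- function(r, n) {
  stopifnot(abs(r) <= 1, n >= 3)
  df <- n - 2
  if (abs(r) == 1) {
    return(data.frame(r = r, n = n, t = Inf * sign(r), df = df, p = 0,
                      exact_fit = TRUE))
  }
  t <- r * sqrt(df) / sqrt(1 - r^2)
  data.frame(r = r, n = n, t = t, df = df, p = 2 * stats::pt(-abs(t), df),
             exact_fit = FALSE)
}

#' Correlate a surrogate biomarker with hemodynamic covariates
#'
#' Within one group, restricted to subjects passing the catheterization
#' window filter, correlates the surrogate probe's log2 expression with each
#' covariate and tests it.
#'
#' @param x an [expr_set()] on the log2 scale.
#' @param surrogate_probe probe id of the surrogate biomarker.
#' @param clinical clinical data.frame (see [generate_hemodynamics()]).
#' @param covariates covariate column names to test.
#' @param group group label to restrict to.
#' @param max_days window width passed to [window_filter()].
#' @return data.frame (covariate, group, n, r, t, df, p); covariates with
#'   fewer than 3 complete pairs are skipped with a warning.
#' @export
biomarker_hemodynamics <- function(x, surrogate_probe, clinical,
                                   covariates = c("RAmean", "CI", "PVRI",
                                                  "PA_sat"),
                                   group, max_days = 120) {
  stopifnot(inherits(x, "expr_set"))
  in_window <- window_filter(clinical, max_days = max_days)
  ids <- intersect(intersect(group_samples(x, group), in_window),
                   clinical$sample_id)
  expr <- x$values[surrogate_probe, ids]
  cl <- clinical[match(ids, clinical$sample_id), , drop = FALSE]
  rows <- list()
  for (v in covariates) {
    y <- cl[[v]]
    ok <- stats::complete.cases(expr, y)
    if (sum(ok) < 3) {
      warnf("covariate '%s' skipped in group '%s': fewer than 3 pairs", v,
            group)
      next
    }
    r <- pearson_r(expr[ok], y[ok])
    ct <- correlation_test(r, sum(ok))
    rows[[v]] <- data.frame(covariate = v, group = group, n = ct$n, r = ct$r,
                            t = ct$t, df = ct$df, p = ct$p,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group mean with 84% confidence interval
#'
#' Mean plus a t-based confidence interval at the 84% level: non-overlap of
#' two groups' 84% intervals is an approximate indicator of a significant
#' mean difference at the 0.05 level.
#'
#' @param values numeric vector for one group, `n >= 2`.
#' @param level confidence level.
#' @return data.frame: n, mean, lower, upper.
#' @export
group_ci84 <- function(values, level = 0.84) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stopf("need at least 2 values for a confidence interval")
  m <- mean(values)
  se <- stats::sd(values) / sqrt(n)
  half <- stats::qt((1 + level) / 2, df = n - 1) * se
  data.frame(n = n, mean = m, lower = m - half, upper = m + half)
}

#' Dichotomize subjects by cardiac index
#'
#' The low stratum (poorer prognosis) is `CI < threshold`; the boundary value
#' is assigned to the high stratum. Missing CI leaves the subject
#' unassigned (`NA`).
#'
#' @param clinical data.frame with `sample_id` and `CI`.
#' @param threshold cardiac-index cut in L/min/m^2.
#' @return named character vector sample_id -> `"low"`/`"high"`/`NA`.
#' @export
dichotomize_ci <- function(clinical, threshold = 2.2) {
  stopifnot(is.data.frame(clinical), "CI" %in% names(clinical))
  out <- ifelse(is.na(clinical$CI), NA_character_,
                ifelse(clinical$CI < threshold, "low", "high"))
  stats::setNames(out, clinical$sample_id)
}

#' Relative expression by the 2^-ddCt method
#'
#' `dCt = Ct_target - mean(Ct of control genes)` per sample;
#' `ddCt = dCt - dCt(calibrator)`; relative quantity `RQ = 2^-ddCt`.
#'
#' @param ct data.frame of Ct values, samples in rows; must contain a
#'   `sample_id` column, the target gene columns and all control genes.
#' @param targets character vector of target gene column names.
#' @param control_genes endogenous control gene columns.
#' @param calibrator `sample_id` of the calibrator sample.
#' @return data.frame sample_id x targets of relative quantities; the
#'   calibrator row is 1 for every target.
#' @export
ddct_relative_expression <- function(ct, targets,
                                     control_genes = c("GAPDH", "ACTB",
                                                       "PGK1"),
                                     calibrator) {
  stopifnot(is.data.frame(ct), "sample_id" %in% names(ct),
            all(targets %in% names(ct)))
  if (!all(control_genes %in% names(ct))) {
    stopf("missing control gene column(s): %s",
          paste(setdiff(control_genes, names(ct)), collapse = ", "))
  }
  ctrl <- as.matrix(ct[control_genes])
  if (anyNA(ctrl)) stopf("missing control Ct value")
  ctrl_mean <- rowMeans(ctrl)
  cal <- match(calibrator, ct$sample_id)
  if (is.na(cal)) stopf("calibrator sample '%s' not found", calibrator)
  out <- data.frame(sample_id = ct$sample_id, stringsAsFactors = FALSE)
  for (g in targets) {
    if (anyNA(ct[[g]])) stopf("missing Ct for target '%s'", g)
    dct <- ct[[g]] - ctrl_mean
    out[[g]] <- 2^-(dct - dct[cal])
  }
  out
}
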