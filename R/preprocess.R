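# Preprocessing: per-sample median scaling to 256, log2 transform,
# detection-based probe filtering, and the two z-transformations used for
# clustering/heatmaps and per-sample gene-set scoring.

#' Scale each sample to a common median intensity
#'
#' Multiplies every sample column by `target / median(column)` so each
#' sample's median intensity equals `target` (256 = 2^8 by default).
#'
#' @param x an [expr_set()] on the intensity scale.
#' @param target desired per-sample median intensity.
#' @return the scaled `expr_set`, still on the intensity scale.
#' @export
median_scale <- function(x, target = 256) {
  stopifnot(inherits(x, "expr_set"))
  if (x$scale != "intensity") stopf("median_scale expects intensity scale")
  med <- apply(x$values, 2, stats::median, na.rm = TRUE)
  if (any(med <= 0)) stopf("nonpositive sample median")
  x$values <- sweep(x$values, 2, target / med, `*`)
  x
}

#' Log2-transform intensities
#'
#' Values below 1 are floored to 1 before taking logs: the upstream pipeline
#' applies no background correction, so small positive intensities can occur
#' and would otherwise produce negative logs.
#'
#' @param x an [expr_set()] on the intensity scale.
#' @param floor lower bound applied before the log.
#' @return the `expr_set` on the log2 scale.
#' @export
log2_transform <- function(x, floor = 1) {
  stopifnot(inherits(x, "expr_set"))
  if (x$scale != "intensity") stopf("log2_transform expects intensity scale")
  v <- pmax(x$values, floor)
  if (any(v <= 0)) stopf("nonpositive values survive the floor")
  x$values <- log2(v)
  x$scale <- "log2"
  x
}

#' Expressed-probe filter
#'
#' Retains probes detected (detection p below `detect_p`) in at least
#' `min_samples` samples and, optionally, carrying a gene symbol.
#'
#' @param x an [expr_set()] with detection p-values.
#' @param detect_p detection p-value threshold.
#' @param min_samples minimum number of samples meeting the threshold.
#' @param require_symbol drop probes without a gene symbol.
#' @return character vector of retained probe ids (possibly empty).
#' @export
expressed_probe_filter <- function(x, detect_p = 0.01, min_samples = 1,
                                   require_symbol = TRUE) {
  stopifnot(inherits(x, "expr_set"))
  if (is.null(x$detection_p)) stopf("no detection p-values available")
  n_det <- rowSums(x$detection_p < detect_p, na.rm = TRUE)
  keep <- n_det >= min_samples
  if (require_symbol) {
    keep <- keep & !is.na(x$probes$symbol) & nzchar(x$probes$symbol)
  }
  rownames(x$values)[keep]
}

#' Z-transform each sample over a probe subset
#'
#' Centers and scales every sample column to mean 0, SD 1 (population SD)
#' over the given probe subset.
#'
#' @param x an [expr_set()] on the log2 scale.
#' @param probes probe ids defining the subset; default all probes.
#' @return an `expr_set` restricted to `probes`, scale `"zscore"`.
#' @export
zscore_within_sample <- function(x, probes = NULL) {
  stopifnot(inherits(x, "expr_set"))
  if (x$scale != "log2") stopf("zscore_within_sample expects log2 scale")
  if (!is.null(probes)) x <- subset_expr(x, probes = probes)
  mu <- colMeans(x$values)
  sdv <- apply(x$values, 2, sd_pop)
  if (any(sdv == 0)) stopf("constant sample column: cannot z-transform")
  x$values <- sweep(sweep(x$values, 2, mu, `-`), 2, sdv, `/`)
  x$scale <- "zscore"
  x
}

#' Z-transform each probe across samples
#'
#' Centers and scales every probe row to mean 0, SD 1 (population SD).
#' Constant rows are emitted as all-zeros with a warning — the display
#' convention for flat probes in heatmaps — and should be excluded from
#' variance ranking and enrichment input.
#'
#' @param x an [expr_set()] (any scale).
#' @return the `expr_set` with row-standardized values, scale `"zscore"`.
#' @export
zscore_across_samples <- function(x) {
  stopifnot(inherits(x, "expr_set"))
  mu <- rowMeans(x$values)
  sdv <- apply(x$values, 1, sd_pop)
  flat <- sdv == 0
  if (any(flat)) {
    warnf("%d constant probe row(s) emitted as zeros", sum(flat))
    sdv[flat] <- 1
  }
  x$values <- sweep(x$values, 1, mu, `-`) / sdv
  x$values[flat, ] <- 0
  x$scale <- "zscore"
  x
}

#' Standard preprocessing of a raw cohort
#'
#' Median-scales to 256, log2-transforms, and applies the expressed-probe
#' filter. Returns the filtered log2 `expr_set`; the z-scored variants are
#' derived from it where needed.
#'
#' @param x an [expr_set()] on the intensity scale with detection p-values.
#' @param target median-scaling target.
#' @param detect_p,min_samples,require_symbol see [expressed_probe_filter()].
#' @return filtered `expr_set` on the log2 scale.
#' @export
preprocess_cohort <- function(x, target = 256, detect_p = 0.01,
                              min_samples = 1, require_symbol = TRUE) {
  x <- log2_transform(median_scale(x, target = target))
  keep <- expressed_probe_filter(x, detect_p = detect_p,
                                 min_samples = min_samples,
                                 require_symbol = require_symbol)
  subset_expr(x, probes = keep)
}
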