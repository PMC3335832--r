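#' Expression set container
#'
#' Lightweight container for a probes x samples expression matrix with
#' parallel detection p-values, probe annotations and sample annotations.
#'
#' @param values numeric matrix, probes x samples; rownames are probe ids,
#'   colnames sample ids.
#' @param detection_p numeric matrix in \[0, 1\] with identical dimnames, or
#'   `NULL` when the source (e.g. an external series matrix) provides none.
#' @param probes data.frame with at least `probe_id` and `symbol` columns,
#'   one row per probe in matrix order. `symbol` may be `NA`.
#' @param samples data.frame with at least `sample_id` and `group` columns,
#'   one row per sample in matrix order.
#' @param scale one of `"intensity"`, `"log2"`, `"zscore"`.
#' @return an object of class `expr_set`.
#' @export
expr_set <- function(values, detection_p = NULL, probes = NULL,
                     samples = NULL, scale = c("intensity", "log2", "zscore")) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values))) stopf("values must have probe rownames")
  if (is.null(colnames(values))) stopf("values must have sample colnames")
  if (anyDuplicated(rownames(values))) stopf("duplicate probe ids")
  if (anyDuplicated(colnames(values))) stopf("duplicate sample ids")
  if (!is.null(detection_p)) {
    if (!identical(dim(detection_p), dim(values))) {
      stopf("detection_p dimensions differ from values")
    }
    rng <- range(detection_p, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 1) stopf("detection p-values must lie in [0, 1]")
  }
  if (scale == "intensity" && any(values <= 0, na.rm = TRUE)) {
    stopf("intensity-scale values must be strictly positive")
  }
  if (is.null(probes)) {
    probes <- data.frame(probe_id = rownames(values),
                         symbol = NA_character_)
  }
  if (is.null(samples)) {
    samples <- data.frame(sample_id = colnames(values),
                          group = NA_character_)
  }
  stopifnot(identical(probes$probe_id, rownames(values)),
            identical(samples$sample_id, colnames(values)))
  structure(list(values = values, detection_p = detection_p,
                 probes = probes, samples = samples, scale = scale),
            class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf("expr_set: %d probes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  if (!is.null(x$samples$group)) {
    tb <- table(x$samples$group)
    cat("  groups:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
        "\n")
  }
  cat(sprintf("  detection p-values: %s\n",
              if (is.null(x$detection_p)) "absent" else "present"))
  invisible(x)
}

#' @export
dim.expr_set <- function(x) dim(x$values)

#' Subset an expression set by probes and/or samples
#'
#' @param x an `expr_set`.
#' @param probes character vector of probe ids (or NULL to keep all).
#' @param samples character vector of sample ids (or NULL to keep all).
#' @return the subsetted `expr_set`.
#' @export
subset_expr <- function(x, probes = NULL, samples = NULL) {
  stopifnot(inherits(x, "expr_set"))
  pi <- if (is.null(probes)) seq_len(nrow(x$values)) else {
    idx <- match(probes, rownames(x$values))
    if (anyNA(idx)) stopf("unknown probe ids: %s",
                          paste(utils::head(probes[is.na(idx)], 3),
                                collapse = ", "))
    idx
  }
  si <- if (is.null(samples)) seq_len(ncol(x$values)) else {
    idx <- match(samples, colnames(x$values))
    if (anyNA(idx)) stopf("unknown sample ids: %s",
                          paste(utils::head(samples[is.na(idx)], 3),
                                collapse = ", "))
    idx
  }
  x$values <- x$values[pi, si, drop = FALSE]
  if (!is.null(x$detection_p)) {
    x$detection_p <- x$detection_p[pi, si, drop = FALSE]
  }
  x$probes <- x$probes[pi, , drop = FALSE]
  x$samples <- x$samples[si, , drop = FALSE]
  rownames(x$probes) <- NULL
  rownames(x$samples) <- NULL
  x
}

group_samples <- function(x, group) {
  stopifnot(inherits(x, "expr_set"))
  ids <- x$samples$sample_id[x$samples$group %in% group]
  if (length(ids) == 0) stopf("no samples in group '%s'",
                              paste(group, collapse = ","))
  ids
}
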