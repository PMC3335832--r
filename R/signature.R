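# Signature discovery: variance ranking, complete-linkage clustering with
# uncentered correlation, seed-cluster extraction, centroid expansion at
# Pearson r >= 0.7, and surrogate biomarker selection.

#' Rank probes by expression variance
#'
#' @param x an [expr_set()] (log2 scale, expressed probes).
#' @param k number of probes to return.
#' @return character vector of the top-`k` probe ids by across-sample
#'   variance, descending; ties broken by probe id. Zero-variance probes are
#'   never selected.
#' @export
rank_by_variance <- function(x, k = 500) {
  stopifnot(inherits(x, "expr_set"))
  v <- apply(x$values, 1, stats::var)
  v <- v[v > 0]
  if (k > length(v)) {
    warnf("only %d probes with positive variance; truncating k", length(v))
    k <- length(v)
  }
  ord <- order(-v, names(v))
  names(v)[ord][seq_len(k)]
}

#' Uncentered correlation of two vectors
#'
#' `sum(x*y) / sqrt(sum(x^2) * sum(y^2))` — the cosine similarity used by the
#' classic Cluster/TreeView "uncentered correlation" setting.
#'
#' @param x,y equal-length numeric vectors; neither may be all zero.
#' @return similarity in \[-1, 1\].
#' @export
uncentered_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stopf("zero-norm vector in uncentered correlation")
  min(max(sum(x * y) / (nx * ny), -1), 1)
}

# All-pairs uncentered correlation of matrix rows.
uncentered_cor_matrix <- function(mat) {
  norms <- sqrt(rowSums(mat^2))
  if (any(norms == 0)) stopf("zero-norm row in uncentered correlation")
  s <- tcrossprod(mat / norms)
  pmin(pmax(s, -1), 1)
}

#' Complete-linkage clustering with uncentered-correlation distance
#'
#' Rows are clustered with distance `1 - uncentered_correlation`. Input rows
#' are expected to be probe-wise z-transformed (the heatmap normalization),
#' under which uncentered and centered correlation coincide.
#'
#' @param mat numeric matrix with >= 2 named rows.
#' @return an object of class `hclust`.
#' @export
hierarchical_cluster <- function(mat) {
  stopifnot(is.matrix(mat))
  if (nrow(mat) < 2) stopf("need at least 2 rows to cluster")
  d <- stats::as.dist(1 - uncentered_cor_matrix(mat))
  stats::hclust(d, method = "complete")
}

#' Extract seed clusters from a dendrogram
#'
#' Cuts the tree into `max_clusters` flat clusters and keeps those with at
#' least `min_size` members, annotated with their mean within-cluster
#' pairwise Pearson correlation and ordered by size.
#'
#' @param hc an `hclust` from [hierarchical_cluster()].
#' @param mat the matrix that was clustered (rows = probes).
#' @param min_size smallest reportable cluster.
#' @param max_clusters number of flat clusters to cut.
#' @return list of character probe-id vectors; each has attribute
#'   `mean_within_cor`.
#' @export
extract_seed_clusters <- function(hc, mat, min_size = 10, max_clusters = 6) {
  stopifnot(inherits(hc, "hclust"))
  cl <- stats::cutree(hc, k = min(max_clusters, length(hc$labels)))
  out <- list()
  for (g in sort(unique(cl))) {
    ids <- names(cl)[cl == g]
    if (length(ids) < min_size) next
    cmat <- stats::cor(t(mat[ids, , drop = FALSE]))
    within <- mean(cmat[upper.tri(cmat)])
    attr(ids, "mean_within_cor") <- within
    out[[length(out) + 1L]] <- ids
  }
  out[order(-vapply(out, length, integer(1)))]
}

#' Per-sample centroid of a seed cluster
#'
#' Arithmetic mean of the seed probes' log2 values in each sample.
#'
#' @param x an [expr_set()] on the log2 scale.
#' @param seed_probes nonempty character vector of probe ids.
#' @return named numeric vector, one value per sample.
#' @export
signature_centroid <- function(x, seed_probes) {
  stopifnot(inherits(x, "expr_set"))
  if (length(seed_probes) == 0) stopf("empty seed cluster")
  sub <- subset_expr(x, probes = seed_probes)
  colMeans(sub$values)
}

#' Expand a seed cluster into a full signature
#'
#' Collects every probe in the matrix whose expression has Pearson
#' correlation at least `r_min` with the seed centroid.
#'
#' @param x an [expr_set()] on the log2 scale (the complete filtered set).
#' @param centroid per-sample centroid from [signature_centroid()], computed
#'   on the same samples.
#' @param r_min correlation threshold for membership.
#' @param seed_probes optional probe ids recorded as the seed.
#' @param name signature label.
#' @return object of class `signature_model` with elements `name`,
#'   `seed_probes`, `centroid`, `members` (data.frame probe_id, symbol, r,
#'   sorted by decreasing r), `r_min`, `n_probes`, `n_genes`.
#' @export
expand_signature <- function(x, centroid, r_min = 0.7, seed_probes = NULL,
                             name = "signature") {
  stopifnot(inherits(x, "expr_set"), length(centroid) == ncol(x$values))
  if (stats::sd(centroid) == 0) stopf("constant centroid")
  r <- as.numeric(stats::cor(t(x$values), centroid))
  names(r) <- rownames(x$values)
  r[is.na(r)] <- 0  # constant probe rows carry no signal
  sel <- which(r >= r_min)
  members <- data.frame(probe_id = names(r)[sel],
                        symbol = x$probes$symbol[sel],
                        r = r[sel], stringsAsFactors = FALSE)
  members <- members[order(-members$r, members$probe_id), ]
  rownames(members) <- NULL
  structure(
    list(name = name, seed_probes = seed_probes, centroid = centroid,
         members = members, r_min = r_min,
         n_probes = nrow(members),
         n_genes = length(unique(stats::na.omit(members$symbol)))),
    class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("signature '%s': %d probes, %d unique genes (r >= %.2f)\n",
              x$name, x$n_probes, x$n_genes, x$r_min))
  if (nrow(x$members)) {
    top <- utils::head(x$members, 3)
    cat("  top members:",
        paste(sprintf("%s (r = %.3f)", top$symbol, top$r), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Select surrogate single-gene biomarkers
#'
#' The `k` member probes most correlated with the signature centroid; a
#' single well-chosen member (e.g. ALAS2 for an erythroid signature) can
#' stand in for the whole signature in downstream clinical correlation.
#'
#' @param model a `signature_model`.
#' @param k number of surrogates.
#' @return data.frame (probe_id, symbol, r), ranked by decreasing r.
#' @export
select_surrogates <- function(model, k = 2) {
  stopifnot(inherits(model, "signature_model"))
  if (nrow(model$members) < k) stopf("fewer than %d members", k)
  utils::head(model$members, k)
}

#' Discover signatures in a preprocessed cohort
#'
#' The full discovery path: rank the `k` most variant probes, cluster them
#' (probe-wise z-transform, uncentered correlation, complete linkage), cut
#' into seed clusters, and expand each seed into a signature over the whole
#' filtered probe set at `r_min`.
#'
#' @param x filtered [expr_set()] on the log2 scale.
#' @param k variance-ranking depth.
#' @param max_clusters,min_size seed-cluster extraction parameters.
#' @param r_min expansion threshold.
#' @return list of `signature_model`s named `C1`, `C2`, ... in decreasing
#'   seed-cluster size, with the seed clusters in `attr(, "seed_clusters")`
#'   and the dendrogram in `attr(, "hclust")`.
#' @export
discover_signatures <- function(x, k = 500, max_clusters = 6, min_size = 10,
                                r_min = 0.7) {
  top <- rank_by_variance(x, k = k)
  zx <- zscore_across_samples(subset_expr(x, probes = top))
  hc <- hierarchical_cluster(zx$values)
  seeds <- extract_seed_clusters(hc, zx$values, min_size = min_size,
                                 max_clusters = max_clusters)
  models <- list()
  for (i in seq_along(seeds)) {
    cen <- signature_centroid(x, seeds[[i]])
    models[[paste0("C", i)]] <- expand_signature(
      x, cen, r_min = r_min, seed_probes = seeds[[i]],
      name = paste0("C", i))
  }
  attr(models, "seed_clusters") <- seeds
  attr(models, "hclust") <- hc
  models
}
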