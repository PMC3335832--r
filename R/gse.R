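# Parametric gene-set enrichment (PAGE): a set's enrichment is the
# size-adjusted z of its mean metric, Z = (Sm - mu) * sqrt(m) / delta, with
# mu and delta the mean and population SD of the whole metric vector.
# Metrics: the z-ratio for within-study contrasts, the simple difference for
# external data, and each sample's own gene z-vector for the per-sample
# "landscape" variant.

#' Gene set collection
#'
#' @param sets named list of character gene-symbol vectors.
#' @param description optional named character vector of set descriptions.
#' @param source provenance label (e.g. `"BioCarta"`, `"custom signature"`).
#' @return object of class `gene_set_collection`. Symbols are uppercased;
#'   matching is case-insensitive exact, without alias expansion.
#' @export
gene_set_collection <- function(sets, description = NULL, source = "custom") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (anyDuplicated(names(sets))) stopf("duplicate gene-set names")
  sets <- lapply(sets, function(g) unique(toupper(g[nzchar(g) & !is.na(g)])))
  if (is.null(description)) {
    description <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(list(sets = sets, description = description, source = source),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- lengths(x$sets)
  cat(sprintf("gene_set_collection: %d sets (sizes %d-%d), source: %s\n",
              length(x$sets), min(sizes), max(sizes), x$source))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Merge gene set collections
#'
#' @param ... `gene_set_collection` objects with disjoint set names.
#' @return the combined collection.
#' @export
merge_collections <- function(...) {
  colls <- list(...)
  sets <- do.call(c, lapply(colls, `[[`, "sets"))
  desc <- do.call(c, lapply(colls, `[[`, "description"))
  if (anyDuplicated(names(sets))) stopf("duplicate set names across collections")
  gene_set_collection(sets, desc,
                      source = paste(unique(vapply(colls, `[[`, character(1),
                                                   "source")),
                                     collapse = "+"))
}

#' Random gene sets from a universe
#'
#' Used for null calibration and as a neutral background collection.
#'
#' @param universe character vector of gene symbols.
#' @param n_sets number of sets.
#' @param size_range inclusive range of set sizes.
#' @param prefix set-name prefix.
#' @return a `gene_set_collection`.
#' @export
random_gene_sets <- function(universe, n_sets, size_range = c(10, 200),
                             prefix = "RND") {
  universe <- unique(toupper(universe))
  sets <- lapply(seq_len(n_sets), function(i) {
    sample(universe, sample(size_range[1]:size_range[2], 1))
  })
  names(sets) <- sprintf("%s_%04d", prefix, seq_len(n_sets))
  gene_set_collection(sets, source = "random background")
}

#' Collapse probe-level values to gene level
#'
#' Multiple probes per symbol are collapsed to the probe with the highest
#' mean expression (computed on `x`, or on `by` when the working matrix is
#' not on an interpretable scale). Probes without a symbol are dropped.
#'
#' @param x an [expr_set()].
#' @param by optional `expr_set` on the log2 scale used to pick the
#'   representative probe per gene; defaults to `x`.
#' @return numeric matrix genes x samples with uppercase symbol rownames.
#' @export
collapse_to_genes <- function(x, by = NULL) {
  stopifnot(inherits(x, "expr_set"))
  ref <- if (is.null(by)) x else by
  stopifnot(identical(rownames(ref$values), rownames(x$values)))
  sym <- toupper(x$probes$symbol)
  keep <- !is.na(sym) & nzchar(sym)
  mu <- rowMeans(ref$values)
  ord <- order(sym, -mu)  # per symbol, highest-mean probe first
  first <- ord[!duplicated(sym[ord])]
  first <- first[keep[first]]
  out <- x$values[first, , drop = FALSE]
  rownames(out) <- sym[first]
  out
}

metric_vector <- function(values, kind, label) {
  stopifnot(is.numeric(values), !is.null(names(values)))
  structure(list(values = values, kind = kind, label = label,
                 mu = mean(values), delta = sd_pop(values)),
            class = "metric_vector")
}

#' Z-ratio contrast metric
#'
#' Per gene, the difference of group means of within-sample z-scores,
#' re-standardized over genes (population SD): the PAGE input used for
#' within-study contrasts.
#'
#' @param gene_z numeric matrix genes x samples of within-sample z-scores
#'   (see [zscore_within_sample()] and [collapse_to_genes()]).
#' @param samplesA,samplesB column names of the two groups.
#' @return a `metric_vector` of kind `"zratio"`. If every per-gene
#'   difference is zero the metric is all zeros, with a warning.
#' @export
zratio_metric <- function(gene_z, samplesA, samplesB) {
  stopifnot(length(samplesA) > 0, length(samplesB) > 0)
  d <- rowMeans(gene_z[, samplesA, drop = FALSE]) -
    rowMeans(gene_z[, samplesB, drop = FALSE])
  s <- sd_pop(d)
  if (s == 0) {
    warnf("degenerate contrast: all per-gene differences equal")
    vals <- d * 0
  } else {
    vals <- (d - mean(d)) / s
  }
  metric_vector(vals, "zratio", "contrast")
}

#' Simple difference metric
#'
#' Per gene, the difference of group mean log2 expression — the metric used
#' for external datasets distributed on heterogeneous processed scales.
#'
#' @param gene_log2 numeric matrix genes x samples of log2 values.
#' @param samplesA,samplesB column names of the two groups.
#' @return a `metric_vector` of kind `"difference"`.
#' @export
difference_metric <- function(gene_log2, samplesA, samplesB) {
  stopifnot(length(samplesA) > 0, length(samplesB) > 0)
  d <- rowMeans(gene_log2[, samplesA, drop = FALSE]) -
    rowMeans(gene_log2[, samplesB, drop = FALSE])
  metric_vector(d, "difference", "contrast")
}

#' PAGE enrichment score for one gene set
#'
#' `Z = (Sm - mu) * sqrt(m) / delta` where `Sm` is the mean metric over the
#' set's `m` genes present in the metric universe and `mu`, `delta` are the
#' mean and population SD of the whole metric vector. `p` is the two-sided
#' standard-normal tail.
#'
#' @param metric a `metric_vector` (or named numeric vector).
#' @param genes character vector of gene symbols.
#' @param min_size sets with fewer than `min_size` genes in the universe are
#'   returned with `reported = FALSE` and `NA` scores.
#' @return list: `m`, `Sm`, `Z`, `p`, `reported`.
#' @export
page_score <- function(metric, genes, min_size = 10) {
  if (!inherits(metric, "metric_vector")) {
    metric <- metric_vector(metric, "custom", "adhoc")
  }
  if (metric$delta == 0) stopf("zero metric SD: PAGE undefined")
  hit <- which(toupper(names(metric$values)) %in% toupper(genes))
  m <- length(hit)
  if (m < min_size) {
    return(list(m = m, Sm = NA_real_, Z = NA_real_, p = NA_real_,
                reported = FALSE))
  }
  Sm <- mean(metric$values[hit])
  Z <- (Sm - metric$mu) * sqrt(m) / metric$delta
  list(m = m, Sm = Sm, Z = Z, p = 2 * stats::pnorm(-abs(Z)), reported = TRUE)
}

#' Score every set of a collection against a metric
#'
#' @param metric a `metric_vector`.
#' @param collection a `gene_set_collection`.
#' @param min_size minimum effective set size for reporting.
#' @param p_cutoff sets with `p <= p_cutoff` are flagged significant.
#' @return data.frame: set, source, m, Sm, Z, p, neg_log10_p, significant;
#'   one row per reportable set, sorted by decreasing |Z|.
#' @export
score_collection <- function(metric, collection, min_size = 10,
                             p_cutoff = 0.01) {
  stopifnot(inherits(collection, "gene_set_collection"))
  rows <- lapply(names(collection$sets), function(nm) {
    s <- page_score(metric, collection$sets[[nm]], min_size = min_size)
    if (!s$reported) return(NULL)
    data.frame(set = nm, source = collection$source, m = s$m, Sm = s$Sm,
               Z = s$Z, p = s$p, neg_log10_p = -log10(max(s$p, 1e-300)),
               significant = s$p <= p_cutoff, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(set = character(0), source = character(0),
                      m = integer(0), Sm = numeric(0), Z = numeric(0),
                      p = numeric(0), neg_log10_p = numeric(0),
                      significant = logical(0)))
  }
  out <- out[order(-abs(out$Z)), ]
  rownames(out) <- NULL
  out
}

#' Per-sample enrichment landscape
#'
#' The landscape variant scores every gene set against each individual
#' sample: the metric for a sample is its own per-gene z vector (within-
#' sample z-scores, row-normalized per gene across samples so each sample's
#' profile is relative to the cohort).
#'
#' @param gene_z genes x samples matrix of within-sample z-scores.
#' @param collection a `gene_set_collection`.
#' @param groups optional character vector of group labels per sample (for
#'   the group-averaged view).
#' @param min_size minimum effective set size.
#' @param row_normalize z-transform each gene across samples before scoring
#'   (the landscape convention); set `FALSE` to score raw columns.
#' @return list: `Z` (sets x samples matrix) and, when `groups` is given,
#'   `group_mean` (sets x groups matrix of Z averaged by group).
#' @export
sample_landscape <- function(gene_z, collection, groups = NULL,
                             min_size = 10, row_normalize = TRUE) {
  stopifnot(is.matrix(gene_z), inherits(collection, "gene_set_collection"))
  mat <- gene_z
  if (row_normalize) {
    mu <- rowMeans(mat)
    sdv <- apply(mat, 1, sd_pop)
    flat <- sdv == 0
    sdv[flat] <- 1
    mat <- (mat - mu) / sdv
    mat[flat, ] <- 0
  }
  keep <- vapply(collection$sets,
                 function(g) sum(toupper(g) %in% rownames(mat)) >= min_size,
                 logical(1))
  sets <- collection$sets[keep]
  if (length(sets) == 0) stopf("no set meets min_size in this universe")
  # indicator algebra: Sm per set/sample in one multiply
  ind <- matrix(0, length(sets), nrow(mat),
                dimnames = list(names(sets), rownames(mat)))
  for (i in seq_along(sets)) {
    ind[i, intersect(toupper(sets[[i]]), rownames(mat))] <- 1
  }
  m <- rowSums(ind)
  Sm <- (ind %*% mat) / m
  mu_s <- colMeans(mat)
  delta_s <- apply(mat, 2, sd_pop)
  if (any(delta_s == 0)) {
    # all-zero sample profile: every set scores 0
    delta_s[delta_s == 0] <- Inf
  }
  Z <- sweep(sweep(Sm, 2, mu_s, `-`), 2, delta_s, `/`) * sqrt(m)
  out <- list(Z = Z, m = m)
  if (!is.null(groups)) {
    stopifnot(length(groups) == ncol(Z))
    gl <- unique(groups)
    gm <- vapply(gl, function(g) rowMeans(Z[, groups == g, drop = FALSE]),
                 numeric(nrow(Z)))
    out$group_mean <- matrix(gm, nrow = nrow(Z),
                             dimnames = list(rownames(Z), gl))
  }
  out
}

#' Score a signature in an (external) expression dataset
#'
#' Embeds the signature in a background collection, computes the simple
#' difference metric for a contrast of the dataset's groups, scores the
#' combined collection, and reports the signature's enrichment and rank.
#'
#' @param x an [expr_set()] on the log2 scale (external data as processed by
#'   the submitter; values are used as provided).
#' @param groupA,groupB group labels of the contrast (A vs B baseline).
#' @param signature_genes character vector of signature gene symbols.
#' @param background a `gene_set_collection` the signature is embedded in.
#' @param signature_name name under which the signature is scored.
#' @param min_size minimum effective set size; a signature below it gets
#'   `reported = FALSE`.
#' @return list: `signature` (one-row data.frame with Z, p, rank,
#'   n_sets, reported) and `table` (the full scored collection).
#' @export
score_signature_in_dataset <- function(x, groupA, groupB, signature_genes,
                                       background,
                                       signature_name = "SIGNATURE",
                                       min_size = 10) {
  stopifnot(inherits(x, "expr_set"))
  gene_mat <- collapse_to_genes(x)
  sA <- group_samples(x, groupA)
  sB <- group_samples(x, groupB)
  metric <- difference_metric(gene_mat, sA, sB)
  sig_coll <- gene_set_collection(
    stats::setNames(list(signature_genes), signature_name),
    source = "query signature")
  combined <- merge_collections(background, sig_coll)
  tab <- score_collection(metric, combined, min_size = min_size, p_cutoff = 0.01)
  row <- tab[tab$set == signature_name, , drop = FALSE]
  if (nrow(row) == 0) {
    sig <- data.frame(set = signature_name, Z = NA_real_, p = NA_real_,
                      rank = NA_integer_, n_sets = nrow(tab),
                      reported = FALSE)
  } else {
    sig <- data.frame(set = signature_name, Z = row$Z, p = row$p,
                      rank = match(signature_name, tab$set),
                      n_sets = nrow(tab), reported = TRUE)
  }
  list(signature = sig, table = tab)
}
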