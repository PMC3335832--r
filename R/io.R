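# Readers and writers: GEO-style series-matrix TSV, detection TSV, GMT gene
# sets, clinical tables and ground-truth JSON. Writers emit stable row order
# and full-precision numerics so outputs diff and round-trip cleanly.

fmt_num <- function(x) {
  ifelse(is.na(x), "", formatC(x, format = "g", digits = 17))
}

#' Write an expression set as a series-matrix-style document
#'
#' Emits "!"-prefixed sample metadata lines (one per sample annotation
#' column), then the probe x sample data block between
#' `!series_matrix_table_begin` / `!series_matrix_table_end` markers.
#'
#' @param x an [expr_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_series_matrix <- function(x, path) {
  stopifnot(inherits(x, "expr_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("!Series_title\t\"synthetic PBMC cohort (%s scale)\"",
                     x$scale), con)
  writeLines(paste0("!Sample_geo_accession\t",
                    paste(sprintf("\"%s\"", x$samples$sample_id),
                          collapse = "\t")), con)
  for (col in setdiff(names(x$samples), "sample_id")) {
    writeLines(paste0("!Sample_characteristics_ch1\t",
                      paste(sprintf("\"%s: %s\"", col, x$samples[[col]]),
                            collapse = "\t")), con)
  }
  writeLines("!series_matrix_table_begin", con)
  writeLines(paste(c("\"ID_REF\"",
                     sprintf("\"%s\"", x$samples$sample_id)),
                   collapse = "\t"), con)
  body <- cbind(rownames(x$values),
                matrix(fmt_num(x$values), nrow = nrow(x$values)))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  writeLines("!series_matrix_table_end", con)
  invisible(path)
}

strip_quotes <- function(x) gsub("^\"|\"$", "", x)

#' Read a series-matrix-style document
#'
#' Parses "!"-prefixed metadata into sample annotations and the data block
#' into a numeric matrix. Sample annotations are extracted from
#' `!Sample_characteristics_ch1` lines whose values look like `"key: value"`;
#' the key that holds the group label is configurable because dialects vary
#' across deposited datasets.
#'
#' @param path file path.
#' @param group_key characteristics key (regex, case-insensitive) holding the
#'   group label.
#' @param detection_path optional parallel detection-p TSV (probes x samples,
#'   with header).
#' @param probe_annotations optional data.frame (`probe_id`, `symbol`) or
#'   path to a TSV with those columns.
#' @return an [expr_set()]; scale is `"log2"` if any value is negative or
#'   the maximum is below 30, else `"intensity"`. Missing cells load as `NA`.
#' @export
read_series_matrix <- function(path, group_key = "group",
                               detection_path = NULL,
                               probe_annotations = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1 || length(end) != 1 || end <= begin) {
    stopf("missing or malformed table begin/end markers")
  }
  header <- strsplit(lines[begin + 1L], "\t", fixed = TRUE)[[1]]
  sample_ids <- strip_quotes(header[-1])
  if (anyDuplicated(sample_ids)) stopf("duplicate sample ids in data header")
  n_col <- length(header)

  data_lines <- lines[(begin + 2L):(end - 1L)]
  # sentinel keeps trailing empty fields (missing last cells) from being lost
  parts <- strsplit(paste0(data_lines, "\tZ"), "\t", fixed = TRUE)
  parts <- lapply(parts, function(p) p[-length(p)])
  lens <- lengths(parts)
  if (any(lens != n_col)) {
    bad <- which(lens != n_col)[1]
    stopf("ragged row at line %d: %d fields, expected %d",
          begin + 1L + bad, lens[bad], n_col)
  }
  probe_ids <- strip_quotes(vapply(parts, `[[`, character(1), 1))
  if (anyDuplicated(probe_ids)) {
    stopf("duplicate probe id: %s", probe_ids[duplicated(probe_ids)][1])
  }
  vals <- vapply(parts, function(p) {
    v <- strip_quotes(p[-1])
    v[v == "" | toupper(v) == "NA" | v == "null"] <- NA
    as.numeric(v)
  }, numeric(length(sample_ids)))
  values <- t(vals)
  dimnames(values) <- list(probe_ids, sample_ids)

  samples <- data.frame(sample_id = sample_ids, stringsAsFactors = FALSE)
  meta <- grep("^!Sample_characteristics", lines[seq_len(begin - 1L)],
               value = TRUE)
  for (ln in meta) {
    fields <- strip_quotes(strsplit(ln, "\t", fixed = TRUE)[[1]][-1])
    if (length(fields) != length(sample_ids)) next
    m <- regmatches(fields, regexec("^([^:]+):\\s*(.*)$", fields))
    keys <- vapply(m, function(z) if (length(z) == 3) z[2] else NA, character(1))
    vals_ch <- vapply(m, function(z) if (length(z) == 3) z[3] else NA,
                      character(1))
    key <- unique(stats::na.omit(keys))
    if (length(key) != 1) next
    col <- if (grepl(group_key, key, ignore.case = TRUE)) "group" else
      make.names(key)
    samples[[col]] <- vals_ch
  }
  if (is.null(samples$group)) samples$group <- NA_character_

  detection <- NULL
  if (!is.null(detection_path)) {
    det <- utils::read.delim(detection_path, row.names = 1,
                             check.names = FALSE)
    detection <- as.matrix(det)[probe_ids, sample_ids, drop = FALSE]
  }
  probes <- data.frame(probe_id = probe_ids, symbol = NA_character_,
                       stringsAsFactors = FALSE)
  if (!is.null(probe_annotations)) {
    ann <- if (is.character(probe_annotations)) {
      utils::read.delim(probe_annotations, stringsAsFactors = FALSE)
    } else probe_annotations
    probes$symbol <- ann$symbol[match(probe_ids, ann$probe_id)]
  }
  mx <- max(values, na.rm = TRUE)
  scale <- if (any(values <= 0, na.rm = TRUE) || mx < 30) "log2" else
    "intensity"
  expr_set(values, detection_p = detection, probes = probes,
           samples = samples, scale = scale)
}

#' Write detection p-values as a TSV parallel to the series matrix
#'
#' @param x an [expr_set()] with detection p-values.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_detection <- function(x, path) {
  stopifnot(inherits(x, "expr_set"))
  if (is.null(x$detection_p)) stopf("no detection p-values to write")
  df <- data.frame(ID_REF = rownames(x$detection_p),
                   x$detection_p, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Tab-separated lines: set name, description, then member symbols. Empty
#' symbol fields are dropped with a warning.
#'
#' @param path file path.
#' @param source provenance label attached to the collection.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path, source = basename(path)) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  lens <- lengths(parts)
  if (any(lens < 3)) {
    stopf("GMT parse error at line %d: fewer than 3 fields",
          which(lens < 3)[1])
  }
  nms <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(nms)) {
    stopf("duplicate gene-set name: %s", nms[duplicated(nms)][1])
  }
  desc <- stats::setNames(vapply(parts, `[[`, character(1), 2), nms)
  sets <- lapply(parts, function(p) {
    g <- p[-(1:2)]
    if (any(!nzchar(g))) warnf("empty symbol field dropped in set '%s'", p[1])
    g[nzchar(g)]
  })
  names(sets) <- nms
  gene_set_collection(sets, description = desc, source = source)
}

#' Write a gene-set collection as GMT
#'
#' @param collection a [gene_set_collection()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$description[[nm]] %||% "",
            collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a generated cohort to a directory
#'
#' Emits the expression matrix as a series-matrix TSV, detection p-values as
#' a parallel TSV, probe annotations and the clinical table as TSV, and the
#' ground truth as JSON.
#'
#' @param cohort list from [generate_cohort()].
#' @param dir output directory (created if absent).
#' @return named character vector of the files written, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    series_matrix = file.path(dir, "series_matrix.tsv"),
    detection = file.path(dir, "detection_p.tsv"),
    probes = file.path(dir, "probe_annotations.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    truth = file.path(dir, "truth.json"))
  write_series_matrix(cohort$expr, files["series_matrix"])
  write_detection(cohort$expr, files["detection"])
  utils::write.table(cohort$expr$probes, files["probes"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$clinical, files["clinical"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cohort$truth, files["truth"], digits = NA,
                       auto_unbox = TRUE, null = "null", na = "null")
  invisible(files)
}

#' Read a written cohort back
#'
#' @param dir directory produced by [write_cohort()].
#' @return list with `expr`, `clinical`, `truth` mirroring
#'   [generate_cohort()] output.
#' @export
read_cohort <- function(dir) {
  expr <- read_series_matrix(
    file.path(dir, "series_matrix.tsv"),
    detection_path = file.path(dir, "detection_p.tsv"),
    probe_annotations = file.path(dir, "probe_annotations.tsv"))
  clinical <- utils::read.delim(file.path(dir, "clinical.tsv"),
                                stringsAsFactors = FALSE)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  list(expr = expr, clinical = clinical, truth = truth)
}
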