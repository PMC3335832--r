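# One-config pipeline driver: runs the simulate -> preprocess -> de ->
# discover -> enrich -> landscape -> clinical stages in dependency order,
# writes per-stage artifacts and a manifest with seeds and checksums, and is
# bit-reproducible for a fixed (config, seed).

PIPELINE_STAGES <- c("simulate", "preprocess", "de", "discover", "enrich",
                     "landscape", "clinical")

default_pipeline_config <- function() {
  list(
    seed = 7,
    stages = PIPELINE_STAGES,
    cohort = list(),
    de = list(contrasts = list(c("IPAH", "Control"),
                               c("SSc-PAH", "Control"),
                               c("SSc", "Control"))),
    discover = list(k = 500, max_clusters = 6, min_size = 10, r_min = 0.7),
    enrich = list(n_background_sets = 200),
    clinical = list(group = "IPAH", window_days = 120)
  )
}

# Pick the discovered signature most specific to the PH groups: largest
# standardized centroid separation between PH groups and Control.
ph_signature_index <- function(models, samples,
                               ph_groups = c("IPAH", "SSc-PAH", "SSc-PH-ILD"),
                               ref_group = "Control") {
  sep <- vapply(models, function(m) {
    cen <- m$centroid
    ph <- cen[samples$group %in% ph_groups]
    ref <- cen[samples$group %in% ref_group]
    if (!length(ph) || !length(ref) || stats::sd(cen) == 0) return(-Inf)
    (mean(ph) - mean(ref)) / stats::sd(cen)
  }, numeric(1))
  which.max(sep)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline from one configuration
#'
#' @param config a configuration list, or path to a YAML/JSON file holding
#'   one. Recognized entries: `seed` (required), `stages` (subset of
#'   simulate/preprocess/de/discover/enrich/landscape/clinical, run in that
#'   order), `cohort` (overrides to [cohort_config()] arguments), and
#'   per-stage parameter lists (`de$contrasts`, `discover`, `enrich`,
#'   `clinical`). Unspecified entries take the defaults.
#' @param out_dir artifact directory.
#' @return (invisibly) list with the manifest and in-memory stage results.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(default_pipeline_config(), config)
  stages <- cfg$stages
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stopf("undefined stage name(s): %s",
                         paste(bad, collapse = ", "))
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  if (is.null(cfg$seed)) stopf("config must declare a seed")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  art <- list()
  files <- character(0)
  need <- function(what, stage) {
    if (is.null(art[[what]])) {
      stopf("stage '%s' needs the '%s' stage to run first", stage, what)
    }
    art[[what]]
  }

  for (stage in stages) {
    sdir <- file.path(out_dir, stage)
    dir.create(sdir, showWarnings = FALSE)
    if (stage == "simulate") {
      ccfg <- do.call(cohort_config, cfg$cohort)
      art$simulate <- generate_cohort(ccfg, seed = cfg$seed)
      files <- c(files, write_cohort(art$simulate, sdir))
    } else if (stage == "preprocess") {
      cohort <- need("simulate", stage)
      art$preprocess <- preprocess_cohort(cohort$expr)
      files <- c(files,
                 write_series_matrix(art$preprocess,
                                     file.path(sdir, "filtered_log2.tsv")))
    } else if (stage == "de") {
      prep <- need("preprocess", stage)
      art$de <- list()
      for (ct in cfg$de$contrasts) {
        res <- call_de(prep, ct[1], ct[2])
        nm <- sprintf("%s_vs_%s", ct[1], ct[2])
        art$de[[nm]] <- res
        files <- c(files, write_tsv(res, file.path(sdir, paste0(nm, ".tsv"))))
      }
    } else if (stage == "discover") {
      prep <- need("preprocess", stage)
      set.seed(cfg$seed + 1L)
      art$discover <- do.call(discover_signatures,
                              c(list(prep), cfg$discover))
      coll <- gene_set_collection(
        lapply(art$discover,
               function(m) unique(stats::na.omit(m$members$symbol))),
        source = "discovered signatures")
      files <- c(files, write_gmt(coll, file.path(sdir, "signatures.gmt")))
      detail <- do.call(rbind, lapply(art$discover, function(m) {
        cbind(signature = m$name, m$members)
      }))
      files <- c(files, write_tsv(detail, file.path(sdir, "members.tsv")))
    } else if (stage == "enrich") {
      prep <- need("preprocess", stage)
      models <- need("discover", stage)
      gene_z <- collapse_to_genes(zscore_within_sample(prep), by = prep)
      set.seed(cfg$seed + 2L)
      background <- random_gene_sets(rownames(gene_z),
                                     cfg$enrich$n_background_sets)
      sig_coll <- gene_set_collection(
        lapply(models, function(m) unique(stats::na.omit(m$members$symbol))),
        source = "discovered signatures")
      coll <- merge_collections(background, sig_coll)
      art$enrich <- list()
      for (ct in cfg$de$contrasts) {
        sA <- prep$samples$sample_id[prep$samples$group == ct[1]]
        sB <- prep$samples$sample_id[prep$samples$group == ct[2]]
        metric <- zratio_metric(gene_z, sA, sB)
        tab <- score_collection(metric, coll)
        nm <- sprintf("%s_vs_%s", ct[1], ct[2])
        art$enrich[[nm]] <- tab
        files <- c(files, write_tsv(tab, file.path(sdir, paste0(nm, ".tsv"))))
      }
      art$enrich_collection <- coll
    } else if (stage == "landscape") {
      prep <- need("preprocess", stage)
      coll <- need("enrich_collection", stage)
      gene_z <- collapse_to_genes(zscore_within_sample(prep), by = prep)
      art$landscape <- sample_landscape(gene_z, coll,
                                        groups = prep$samples$group)
      files <- c(files,
                 write_tsv(data.frame(set = rownames(art$landscape$Z),
                                      art$landscape$Z, check.names = FALSE),
                           file.path(sdir, "landscape_z.tsv")),
                 write_tsv(data.frame(set = rownames(art$landscape$group_mean),
                                      art$landscape$group_mean,
                                      check.names = FALSE),
                           file.path(sdir, "landscape_group_mean.tsv")))
    } else if (stage == "clinical") {
      prep <- need("preprocess", stage)
      models <- need("discover", stage)
      cohort <- need("simulate", stage)
      idx <- ph_signature_index(models, prep$samples)
      surro <- select_surrogates(models[[idx]], k = 2)
      art$clinical <- biomarker_hemodynamics(
        prep, surro$probe_id[1], cohort$clinical,
        group = cfg$clinical$group,
        max_days = cfg$clinical$window_days)
      art$surrogates <- surro
      files <- c(files,
                 write_tsv(art$clinical, file.path(sdir, "correlations.tsv")),
                 write_tsv(surro, file.path(sdir, "surrogates.tsv")))
    }
  }

  strip_classes <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip_classes) else x
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("edsig")),
    seed = cfg$seed,
    stages = stages,
    config = strip_classes(cfg[setdiff(names(cfg), "stages")]),
    files = lapply(stats::setNames(nm = basename(unname(files))), function(f) {
      full <- files[basename(files) == f][1]
      list(path = sub(paste0("^", out_dir, "/?"), "", full),
           md5 = unname(tools::md5sum(full)))
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(manifest = manifest, artifacts = art))
}
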