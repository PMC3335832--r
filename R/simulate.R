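# Synthetic cohort generator.
#
# The generator plants correlated probe modules on top of a background of
# expressed and unexpressed probes. Each module's member probes share a
# per-subject activation amplitude; the pairwise correlation of member probes
# is calibrated to the module's within_module_corr target by either adding a
# shared per-subject nuisance component (when the amplitude variance falls
# short of the variance the target implies) or extra per-probe noise (when it
# exceeds it). Intensities are emitted on the raw scale with a per-sample
# multiplicative jitter so the median-scaling entry point is exercised.

DETECTION_EXPRESSED_RATE <- 0.97  # per-cell chance an expressed probe is called

curated_module_genes <- list(
  EDS = c("ALAS2", "AHSP", "HBB", "HBA1", "HBA2", "HBD", "HBG1", "HBG2",
          "HBM", "HBQ1", "GATA1", "KLF1", "CA2", "EPB42", "SLC4A1"),
  SEX = c("XIST", "RPS4Y1", "KDM5D", "DDX3Y", "UTY", "USP9Y", "EIF1AY",
          "NLGN4Y", "TXLNGY", "ZFY")
)

module_gene_names <- function(m) {
  curated <- curated_module_genes[[m$name]] %||% character(0)
  extra <- sprintf("%s_%03d", m$name, seq_len(m$n_genes))
  genes <- c(curated, extra)[seq_len(m$n_genes)]
  # duplicate leading genes so probe_count probes map onto n_genes symbols
  genes[c(seq_len(m$n_genes), seq_len(m$probe_count - m$n_genes))]
}

# Graded activation amplitudes for one module across the cohort.
raw_amplitudes <- function(m, groups, sex, leak_sd = 0.1) {
  n <- length(groups)
  if (isTRUE(m$sex_driven)) {
    return(m$amplitude_log2 * as.numeric(sex == "F") + stats::rnorm(n, 0, leak_sd))
  }
  pen <- m$penetrance[groups]
  pen[is.na(pen)] <- 0
  active <- stats::runif(n) < pen
  grade <- exp(stats::rnorm(n, 0, 0.25))
  ifelse(active, m$amplitude_log2 * grade, stats::rnorm(n, 0, leak_sd))
}

# Blend a module's amplitudes with an earlier module's so the sample
# correlation equals the target exactly (orthogonalized construction).
blend_amplitudes <- function(a_raw, a_ref, target_r) {
  mu <- mean(a_raw); s <- stats::sd(a_raw)
  if (s == 0 || stats::sd(a_ref) == 0) return(a_raw)
  z_ref <- as.numeric(scale(a_ref))
  z_raw <- as.numeric(scale(a_raw))
  z_perp <- z_raw - stats::cor(z_raw, z_ref) * z_ref
  sp <- stats::sd(z_perp)
  if (sp == 0) return(a_raw)
  z_perp <- z_perp / sp
  mu + s * (target_r * z_ref + sqrt(1 - target_r^2) * z_perp)
}

#' Generate a seeded synthetic PBMC cohort
#'
#' Produces raw-scale probe intensities with detection p-values, a clinical
#' covariate table, and the ground truth (module memberships, subject
#' activation amplitudes, planted differential expression) that downstream
#' validation compares against.
#'
#' @param config a [cohort_config()].
#' @param seed integer RNG seed; required, there is no implicit default.
#' @return list with elements `expr` (an [expr_set()] on the intensity
#'   scale), `clinical` (data.frame, see [generate_hemodynamics()]) and
#'   `truth` (list: `module_membership`, `subject_amplitudes`, `planted_de`,
#'   `covariate_couplings`, `calibration`).
#' @export
generate_cohort <- function(config, seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (missing(seed) || is.null(seed)) stopf("a seed is required")
  set.seed(as.integer(seed))

  gs <- config$group_sizes
  n_samp <- sum(gs)
  groups <- rep(names(gs), gs)
  samples <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n_samp)),
    subject_id = sprintf("SUBJ%03d", seq_len(n_samp)),
    group = groups,
    stringsAsFactors = FALSE)
  ff <- female_fractions()
  pf <- ff[samples$group]
  pf[is.na(pf)] <- 0.5
  samples$sex <- ifelse(stats::runif(n_samp) < pf, "F", "M")

  np <- config$n_probes
  probe_ids <- sprintf("ILMN_%07d", seq_len(np))
  n_bg <- round(config$detection_background_fraction * np)
  expressed <- rep(TRUE, np)
  if (n_bg > 0) expressed[sample.int(np, n_bg)] <- FALSE
  expr_idx <- which(expressed)

  # disjoint module probe assignment among expressed probes
  mods <- config$modules
  n_mod_probes <- sum(vapply(mods, function(m) m$probe_count, integer(1)))
  if (length(expr_idx) < n_mod_probes) {
    stopf("too few expressed probes (%d) for planted modules (%d)",
          length(expr_idx), n_mod_probes)
  }
  mod_idx_pool <- sample(expr_idx, n_mod_probes)
  membership <- rep(NA_character_, np)
  symbols <- rep(NA_character_, np)
  offset <- 0L
  mod_probe_idx <- list()
  for (m in mods) {
    idx <- mod_idx_pool[offset + seq_len(m$probe_count)]
    if (any(!is.na(membership[idx]))) stopf("overlapping module assignment")
    membership[idx] <- m$name
    symbols[idx] <- module_gene_names(m)
    mod_probe_idx[[m$name]] <- idx
    offset <- offset + m$probe_count
  }

  # background symbols: expressed background mostly unique genes, a few
  # duplicated probes and a few missing symbols; unexpressed probes likewise
  bg_expr <- setdiff(expr_idx, mod_idx_pool)
  symbols[bg_expr] <- sprintf("GENE%05d", seq_along(bg_expr))
  dup <- sample(seq_along(bg_expr), round(0.05 * length(bg_expr)))
  symbols[bg_expr[dup]] <-
    sprintf("GENE%05d", sample(seq_along(bg_expr), length(dup)))
  symbols[bg_expr[sample(seq_along(bg_expr),
                         round(0.03 * length(bg_expr)))]] <- NA
  bg_unexpr <- which(!expressed)
  if (length(bg_unexpr)) {
    symbols[bg_unexpr] <- sprintf("BKG%05d", seq_along(bg_unexpr))
    symbols[bg_unexpr[sample(seq_along(bg_unexpr),
                             round(0.05 * length(bg_unexpr)))]] <- NA
  }

  # baselines
  baseline <- numeric(np)
  baseline[expressed] <- stats::rnorm(sum(expressed),
                                      config$baseline_log2_mean, 1.2)
  baseline[!expressed] <- stats::rnorm(sum(!expressed), 4, 0.6)

  log2_mat <- matrix(stats::rnorm(np * n_samp, 0, config$noise_sd),
                     np, n_samp) + baseline

  # Plant modules with within-module correlation calibration, blending the
  # shared per-subject component with earlier modules so cross_module_corr
  # targets hold at the centroid level (the centroid is essentially the
  # shared component, probe noise averaging out over members).
  v_sigma <- config$noise_sd^2
  calibration <- list()
  amp <- matrix(0, n_samp, length(mods),
                dimnames = list(samples$sample_id,
                                vapply(mods, `[[`, character(1), "name")))
  for (m in mods) {
    idx <- mod_probe_idx[[m$name]]
    a <- raw_amplitudes(m, samples$group, samples$sex)
    rho <- m$within_module_corr
    v_target <- rho / (1 - rho) * v_sigma
    v_a <- stats::var(a)
    if (v_a < v_target) {
      shared <- a + stats::rnorm(n_samp, 0, sqrt(v_target - v_a))
      extra_sd <- 0
    } else {
      shared <- a
      extra_var <- v_a * (1 - rho) / rho - v_sigma
      extra_sd <- sqrt(max(extra_var, 0))
    }
    if (!is.null(m$cross_module_corr) && length(m$cross_module_corr)) {
      ref <- names(m$cross_module_corr)[1]
      shared <- blend_amplitudes(shared, amp[, ref], m$cross_module_corr[[1]])
    }
    amp[, m$name] <- shared
    block <- matrix(shared, length(idx), n_samp, byrow = TRUE)
    if (extra_sd > 0) {
      block <- block + matrix(stats::rnorm(length(idx) * n_samp, 0, extra_sd),
                              length(idx), n_samp)
    }
    log2_mat[idx, ] <- log2_mat[idx, ] + block
    calibration[[m$name]] <- list(amplitude_var = v_a,
                                  shared_var_target = v_target,
                                  extra_probe_sd = extra_sd)
  }

  # per-sample multiplicative scale jitter, then back to the intensity scale
  scale_jitter <- stats::rnorm(n_samp, 0, config$sample_scale_sd)
  log2_mat <- sweep(log2_mat, 2, scale_jitter, `+`)
  values <- 2^log2_mat
  dimnames(values) <- list(probe_ids, samples$sample_id)

  # detection p-values
  det <- matrix(stats::runif(np * n_samp, 0.02, 1), np, n_samp,
                dimnames = dimnames(values))
  n_expr_cells <- sum(expressed) * n_samp
  called <- stats::runif(n_expr_cells) < DETECTION_EXPRESSED_RATE
  det_expr <- ifelse(called, stats::runif(n_expr_cells, 0, 0.005),
                     stats::runif(n_expr_cells, 0.02, 1))
  det[expressed, ] <- det_expr

  probes <- data.frame(probe_id = probe_ids, symbol = symbols,
                       stringsAsFactors = FALSE)
  expr <- expr_set(values, detection_p = det, probes = probes,
                   samples = samples, scale = "intensity")

  subject_amplitudes <- data.frame(samples[c("sample_id", "subject_id",
                                             "group", "sex")], amp,
                                   check.names = FALSE)
  clinical <- generate_hemodynamics(subject_amplitudes, config)

  truth <- list(
    module_membership = data.frame(
      probe_id = probe_ids[!is.na(membership)],
      symbol = symbols[!is.na(membership)],
      module = membership[!is.na(membership)],
      stringsAsFactors = FALSE),
    subject_amplitudes = subject_amplitudes,
    planted_de = planted_de_table(config),
    covariate_couplings = config$hemodynamic_coupling,
    expressed_probes = probe_ids[expressed],
    calibration = calibration,
    seed = as.integer(seed))
  list(expr = expr, clinical = clinical, truth = truth)
}

# Expected per-module log2 group-mean shifts for every group pair; a module is
# planted-DE for a contrast when the expected shift exceeds the fold-change
# threshold.
planted_de_table <- function(config, fc_min = 1.5) {
  grp <- names(config$group_sizes)
  out <- list()
  for (m in config$modules) {
    if (isTRUE(m$sex_driven)) next
    pen <- m$penetrance[grp]
    pen[is.na(pen)] <- 0
    for (i in seq_along(grp)) for (j in seq_along(grp)) {
      if (i == j) next
      diff <- m$amplitude_log2 * (pen[i] - pen[j])
      if (abs(diff) >= log2(fc_min)) {
        out[[length(out) + 1L]] <- data.frame(
          module = m$name, groupA = grp[i], groupB = grp[j],
          expected_log2_diff = unname(diff),
          direction = if (diff > 0) "up" else "down",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(module = character(0), groupA = character(0),
                      groupB = character(0), expected_log2_diff = numeric(0),
                      direction = character(0)))
  }
  do.call(rbind, out)
}

#' Generate hemodynamic covariates coupled to module amplitudes
#'
#' For each catheterized group, each covariate is drawn as
#' `baseline_mean + coupling * sd * z(EDS amplitude) +
#' sd * sqrt(1 - coupling^2) * noise`, so the population correlation between
#' the covariate and the group's EDS activation equals the configured target.
#' Non-catheterized groups (Control, SSc) receive `NA` hemodynamics. Offsets
#' between catheterization and blood draw are uniform on 0..300 days, so the
#' four-month window filter is selective.
#'
#' @param subject_amplitudes data.frame with `sample_id`, `group` and one
#'   column per module (at least `EDS`), as produced by [generate_cohort()].
#' @param config a [cohort_config()]; uses its `hemodynamic_coupling` and
#'   `missing_rate`.
#' @return data.frame with columns `sample_id`, `group`, `RAmean` (mmHg),
#'   `CI` (L/min/m^2), `PVRI`, `PA_sat` (%), `sixMWD` (ft), `NYHA`,
#'   `days_cath_to_draw`. Cells blanked by missing-value injection are `NA`;
#'   the injected positions are returned in `attr(, "injected_missing")`.
#' @export
generate_hemodynamics <- function(subject_amplitudes, config) {
  stopifnot(is.data.frame(subject_amplitudes),
            all(c("sample_id", "group") %in% names(subject_amplitudes)))
  if (is.null(subject_amplitudes$EDS)) {
    # no erythroid module in this configuration: covariates are decoupled
    subject_amplitudes$EDS <- 0
  }
  for (cpl in config$hemodynamic_coupling) {
    if (any(abs(unlist(cpl)) >= 1)) stopf("couplings must lie in (-1, 1)")
  }
  base <- hemodynamic_baselines()
  n <- nrow(subject_amplitudes)
  covars <- c("RAmean", "CI", "PVRI", "PA_sat")
  out <- data.frame(sample_id = subject_amplitudes$sample_id,
                    group = subject_amplitudes$group,
                    stringsAsFactors = FALSE)
  for (v in covars) out[[v]] <- NA_real_
  out$sixMWD <- NA_real_
  out$NYHA <- NA_integer_
  out$days_cath_to_draw <- NA_real_

  for (g in intersect(unique(out$group), names(base))) {
    rows <- which(out$group == g)
    amp <- subject_amplitudes$EDS[rows]
    z <- if (length(rows) > 1 && stats::sd(amp) > 0) {
      as.numeric(scale(amp))
    } else rep(0, length(rows))
    cpl <- config$hemodynamic_coupling[[g]] %||% list()
    for (v in covars) {
      mu <- base[[g]][[v]][1]; sdv <- base[[g]][[v]][2]
      r <- cpl[[v]] %||% 0
      x <- mu + sdv * (r * z + sqrt(1 - r^2) * stats::rnorm(length(rows)))
      if (v == "PA_sat") x <- pmin(pmax(x, 0), 100)
      if (v %in% c("CI", "PVRI", "RAmean")) x <- pmax(x, 0.1)
      out[[v]][rows] <- x
    }
    out$sixMWD[rows] <- pmax(stats::rnorm(length(rows), 1100, 350), 0)
    out$NYHA[rows] <- sample(1:4, length(rows), replace = TRUE,
                             prob = c(0.05, 0.35, 0.45, 0.15))
    out$days_cath_to_draw[rows] <- stats::runif(length(rows), 0, 300)
  }

  injected <- data.frame(sample_id = character(0), covariate = character(0))
  if (config$missing_rate > 0) {
    cath <- which(out$group %in% names(base))
    cells <- expand.grid(row = cath, covariate = covars,
                         stringsAsFactors = FALSE)
    hit <- which(stats::runif(nrow(cells)) < config$missing_rate)
    for (k in hit) out[[cells$covariate[k]]][cells$row[k]] <- NA_real_
    injected <- data.frame(sample_id = out$sample_id[cells$row[hit]],
                           covariate = cells$covariate[hit],
                           stringsAsFactors = FALSE)
  }
  attr(out, "injected_missing") <- injected
  out
}
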