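#' Specification of one planted correlated gene module
#'
#' A module is a block of probes whose expression is driven by a shared
#' per-subject activation amplitude. Penetrance gives, per subject group, the
#' fraction of subjects in which the module is active; activation is graded
#' (log-normally jittered around `amplitude_log2`), not binary, so cohorts show
#' the spread of signature levels seen in real PBMC data.
#'
#' @param name module label, e.g. `"EDS"`.
#' @param probe_count number of member probes.
#' @param penetrance named numeric vector, group -> fraction of subjects with
#'   the module active. Groups not named default to 0.
#' @param amplitude_log2 mean activation effect on the log2 scale (may be
#'   negative for down-regulated modules).
#' @param within_module_corr target pairwise correlation of member probes
#'   across the cohort, in (0, 1).
#' @param cross_module_corr named numeric vector: target correlation of this
#'   module's subject amplitudes with those of previously declared modules.
#' @param n_genes number of unique gene symbols over the probes; if smaller
#'   than `probe_count`, some genes get several probes (as on bead arrays).
#'   Defaults to `probe_count`.
#' @param sex_driven if `TRUE` the module's activation is determined by the
#'   simulated sex label instead of penetrance draws (positive-control
#'   cluster).
#' @return an object of class `module_spec`.
#' @export
module_spec <- function(name, probe_count, penetrance, amplitude_log2,
                        within_module_corr = 0.8, cross_module_corr = NULL,
                        n_genes = probe_count, sex_driven = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, probe_count >= 1)
  if (any(penetrance < 0 | penetrance > 1)) {
    stopf("module '%s': penetrance must lie in [0, 1]", name)
  }
  if (within_module_corr <= 0 || within_module_corr >= 1) {
    stopf("module '%s': within_module_corr must lie in (0, 1)", name)
  }
  if (!is.null(cross_module_corr) &&
      any(abs(cross_module_corr) >= 1)) {
    stopf("module '%s': cross-module correlations must lie in (-1, 1)", name)
  }
  if (n_genes > probe_count) stopf("module '%s': n_genes > probe_count", name)
  structure(
    list(name = name, probe_count = as.integer(probe_count),
         penetrance = penetrance, amplitude_log2 = amplitude_log2,
         within_module_corr = within_module_corr,
         cross_module_corr = cross_module_corr,
         n_genes = as.integer(n_genes), sex_driven = sex_driven),
    class = "module_spec")
}

#' Default planted modules of the five-group PBMC cohort
#'
#' Six modules emulating the major correlated expression patterns of a PBMC
#' pulmonary-hypertension study: an erythroid development signature (EDS, 169
#' probes / 149 genes) penetrant mainly in the PH groups; a platelet signature
#' (PL, 456 probes / 384 genes) whose subject amplitudes correlate 0.6 with the
#' EDS; immune-response blocks up- and down-regulated in all disease groups
#' (IR_UR, IR_DR); a nonspecifically distributed immature-neutrophil signature
#' (INS); and a sex-driven positive-control cluster (SEX).
#'
#' @return list of [module_spec()] objects.
#' @export
default_module_specs <- function() {
  ph <- c(Control = 0.02, SSc = 0.10, IPAH = 0.50,
          "SSc-PAH" = 0.50, "SSc-PH-ILD" = 0.90)
  disease <- c(Control = 0.02, SSc = 0.90, IPAH = 0.90,
               "SSc-PAH" = 0.90, "SSc-PH-ILD" = 0.90)
  list(
    module_spec("EDS", 169, penetrance = ph, amplitude_log2 = 2.0,
                within_module_corr = 0.8, n_genes = 149),
    module_spec("PL", 456,
                penetrance = c(Control = 0.05, SSc = 0.10, IPAH = 0.50,
                               "SSc-PAH" = 0.50, "SSc-PH-ILD" = 0.50),
                amplitude_log2 = 1.5, within_module_corr = 0.8,
                cross_module_corr = c(EDS = 0.6), n_genes = 384),
    module_spec("IR_UR", 81, penetrance = disease, amplitude_log2 = 1.5,
                within_module_corr = 0.8),
    module_spec("IR_DR", 58, penetrance = disease, amplitude_log2 = -1.5,
                within_module_corr = 0.8),
    module_spec("INS", 40,
                penetrance = c(Control = 0.10, SSc = 0.30, IPAH = 0.40,
                               "SSc-PAH" = 0.40, "SSc-PH-ILD" = 0.40),
                amplitude_log2 = 1.8, within_module_corr = 0.8),
    module_spec("SEX", 10, penetrance = c(Control = 0), amplitude_log2 = 3.0,
                within_module_corr = 0.9, sex_driven = TRUE)
  )
}

# Hemodynamic baselines (mean, SD) per catheterized group, and female
# fractions per group, as in the study cohort's demographic table.
hemodynamic_baselines <- function() {
  list(
    IPAH = list(RAmean = c(7.7, 4.2), CI = c(2.61, 0.69),
                PVRI = c(1214, 573), PA_sat = c(66.1, 9.1)),
    "SSc-PAH" = list(RAmean = c(7.9, 4.4), CI = c(2.66, 0.74),
                     PVRI = c(955, 556), PA_sat = c(67.1, 8.0)),
    "SSc-PH-ILD" = list(RAmean = c(7.5, 3.8), CI = c(2.88, 0.80),
                        PVRI = c(1042, 610), PA_sat = c(66.9, 6.7))
  )
}

female_fractions <- function() {
  c(Control = 0.829, SSc = 1.0, IPAH = 0.833,
    "SSc-PAH" = 0.786, "SSc-PH-ILD" = 0.75)
}

#' Configuration of a synthetic PBMC cohort
#'
#' Defaults reproduce the study conditions: 140 subjects in five groups
#' (Control 41, SSc 19, IPAH 30, SSc-PAH 42, SSc-PH-ILD 8), 20000 probes, the
#' six default modules, log2-scale noise SD 0.5, expressed-probe baseline at
#' log2 = 8 (intensity 256), 35% of probes unexpressed background, and IPAH
#' hemodynamics coupled to the EDS amplitude at the correlations reported for
#' that group (RAmean 0.776, PVRI 0.752, PA saturation -0.71, CI -0.449) with
#' the SSc-PAH and SSc-PH-ILD groups decoupled.
#'
#' @param group_sizes named integer vector of subjects per group.
#' @param n_probes total probes on the simulated array.
#' @param modules list of [module_spec()]; probe assignments are disjoint.
#' @param noise_sd log2-scale SD of per-probe, per-sample noise.
#' @param baseline_log2_mean location of expressed-probe baselines.
#' @param detection_background_fraction fraction of probes that are
#'   unexpressed background (high detection p, low intensity).
#' @param hemodynamic_coupling nested named list group -> covariate -> target
#'   correlation of the covariate with the group's EDS amplitude.
#' @param missing_rate fraction of hemodynamic cells flagged missing.
#' @param sample_scale_sd log2-scale SD of the per-sample multiplicative scale
#'   jitter that median scaling must remove.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(group_sizes = c(Control = 41, SSc = 19, IPAH = 30,
                                          "SSc-PAH" = 42, "SSc-PH-ILD" = 8),
                          n_probes = 20000,
                          modules = default_module_specs(),
                          noise_sd = 0.5,
                          baseline_log2_mean = 8,
                          detection_background_fraction = 0.35,
                          hemodynamic_coupling = default_hemodynamic_coupling(),
                          missing_rate = 0,
                          sample_scale_sd = 0.15) {
  group_sizes <- unlist(group_sizes)  # tolerate YAML/JSON named lists
  if (any(group_sizes < 1)) stopf("all group sizes must be >= 1")
  if (is.null(names(group_sizes)) || anyDuplicated(names(group_sizes))) {
    stopf("group_sizes must have unique names")
  }
  total_module <- sum(vapply(modules, function(m) m$probe_count, integer(1)))
  if (n_probes < total_module) {
    stopf("n_probes (%d) < total planted module probes (%d)",
          n_probes, total_module)
  }
  nm <- vapply(modules, function(m) m$name, character(1))
  if (anyDuplicated(nm)) stopf("module names must be unique")
  for (m in modules) {
    for (ref in names(m$cross_module_corr)) {
      if (!ref %in% nm[seq_len(match(m$name, nm) - 1L)]) {
        stopf("module '%s' references '%s', which must be declared earlier",
              m$name, ref)
      }
    }
  }
  for (cpl in hemodynamic_coupling) {
    if (any(abs(unlist(cpl)) >= 1)) stopf("couplings must lie in (-1, 1)")
  }
  structure(
    list(group_sizes = group_sizes, n_probes = as.integer(n_probes),
         modules = modules, noise_sd = noise_sd,
         baseline_log2_mean = baseline_log2_mean,
         detection_background_fraction = detection_background_fraction,
         hemodynamic_coupling = hemodynamic_coupling,
         missing_rate = missing_rate, sample_scale_sd = sample_scale_sd),
    class = "cohort_config")
}

#' Default EDS-hemodynamics couplings
#'
#' IPAH covariates track the EDS activation amplitude at the correlations
#' reported for that group; the SSc-PAH and SSc-PH-ILD groups are decoupled
#' (coupling 0), reproducing the dissociation between EDS level and
#' hemodynamic severity outside IPAH.
#'
#' @return nested list group -> covariate -> correlation.
#' @export
default_hemodynamic_coupling <- function() {
  zero <- list(RAmean = 0, PVRI = 0, PA_sat = 0, CI = 0)
  list(
    IPAH = list(RAmean = 0.776, PVRI = 0.752, PA_sat = -0.71, CI = -0.449),
    "SSc-PAH" = zero,
    "SSc-PH-ILD" = zero
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic PBMC cohort configuration\n")
  cat(sprintf("  groups: %s (n = %d)\n",
              paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes),
                    collapse = ", "), sum(x$group_sizes)))
  cat(sprintf("  probes: %d (%d in %d planted modules)\n", x$n_probes,
              sum(vapply(x$modules, function(m) m$probe_count, integer(1))),
              length(x$modules)))
  cat(sprintf("  noise SD (log2): %.2f; background fraction: %.2f\n",
              x$noise_sd, x$detection_background_fraction))
  invisible(x)
}
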