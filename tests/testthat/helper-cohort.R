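# Shared fixtures: scaled-down cohort configurations so unit tests run in
# seconds while keeping the five-group structure and all six module kinds.

small_modules <- function(eds_amplitude = 2.0) {
  ph <- c(Control = 0.02, SSc = 0.10, IPAH = 0.50,
          "SSc-PAH" = 0.50, "SSc-PH-ILD" = 0.90)
  disease <- c(Control = 0.02, SSc = 0.90, IPAH = 0.90,
               "SSc-PAH" = 0.90, "SSc-PH-ILD" = 0.90)
  list(
    module_spec("EDS", 40, penetrance = ph, amplitude_log2 = eds_amplitude,
                within_module_corr = 0.8, n_genes = 36),
    module_spec("PL", 60,
                penetrance = c(Control = 0.05, SSc = 0.10, IPAH = 0.50,
                               "SSc-PAH" = 0.50, "SSc-PH-ILD" = 0.50),
                amplitude_log2 = 1.5, within_module_corr = 0.8,
                cross_module_corr = c(EDS = 0.6), n_genes = 54),
    module_spec("IR_UR", 25, penetrance = disease, amplitude_log2 = 1.5,
                within_module_corr = 0.7),
    module_spec("IR_DR", 20, penetrance = disease, amplitude_log2 = -1.5,
                within_module_corr = 0.7),
    module_spec("INS", 12,
                penetrance = c(Control = 0.10, SSc = 0.30, IPAH = 0.40,
                               "SSc-PAH" = 0.40, "SSc-PH-ILD" = 0.40),
                amplitude_log2 = 1.8, within_module_corr = 0.7),
    module_spec("SEX", 8, penetrance = c(Control = 0), amplitude_log2 = 3.0,
                within_module_corr = 0.9, sex_driven = TRUE)
  )
}

small_config <- function(n_probes = 1200, ...) {
  cohort_config(
    group_sizes = c(Control = 20, SSc = 10, IPAH = 15,
                    "SSc-PAH" = 15, "SSc-PH-ILD" = 6),
    n_probes = n_probes,
    modules = small_modules(),
    ...)
}

small_cohort <- function(seed = 42, ...) generate_cohort(small_config(...), seed)

# two-group config with no planted signal (penetrance 0 everywhere)
null_config <- function(n_probes = 2000) {
  cohort_config(
    group_sizes = c(Control = 41, IPAH = 30),
    n_probes = n_probes,
    modules = list(module_spec("EDS", 40,
                               penetrance = c(Control = 0, IPAH = 0),
                               amplitude_log2 = 2.0)))
}

# two-group config with one fully penetrant planted module (power scenario)
power_config <- function(n_probes = 2000, amplitude = 2.0) {
  cohort_config(
    group_sizes = c(Control = 41, IPAH = 30),
    n_probes = n_probes,
    modules = list(module_spec("DEMOD", 100,
                               penetrance = c(Control = 0, IPAH = 1),
                               amplitude_log2 = amplitude)))
}

module_probes <- function(cohort, module) {
  mm <- cohort$truth$module_membership
  mm$probe_id[mm$module == module]
}

module_genes <- function(cohort, module) {
  mm <- cohort$truth$module_membership
  unique(stats::na.omit(mm$symbol[mm$module == module]))
}

# map discovered signature models onto planted modules by majority membership
match_models_to_modules <- function(models, cohort) {
  memb <- stats::setNames(cohort$truth$module_membership$module,
                          cohort$truth$module_membership$probe_id)
  vapply(models, function(m) {
    hits <- memb[m$members$probe_id]
    hits <- hits[!is.na(hits)]
    if (!length(hits)) return(NA_character_)
    names(sort(table(hits), decreasing = TRUE))[1]
  }, character(1))
}
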