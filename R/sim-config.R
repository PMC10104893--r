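SIM_CATEGORIES <- c("control_only", "ko_only_scap_dep", "ko_only_scap_indep",
                    "shared", "arrhythmic")

#' Configuration of the synthetic-data generator
#'
#' Defines a multi-genotype diurnal time-course simulation with planted
#' rhythm-remodeling ground truth. Features fall into five categories:
#' `control_only` (rhythm in the control genotype only, i.e. lost upon KO),
#' `ko_only_scap_dep` (gained in the KO, absent again in the triple KO),
#' `ko_only_scap_indep` (gained in the KO and persisting in the triple KO),
#' `shared` (rhythmic in all genotypes) and `arrhythmic` (the majority
#' background). Category assignment is deterministic -- the first
#' `floor(f * n)` features go to each category in the order above, the
#' remainder to `arrhythmic` -- so truth-table fractions are exact.
#'
#' Planted rhythms follow the cosine mean model
#' `b * (1 + a * cos(2 * pi * (t - phase) / 24))` with
#' `a = relative_amplitude`, so the peak/trough ratio of the per-timepoint
#' means is `(1 + a) / (1 - a)` (3 at the default `a = 0.5`). The default
#' phases (ZT15 for control-planted rhythms, ZT3 for KO-gained ones) lie on
#' the default 3/9/15/21 h grid, making that ratio exact on the grid.
#'
#' @param seed Integer seed; every simulation is reproducible given it.
#' @param n_features Number of features.
#' @param timepoints ZT sampling times (default 3, 9, 15, 21).
#' @param replicates Replicates per timepoint (>= 2; default 3).
#' @param genotypes Ordered genotype labels; position 1 is the control,
#'   2 the KO, 3 (when present) the triple KO.
#' @param category_fractions Named proportions over the five categories,
#'   summing to 1.
#' @param baseline_log_mean,baseline_log_sd Lognormal baseline parameters.
#' @param relative_amplitude Relative cosine amplitude `a` in (0, 1].
#' @param dispersion Negative-binomial size parameter for count noise (> 0).
#' @param fragment_depth Mean fragments per locus per sample in the enhancer
#'   simulation.
#' @param lipid_log_sd Lognormal noise sd for lipid abundances.
#' @param phase_lost ZT peak phase planted for control-side rhythms
#'   (`control_only`, `shared`).
#' @param phase_gained ZT peak phase planted for KO-gained rhythms.
#' @param phase_mode `"crisp"` plants phases exactly; `"noisy"` jitters each
#'   feature's phase by up to +/- 1 h.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_features = 2000L,
                       timepoints = c(3, 9, 15, 21),
                       replicates = 3L,
                       genotypes = c("control", "dko", "tko"),
                       category_fractions = c(control_only = 0.15,
                                              ko_only_scap_dep = 0.135,
                                              ko_only_scap_indep = 0.015,
                                              shared = 0.10,
                                              arrhythmic = 0.60),
                       baseline_log_mean = log(100),
                       baseline_log_sd = 0.5,
                       relative_amplitude = 0.5,
                       dispersion = 10,
                       fragment_depth = 100,
                       lipid_log_sd = 0.2,
                       phase_lost = 15,
                       phase_gained = 3,
                       phase_mode = c("crisp", "noisy")) {
  phase_mode <- match.arg(phase_mode)
  if (abs(sum(category_fractions) - 1) > 1e-9)
    stop("category_fractions must sum to 1")
  if (!all(names(category_fractions) %in% SIM_CATEGORIES))
    stop("unknown category in category_fractions; allowed: ",
         paste(SIM_CATEGORIES, collapse = ", "))
  if (any(category_fractions < 0)) stop("category_fractions must be non-negative")
  if (any(diff(timepoints) <= 0) || any(timepoints < 0 | timepoints >= 24))
    stop("timepoints must be strictly increasing and in [0, 24)")
  if (replicates < 2) stop("replicates must be >= 2")
  if (dispersion <= 0) stop("dispersion must be > 0")
  if (relative_amplitude <= 0 || relative_amplitude > 1)
    stop("relative_amplitude must be in (0, 1]")
  if (length(genotypes) < 2) stop("at least two genotypes are required")
  fr <- setNames(rep(0, length(SIM_CATEGORIES)), SIM_CATEGORIES)
  fr[names(category_fractions)] <- category_fractions
  structure(list(seed = as.integer(seed), n_features = as.integer(n_features),
                 timepoints = as.numeric(timepoints),
                 replicates = as.integer(replicates),
                 genotypes = genotypes, category_fractions = fr,
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 relative_amplitude = relative_amplitude,
                 dispersion = dispersion, fragment_depth = fragment_depth,
                 lipid_log_sd = lipid_log_sd,
                 phase_lost = phase_lost, phase_gained = phase_gained,
                 phase_mode = phase_mode),
            class = "sim_config")
}

#' Lipidomics flavor of the simulation configuration
#'
#' Same generator, with defaults sized to a lipidomics panel: 400 species of
#' which 48 lose rhythm upon KO, 80 gain it (72 of them SCAP-dependent) and
#' 32 are rhythmic throughout, over a 60% arrhythmic background.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
lipid_sim_config <- function(seed = 1L, ...) {
  args <- list(...)
  defaults <- list(seed = seed, n_features = 400L,
                   category_fractions = c(control_only = 0.12,
                                          ko_only_scap_dep = 0.18,
                                          ko_only_scap_indep = 0.02,
                                          shared = 0.08,
                                          arrhythmic = 0.60),
                   baseline_log_mean = log(1e6), baseline_log_sd = 1)
  do.call(sim_config, modifyList(defaults, args))
}

#' Cosine mean model of a planted rhythm
#'
#' `baseline * (1 + a * cos(2 * pi * (zt - phase_zt) / 24))` with
#' `a = (amplitude_fold - 1) / (amplitude_fold + 1)`, so the continuous peak
#' and trough means are `baseline * (1 + a)` and `baseline * (1 - a)` and
#' their ratio is `amplitude_fold`. `amplitude_fold = 1` gives a flat mean.
#'
#' @param baseline Mean level (> 0).
#' @param amplitude_fold Planted peak/trough ratio (>= 1).
#' @param phase_zt Peak phase, ZT hours.
#' @param zt ZT times at which to evaluate.
#' @return Vector of means.
#' @export
rhythm_mean_model <- function(baseline, amplitude_fold, phase_zt, zt) {
  a <- (amplitude_fold - 1) / (amplitude_fold + 1)
  baseline * (1 + a * cos(2 * pi * (zt - phase_zt) / 24))
}

# deterministic category assignment: first floor(f*n) features per category,
# remainder arrhythmic
assign_categories <- function(n, fractions) {
  counts <- floor(fractions[setdiff(SIM_CATEGORIES, "arrhythmic")] * n)
  if (sum(counts) > n) stop("category fractions exceed the feature count")
  cats <- rep(names(counts), counts)
  c(cats, rep("arrhythmic", n - length(cats)))
}

# which genotypes a category plants a rhythm in, by role position
planted_in <- function(category, role) {
  switch(category,
         control_only = role == "control",
         ko_only_scap_dep = role == "ko",
         ko_only_scap_indep = role %in% c("ko", "tko"),
         shared = TRUE,
         arrhythmic = FALSE)
}

genotype_roles <- function(genotypes) {
  roles <- c("control", "ko", "tko")[seq_along(genotypes)]
  setNames(roles, genotypes)
}

# truth table: feature_id, category, baseline, phase_<g>, fold_<g> per genotype
# (consumes RNG: baselines, and phase jitter in noisy mode)
build_truth <- function(config, feature_prefix = "feature") {
  n <- config$n_features
  cats <- assign_categories(n, config$category_fractions)
  baseline <- rlnorm(n, config$baseline_log_mean, config$baseline_log_sd)
  fold <- (1 + config$relative_amplitude) / (1 - config$relative_amplitude)
  if (config$relative_amplitude == 1) fold <- Inf
  truth <- data.frame(feature_id = sprintf("%s_%04d", feature_prefix, seq_len(n)),
                      category = cats, baseline = baseline,
                      stringsAsFactors = FALSE)
  jit <- if (config$phase_mode == "noisy") runif(n, -1, 1) else rep(0, n)
  roles <- genotype_roles(config$genotypes)
  for (g in config$genotypes) {
    on <- vapply(cats, planted_in, logical(1), role = roles[[g]])
    base_phase <- ifelse(cats %in% c("control_only", "shared"),
                         config$phase_lost, config$phase_gained)
    truth[[paste0("phase_", g)]] <- ifelse(on, (base_phase + jit) %% 24, NA_real_)
    truth[[paste0("fold_", g)]] <- ifelse(on, fold, 1)
  }
  truth
}

sim_sample_sheet <- function(config) {
  grid <- time_grid(config$timepoints, config$replicates)
  do.call(rbind, lapply(config$genotypes, function(g) {
    data.frame(
      sample_id = sprintf("%s_ZT%g_rep%d", g,
                          rep(config$timepoints, each = config$replicates),
                          rep(seq_len(config$replicates), length(config$timepoints))),
      genotype = g,
      zt = rep(config$timepoints, each = config$replicates),
      replicate = rep(seq_len(config$replicates), length(config$timepoints)),
      stringsAsFactors = FALSE)
  }))
}
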