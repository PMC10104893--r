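#' Simulate multi-genotype time-course expression counts
#'
#' Draws one feature-by-sample count matrix per genotype from a negative
#' binomial whose mean follows the planted cosine model (see
#' [rhythm_mean_model()]): `NB(mu = b * (1 + a * cos(2 * pi * (t - phase) / 24)),
#' size = dispersion)`. The feature set and baselines are identical across
#' genotypes; only the planted amplitude/phase differ according to each
#' feature's remodeling category. The run is fully reproducible given
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `matrices` (named list per genotype), `truth` (planted
#'   feature table), `grid` ([time_grid()]), `sample_sheet`, `lengths`
#'   (named vector, 1000 bp per feature) and `libstats` (1e7 mapped reads
#'   per sample, so RPKTM equals the raw count at the default length).
#' @export
simulate_expression <- function(config = sim_config()) {
  set.seed(config$seed)
  truth <- build_truth(config, "gene")
  grid <- time_grid(config$timepoints, config$replicates)
  tt <- sample_times(grid)
  sheet <- sim_sample_sheet(config)
  n <- config$n_features
  tmat <- matrix(tt, n, length(tt), byrow = TRUE)
  matrices <- list()
  for (g in config$genotypes) {
    ph <- truth[[paste0("phase_", g)]]
    a <- (truth[[paste0("fold_", g)]] - 1) / (truth[[paste0("fold_", g)]] + 1)
    mu <- truth$baseline *
      (1 + ifelse(is.na(ph), 0, a) * cos(2 * pi * (tmat - ifelse(is.na(ph), 0, ph)) / 24))
    m <- matrix(rnbinom(length(mu), mu = mu, size = config$dispersion),
                nrow = n,
                dimnames = list(truth$feature_id,
                                sheet$sample_id[sheet$genotype == g]))
    matrices[[g]] <- m
  }
  lengths <- setNames(rep(1000, n), truth$feature_id)
  libstats <- data.frame(sample_id = sheet$sample_id,
                         total_mapped_reads = 1e7,
                         stringsAsFactors = FALSE)
  list(matrices = matrices, truth = truth, grid = grid, sample_sheet = sheet,
       lengths = lengths, libstats = libstats)
}

#' Simulate multi-genotype time-course lipid abundances
#'
#' As [simulate_expression()] but with multiplicative lognormal noise
#' (`mu * exp(N(0, lipid_log_sd))`) instead of counts, no length field, and
#' deterministic per-sample scale offsets (logarithmically spaced between
#' 1/3 and 3 across each genotype's samples) injected to exercise quantile
#' normalization. The truth table stores the unscaled means.
#'
#' @param config A [sim_config()]; see [lipid_sim_config()] for
#'   lipidomics-sized defaults.
#' @return List with `matrices`, `truth`, `grid`, `sample_sheet` and
#'   `scale_factors` (named per sample).
#' @export
simulate_lipids <- function(config = lipid_sim_config()) {
  set.seed(config$seed)
  truth <- build_truth(config, "lipid")
  grid <- time_grid(config$timepoints, config$replicates)
  tt <- sample_times(grid)
  sheet <- sim_sample_sheet(config)
  n <- config$n_features
  ns <- length(tt)
  tmat <- matrix(tt, n, ns, byrow = TRUE)
  scale_per_g <- exp(seq(log(1 / 3), log(3), length.out = ns))
  matrices <- list()
  scale_factors <- numeric(0)
  for (g in config$genotypes) {
    ph <- truth[[paste0("phase_", g)]]
    a <- (truth[[paste0("fold_", g)]] - 1) / (truth[[paste0("fold_", g)]] + 1)
    mu <- truth$baseline *
      (1 + ifelse(is.na(ph), 0, a) * cos(2 * pi * (tmat - ifelse(is.na(ph), 0, ph)) / 24))
    noise <- matrix(exp(rnorm(n * ns, 0, config$lipid_log_sd)), n, ns)
    m <- mu * noise
    m <- sweep(m, 2, scale_per_g, "*")
    dimnames(m) <- list(truth$feature_id, sheet$sample_id[sheet$genotype == g])
    matrices[[g]] <- m
    scale_factors <- c(scale_factors,
                       setNames(scale_per_g, colnames(m)))
  }
  list(matrices = matrices, truth = truth, grid = grid, sample_sheet = sheet,
       scale_factors = scale_factors)
}
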