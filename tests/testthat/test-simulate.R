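test_that("simulation is byte-identical for a fixed seed", {
  cfg <- sim_config(seed = 7, n_features = 50)
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a$matrices, b$matrices)
  expect_identical(a$truth, b$truth)
  l1 <- simulate_lipids(lipid_sim_config(seed = 7, n_features = 50))
  l2 <- simulate_lipids(lipid_sim_config(seed = 7, n_features = 50))
  expect_identical(l1$matrices, l2$matrices)
})

test_that("analytic per-timepoint mean ratio equals the planted amplitude fold", {
  cfg <- sim_config(seed = 1, n_features = 40)
  sim <- simulate_expression(cfg)
  tr <- sim$truth
  for (g in cfg$genotypes) {
    fold <- tr[[paste0("fold_", g)]]
    ph <- tr[[paste0("phase_", g)]]
    for (i in which(fold > 1)) {
      mu <- rhythm_mean_model(tr$baseline[i], fold[i], ph[i], cfg$timepoints)
      expect_equal(max(mu) / min(mu), fold[i], tolerance = 1e-9)
    }
  }
})

test_that("flat features have equal population means; planted means match Monte Carlo", {
  # all-flat config: per-timepoint sample means equal within sampling error
  cfg <- sim_config(seed = 2, n_features = 400,
                    category_fractions = c(arrhythmic = 1))
  sim <- simulate_expression(cfg)
  m <- sim$matrices$control
  tp <- rep(cfg$timepoints, each = cfg$replicates)
  tp_means <- vapply(split(seq_len(ncol(m)), tp), function(j) mean(m[, j]), 0)
  expect_lt(diff(range(tp_means)) / mean(tp_means), 0.05)

  # planted b=100, fold 3, phase 15: sample means vs the closed-form means
  # at 10^4 draws per timepoint
  cfg2 <- sim_config(seed = 3, n_features = 4, replicates = 2500,
                     category_fractions = c(control_only = 1),
                     baseline_log_sd = 1e-9, baseline_log_mean = log(100))
  sim2 <- simulate_expression(cfg2)
  mu <- rhythm_mean_model(100, 3, 15, cfg2$timepoints)  # 50, 100, 150, 100
  expect_equal(mu, c(50, 100, 150, 100), tolerance = 1e-12)
  m2 <- sim2$matrices$control
  tp2 <- rep(cfg2$timepoints, each = cfg2$replicates)
  for (k in seq_along(cfg2$timepoints)) {
    got <- mean(m2[1, tp2 == cfg2$timepoints[k]])
    expect_equal(got, mu[k], tolerance = 0.02 * mu[k])
  }
})

test_that("deterministic category assignment makes truth fractions exact", {
  cfg <- sim_config(seed = 1, n_features = 2000)
  sim <- simulate_expression(cfg)
  counts <- table(sim$truth$category)
  expect_equal(unname(counts["control_only"]), 300)
  expect_equal(unname(counts["ko_only_scap_dep"]), 270)
  expect_equal(unname(counts["ko_only_scap_indep"]), 30)
  expect_equal(unname(counts["shared"]), 200)
  expect_equal(unname(counts["arrhythmic"]), 1200)
  # lipid defaults reproduce the 48 lost / 80 gained / 72-of-80 structure
  lt <- simulate_lipids(lipid_sim_config(seed = 1))$truth
  gained <- lt$category %in% c("ko_only_scap_dep", "ko_only_scap_indep")
  expect_equal(sum(lt$category == "control_only"), 48)
  expect_equal(sum(gained), 80)
  expect_equal(mean(lt$category[gained] == "ko_only_scap_dep"), 0.9)
})

test_that("category invariants hold: rhythm planted only where the category says", {
  cfg <- sim_config(seed = 4, n_features = 100)
  tr <- simulate_expression(cfg)$truth
  expect_true(all(tr$fold_control[tr$category %in%
    c("ko_only_scap_dep", "ko_only_scap_indep", "arrhythmic")] == 1))
  expect_true(all(tr$fold_dko[tr$category == "ko_only_scap_dep"] > 1))
  expect_true(all(tr$fold_tko[tr$category == "ko_only_scap_dep"] == 1))
  expect_true(all(tr$fold_tko[tr$category == "ko_only_scap_indep"] > 1))
  expect_true(all(tr$fold_dko[tr$category == "control_only"] == 1))
})

test_that("lipid simulation injects column scale offsets the truth ignores", {
  cfg <- lipid_sim_config(seed = 5, n_features = 30)
  sim <- simulate_lipids(cfg)
  expect_equal(unname(range(sim$scale_factors)), c(1 / 3, 3), tolerance = 1e-9)
  # undoing the per-sample scales leaves roughly level column medians
  m <- sim$matrices$control
  sf <- sim$scale_factors[colnames(m)]
  unscaled <- sweep(m, 2, sf, "/")
  cv_raw <- sd(apply(m, 2, median)) / mean(apply(m, 2, median))
  cv_unscaled <- sd(apply(unscaled, 2, median)) / mean(apply(unscaled, 2, median))
  expect_gt(cv_raw, 2 * cv_unscaled)
  expect_false(any(grepl("sample", names(sim$truth))))
})

test_that("enhancer simulation labels boundary peaks and follows the cosine fragment model", {
  cfg <- sim_config(seed = 6, n_features = 4, genotypes = c("control", "dko"),
                    fragment_depth = 1000, relative_amplitude = 0.6,
                    category_fractions = c(control_only = 1))
  sim <- simulate_enhancer_data(cfg)
  tr <- sim$truth
  expect_equal(tr$status[tr$peak_id == "pk_body"], "excluded")
  expect_equal(tr$status[tr$peak_id == "pk_999"], "excluded")
  expect_equal(tr$status[tr$peak_id == "pk_1001"], "retained")
  expect_equal(tr$status[tr$peak_id == "pk_touch"], "retained")

  # planted fold-4 loci: window counts reproduce the cosine mean within
  # Poisson error at this depth
  zones <- exclusion_zones(sim$genes)
  kept <- intergenic_peaks(sim$peaks, zones)
  loci <- make_loci(kept, seqlengths = sim$seqlengths)
  counts <- count_fragments(loci, sim$fragments,
                            sample_ids = sim$sample_sheet$sample_id)
  planted <- tr[tr$fold_control > 1, ]
  expect_equal((1 + 0.6) / (1 - 0.6), 4)
  for (pid in planted$peak_id[1:3]) {
    for (t in cfg$timepoints) {
      cols <- sim$sample_sheet$sample_id[sim$sample_sheet$genotype == "control" &
                                           sim$sample_sheet$zt == t]
      lam <- 1000 * (1 + 0.6 * cos(2 * pi * (t - 15) / 24))
      got <- mean(counts[pid, cols])
      expect_lt(abs(got - lam), 5 * sqrt(lam / length(cols)))
    }
  }
})

test_that("generated files round-trip through the package readers", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 9, n_features = 20)
  out <- run_simulate(dir, seed = 9, transcripts = cfg,
                      enhancers = sim_config(seed = 10, n_features = 8),
                      lipids = lipid_sim_config(seed = 11, n_features = 20))
  m <- read_matrix_tsv(file.path(dir, "transcripts/counts_control.tsv"))
  expect_equal(m, out$transcripts$matrices$control)
  tr <- read_tsv_table(file.path(dir, "transcripts/truth.tsv"))
  expect_equal(tr$category, out$transcripts$truth$category)
  genes <- read_gene_models(file.path(dir, "enhancers/annotation.gtf"))
  expect_equal(GenomicRanges::start(genes), GenomicRanges::start(out$enhancers$genes))
  expect_equal(genes$biotype, out$enhancers$genes$biotype)
  peaks <- read_bed(file.path(dir, "enhancers/peaks.bed"))
  expect_equal(GenomicRanges::start(peaks), GenomicRanges::start(out$enhancers$peaks))
  expect_equal(peaks$name, out$enhancers$peaks$name)
  fr <- read_fragments_tsv(file.path(dir, "enhancers/fragments.tsv"))
  expect_equal(nrow(fr), nrow(out$enhancers$fragments))
  expect_equal(fr$start, out$enhancers$fragments$start)
})
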