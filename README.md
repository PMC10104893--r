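# chronoremodel

Detection of diurnal (~24 h) rhythms in short time-course omics data and
classification of how those rhythms remodel between genotypes.

## What it is for

Time-course studies of the liver clock ask, per transcript, enhancer locus
or lipid species: *is it rhythmic in this genotype, and what happens to
that rhythm when the clock (or a signaling pathway such as SCAP/SREBP) is
knocked out?* Typical designs are small — four zeitgeber times (ZT 3, 9,
15, 21) with three replicates — and span one day. `chronoremodel`
implements the standard analysis chain for that question:

- a **JTK_CYCLE-style nonparametric test**: the series is compared against
  cosine reference waveforms by Kendall's S,
  `S = sum over pairs of sign(x_i - x_j) * sign(r_i - r_j)`,
  with an **exact null distribution** of S (Gaussian-multinomial
  convolution, valid under arbitrary reference tie structures, proven
  against exhaustive enumeration), Bonferroni over the (period, lag)
  waveform grid, and Benjamini–Hochberg adjustment across features;
- the **series-duplication preprocessing** for 4-timepoint designs (the
  vector is duplicated and tested as 8 timepoints over 48 h);
- **oscillation calls** at the standard thresholds: adjusted P < 0.05,
  peak/trough amplitude > 1.5, period 21–24 h (relaxed to adjusted
  P < 0.06 and max RPKTM > 0.2 for enhancers);
- normalization and filtering: **RPKTM**
  (`count / (length/1kb) / (reads/1e7)`), detection filters, and
  **quantile normalization** for lipidomics;
- an **enhancer stage**: intergenic ATAC peaks (1 kb-extended
  coding/lncRNA exclusion zones), eRNA counting in half-open 1000 bp
  windows around peak centers by fragment midpoint;
- **remodeling set logic**: control-specific (lost), KO-specific (gained),
  shared (with amplified/attenuated flags), arrhythmic; SCAP dependence as
  restoration in a triple KO; phase-enrichment histograms with a Rayleigh
  test; TF activity/target phase matching;
- a **synthetic-data generator** that plants all of the above as ground
  truth, so every stage is validated end to end.

## Worked example

```r
library(chronoremodel)
sim <- simulate_expression(sim_config(seed = 42, n_features = 300))
res <- jtk_test(sim$matrices$control, sim$grid)   # duplicated-series JTK
head(res[order(res$p_adj), ], 5)
#>     feature_id    p_raw    p_adj period_h peak_zt amplitude_fold  ties rhythmic
#> 26   gene_0026 1.20e-08 9.00e-07       24      15           5.78 FALSE     TRUE
#> 93   gene_0093 1.20e-08 9.00e-07       24      15           4.51 FALSE     TRUE
#> 98   gene_0098 1.20e-08 9.00e-07       24      15           5.65  TRUE     TRUE
#> 104  gene_0104 1.20e-08 9.00e-07       24      15           4.93 FALSE     TRUE
#> 6    gene_0006 4.56e-07 1.24e-05       24      15           3.69 FALSE     TRUE
```

Each row is one feature: the raw and BH-adjusted exact p, the best-fitting
period and peak phase (these planted rhythms peak at ZT15, correctly
recovered), the peak/trough amplitude of the per-timepoint means, and the
oscillation call at the standard thresholds.

Cross-genotype remodeling against the double and triple KO:

```r
results <- lapply(sim$matrices, function(m) jtk_test(m, sim$grid))
calls <- classify_remodeling(results, control = "control", ko = "dko")
sd <- scap_dependence(calls, results$tko)
table(sd$calls$category)
#>       arrhythmic control_specific      ko_specific           shared
#>              172               56               50               22
sd$summary$fraction_restored
#> [1] 0.74
phase_histogram(results$control$peak_zt[results$control$rhythmic])
#> phase_enrichment: n = 78, modal bin(s) starting ZT 15, Rayleigh P = 9.2e-23
```

56 features lost their rhythm upon KO and 50 gained one, of which 74% were
restored (no longer rhythmic) in the triple KO; the rhythmic cohort peaks
in the ZT15 bin, matching the planted phase.

The full pipelines (`run_simulate()`, `run_transcripts()`,
`run_enhancers()`, `run_lipids()`) read/write plain TSV/GTF/BED files,
log the feature counts surviving each filtering stage, and are
byte-identical across re-runs with the same seed.

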