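gr <- function(contig, start0, end0, ...) {
  GenomicRanges::GRanges(contig, IRanges::IRanges(start0 + 1, end0), ...)
}
coords0 <- function(x) cbind(GenomicRanges::start(x) - 1, GenomicRanges::end(x))

test_that("exclusion zones extend gene bodies by 1 kb, merge and clip", {
  genes <- gr("c1", 5000, 8000, gene_id = "g", biotype = "coding")
  z <- exclusion_zones(genes)
  expect_equal(unname(coords0(z)), cbind(4000, 9000))

  # gene at the contig start clips at zero
  g2 <- gr("c1", 100, 500, gene_id = "g", biotype = "coding")
  expect_equal(unname(coords0(exclusion_zones(g2))), cbind(0, 1500))

  # two genes whose extensions overlap merge into one zone
  g3 <- c(gr("c1", 1000, 2000, gene_id = "a", biotype = "coding"),
          gr("c1", 2500, 3000, gene_id = "b", biotype = "lncRNA"))
  expect_equal(unname(coords0(exclusion_zones(g3))), cbind(0, 4000))

  # "other" biotypes create no zone
  g4 <- gr("c1", 1000, 2000, gene_id = "p", biotype = "other")
  expect_length(exclusion_zones(g4), 0)
})

test_that("intergenic filtering removes peaks overlapping a zone by >= 1 bp", {
  zones <- gr("c1", 4000, 9000)
  inside <- gr("c1", 5000, 5100, name = "inside")
  onebp <- gr("c1", 3001, 4001, name = "onebp")
  touch <- gr("c1", 3000, 4000, name = "touch")
  other_contig <- gr("c2", 4500, 4600, name = "c2peak")
  peaks <- suppressWarnings(c(inside, onebp, touch, other_contig))
  kept <- intergenic_peaks(peaks, zones)
  expect_setequal(kept$name, c("touch", "c2peak"))
  expect_equal(length(intergenic_peaks(peaks, GenomicRanges::GRanges())), 4)
})

test_that("loci are 1000 bp half-open windows around floored peak centers", {
  p <- c(gr("c1", 1000, 2000, name = "even"),
         gr("c1", 10010, 10021, name = "odd"))
  loci <- make_loci(p)
  expect_equal(loci$center, c(1500, 10015))
  expect_equal(unname(coords0(loci)), cbind(c(1000, 9515), c(2000, 10515)))
  expect_equal(loci$locus_id, c("even", "odd"))
  # clipping at contig bounds warns
  expect_warning(l2 <- make_loci(gr("c1", 0, 300, name = "edge"),
                                 seqlengths = c(c1 = 100000)), "clipped")
  expect_equal(unname(coords0(l2)), cbind(0, 650))
})

test_that("fragment counting uses half-open midpoint membership", {
  loci <- make_loci(gr("c1", 1000, 2000, name = "L"))  # window [1000, 2000)
  frag_at <- function(mid, sample = "s1")
    data.frame(sample_id = sample, contig = "c1", start = mid - 25, end = mid + 25)
  # midpoint exactly at window start counts; at window end it does not
  expect_equal(count_fragments(loci, frag_at(1000))["L", "s1"], 1L)
  expect_equal(count_fragments(loci, frag_at(2000))["L", "s1"], 0L)
  expect_equal(count_fragments(loci, frag_at(1999))["L", "s1"], 1L)
  ten <- do.call(rbind, lapply(seq(1100, 1900, length.out = 10), frag_at))
  expect_equal(count_fragments(loci, ten)["L", "s1"], 10L)
  # permutation invariance and additivity over sample pooling
  two <- rbind(frag_at(1500, "s1"), frag_at(1600, "s2"), frag_at(1700, "s2"))
  c2 <- count_fragments(loci, two)
  expect_equal(c2["L", ], c(s1 = 1L, s2 = 2L))
  c2p <- count_fragments(loci, two[sample(nrow(two)), ])
  expect_equal(c2p, c2)
  pooled <- two; pooled$sample_id <- "all"
  expect_equal(count_fragments(loci, pooled)["L", "all"], sum(c2))
})

test_that("presence filter keeps loci detected in at least two pooled samples", {
  m <- rbind(a = c(3, 1, 0, 0), b = c(5, 0, 0, 0), c = rep(0, 4))
  colnames(m) <- paste0("s", 1:4)
  expect_setequal(presence_filter(m), "a")
  expect_setequal(presence_filter(m, c("s1", "s2")), "a")
  expect_length(presence_filter(m[c("c"), , drop = FALSE]), 0)
  # expression rule applies a strict threshold: only "a" exceeds 0.5 twice
  expect_setequal(presence_filter(m, rule = "expression", min_value = 0.5), "a")
  expect_length(presence_filter(m, rule = "expression", min_value = 2), 0)
})

test_that("retained windows never overlap exclusion zones on simulated data", {
  sim <- simulate_enhancer_data(sim_config(seed = 12, n_features = 10))
  zones <- exclusion_zones(sim$genes)
  kept <- intergenic_peaks(sim$peaks, zones)
  loci <- make_loci(kept, seqlengths = sim$seqlengths)
  expect_length(audit_loci(loci, zones), 0)
})

test_that("rhythmic enhancers are recovered end to end at the relaxed thresholds", {
  cfg <- sim_config(seed = 13, n_features = 40, fragment_depth = 100,
                    relative_amplitude = 0.6)  # planted fold 4
  sim <- simulate_enhancer_data(cfg)
  zones <- exclusion_zones(sim$genes)
  loci <- make_loci(intergenic_peaks(sim$peaks, zones), seqlengths = sim$seqlengths)
  counts <- count_fragments(loci, sim$fragments, sample_ids = sim$sample_sheet$sample_id)
  ctrl <- sim$sample_sheet$sample_id[sim$sample_sheet$genotype == "control"]
  gs <- sim$sample_sheet[sim$sample_sheet$genotype == "control", ]
  grid <- time_grid(sort(unique(gs$zt)), replicates = max(gs$replicate))
  res <- suppressWarnings(call_rhythmic_enhancers(counts[, ctrl], grid, sim$libstats))
  tr <- sim$truth[match(rownames(counts), sim$truth$peak_id), ]
  planted <- tr$fold_control > 1
  expect_gte(mean(res$rhythmic[planted]), 0.9)
  expect_lte(mean(res$rhythmic[!planted]), 0.1)
  # the relaxed thresholds are wired in: p_adj < 0.06 strict, max RPKTM > 0.2
  expect_true(all(res$p_adj[res$rhythmic] < 0.06))
  expect_true(all(res$max_rpktm[res$rhythmic] > 0.2))
})
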