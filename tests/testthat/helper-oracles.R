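# Independent oracles and small builders shared across the test files.

# all permutations of 1..n as rows (n <= 8 keeps this < 41k rows)
perms <- function(n) {
  if (n == 1) return(matrix(1L))
  p <- perms(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    q <- p
    q[q >= k] <- q[q >= k] + 1L
    out[[k]] <- cbind(rep(k, nrow(q)), q, deparse.level = 0)
  }
  do.call(rbind, out)
}

# all integer partitions of n (as decreasing vectors of group sizes)
partitions <- function(n, max_part = n) {
  if (n == 0) return(list(integer(0)))
  out <- list()
  for (k in seq_len(min(n, max_part)))
    for (p in partitions(n - k, k)) out <- c(out, list(c(k, p)))
  out
}

# brute-force null of Kendall's S: enumerate every ordering of tie-free data
# against the tied reference rep(seq_along(groups), groups)
brute_s_dist <- function(groups) {
  n <- sum(groups)
  ref <- rep(seq_along(groups), groups)
  pm <- perms(n)
  s <- numeric(nrow(pm))
  ij <- combn(n, 2)
  for (k in seq_len(ncol(ij))) {
    i <- ij[1, k]; j <- ij[2, k]
    rs <- sign(ref[i] - ref[j])
    if (rs != 0) s <- s + sign(pm[, i] - pm[, j]) * rs
  }
  tab <- table(s)
  list(s = as.numeric(names(tab)), prob = as.numeric(tab) / nrow(pm))
}

# hand-coded BH step-up, independent of stats::p.adjust
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# noiseless cosine series on a grid
cosine_series <- function(grid, phase, baseline = 100, amp = 50) {
  rep(baseline + amp * cos(2 * pi * (grid$zt_times - phase) / 24),
      each = grid$replicates)
}

toy_path <- function(file) {
  p <- system.file("extdata", "toy", file, package = "chronoremodel")
  if (!nzchar(p)) p <- file.path("../../inst/extdata/toy", file)  # devtools::test()
  p
}

# map a planted truth category to the expected two-genotype remodeling call
truth_to_category <- function(category) {
  ifelse(category %in% c("ko_only_scap_dep", "ko_only_scap_indep"), "ko_specific",
  ifelse(category == "control_only", "control_specific",
  ifelse(category == "shared", "shared", "arrhythmic")))
}

# config builders over a run_simulate() output directory
tx_config <- function(dir, out_dir,
                      roles = list(control = "control", ko = "dko", triple_ko = "tko")) {
  list(counts = list(control = file.path(dir, "transcripts/counts_control.tsv"),
                     dko = file.path(dir, "transcripts/counts_dko.tsv"),
                     tko = file.path(dir, "transcripts/counts_tko.tsv")),
       sample_sheet = file.path(dir, "transcripts/sample_sheet.tsv"),
       lengths = file.path(dir, "transcripts/lengths.tsv"),
       libstats = file.path(dir, "transcripts/libstats.tsv"),
       roles = roles, out_dir = out_dir)
}

en_config <- function(dir, out_dir,
                      roles = list(control = "control", ko = "dko", triple_ko = "tko")) {
  list(annotation = file.path(dir, "enhancers/annotation.gtf"),
       peaks = file.path(dir, "enhancers/peaks.bed"),
       fragments = file.path(dir, "enhancers/fragments.tsv"),
       contigs = file.path(dir, "enhancers/contigs.tsv"),
       sample_sheet = file.path(dir, "enhancers/sample_sheet.tsv"),
       libstats = file.path(dir, "enhancers/libstats.tsv"),
       roles = roles, out_dir = out_dir)
}

lp_config <- function(dir, out_dir,
                      roles = list(control = "control", ko = "dko", triple_ko = "tko")) {
  list(abundance = list(control = file.path(dir, "lipids/abundance_control.tsv"),
                        dko = file.path(dir, "lipids/abundance_dko.tsv"),
                        tko = file.path(dir, "lipids/abundance_tko.tsv")),
       sample_sheet = file.path(dir, "lipids/sample_sheet.tsv"),
       roles = roles, out_dir = out_dir)
}

md5_tree <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = FALSE))
  vapply(files, function(f) unname(tools::md5sum(file.path(dir, f))), "")
}
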