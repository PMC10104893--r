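# fixed toy annotation used by the enhancer simulation: four genes on one
# contig, chosen so that peaks placed around them exercise the 1 kb-extension
# and half-open boundary rules (coordinates below are 0-based half-open)
toy_gene_table <- function() {
  data.frame(
    gene_id = c("G1", "G2", "G3", "G4"),
    contig = "chrS",
    start = c(5000, 10000, 20000, 30000),
    end = c(8000, 11000, 22000, 32000),
    biotype = c("coding", "coding", "lncRNA", "other"),
    stringsAsFactors = FALSE)
}

# boundary-case peaks with their expected intergenic status:
# zones are G1+G2 merged [4000, 12000) and G3 [19000, 23000); G4 ("other")
# creates no zone
toy_boundary_peaks <- function() {
  data.frame(
    peak_id = c("pk_body", "pk_1bp", "pk_touch", "pk_999", "pk_1000",
                "pk_1001", "pk_other"),
    start = c(6000, 3001, 3000, 22999, 23000, 23001, 30500),
    end = c(6500, 4001, 4000, 23999, 24000, 24001, 30900),
    status = c("excluded", "excluded", "retained", "excluded", "retained",
               "retained", "retained"),
    stringsAsFactors = FALSE)
}

#' Simulate enhancer inputs: annotation, ATAC peaks and eRNA fragments
#'
#' Builds a toy one-contig genome with four gene models (two coding, one
#' lncRNA, one other-biotype), a set of boundary-case peaks probing the 1 kb
#' TSS/TES extension rule, and `config$n_features` intergenic peaks with
#' planted rhythm categories. For every retained locus and sample, the
#' fragment count is Poisson with mean
#' `fragment_depth * (1 + a * cos(2 * pi * (t - phase) / 24))` and fragment
#' midpoints are uniform within the locus's 1000 bp window (the counting
#' rule, not spatial structure, is under test). Decoy fragments are placed in
#' the excluded peaks. Boundary-case retained peaks carry flat (arrhythmic)
#' signal.
#'
#' @param config A [sim_config()]; `n_features` is the number of planted
#'   intergenic loci (a few dozen is typical).
#' @return List with `genes` (`GRanges`), `peaks` (`GRanges` with `name`),
#'   `fragments` (data frame `sample_id`, `contig`, `start`, `end`, 0-based
#'   half-open), `truth` (peak table with `status`, `category`, per-genotype
#'   phase/fold), `grid`, `sample_sheet`, `libstats` (fixed 1e7 so window
#'   RPKTM equals the count) and `seqlengths`.
#' @export
simulate_enhancer_data <- function(config = sim_config(n_features = 60)) {
  set.seed(config$seed)
  n <- config$n_features
  gt <- toy_gene_table()
  bp <- toy_boundary_peaks()

  planted_start <- 1e6 + (seq_len(n) - 1) * 4000
  contig_len <- 1e6 + n * 4000 + 10000
  seqlengths <- c(chrS = contig_len)

  genes <- GenomicRanges::GRanges(gt$contig,
                                  IRanges::IRanges(gt$start + 1, gt$end),
                                  gene_id = gt$gene_id, biotype = gt$biotype,
                                  seqlengths = seqlengths)

  peak_df <- rbind(
    data.frame(peak_id = bp$peak_id, start = bp$start, end = bp$end,
               status = bp$status, stringsAsFactors = FALSE),
    data.frame(peak_id = sprintf("pk_%04d", seq_len(n)),
               start = planted_start, end = planted_start + 1000,
               status = "retained", stringsAsFactors = FALSE))
  peaks <- GenomicRanges::GRanges("chrS",
                                  IRanges::IRanges(peak_df$start + 1, peak_df$end),
                                  name = peak_df$peak_id,
                                  seqlengths = seqlengths)

  # planted categories for the n intergenic loci; boundary retained peaks
  # are flat, excluded peaks carry no category
  cats <- assign_categories(n, config$category_fractions)
  truth <- data.frame(peak_id = peak_df$peak_id,
                      start = peak_df$start, end = peak_df$end,
                      status = peak_df$status,
                      category = c(ifelse(bp$status == "retained",
                                          "arrhythmic", NA_character_), cats),
                      stringsAsFactors = FALSE)
  fold <- (1 + config$relative_amplitude) / (1 - config$relative_amplitude)
  roles <- genotype_roles(config$genotypes)
  for (g in config$genotypes) {
    on <- !is.na(truth$category) &
      vapply(ifelse(is.na(truth$category), "arrhythmic", truth$category),
             planted_in, logical(1), role = roles[[g]])
    base_phase <- ifelse(truth$category %in% c("control_only", "shared"),
                         config$phase_lost, config$phase_gained)
    truth[[paste0("phase_", g)]] <- ifelse(on, base_phase, NA_real_)
    truth[[paste0("fold_", g)]] <- ifelse(on, fold, 1)
  }

  grid <- time_grid(config$timepoints, config$replicates)
  sheet <- sim_sample_sheet(config)

  # counting windows of each peak (same rule the pipeline applies)
  c0 <- floor((peak_df$start + peak_df$end) / 2)
  win_start <- c0 - 500
  win_end <- c0 + 500

  frags <- list()
  for (si in seq_len(nrow(sheet))) {
    g <- sheet$genotype[si]
    t <- sheet$zt[si]
    ph <- truth[[paste0("phase_", g)]]
    a <- (truth[[paste0("fold_", g)]] - 1) / (truth[[paste0("fold_", g)]] + 1)
    lam <- ifelse(truth$status == "retained",
                  config$fragment_depth *
                    (1 + ifelse(is.na(ph), 0, a) *
                       cos(2 * pi * (t - ifelse(is.na(ph), 0, ph)) / 24)),
                  config$fragment_depth)  # decoys in excluded peaks
  # excluded peaks: place decoys in the peak itself, retained: in the window
    lo <- ifelse(truth$status == "retained", win_start, peak_df$start)
    hi <- ifelse(truth$status == "retained", win_end, peak_df$end)
    counts <- rpois(nrow(truth), lam)
    mids <- unlist(lapply(seq_len(nrow(truth)), function(k) {
      if (counts[k] == 0) return(numeric(0))
      floor(runif(counts[k], lo[k], hi[k]))
    }))
    if (length(mids))
      frags[[length(frags) + 1L]] <- data.frame(
        sample_id = sheet$sample_id[si], contig = "chrS",
        start = pmax(mids - 25, 0), end = mids + 25,
        stringsAsFactors = FALSE)
  }
  fragments <- do.call(rbind, frags)
  libstats <- data.frame(sample_id = sheet$sample_id,
                         total_mapped_reads = 1e7, stringsAsFactors = FALSE)
  list(genes = genes, peaks = peaks, fragments = fragments, truth = truth,
       grid = grid, sample_sheet = sheet, libstats = libstats,
       seqlengths = seqlengths)
}
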