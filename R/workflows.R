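#' Read a pipeline configuration from YAML
#'
#' The configuration is a nested key-value structure naming the input files,
#' the genotype roles (`control`, `ko`, optionally `triple_ko`), per-assay
#' rhythm parameters and the output directory. See the pipeline runners for
#' the keys each expects.
#'
#' @param path YAML file.
#' @return Nested list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

check_roles <- function(roles, need_tko = FALSE) {
  for (r in c("control", "ko", if (need_tko) "triple_ko"))
    if (is.null(roles[[r]])) stop("genotype role '", r, "' missing from config")
  vals <- unlist(roles)
  if (anyDuplicated(vals)) stop("genotype roles must be distinct")
  roles
}

params_from_config <- function(x, ...) {
  do.call(rhythm_params, modifyList(list(...), as.list(x %||% list())))
}

# order a genotype's samples by (timepoint, replicate) and derive its grid
grid_from_sheet <- function(sheet, genotype) {
  s <- sheet[sheet$genotype == genotype, , drop = FALSE]
  if (!nrow(s)) stop("no samples for genotype '", genotype, "' in the sample sheet")
  s <- s[order(s$zt, s$replicate), , drop = FALSE]
  zts <- sort(unique(s$zt))
  reps <- table(s$zt)
  if (length(unique(reps)) != 1)
    stop("unequal replicate counts across timepoints for genotype '", genotype, "'")
  list(grid = time_grid(zts, as.integer(reps[1])), sample_ids = s$sample_id)
}

write_log <- function(lines, out_dir) {
  writeLines(lines, file.path(out_dir, "log.txt"))
}

write_summary_json <- function(x, out_dir) {
  jsonlite::write_json(x, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Simulate and write a full synthetic dataset directory
#'
#' Generates the inputs of the three analysis pipelines -- transcript count
#' matrices, enhancer annotation/peaks/fragments and lipid abundance
#' matrices, each with its planted-truth table -- and writes them as plain
#' TSV/GTF/BED files under `out_dir` (subdirectories `transcripts/`,
#' `enhancers/`, `lipids/`). Stage seeds are derived from `seed` so the
#' directory is byte-identical across re-runs.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed.
#' @param transcripts,enhancers,lipids Optional [sim_config()] overrides for
#'   each assay (defaults: transcript defaults; 60 enhancer loci; lipidomics
#'   defaults of [lipid_sim_config()]).
#' @return Invisibly, the list of generated objects.
#' @export
run_simulate <- function(out_dir, seed = 1L, transcripts = NULL,
                         enhancers = NULL, lipids = NULL) {
  seed <- as.integer(seed)
  transcripts <- transcripts %||% sim_config(seed = seed)
  enhancers <- enhancers %||% sim_config(seed = seed + 1L, n_features = 60)
  lipids <- lipids %||% lipid_sim_config(seed = seed + 2L)

  dir.create(file.path(out_dir, "transcripts"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "enhancers"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "lipids"), recursive = TRUE, showWarnings = FALSE)

  tx <- simulate_expression(transcripts)
  td <- file.path(out_dir, "transcripts")
  for (g in names(tx$matrices))
    write_matrix_tsv(tx$matrices[[g]], file.path(td, paste0("counts_", g, ".tsv")))
  write_tsv_table(tx$sample_sheet, file.path(td, "sample_sheet.tsv"))
  write_tsv_table(data.frame(feature_id = names(tx$lengths),
                             length_bp = as.numeric(tx$lengths)),
                  file.path(td, "lengths.tsv"))
  write_tsv_table(tx$libstats, file.path(td, "libstats.tsv"))
  write_tsv_table(tx$truth, file.path(td, "truth.tsv"))

  en <- simulate_enhancer_data(enhancers)
  ed <- file.path(out_dir, "enhancers")
  write_gtf(en$genes, file.path(ed, "annotation.gtf"))
  write_bed(en$peaks, file.path(ed, "peaks.bed"))
  write_fragments_tsv(en$fragments, file.path(ed, "fragments.tsv"))
  write_tsv_table(data.frame(contig = names(en$seqlengths),
                             length = as.numeric(en$seqlengths)),
                  file.path(ed, "contigs.tsv"))
  write_tsv_table(en$sample_sheet, file.path(ed, "sample_sheet.tsv"))
  write_tsv_table(en$libstats, file.path(ed, "libstats.tsv"))
  write_tsv_table(en$truth, file.path(ed, "truth.tsv"))

  lp <- simulate_lipids(lipids)
  ld <- file.path(out_dir, "lipids")
  for (g in names(lp$matrices))
    write_matrix_tsv(lp$matrices[[g]], file.path(ld, paste0("abundance_", g, ".tsv")))
  write_tsv_table(lp$sample_sheet, file.path(ld, "sample_sheet.tsv"))
  write_tsv_table(lp$truth, file.path(ld, "truth.tsv"))

  invisible(list(transcripts = tx, enhancers = en, lipids = lp))
}

#' Transcript pipeline: RPKTM, filtering, rhythm calls, remodeling
#'
#' Runs the full transcript chain per genotype -- counts to RPKTM, the
#' expression-detection filter, duplicated-series rhythm testing with BH
#' adjustment and oscillation calls -- then classifies cross-genotype
#' remodeling, determines SCAP dependence against the triple KO (when a
#' `triple_ko` role is configured) and writes phase histograms of the
#' genotype-specific oscillators.
#'
#' @param config List (or [read_pipeline_config()] output) with elements
#'   `counts` (named genotype -> path map), `sample_sheet`, `lengths`,
#'   `libstats` (paths), `roles` (`control`, `ko`, optionally `triple_ko`),
#'   `out_dir`, optional `params` (arguments to [rhythm_params()]) and
#'   `seed`.
#' @return Invisibly, a list with the per-genotype results, remodeling calls
#'   and summary.
#' @export
run_transcripts <- function(config) {
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed %||% 0L)
  roles <- check_roles(config$roles)
  params <- params_from_config(config$params)
  sheet <- read_tsv_table(config$sample_sheet)
  lengths_df <- read_tsv_table(config$lengths)
  lengths <- setNames(lengths_df$length_bp, lengths_df$feature_id)
  libstats <- read_tsv_table(config$libstats)

  genotypes <- unlist(roles)
  log <- c(sprintf("transcript pipeline: genotypes %s",
                   paste(sprintf("%s=%s", names(roles), genotypes), collapse = ", ")))
  results <- list()
  for (g in genotypes) {
    if (is.null(config$counts[[g]])) stop("no counts path configured for genotype '", g, "'")
    counts <- read_matrix_tsv(config$counts[[g]])
    gs <- grid_from_sheet(sheet, g)
    missing <- setdiff(gs$sample_ids, colnames(counts))
    extra <- setdiff(colnames(counts), gs$sample_ids)
    if (length(missing) || length(extra))
      stop("sample sheet/matrix mismatch for genotype '", g, "': missing [",
           paste(missing, collapse = ", "), "], unexpected [",
           paste(extra, collapse = ", "), "]")
    counts <- counts[, gs$sample_ids, drop = FALSE]
    rp <- rpktm(counts, lengths, libstats)
    keep <- expression_filter(rp, params$expression_min, params$min_samples_detected)
    log <- c(log, sprintf("%s: %d features, %d pass expression filter (> %g in >= %d samples)",
                          g, nrow(rp), length(keep), params$expression_min,
                          params$min_samples_detected))
    res <- jtk_test(rp[keep, , drop = FALSE], gs$grid, params, duplicate = TRUE)
    log <- c(log, sprintf("%s: %d rhythmic of %d tested", g, sum(res$rhythmic), nrow(res)))
    write_tsv_table(res, file.path(out_dir, paste0("rhythm_", g, ".tsv")))
    results[[g]] <- res
  }

  calls <- classify_remodeling(results, control = roles$control, ko = roles$ko)
  summary <- list(categories = as.list(table(calls$category)))
  if (!is.null(roles$triple_ko)) {
    sd <- scap_dependence(calls, results[[roles$triple_ko]])
    calls <- sd$calls
    summary$restoration <- sd$summary
    log <- c(log, sprintf("restoration: %d of %d gained rhythms SCAP-dependent",
                          sd$summary$n_restored, sd$summary$n_gained))
  }
  write_tsv_table(calls, file.path(out_dir, "remodeling.tsv"))
  log <- c(log, sprintf("remodeling: %s",
                        paste(sprintf("%s=%d", names(table(calls$category)),
                                      as.integer(table(calls$category))), collapse = ", ")))

  for (cat in c("control_specific", "ko_specific")) {
    src <- if (cat == "control_specific") roles$control else roles$ko
    ph <- results[[src]]$peak_zt[match(calls$feature_id[calls$category == cat],
                                       results[[src]]$feature_id)]
    ph <- ph[!is.na(ph)]
    if (length(ph) >= 2) {
      h <- phase_histogram(ph)
      write_tsv_table(data.frame(bin_start = h$bin_start, bin_end = h$bin_end,
                                 count = h$counts),
                      file.path(out_dir, paste0("phase_hist_", cat, ".tsv")))
      summary[[paste0("phase_", cat)]] <-
        list(modal_bins = h$modal_bins, rayleigh_p = h$rayleigh_p, n = h$n)
    }
  }
  write_summary_json(summary, out_dir)
  write_log(log, out_dir)
  invisible(list(results = results, calls = calls, summary = summary))
}

#' Enhancer pipeline: intergenic loci, eRNA counting, rhythm calls
#'
#' Reads the annotation, ATAC peaks and fragment table; removes peaks inside
#' the 1 kb-extended exclusion zones of coding/lncRNA genes (writing an audit
#' of exclusions); builds 1000 bp windows around the retained peak centers;
#' counts fragment midpoints per window and sample; applies the presence
#' filter pooled over the control and KO samples; and calls rhythmic
#' enhancers per genotype at the relaxed thresholds, followed by remodeling
#' classification.
#'
#' @param config List with `annotation`, `peaks`, `fragments`, `contigs`,
#'   `sample_sheet`, `libstats` (paths), `roles`, `out_dir`, optional
#'   `params` and `seed`.
#' @return Invisibly, list with `loci`, `counts`, per-genotype `results`,
#'   `calls`, `summary`.
#' @export
run_enhancers <- function(config) {
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed %||% 0L)
  roles <- check_roles(config$roles)
  params <- params_from_config(config$params, p_adj_max = 0.06, expression_min = 0.2)
  sheet <- read_tsv_table(config$sample_sheet)
  libstats <- read_tsv_table(config$libstats)
  contigs <- read_tsv_table(config$contigs)
  seqlengths <- setNames(contigs$length, contigs$contig)

  genes <- if (file.size(config$annotation) > 0) read_gene_models(config$annotation)
           else GenomicRanges::GRanges()
  peaks <- read_bed(config$peaks)
  fragments <- read_fragments_tsv(config$fragments)

  zones <- exclusion_zones(genes)
  kept <- intergenic_peaks(peaks, zones)
  excluded <- setdiff(peaks$name, kept$name)
  write_tsv_table(data.frame(peak_id = excluded,
                             reason = rep("overlaps_exclusion_zone", length(excluded))),
                  file.path(out_dir, "excluded_peaks.tsv"))
  log <- c(sprintf("enhancer pipeline: %d peaks, %d exclusion zones, %d intergenic",
                   length(peaks), length(zones), length(kept)))
  if (!length(kept)) {
    warning("no intergenic peaks remain after exclusion-zone filtering")
    write_log(log, out_dir)
    write_summary_json(list(n_peaks = length(peaks), n_retained = 0), out_dir)
    return(invisible(list(loci = GenomicRanges::GRanges(),
                          counts = NULL, results = list(), calls = NULL,
                          summary = list(n_retained = 0))))
  }

  loci <- make_loci(kept, seqlengths = seqlengths)
  bad <- audit_loci(loci, zones)
  if (length(bad))
    log <- c(log, sprintf("audit: %d locus window(s) overlap exclusion zones: %s",
                          length(bad), paste(bad, collapse = ",")))
  counts <- count_fragments(loci, fragments, sample_ids = sheet$sample_id)

  pool <- sheet$sample_id[sheet$genotype %in% c(roles$control, roles$ko)]
  present <- presence_filter(counts, pool, min_samples = params$min_samples_detected)
  log <- c(log, sprintf("presence filter: %d of %d loci nonzero in >= %d control/KO samples",
                        length(present), nrow(counts), params$min_samples_detected))
  counts <- counts[present, , drop = FALSE]
  write_bed(loci[match(present, loci$locus_id)], file.path(out_dir, "retained_loci.bed"))
  write_matrix_tsv(counts, file.path(out_dir, "counts.tsv"))

  genotypes <- unlist(roles)
  results <- list()
  for (g in genotypes) {
    gs <- grid_from_sheet(sheet, g)
    res <- call_rhythmic_enhancers(counts[, gs$sample_ids, drop = FALSE],
                                   gs$grid, libstats, params = params)
    log <- c(log, sprintf("%s: %d oscillating of %d loci", g, sum(res$rhythmic), nrow(res)))
    write_tsv_table(res, file.path(out_dir, paste0("rhythm_", g, ".tsv")))
    results[[g]] <- res
  }
  calls <- classify_remodeling(results, control = roles$control, ko = roles$ko)
  summary <- list(n_peaks = length(peaks), n_retained_peaks = length(kept),
                  n_loci_tested = nrow(counts),
                  categories = as.list(table(calls$category)))
  if (!is.null(roles$triple_ko)) {
    sd <- scap_dependence(calls, results[[roles$triple_ko]])
    calls <- sd$calls
    summary$restoration <- sd$summary
  }
  write_tsv_table(calls, file.path(out_dir, "remodeling.tsv"))
  write_summary_json(summary, out_dir)
  write_log(log, out_dir)
  invisible(list(loci = loci, counts = counts, results = results,
                 calls = calls, summary = summary))
}

#' Lipid pipeline: quantile normalization, rhythm calls, remodeling
#'
#' Quantile-normalizes the combined abundance matrix across all genotypes'
#' samples (making every sample's distribution identical), splits it back per
#' genotype, tests each species with the duplicated-series rhythm test at the
#' standard thresholds, and classifies remodeling and SCAP dependence.
#'
#' @param config List with `abundance` (named genotype -> path map),
#'   `sample_sheet`, `roles`, `out_dir`, optional `params` and `seed`.
#' @return Invisibly, list with per-genotype `results`, `calls`, `summary`.
#' @export
run_lipids <- function(config) {
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed %||% 0L)
  roles <- check_roles(config$roles)
  params <- params_from_config(config$params)
  sheet <- read_tsv_table(config$sample_sheet)

  genotypes <- unlist(roles)
  mats <- lapply(genotypes, function(g) {
    if (is.null(config$abundance[[g]]))
      stop("no abundance path configured for genotype '", g, "'")
    read_matrix_tsv(config$abundance[[g]])
  })
  names(mats) <- genotypes
  combined <- do.call(cbind, mats)
  norm <- quantile_normalize(combined)
  write_matrix_tsv(norm, file.path(out_dir, "normalized.tsv"))
  log <- c(sprintf("lipid pipeline: %d species, %d samples quantile-normalized",
                   nrow(norm), ncol(norm)))

  results <- list()
  for (g in genotypes) {
    gs <- grid_from_sheet(sheet, g)
    missing <- setdiff(gs$sample_ids, colnames(norm))
    if (length(missing))
      stop("sample sheet/matrix mismatch for genotype '", g, "': missing [",
           paste(missing, collapse = ", "), "]")
    res <- jtk_test(norm[, gs$sample_ids, drop = FALSE], gs$grid, params,
                    duplicate = TRUE)
    log <- c(log, sprintf("%s: %d rhythmic of %d species", g, sum(res$rhythmic), nrow(res)))
    write_tsv_table(res, file.path(out_dir, paste0("rhythm_", g, ".tsv")))
    results[[g]] <- res
  }
  calls <- classify_remodeling(results, control = roles$control, ko = roles$ko)
  summary <- list(categories = as.list(table(calls$category)))
  if (!is.null(roles$triple_ko)) {
    sd <- scap_dependence(calls, results[[roles$triple_ko]])
    calls <- sd$calls
    summary$restoration <- sd$summary
    log <- c(log, sprintf("restoration: %d of %d gained rhythms SCAP-dependent",
                          sd$summary$n_restored, sd$summary$n_gained))
  }
  write_tsv_table(calls, file.path(out_dir, "remodeling.tsv"))
  write_summary_json(summary, out_dir)
  write_log(log, out_dir)
  invisible(list(results = results, calls = calls, summary = summary))
}
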