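#' Exclusion zones around annotated genes
#'
#' Every coding and lncRNA gene body, extended by `extension_bp` beyond both
#' the transcription start and end site, defines a zone inside which ATAC
#' peaks are not considered intergenic. Genes of other biotypes do not
#' exclude. Overlapping zones are merged; zones are clipped at position 1
#' (and at the contig end when sequence lengths are known).
#'
#' @param genes A [GenomicRanges::GRanges] of genes with a `biotype` metadata
#'   column (values `coding`, `lncRNA`, `other`), e.g. from
#'   [read_gene_models()].
#' @param extension_bp Extension beyond TSS and TES (default 1000).
#' @return Merged, unstranded `GRanges` of exclusion zones.
#' @export
exclusion_zones <- function(genes, extension_bp = 1000) {
  b <- genes$biotype %||% rep("coding", length(genes))
  g <- genes[b %in% c("coding", "lncRNA")]
  if (!length(g)) return(GenomicRanges::GRanges())
  z <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(g),
    IRanges::IRanges(pmax(GenomicRanges::start(g) - extension_bp, 1L),
                     GenomicRanges::end(g) + extension_bp))
  GenomeInfoDb::seqlevels(z) <- GenomeInfoDb::seqlevels(g)
  sl <- GenomeInfoDb::seqlengths(g)
  if (!all(is.na(sl))) {
    GenomeInfoDb::seqlengths(z) <- sl
    z <- suppressWarnings(IRanges::trim(z))
  }
  GenomicRanges::reduce(z, ignore.strand = TRUE)
}

#' Filter peaks down to intergenic ones
#'
#' A peak is removed if it overlaps any exclusion zone by one or more bp.
#'
#' @param peaks `GRanges` of ATAC peaks.
#' @param zones `GRanges` from [exclusion_zones()].
#' @return The retained (intergenic) peaks.
#' @export
intergenic_peaks <- function(peaks, zones) {
  if (!length(zones)) return(peaks)
  peaks[!IRanges::overlapsAny(peaks, zones, ignore.strand = TRUE)]
}

#' Enhancer loci: fixed windows around peak centers
#'
#' The locus center is the midpoint of the peak, `floor((start0 + end0) / 2)`
#' in 0-based half-open coordinates, and the counting window is the 1000 bp
#' half-open interval `[center - 500, center + 500)`, clipped at contig
#' bounds with a warning.
#'
#' @param peaks `GRanges` of intergenic peaks; a `name` metadata column is
#'   used for locus ids if present.
#' @param seqlengths Optional named vector of contig lengths used for
#'   clipping (taken from `peaks` when already set there).
#' @return `GRanges` of windows with metadata `locus_id`, `center` (0-based),
#'   `peak_start`, `peak_end` (0-based half-open).
#' @export
make_loci <- function(peaks, seqlengths = NULL) {
  if (!length(peaks)) return(GenomicRanges::GRanges())
  s0 <- GenomicRanges::start(peaks) - 1L
  e0 <- GenomicRanges::end(peaks)
  c0 <- floor((s0 + e0) / 2)
  ws <- c0 - 500
  we <- c0 + 500
  if (is.null(seqlengths)) {
    sl <- GenomeInfoDb::seqlengths(peaks)
    if (!all(is.na(sl))) seqlengths <- sl
  }
  clipped <- ws < 0
  ws <- pmax(ws, 0)
  if (!is.null(seqlengths)) {
    lim <- as.numeric(seqlengths[as.character(GenomicRanges::seqnames(peaks))])
    over <- !is.na(lim) & we > lim
    we <- ifelse(over, lim, we)
    clipped <- clipped | over
  }
  if (any(clipped))
    warning(sum(clipped), " window(s) clipped at contig bounds")
  ids <- peaks$name %||% paste0("locus_", seq_along(peaks))
  gr <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(peaks), IRanges::IRanges(ws + 1, we),
    locus_id = ids, center = c0, peak_start = s0, peak_end = e0)
  GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(peaks)
  if (!is.null(seqlengths))
    GenomeInfoDb::seqlengths(gr) <- seqlengths[GenomeInfoDb::seqlevels(gr)]
  gr
}

#' Count fragments per locus window and sample
#'
#' A fragment is assigned to a window iff its midpoint (0-based,
#' `floor((start0 + end0) / 2)`) lies inside the half-open window. A fragment
#' whose midpoint falls in two overlapping windows counts for both.
#'
#' @param loci `GRanges` from [make_loci()].
#' @param fragments `GRanges` of fragments with a `sample_id` metadata
#'   column, or a data frame with columns `sample_id`, `contig`, `start`,
#'   `end` in 0-based half-open (BED) coordinates.
#' @param sample_ids Optional sample ordering for the output columns
#'   (defaults to the sorted unique sample ids present).
#' @return Integer matrix, loci x samples, rownames `locus_id`.
#' @export
count_fragments <- function(loci, fragments, sample_ids = NULL) {
  if (is.data.frame(fragments)) {
    fragments <- GenomicRanges::GRanges(
      fragments$contig,
      IRanges::IRanges(fragments$start + 1L, fragments$end),
      sample_id = fragments$sample_id)
  }
  sid <- as.character(fragments$sample_id)
  if (is.null(sample_ids)) sample_ids <- sort(unique(sid))
  mid0 <- floor((GenomicRanges::start(fragments) - 1 + GenomicRanges::end(fragments)) / 2)
  mids <- GenomicRanges::GRanges(GenomicRanges::seqnames(fragments),
                                 IRanges::IRanges(mid0 + 1, width = 1))
  hits <- GenomicRanges::findOverlaps(loci, mids, ignore.strand = TRUE)
  counts <- table(factor(loci$locus_id[S4Vectors::queryHits(hits)],
                         levels = loci$locus_id),
                  factor(sid[S4Vectors::subjectHits(hits)], levels = sample_ids))
  out <- matrix(as.integer(counts), nrow = length(loci),
                dimnames = list(loci$locus_id, sample_ids))
  out
}

#' Presence filter on locus counts
#'
#' Keeps loci with a nonzero count in at least `min_samples` of the named
#' samples (pooled across the compared genotypes). With
#' `rule = "expression"`, detection instead requires `value > min_value`.
#'
#' @param counts Loci-by-sample matrix.
#' @param sample_ids Columns over which presence is evaluated (default all).
#' @param min_samples Required number of detected samples.
#' @param rule `"nonzero"` (default) or `"expression"`.
#' @param min_value Threshold for the `"expression"` rule.
#' @return Character vector of retained locus ids.
#' @export
presence_filter <- function(counts, sample_ids = colnames(counts),
                            min_samples = 2, rule = c("nonzero", "expression"),
                            min_value = 0.2) {
  rule <- match.arg(rule)
  m <- as.matrix(counts)[, sample_ids, drop = FALSE]
  det <- if (rule == "nonzero") m > 0 else m > min_value
  rownames(counts)[rowSums(det) >= min_samples]
}

#' Rhythm calls for enhancer loci
#'
#' Window counts are normalized to RPKTM using the window length, tested with
#' the duplicated-series JTK procedure and called oscillating at the relaxed
#' enhancer thresholds: adjusted P < 0.06, maximum RPKTM > 0.2, amplitude
#' > 1.5 and period 21-24 h.
#'
#' @param counts Loci-by-sample fragment count matrix (one genotype).
#' @param grid The [time_grid()] of the columns.
#' @param libstats Library sizes, as in [rpktm()].
#' @param window_bp Window length used as the RPKTM length denominator.
#' @param params [rhythm_params()]; defaults to the enhancer settings.
#' @return Data frame as [jtk_test()] plus a `max_rpktm` column; `rhythmic`
#'   includes the maximum-RPKTM condition.
#' @export
call_rhythmic_enhancers <- function(counts, grid, libstats, window_bp = 1000,
                                    params = rhythm_params(p_adj_max = 0.06,
                                                           expression_min = 0.2)) {
  counts <- as.matrix(counts)
  rp <- rpktm(counts, setNames(rep(window_bp, nrow(counts)), rownames(counts)),
              libstats)
  res <- jtk_test(rp, grid, params, duplicate = TRUE)
  res$max_rpktm <- apply(rp, 1, max)
  res$rhythmic <- res$rhythmic & res$max_rpktm > params$expression_min
  res
}

#' Audit locus windows against exclusion zones
#'
#' Post-condition check of the enhancer stage: no retained locus window
#' should overlap an exclusion zone. Returns the offending locus ids.
#'
#' @param loci `GRanges` from [make_loci()].
#' @param zones `GRanges` from [exclusion_zones()].
#' @return Character vector (empty when the audit passes).
#' @export
audit_loci <- function(loci, zones) {
  if (!length(loci) || !length(zones)) return(character(0))
  loci$locus_id[IRanges::overlapsAny(loci, zones, ignore.strand = TRUE)]
}
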