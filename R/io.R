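#' Read and write feature-by-sample matrices as TSV
#'
#' Matrices are stored with a header row whose first column is `feature_id`
#' followed by sample ids (`<genotype>_ZT<t>_rep<r>`).
#'
#' @param mat Matrix with row and column names.
#' @param path File path.
#' @return `read_matrix_tsv` returns the matrix; `write_matrix_tsv` the path,
#'   invisibly.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(feature_id = rownames(mat), as.data.frame(mat),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read and write simple TSV tables
#'
#' Plain data-frame TSV I/O used for sample sheets (`sample_id`, `genotype`,
#' `zt`, `replicate`), library stats (`sample_id`, `total_mapped_reads`),
#' feature lengths (`feature_id`, `length_bp`) and truth tables.
#'
#' @param df Data frame.
#' @param path File path.
#' @return `read_tsv_table` returns a data frame.
#' @export
write_tsv_table <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Gene models from a GTF annotation
#'
#' Imports `gene`-typed records (all records when no `type` column is
#' present) and normalizes the biotype to `coding` / `lncRNA` / `other`.
#'
#' @param path GTF file (1-based, closed intervals).
#' @return `GRanges` with metadata `gene_id`, `biotype`.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  if (!is.null(gr$type) && any(gr$type == "gene")) gr <- gr[gr$type == "gene"]
  raw <- gr$gene_biotype %||% gr$biotype %||% rep("protein_coding", length(gr))
  biotype <- ifelse(raw %in% c("protein_coding", "coding"), "coding",
                    ifelse(raw %in% c("lncRNA", "lincRNA"), "lncRNA", "other"))
  out <- GenomicRanges::granges(gr)
  out$gene_id <- gr$gene_id %||% paste0("gene_", seq_along(gr))
  out$biotype <- biotype
  out
}

#' Write gene models as GTF
#'
#' @param genes `GRanges` with `gene_id` and `biotype` metadata.
#' @param path Output GTF path.
#' @export
write_gtf <- function(genes, path) {
  gr <- GenomicRanges::granges(genes)
  gr$source <- "chronoremodel"
  gr$type <- "gene"
  gr$gene_id <- genes$gene_id
  gr$gene_biotype <- ifelse(genes$biotype == "coding", "protein_coding",
                            genes$biotype)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' BED interval I/O
#'
#' Thin wrappers over rtracklayer; BED files are 0-based half-open on disk
#' and become 1-based closed `GRanges` in memory.
#'
#' @param gr `GRanges` (a `name` column is written when present).
#' @param path BED file path.
#' @return `read_bed` returns a `GRanges`.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  rtracklayer::import(path, format = "bed")
}

#' Fragment table I/O
#'
#' Fragments are stored as a TSV with columns `sample_id`, `contig`, `start`,
#' `end` in 0-based half-open (BED) coordinates.
#'
#' @param fragments Data frame in that layout.
#' @param path File path.
#' @return `read_fragments_tsv` returns the data frame.
#' @export
write_fragments_tsv <- function(fragments, path) {
  write_tsv_table(fragments, path)
}

#' @rdname write_fragments_tsv
#' @export
read_fragments_tsv <- function(path) {
  read_tsv_table(path)
}
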