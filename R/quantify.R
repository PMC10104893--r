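#' Reads per kilobase per 10 million mapped reads (RPKTM)
#'
#' The expression unit used throughout the transcript and enhancer pipelines:
#' `count / (length_bp / 1000) / (total_mapped_reads / 1e7)`.
#'
#' @param counts Feature-by-sample count matrix with row and column names.
#' @param lengths Named numeric vector of feature lengths in bp (> 0); every
#'   row of `counts` must be present.
#' @param libstats Data frame with columns `sample_id`, `total_mapped_reads`
#'   covering every column of `counts`.
#' @return Matrix of RPKTM values, same dimnames as `counts`.
#' @examples
#' m <- matrix(100, 1, 1, dimnames = list("g1", "s1"))
#' rpktm(m, c(g1 = 1000), data.frame(sample_id = "s1", total_mapped_reads = 1e7))
#' @export
rpktm <- function(counts, lengths, libstats) {
  counts <- as.matrix(counts)
  miss <- setdiff(rownames(counts), names(lengths))
  if (length(miss))
    stop("missing length for feature(s): ", paste(head(miss, 5), collapse = ", "))
  l <- as.numeric(lengths[rownames(counts)])
  if (any(!is.finite(l) | l <= 0)) stop("feature lengths must be positive")
  idx <- match(colnames(counts), libstats$sample_id)
  if (anyNA(idx))
    stop("missing library stats for sample(s): ",
         paste(head(colnames(counts)[is.na(idx)], 5), collapse = ", "))
  tot <- as.numeric(libstats$total_mapped_reads[idx])
  if (any(!is.finite(tot) | tot <= 0)) stop("total_mapped_reads must be positive")
  sweep(sweep(counts, 1, l / 1000, "/"), 2, tot / 1e7, "/")
}

#' Expression-detection filter
#'
#' Keeps features whose value exceeds `min_value` (strict `>`) in at least
#' `min_samples` samples. By default detection anywhere in the series counts;
#' with `per_timepoint = TRUE` the requirement must hold within every
#' timepoint (the stricter reading), for which `grid` must be supplied.
#'
#' @param mat Feature-by-sample matrix (e.g. RPKTM).
#' @param min_value Detection threshold (strict `>`).
#' @param min_samples Required number of samples above threshold.
#' @param per_timepoint Require `min_samples` detections at each timepoint.
#' @param grid [time_grid()] describing the columns; needed only when
#'   `per_timepoint = TRUE`.
#' @return Character vector of retained feature ids (row names).
#' @export
expression_filter <- function(mat, min_value = 5, min_samples = 2,
                              per_timepoint = FALSE, grid = NULL) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat))) rownames(mat) <- paste0("feature_", seq_len(nrow(mat)))
  det <- mat > min_value
  if (!per_timepoint) {
    keep <- rowSums(det) >= min_samples
  } else {
    if (is.null(grid)) stop("per_timepoint filtering requires a grid")
    tp <- rep(grid$zt_times %% 24, each = grid$replicates)
    per_tp <- vapply(split(seq_len(ncol(mat)), tp),
                     function(idx) rowSums(det[, idx, drop = FALSE]) >= min_samples,
                     logical(nrow(mat)))
    if (is.null(dim(per_tp))) per_tp <- matrix(per_tp, nrow = 1)
    keep <- apply(per_tp, 1, all)
  }
  rownames(mat)[keep]
}

#' Quantile normalization across samples
#'
#' Standard quantile normalization: each column is ranked and its values are
#' replaced by the across-column row means of the sorted columns, making all
#' sample distributions identical. Ties within a column receive the mean of
#' the quantile values they span. No outlier handling is applied. A constant
#' column (all its entries map to the mean of the reference distribution) is
#' allowed but triggers a warning.
#'
#' @param mat Feature-by-sample numeric matrix.
#' @return Normalized matrix, same dimnames.
#' @examples
#' quantile_normalize(matrix(c(1, 3, 2, 4), 2))  # rows 1.5, 3.5
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (any(apply(mat, 2, function(x) diff(range(x)) == 0)))
    warning("constant column(s) in quantile normalization: all their entries map to the reference mean")
  ref <- rowMeans(apply(mat, 2, sort))
  out <- apply(mat, 2, function(x) {
    v <- numeric(length(x))
    v[order(x)] <- ref
    ave(v, match(x, x), FUN = mean)  # ties -> mean of their would-be quantiles
  })
  dimnames(out) <- dimnames(mat)
  out
}
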