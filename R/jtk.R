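#' Parameters of the rhythm test and oscillation call
#'
#' Defaults are the transcript-calling settings: BH-adjusted P < 0.05,
#' peak/trough amplitude > 1.5 and a best period of 21-24 h define an
#' oscillating feature; expression filtering keeps features exceeding
#' `expression_min` in at least `min_samples_detected` samples. Enhancer
#' calling uses the relaxed `p_adj_max = 0.06`, `expression_min = 0.2`.
#'
#' @param p_adj_max Adjusted-P cutoff (strict `<`).
#' @param amp_min Peak/trough amplitude cutoff (strict `>`).
#' @param period_min_h,period_max_h Accepted period range, inclusive.
#' @param expression_min Detection threshold on the expression unit (strict `>`).
#' @param min_samples_detected Samples that must exceed `expression_min`.
#' @param pseudocount Added to peak and trough means before their ratio, so
#'   zero troughs yield a finite amplitude.
#' @param lag_step Lag-grid resolution as a fraction of the sampling interval.
#' @param exact_cap Largest sample count for which the exact S null is used.
#' @return A list of class `rhythm_params`.
#' @export
rhythm_params <- function(p_adj_max = 0.05, amp_min = 1.5,
                          period_min_h = 21, period_max_h = 24,
                          expression_min = 5, min_samples_detected = 2,
                          pseudocount = 0.01, lag_step = 0.5, exact_cap = 30) {
  if (p_adj_max <= 0 || p_adj_max >= 1) stop("p_adj_max must be in (0, 1)")
  if (amp_min <= 1) stop("amp_min must be > 1")
  if (period_min_h > period_max_h) stop("period_min_h must be <= period_max_h")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  structure(list(p_adj_max = p_adj_max, amp_min = amp_min,
                 period_min_h = period_min_h, period_max_h = period_max_h,
                 expression_min = expression_min,
                 min_samples_detected = min_samples_detected,
                 pseudocount = pseudocount, lag_step = lag_step,
                 exact_cap = exact_cap),
            class = "rhythm_params")
}

#' Peak/trough amplitude of a series
#'
#' Replicates are averaged per timepoint (ZT taken modulo 24, so a duplicated
#' grid gives the same means as the original) and the amplitude is
#' `(max + eps) / (min + eps)`. A constant series has amplitude 1.
#'
#' @param series Numeric series ordered by (timepoint, replicate).
#' @param grid The [time_grid()] of the series.
#' @param eps Pseudocount guarding zero troughs.
#' @return Amplitude fold >= 1 (for non-negative data).
#' @examples
#' g <- time_grid(c(3, 9, 15, 21))
#' amplitude_fold(c(10, 20, 30, 20), g, eps = 0)  # 3
#' @export
amplitude_fold <- function(series, grid, eps = 0.01) {
  if (length(series) != n_samples(grid)) stop("series length does not match grid")
  m <- tapply(series, rep(grid$zt_times %% 24, each = grid$replicates), mean)
  (max(m) + eps) / (min(m) + eps)
}

amplitude_fold_matrix <- function(mat, grid, eps = 0.01) {
  tp <- rep(grid$zt_times %% 24, each = grid$replicates)
  means <- vapply(split(seq_len(ncol(mat)), tp),
                  function(idx) rowMeans(mat[, idx, drop = FALSE]),
                  numeric(nrow(mat)))
  if (is.null(dim(means))) means <- matrix(means, nrow = 1)
  (apply(means, 1, max) + eps) / (apply(means, 1, min) + eps)
}

#' Benjamini-Hochberg adjustment of raw rhythm P values
#'
#' The adjustment family is all features tested together in one matrix (one
#' assay/compartment/genotype).
#'
#' @param p_raw Numeric vector of raw P values.
#' @return Adjusted P values (same length; empty in, empty out).
#' @export
adjust_pvalues <- function(p_raw) {
  if (!length(p_raw)) return(numeric(0))
  p.adjust(p_raw, method = "BH")
}

#' Oscillation call from test results and thresholds
#'
#' A feature is rhythmic iff `p_adj < p_adj_max`, `amplitude_fold > amp_min`
#' and the best period lies within `[period_min_h, period_max_h]`. The
#' inequalities on P and amplitude are strict.
#'
#' @param result Data frame with columns `p_adj`, `amplitude_fold`, `period_h`.
#' @param params A [rhythm_params()].
#' @return Logical vector.
#' @export
call_rhythmic <- function(result, params = rhythm_params()) {
  ok_period <- !is.na(result$period_h) &
    result$period_h >= params$period_min_h &
    result$period_h <= params$period_max_h
  result$p_adj < params$p_adj_max &
    result$amplitude_fold > params$amp_min &
    ok_period
}

#' JTK-style rhythm test of a feature-by-sample matrix
#'
#' For each feature, Kendall's S against every reference waveform is converted
#' to an exact two-sided P value (`min(1, 2 * P(S >= |s|))` under the
#' waveform's tie-structure null); the feature's raw P is the Bonferroni
#' bound `min(1, W * min_w p_w)` over the W waveforms, and the best waveform
#' (smallest p, ties broken by smallest lag then smallest period) supplies the
#' reported period and peak phase. Adjusted P values (BH across the matrix's
#' features) and the oscillation call at `params` thresholds are filled in.
#'
#' Data ties are scored by the midrank convention (tied pairs contribute 0 to
#' S); because the exact null assumes tie-free data, features with ties are
#' annotated in the `ties` column and a single warning is raised. Constant
#' features get `p_raw = 1`, amplitude 1 and `NA` period/phase.
#'
#' @param mat Numeric matrix, features x samples, columns ordered by
#'   (timepoint, replicate) as in [sample_times()].
#' @param grid The (non-duplicated) [time_grid()] of the columns.
#' @param params A [rhythm_params()].
#' @param duplicate Duplicate the series over a second cycle before testing
#'   (the standard preprocessing for 4-timepoint designs).
#' @param refset Optional precomputed [build_reference_set()] matching the
#'   (possibly duplicated) grid.
#' @return Data frame with columns `feature_id`, `p_raw`, `p_adj`, `period_h`,
#'   `peak_zt`, `amplitude_fold`, `ties`, `rhythmic`; attribute `n_waveforms`.
#' @examples
#' g <- time_grid(c(3, 9, 15, 21), replicates = 2)
#' x <- rbind(planted = rep(cos(2 * pi * (c(3, 9, 15, 21) - 15) / 24) + 2, each = 2),
#'            flat = rep(1, 8))
#' jtk_test(x, g)[, c("feature_id", "p_raw", "peak_zt")]
#' @export
jtk_test <- function(mat, grid, params = rhythm_params(), duplicate = TRUE,
                     refset = NULL) {
  mat <- as.matrix(mat)
  if (ncol(mat) != n_samples(grid))
    stop("matrix has ", ncol(mat), " columns but the grid implies ",
         n_samples(grid), " samples")
  if (is.null(rownames(mat))) rownames(mat) <- paste0("feature_", seq_len(nrow(mat)))
  amp <- amplitude_fold_matrix(mat, grid, params$pseudocount)

  if (duplicate) {
    dm <- duplicate_matrix(mat, grid)
    tmat <- dm$mat; tgrid <- dm$grid
  } else {
    tmat <- mat; tgrid <- grid
  }
  if (is.null(refset))
    refset <- build_reference_set(tgrid, params$period_min_h, params$period_max_h,
                                  params$lag_step)
  W <- length(refset)
  n <- ncol(tmat)
  ij <- combn(n, 2)
  i <- ij[1, ]; j <- ij[2, ]
  RS <- vapply(refset, function(w) sign(w$ref[i] - w$ref[j]), numeric(length(i)))
  SX <- sign(tmat[, i, drop = FALSE] - tmat[, j, drop = FALSE])
  S <- SX %*% RS

  keys <- vapply(refset, function(w) paste(w$tie_groups, collapse = ","), "")
  nulls <- lapply(unique(keys), function(k)
    exact_null(as.integer(strsplit(k, ",", fixed = TRUE)[[1]]), params$exact_cap))
  names(nulls) <- unique(keys)

  P <- matrix(1, nrow(tmat), W)
  for (w in seq_len(W))
    P[, w] <- pmin(1, 2 * jtk_tail_p(nulls[[keys[w]]], abs(S[, w])))

  lag <- vapply(refset, `[[`, numeric(1), "lag_offset_h")
  per <- vapply(refset, `[[`, numeric(1), "period_h")
  pk <- vapply(refset, `[[`, numeric(1), "peak_zt")

  minp <- apply(P, 1, min)
  best <- integer(nrow(P))
  for (f in seq_len(nrow(P))) {
    cand <- which(P[f, ] <= minp[f])
    # the two-sided p cannot tell a waveform from its antiphase: report the
    # phase of positive concordance when available
    if (any(S[f, cand] > 0)) cand <- cand[S[f, cand] > 0]
    cand <- cand[lag[cand] == min(lag[cand])]
    best[f] <- cand[which.min(per[cand])]
  }

  constant <- apply(mat, 1, function(x) diff(range(x)) == 0)
  has_ties <- apply(mat, 1, function(x) anyDuplicated(x) > 0) & !constant
  if (any(has_ties))
    warning(sum(has_ties),
            " feature(s) contain tied values; midranks used, exact null assumes tie-free data")

  res <- data.frame(
    feature_id = rownames(mat),
    p_raw = pmin(1, minp * W),
    period_h = per[best],
    peak_zt = pk[best],
    amplitude_fold = amp,
    ties = has_ties,
    stringsAsFactors = FALSE
  )
  res$p_raw[constant] <- 1
  res$period_h[constant] <- NA_real_
  res$peak_zt[constant] <- NA_real_
  res$p_adj <- adjust_pvalues(res$p_raw)
  res$rhythmic <- call_rhythmic(res, params)
  rownames(res) <- NULL
  res <- res[, c("feature_id", "p_raw", "p_adj", "period_h", "peak_zt",
                 "amplitude_fold", "ties", "rhythmic")]
  attr(res, "n_waveforms") <- W
  attr(res, "exact_null") <- all(vapply(nulls, `[[`, logical(1), "exact"))
  res
}

#' Rhythm test of a single series
#'
#' Convenience wrapper around [jtk_test()] for one feature.
#'
#' @inheritParams jtk_test
#' @param series Numeric series ordered by (timepoint, replicate).
#' @param feature_id Label for the output row.
#' @return One-row data frame as in [jtk_test()].
#' @export
test_feature <- function(series, grid, params = rhythm_params(),
                         duplicate = TRUE, refset = NULL, feature_id = "feature") {
  m <- matrix(series, nrow = 1, dimnames = list(feature_id, NULL))
  jtk_test(m, grid, params, duplicate = duplicate, refset = refset)
}
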