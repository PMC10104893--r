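#' Cosine reference waveforms for rhythm testing
#'
#' Builds the set of reference waveforms scanned by the rhythm test: one per
#' (period, lag) pair. Periods are all multiples of `lag_step * interval`
#' falling in `[period_min_h, period_max_h]`; lags cover one full period at
#' the same resolution (half the sampling interval by default, which is what
#' allows peak phases between sampled timepoints to be reported). Each
#' waveform is the cosine evaluated at the grid's sample times, so replicates
#' of a timepoint are tied by construction; additional ties arise where the
#' cosine takes equal values at two timepoints (symmetry about the peak).
#'
#' @param grid A [time_grid()] (duplicated or not) the data are ordered on.
#' @param period_min_h,period_max_h Period search range in hours.
#' @param lag_step Lag (and period) resolution as a fraction of the sampling
#'   interval; default 1/2.
#' @return List of `reference_waveform` objects with fields `period_h`,
#'   `lag_offset_h`, `ref` (cosine values, rounded so exact ties rank
#'   together), `ranks`, `peak_zt`, `tie_groups`.
#' @examples
#' g <- time_grid(c(3, 9, 15, 21), replicates = 3)
#' length(build_reference_set(g))  # periods {21, 24} -> 7 + 8 waveforms
#' @export
build_reference_set <- function(grid, period_min_h = 21, period_max_h = 24,
                                lag_step = 0.5) {
  if (period_min_h > period_max_h) stop("period_min_h must be <= period_max_h")
  step <- grid$interval * lag_step
  kmin <- max(1, ceiling(period_min_h / step - 1e-9))
  kmax <- floor(period_max_h / step + 1e-9)
  periods <- if (kmax >= kmin) (kmin:kmax) * step else numeric(0)
  if (!length(periods))
    stop(sprintf(
      "no period in [%g, %g] h is representable at %g h resolution on a grid with %g h interval",
      period_min_h, period_max_h, step, grid$interval))
  tt <- sample_times(grid)
  t0 <- grid$zt_times[1]
  out <- list()
  for (P in periods) {
    for (L in seq(0, P - step, by = step)) {
      ref <- round(cos(2 * pi * (tt - t0 - L) / P), 9)
      out[[length(out) + 1L]] <- structure(
        list(period_h = P, lag_offset_h = L, ref = ref,
             ranks = rank(ref, ties.method = "average"),
             peak_zt = (t0 + L) %% 24,
             tie_groups = sort(as.integer(table(ref)))),
        class = "reference_waveform")
    }
  }
  out
}

#' @export
print.reference_waveform <- function(x, ...) {
  cat(sprintf("reference_waveform: period %g h, lag %g h (peak ZT%g), ties {%s}\n",
              x$period_h, x$lag_offset_h, x$peak_zt,
              paste(x$tie_groups, collapse = ",")))
  invisible(x)
}
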