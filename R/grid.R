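#' Sampling design for a diurnal time course
#'
#' A `time_grid` records the ordered zeitgeber times (ZT, hours after lights
#' on) at which samples were collected, the spacing between consecutive
#' timepoints and the number of replicates per timepoint. Sampling must be
#' uniform; rhythm testing relies on the grid spacing to build its reference
#' waveforms.
#'
#' @param zt_times Numeric vector of ordered ZT hours (strictly increasing).
#'   For an ordinary grid all values lie in `[0, 24)`; a duplicated grid
#'   (see [duplicate_series()]) repeats the cycle once, extending into the
#'   `[24, 48)` range.
#' @param replicates Number of replicates per timepoint (>= 1).
#' @param duplicated Whether this grid is the result of series duplication.
#' @return An object of class `time_grid` with fields `zt_times`, `interval`,
#'   `replicates`, `duplicated`.
#' @examples
#' time_grid(c(3, 9, 15, 21), replicates = 3)
#' @export
time_grid <- function(zt_times, replicates = 1, duplicated = FALSE) {
  zt_times <- as.numeric(zt_times)
  if (length(zt_times) < 2) stop("a time grid needs at least two timepoints")
  d <- diff(zt_times)
  if (any(d <= 0)) stop("zt_times must be strictly increasing")
  if (diff(range(d)) > 1e-9) stop("uniform timepoint spacing is required")
  interval <- d[1]
  if (!duplicated && any(zt_times < 0 | zt_times >= 24))
    stop("zt_times must lie in [0, 24)")
  if (duplicated) {
    nt <- length(zt_times)
    if (nt %% 2 != 0) stop("a duplicated grid has an even number of timepoints")
    half <- zt_times[seq_len(nt / 2)]
    if (max(abs(zt_times[-seq_len(nt / 2)] - (half + 24))) > 1e-9)
      stop("a duplicated grid must repeat the ZT cycle once, offset by 24 h")
  }
  replicates <- as.integer(replicates)
  if (replicates < 1) stop("replicates must be >= 1")
  structure(
    list(zt_times = zt_times, interval = interval, replicates = replicates,
         duplicated = duplicated),
    class = "time_grid"
  )
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("time_grid: %d timepoints (ZT %s), interval %g h, %d replicate(s)%s\n",
              length(x$zt_times), paste(x$zt_times, collapse = ","),
              x$interval, x$replicates,
              if (x$duplicated) ", duplicated" else ""))
  invisible(x)
}

#' Sample collection times of a grid
#'
#' Expands the grid's timepoints to one entry per sample, replicate-major
#' within timepoint. This ordering, (timepoint, replicate), is the column
#' order assumed for all series and matrices in the package.
#'
#' @param grid A [time_grid()].
#' @return Numeric vector of length `timepoints * replicates`.
#' @export
sample_times <- function(grid) rep(grid$zt_times, each = grid$replicates)

#' Number of samples implied by a grid
#'
#' @param grid A [time_grid()].
#' @return `timepoints * replicates`.
#' @export
n_samples <- function(grid) length(grid$zt_times) * grid$replicates

#' Duplicate a time series over a second identical cycle
#'
#' Short designs (e.g. 4 timepoints over 24 h) are commonly duplicated before
#' rhythm testing: the observed series is concatenated with itself and treated
#' as covering two full cycles, so that oscillation patterns starting at every
#' timepoint can be scored. The duplicated grid repeats each ZT at ZT + 24.
#' Note that duplication makes the test anti-conservative (the second cycle is
#' not independent data); raw p values from a duplicated design should be read
#' as a ranking device, as validated against planted truth.
#'
#' @param values Numeric series ordered by (timepoint, replicate).
#' @param grid The (non-duplicated) [time_grid()] the series was sampled on.
#'   The timepoints must tile a full 24 h cycle.
#' @return A list with `values` (doubled length) and `grid` (duplicated).
#' @examples
#' g <- time_grid(c(3, 9, 15, 21))
#' duplicate_series(c(1, 2, 3, 4), g)$values
#' @export
duplicate_series <- function(values, grid) {
  if (!length(values)) stop("cannot duplicate an empty series")
  if (!is(grid, "time_grid")) stop("grid must be a time_grid")
  if (grid$duplicated) stop("grid is already duplicated; duplicating twice is not allowed")
  if (length(values) != n_samples(grid))
    stop("series length does not match the grid (", n_samples(grid), " samples expected)")
  if (abs(length(grid$zt_times) * grid$interval - 24) > 1e-9)
    stop("duplication requires the timepoints to tile a full 24 h cycle")
  list(values = c(values, values),
       grid = time_grid(c(grid$zt_times, grid$zt_times + 24),
                        replicates = grid$replicates, duplicated = TRUE))
}

# matrix version: columns ordered by (timepoint, replicate)
duplicate_matrix <- function(mat, grid) {
  ds <- duplicate_series(rep(0, n_samples(grid)), grid)
  list(mat = cbind(mat, mat), grid = ds$grid)
}
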