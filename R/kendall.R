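#' Kendall's S between a data series and a reference waveform
#'
#' S is the concordant-minus-discordant pair count: over all sample pairs
#' (i, j), `sign(x_i - x_j) * sign(ref_i - ref_j)` is summed. Pairs tied in
#' the reference contribute 0, as do pairs tied in the data (the midrank
#' convention: equal data values carry equal ranks, so their sign is 0).
#'
#' @param x Numeric data values.
#' @param ref Reference values (or ranks; only their ordering matters) of the
#'   same length.
#' @return Integer-valued S.
#' @examples
#' kendall_s(1:4, 1:4)    # perfect concordance: 4*3/2 = 6
#' kendall_s(4:1, 1:4)    # perfect discordance: -6
#' @export
kendall_s <- function(x, ref) {
  if (length(x) != length(ref)) stop("x and ref must have equal length")
  n <- length(x)
  if (n < 2) return(0)
  ij <- combn(n, 2)
  sum(sign(x[ij[1, ]] - x[ij[2, ]]) * sign(ref[ij[1, ]] - ref[ij[2, ]]))
}

# coefficients of the Gaussian binomial [m + r choose r]_q, normalized to a
# probability vector over 0..(m*r): the distribution of inversions added when
# r indistinct items are merged into m existing ones.
gauss_binom_dist <- function(m, r) {
  p <- 1
  for (i in seq_len(r)) {
    d <- length(p)
    p2 <- c(p, rep(0, m + i))
    idx <- (m + i + 1):(m + i + d)
    p2[idx] <- p2[idx] - p
    if (length(p2) > i)
      for (k in (i + 1):length(p2)) p2[k] <- p2[k] + p2[k - i]
    p <- p2[seq_len(d + m)]
  }
  p / sum(p)
}

convolve_poly <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  la <- length(a)
  for (k in seq_along(b)) {
    idx <- k:(k + la - 1L)
    out[idx] <- out[idx] + a * b[k]
  }
  out
}

#' Exact null distribution of Kendall's S against a tied reference
#'
#' Under the null, tie-free data values are in uniform random order relative
#' to a reference whose tie structure is given by `tie_group_sizes` (replicates
#' share their timepoint's reference value; cosine symmetry can merge further
#' timepoints). S is then a linear transform of the generalized inversion
#' count, whose generating function is the Gaussian multinomial coefficient;
#' the distribution is built by convolving Gaussian binomial factors. Above
#' `exact_cap` samples a normal approximation with tie-corrected variance and
#' continuity correction is returned instead, flagged via `exact = FALSE`.
#'
#' @param tie_group_sizes Integer sizes of the reference tie groups
#'   (summing to the number of samples n).
#' @param exact_cap Largest n for which the exact convolution is used.
#' @return An object of class `jtk_null` with fields `n`, `groups`, `max_s`,
#'   `exact`, and either (`s`, `prob`, `upper_tail`) or `sd`.
#' @examples
#' nd <- exact_null(c(1, 1, 1))   # n = 3, untied reference
#' nd$prob                         # 1/6, 2/6, 2/6, 1/6 over S = -3,-1,1,3
#' @export
exact_null <- function(tie_group_sizes, exact_cap = 30) {
  g <- as.integer(tie_group_sizes)
  if (!length(g) || any(g < 1)) stop("tie group sizes must be positive integers")
  n <- sum(g)
  max_s <- (n^2 - sum(g^2)) / 2
  if (max_s == 0) {
    return(structure(list(n = n, groups = g, s = 0, prob = 1, upper_tail = 1,
                          max_s = 0, exact = TRUE), class = "jtk_null"))
  }
  if (n <= exact_cap) {
    dist <- 1
    m <- 0
    for (r in g) {
      if (m > 0) dist <- convolve_poly(dist, gauss_binom_dist(m, r))
      m <- m + r
    }
    s <- 2 * (0:max_s) - max_s
    structure(list(n = n, groups = g, s = s, prob = dist,
                   upper_tail = rev(cumsum(rev(dist))),
                   max_s = max_s, exact = TRUE), class = "jtk_null")
  } else {
    v <- (n * (n - 1) * (2 * n + 5) - sum(g * (g - 1) * (2 * g + 5))) / 18
    structure(list(n = n, groups = g, sd = sqrt(v), max_s = max_s,
                   exact = FALSE), class = "jtk_null")
  }
}

#' Upper-tail probability P(S >= s) of a null distribution
#'
#' @param null A `jtk_null` from [exact_null()].
#' @param s Numeric vector of S values.
#' @return P(S >= s), exact or normal-approximated (continuity-corrected).
#' @export
jtk_tail_p <- function(null, s) {
  if (null$exact) {
    idx <- findInterval(s - 0.5, null$s) + 1L
    out <- numeric(length(s))
    ok <- idx <= length(null$s)
    out[ok] <- null$upper_tail[idx[ok]]
    out
  } else {
    pnorm((s - 1) / null$sd, lower.tail = FALSE)
  }
}

#' @export
print.jtk_null <- function(x, ...) {
  cat(sprintf("jtk_null: n = %d, groups = {%s}, |S| <= %d, %s\n",
              x$n, paste(x$groups, collapse = ","), x$max_s,
              if (x$exact) "exact" else "normal approximation"))
  invisible(x)
}
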