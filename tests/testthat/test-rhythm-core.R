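test_that("series duplication concatenates the series and extends the grid by one cycle", {
  g <- time_grid(c(3, 9, 15, 21))
  d <- duplicate_series(c(1, 2, 3, 4), g)
  expect_equal(d$values, c(1, 2, 3, 4, 1, 2, 3, 4))
  expect_equal(d$grid$zt_times, c(3, 9, 15, 21, 27, 33, 39, 45))
  expect_true(d$grid$duplicated)

  # replicate-blocked input preserves block order
  g2 <- time_grid(c(0, 12), replicates = 2)
  d2 <- duplicate_series(c(10, 11, 20, 21), g2)
  expect_equal(d2$values, c(10, 11, 20, 21, 10, 11, 20, 21))

  expect_error(duplicate_series(numeric(0), g), "empty")
  expect_error(duplicate_series(d$values, d$grid), "already duplicated")
  # grids that do not tile 24 h cannot be duplicated
  g3 <- time_grid(c(0, 6, 12))
  expect_error(duplicate_series(1:3, g3), "24 h")
})

test_that("time grids validate spacing, range and replicate counts", {
  expect_error(time_grid(c(3, 9, 16, 21)), "uniform")
  expect_error(time_grid(c(6, 12, 18, 24)), "\\[0, 24\\)")
  expect_error(time_grid(c(9, 3)), "increasing")
  expect_error(time_grid(c(3, 9), replicates = 0), "replicates")
  g <- time_grid(c(3, 9, 15, 21), replicates = 3)
  expect_equal(sample_times(g), rep(c(3, 9, 15, 21), each = 3))
})

test_that("reference set enumerates representable periods and lag offsets", {
  g <- time_grid(c(3, 9, 15, 21), replicates = 1)
  rs <- build_reference_set(g, 21, 24, 0.5)
  expect_setequal(unique(vapply(rs, `[[`, 0, "period_h")), c(21, 24))
  p24 <- Filter(function(w) w$period_h == 24, rs)
  expect_length(p24, 8)  # lags 0, 3, ..., 21
  expect_equal(sort(vapply(p24, `[[`, 0, "lag_offset_h")), seq(0, 21, by = 3))

  # single 24 h period at lag 0 peaks at the first timepoint
  rs24 <- build_reference_set(g, 24, 24, 0.5)
  w0 <- Filter(function(w) w$lag_offset_h == 0, rs24)[[1]]
  expect_equal(w0$peak_zt, 3)
  expect_equal(which.max(w0$ref), 1)

  # shifting all ZT labels leaves the rank patterns unchanged
  g_shift <- time_grid(c(3, 9, 15, 21) + 2, replicates = 1)
  rs_shift <- build_reference_set(g_shift, 21, 24, 0.5)
  for (k in seq_along(rs))
    expect_equal(rs_shift[[k]]$ranks, rs[[k]]$ranks)

  # no representable period in range -> error naming the resolution
  g10 <- time_grid(c(0, 10, 20), replicates = 1)
  expect_error(build_reference_set(g10, 21, 24, 0.5), "no period")
})

test_that("kendall_s counts concordant minus discordant pairs, ties contribute zero", {
  expect_equal(kendall_s(1:4, 1:4), 6)     # n(n-1)/2
  expect_equal(kendall_s(4:1, 1:4), -6)
  # midrank case, verified by explicit pair enumeration
  x <- c(3, 1, 2); r <- c(1, 2, 2)
  brute <- 0
  for (i in 1:2) for (j in (i + 1):3)
    brute <- brute + sign(x[i] - x[j]) * sign(r[i] - r[j])
  expect_equal(brute, -2)
  expect_equal(kendall_s(x, r), -2)
  expect_error(kendall_s(1:3, 1:4), "equal length")
})

test_that("exact null matches hand enumeration for n = 3 and is symmetric", {
  nd <- exact_null(c(1, 1, 1))
  expect_equal(nd$s, c(-3, -1, 1, 3))
  expect_equal(nd$prob, c(1, 2, 2, 1) / 6)
  expect_equal(sum(nd$prob), 1)
  # two timepoints x three replicates against a tied reference
  nd2 <- exact_null(c(3, 3))
  br <- brute_s_dist(c(3, 3))
  expect_equal(nd2$s[nd2$prob > 0], br$s)
  expect_equal(nd2$prob[nd2$prob > 0], br$prob, tolerance = 1e-12)
  # symmetry about zero for assorted structures
  for (gr in list(c(2, 2, 2), c(1, 2, 3), c(4, 1, 1), c(2, 3))) {
    d <- exact_null(gr)
    expect_equal(d$prob, rev(d$prob), tolerance = 1e-12)
    expect_gt(jtk_tail_p(d, d$max_s), 0)
  }
})

test_that("normal fallback beyond the exact cap is flagged and close to exact", {
  groups <- rep(3, 4)  # n = 12
  ex <- exact_null(groups, exact_cap = 30)
  ap <- exact_null(groups, exact_cap = 8)
  expect_true(ex$exact)
  expect_false(ap$exact)
  s <- 30
  expect_equal(jtk_tail_p(ap, s), jtk_tail_p(ex, s), tolerance = 0.3)
})

test_that("feature test recovers noiseless planted cosines exactly on the lag grid", {
  g <- time_grid(c(3, 9, 15, 21), replicates = 3)
  for (phi in seq(0, 21, by = 3)) {
    r <- suppressWarnings(test_feature(cosine_series(g, phi), g))
    expect_equal(r$peak_zt, phi)
    expect_equal(r$period_h, 24)
    expect_lt(r$p_raw, 1e-4)
  }
})

test_that("constant series yield p_raw 1 and amplitude 1", {
  g <- time_grid(c(3, 9, 15, 21), replicates = 3)
  r <- suppressWarnings(test_feature(rep(5, 12), g))
  expect_equal(r$p_raw, 1)
  expect_equal(r$amplitude_fold, 1)
  expect_true(is.na(r$period_h))
  expect_false(r$rhythmic)
})

test_that("amplitude fold is the pseudocounted ratio of per-timepoint means", {
  g <- time_grid(c(3, 9, 15, 21))
  expect_equal(amplitude_fold(c(10, 20, 30, 20), g, eps = 0), 3)
  expect_equal(amplitude_fold(c(0, 2, 5, 2), g, eps = 0.01), 5.01 / 0.01)
  expect_equal(amplitude_fold(rep(7, 4), g), 1)
  # duplication does not change per-timepoint means
  d <- duplicate_series(c(10, 20, 30, 20), g)
  expect_equal(amplitude_fold(d$values, d$grid, eps = 0), 3)
})

test_that("BH adjustment agrees with an independent step-up implementation", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(adjust_pvalues(p), bh_oracle(p))
  p2 <- c(0.7, 0.001, 0.2, 0.04, 0.04, 1)
  expect_equal(adjust_pvalues(p2), bh_oracle(p2))
  expect_equal(adjust_pvalues(0.37), 0.37)
  expect_equal(adjust_pvalues(rep(1, 5)), rep(1, 5))
  expect_equal(adjust_pvalues(numeric(0)), numeric(0))
})

test_that("oscillation call applies the printed thresholds strictly", {
  params <- rhythm_params()
  row <- function(p, fold, per) data.frame(p_adj = p, amplitude_fold = fold, period_h = per)
  expect_true(call_rhythmic(row(0.049, 1.6, 24), params))
  expect_false(call_rhythmic(row(0.05, 1.6, 24), params))    # strict <
  expect_false(call_rhythmic(row(0.049, 1.5, 24), params))   # strict >
  expect_true(call_rhythmic(row(0.049, 1.6, 21), params))    # bounds inclusive
  expect_false(call_rhythmic(row(0.049, 1.6, 20.9), params))
  expect_false(call_rhythmic(row(0.049, 1.6, NA), params))
})

test_that("stronger planted amplitude never increases the median raw p", {
  g <- time_grid(c(3, 9, 15, 21), replicates = 3)
  tt <- sample_times(g)
  set.seed(42)
  folds <- c(1, 1.5, 2, 3, 5)
  med <- vapply(folds, function(f) {
    a <- (f - 1) / (f + 1)
    mu <- 100 * (1 + a * cos(2 * pi * (tt - 15) / 24))
    m <- t(vapply(seq_len(80), function(i) rnbinom(length(tt), mu = mu, size = 10),
                  numeric(length(tt))))
    median(suppressWarnings(jtk_test(m, g))$p_raw)
  }, 0)
  expect_true(all(diff(med) <= 1e-12))
})

test_that("duplication makes raw p values at most the non-duplicated ones for planted cosines", {
  g <- time_grid(c(3, 9, 15, 21), replicates = 3)
  set.seed(99)
  for (phi in c(3, 9, 15, 21)) {
    x <- cosine_series(g, phi) + rnorm(12, sd = 5)
    pd <- suppressWarnings(test_feature(x, g, duplicate = TRUE))$p_raw
    pn <- suppressWarnings(test_feature(x, g, duplicate = FALSE))$p_raw
    expect_lte(pd, pn)
  }
})
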