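#' Classify rhythm remodeling between two genotypes
#'
#' Given per-genotype rhythm results over the same feature universe, each
#' feature is assigned exactly one category: `control_specific` (rhythmic in
#' the control only, i.e. rhythm lost upon KO), `ko_specific` (rhythmic in
#' the KO only, i.e. gained), `shared` (rhythmic in both) or `arrhythmic`
#' (neither). Features rhythmic in both genotypes additionally carry an
#' amplitude flag: `attenuated` when the KO/control amplitude ratio is
#' `<= 1/attenuation_factor`, `amplified` when `>= attenuation_factor`.
#'
#' @param results Named list of rhythm-result data frames (from
#'   [jtk_test()]), one per genotype, each with `feature_id`, `rhythmic`,
#'   `amplitude_fold`.
#' @param control,ko Names of the control and KO entries in `results`.
#' @param attenuation_factor Fold-change cut for the amplitude flags.
#' @return Data frame of class `remodeling_calls`: `feature_id`, `category`,
#'   `amplitude_change` (KO fold / control fold), `amplitude_flag`,
#'   `scap_status` (`not_applicable` until [scap_dependence()] is applied).
#' @export
classify_remodeling <- function(results, control = "control", ko = "dko",
                                attenuation_factor = 1.5) {
  for (g in c(control, ko))
    if (!g %in% names(results)) stop("genotype '", g, "' missing from results")
  rc <- results[[control]]
  rk <- results[[ko]]
  univ <- intersect(rc$feature_id, rk$feature_id)
  if (length(univ) < max(nrow(rc), nrow(rk)))
    message("feature universes differ across genotypes; using their intersection (",
            length(univ), " features)")
  ic <- match(univ, rc$feature_id)
  ik <- match(univ, rk$feature_id)
  in_c <- rc$rhythmic[ic]
  in_k <- rk$rhythmic[ik]
  category <- ifelse(in_c & !in_k, "control_specific",
              ifelse(!in_c & in_k, "ko_specific",
              ifelse(in_c & in_k, "shared", "arrhythmic")))
  change <- rk$amplitude_fold[ik] / rc$amplitude_fold[ic]
  flag <- rep(NA_character_, length(univ))
  both <- category == "shared"
  flag[both & change >= attenuation_factor] <- "amplified"
  flag[both & change <= 1 / attenuation_factor] <- "attenuated"
  out <- data.frame(feature_id = univ, category = category,
                    amplitude_change = change, amplitude_flag = flag,
                    scap_status = "not_applicable",
                    stringsAsFactors = FALSE)
  class(out) <- c("remodeling_calls", class(out))
  attr(out, "control") <- control
  attr(out, "ko") <- ko
  out
}

#' SCAP dependence of gained rhythms (triple-KO restoration)
#'
#' A KO-specific (gained) rhythm is `scap_dependent` when it is absent again
#' in the triple KO -- deleting SCAP on top of the KO "restores" the
#' non-rhythmic state -- and `scap_independent` when it persists. Lost
#' (control-specific) rhythms are audited for whether the triple KO leaves
#' them non-rhythmic too.
#'
#' @param calls Output of [classify_remodeling()].
#' @param tko_results Rhythm results of the triple-KO genotype.
#' @return List with `calls` (updated `scap_status`) and `summary`: counts
#'   `n_gained`, `n_restored`, `fraction_restored`, `n_lost`,
#'   `n_lost_unchanged_by_tko`.
#' @export
scap_dependence <- function(calls, tko_results) {
  idx <- match(calls$feature_id, tko_results$feature_id)
  if (anyNA(idx))
    stop("triple-KO results missing ", sum(is.na(idx)), " feature(s)")
  in_t <- tko_results$rhythmic[idx]
  gained <- calls$category == "ko_specific"
  calls$scap_status[gained] <- ifelse(in_t[gained], "scap_independent",
                                      "scap_dependent")
  lost <- calls$category == "control_specific"
  summary <- list(
    n_gained = sum(gained),
    n_restored = sum(gained & !in_t),
    fraction_restored = if (sum(gained)) sum(gained & !in_t) / sum(gained) else NA_real_,
    n_lost = sum(lost),
    n_lost_unchanged_by_tko = sum(lost & !in_t))
  list(calls = calls, summary = summary)
}

#' Rayleigh test of circular uniformity
#'
#' Tests whether phases on a circle of the given period are uniformly
#' distributed, using the standard approximation to the distribution of
#' `Z = n * Rbar^2` (Rbar = mean resultant length).
#'
#' @param phases_h Phases in hours.
#' @param period Circle period in hours (default 24).
#' @return List with `statistic` (Z), `r_bar`, `p_value`, `n`.
#' @export
rayleigh_test <- function(phases_h, period = 24) {
  th <- 2 * pi * phases_h / period
  n <- length(th)
  if (n < 2) return(list(statistic = NA_real_, r_bar = NA_real_,
                         p_value = NA_real_, n = n))
  r_bar <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  z <- n * r_bar^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  list(statistic = z, r_bar = r_bar, p_value = min(max(p, 0), 1), n = n)
}

#' Phase-enrichment histogram of peak phases
#'
#' Bins peak phases over [0, 24) and tests circular uniformity with the
#' Rayleigh test. Modal bins are all bins whose count is within 10% of the
#' maximum.
#'
#' @param peak_zt Peak phases in ZT hours, in [0, 24).
#' @param bin_h Bin width in hours; must divide 24 (default 3).
#' @return Object of class `phase_enrichment`: `bin_start`, `bin_end`,
#'   `counts`, `modal_bins` (bin start hours), `rayleigh_p`, `n`.
#' @export
phase_histogram <- function(peak_zt, bin_h = 3) {
  if (24 %% bin_h != 0) stop("bin_h must divide 24")
  peak_zt <- peak_zt[!is.na(peak_zt)]
  if (any(peak_zt < 0 | peak_zt >= 24)) stop("peak phases must lie in [0, 24)")
  nb <- 24 / bin_h
  counts <- tabulate(floor(peak_zt / bin_h) + 1L, nbins = nb)
  bin_start <- seq(0, 24 - bin_h, by = bin_h)
  modal <- bin_start[counts >= 0.9 * max(counts)]
  ray <- rayleigh_test(peak_zt)
  structure(list(bin_start = bin_start, bin_end = bin_start + bin_h,
                 counts = counts, modal_bins = modal,
                 rayleigh_p = ray$p_value, n = length(peak_zt)),
            class = "phase_enrichment")
}

#' @export
print.phase_enrichment <- function(x, ...) {
  cat(sprintf("phase_enrichment: n = %d, modal bin(s) starting ZT %s, Rayleigh P = %.3g\n",
              x$n, paste(x$modal_bins, collapse = ","), x$rayleigh_p))
  invisible(x)
}

#' Circular distance between two phases
#'
#' @param a,b Phases in hours.
#' @param period Circle period (default 24 h).
#' @return Shortest distance around the circle, in hours.
#' @examples
#' circular_distance(23, 1)  # 2
#' @export
circular_distance <- function(a, b, period = 24) {
  d <- abs(a - b) %% period
  pmin(d, period - d)
}

#' Phase matching of TF activity against target expression
#'
#' A predicted TF passes the phase-match screen when (a) the peak phase of
#' its activity series matches the peak phase of the mean expression of its
#' putative targets within `tolerance_h` (circular distance), and (b) the
#' TF's own transcript is rhythmic, i.e. validated in the rhythmic
#' transcriptome. Peak phases are estimated as the argmax of per-timepoint
#' means, unless a full rhythm result with `peak_zt` is supplied for the TF.
#'
#' @param tf_activity Numeric TF-activity series ordered as `zt`.
#' @param target_mean_expression Mean target-expression series ordered as `zt`.
#' @param zt ZT hour of each entry of the two series.
#' @param tf_transcript_result One-row rhythm result for the TF transcript
#'   (needs `rhythmic`; `peak_zt` is used for the activity phase if present
#'   and non-NA... the activity series argmax is used otherwise).
#' @param tolerance_h Maximal circular distance in hours (default 3).
#' @return List with `matched`, `tf_phase`, `target_phase`, `distance_h`,
#'   `tf_rhythmic`.
#' @export
tf_phase_match <- function(tf_activity, target_mean_expression, zt,
                           tf_transcript_result, tolerance_h = 3) {
  peak_phase <- function(v) {
    m <- tapply(v, zt %% 24, mean)
    as.numeric(names(m))[which.max(m)]
  }
  tf_phase <- peak_phase(tf_activity)
  target_phase <- peak_phase(target_mean_expression)
  d <- circular_distance(tf_phase, target_phase)
  tf_rhythmic <- isTRUE(tf_transcript_result$rhythmic)
  list(matched = d <= tolerance_h && tf_rhythmic,
       tf_phase = tf_phase, target_phase = target_phase,
       distance_h = d, tf_rhythmic = tf_rhythmic)
}
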