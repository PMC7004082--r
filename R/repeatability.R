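#' Group-level repeatability of trip metrics
#'
#' Estimates repeatability of log10-transformed trip metrics (distance,
#' duration, maximum range) separately for bold and shy birds, using the
#' same mixed-model variance-ratio estimator as
#' [adjusted_repeatability()] with no fixed covariates, and 84% and 95%
#' parametric-bootstrap quantile intervals. Each trip contributes one
#' row, so repeatability measures within-bird consistency across trips.
#'
#' @param metrics data frame with one row per trip: `bird_id`,
#'   `distance_km`, `duration_hr`, `max_range_km` (NAs allowed and
#'   dropped per metric).
#' @param groups data frame `bird_id`, `group` from [classify_bold_shy()].
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed for the bootstrap.
#' @param which subset of metrics to analyse.
#' @return data frame with one row per group x metric: `group`, `metric`,
#'   `R`, `ci84_lo`, `ci84_hi`, `ci95_lo`, `ci95_hi`, `n_birds`,
#'   `n_trips`.
#' @export
group_repeatability <- function(metrics, groups, n_boot = 1000, seed = 1,
                                which = c("distance", "duration", "max_range")) {
  metric_cols <- c(distance = "distance_km", duration = "duration_hr",
                   max_range = "max_range_km")[which]
  d <- merge(metrics, groups[, c("bird_id", "group")], by = "bird_id")
  out <- list()
  for (g in unique(d$group)) {
    for (m in names(metric_cols)) {
      v <- d[d$group == g & !is.na(d[[metric_cols[m]]]), ]
      if (nrow(v) == 0 || !any(table(v$bird_id) >= 2))
        abort_fmt("group '%s' has no repeated measures for metric '%s'", g, m)
      x <- log10(v[[metric_cols[m]]])
      r <- adjusted_repeatability(x, v$bird_id, covariates = NULL,
                                  n_boot = n_boot, ci_levels = c(0.84, 0.95),
                                  seed = seed)
      out[[length(out) + 1L]] <- data.frame(
        group = g, metric = m, R = r$R,
        ci84_lo = r$ci["84%", "lower"], ci84_hi = r$ci["84%", "upper"],
        ci95_lo = r$ci["95%", "lower"], ci95_hi = r$ci["95%", "upper"],
        n_birds = length(unique(v$bird_id)), n_trips = nrow(v),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' 84% confidence-interval overlap rule
#'
#' Declares two group estimates different exactly when their 84%
#' confidence intervals are disjoint; a shared endpoint counts as
#' overlap. For independent normal estimates with similar standard
#' errors, non-overlap of 84% intervals approximates a z test at the
#' 0.05 level.
#'
#' @param a,b rows (or lists) with elements `ci84_lo` and `ci84_hi` for
#'   the same metric.
#' @return `"different"` or `"not_different"`.
#' @export
ci_overlap_test <- function(a, b) {
  if (a$ci84_hi < b$ci84_lo || b$ci84_hi < a$ci84_lo) "different" else "not_different"
}

#' Monte-Carlo calibration of the 84% CI overlap rule
#'
#' Simulates pairs of independent normal group estimates with equal true
#' means and equal known standard errors, builds 84% normal confidence
#' intervals (`mean +/- z(0.92) * se`) and reports the fraction of pairs
#' whose intervals are disjoint: the empirical type-I error of the
#' overlap rule, expected near 0.047.
#'
#' @param n_rep number of replicate pairs.
#' @param se common standard error of the two estimates.
#' @param seed RNG seed.
#' @return the empirical type-I error rate (scalar).
#' @export
ci_overlap_calibration <- function(n_rep = 1e5, se = 1, seed = 1) {
  set.seed(seed)
  m1 <- stats::rnorm(n_rep, 0, se)
  m2 <- stats::rnorm(n_rep, 0, se)
  z <- stats::qnorm(0.92)
  mean(abs(m1 - m2) > 2 * z * se)
}
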