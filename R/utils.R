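#' boldforage: personality and foraging-site fidelity in central-place foragers
#'
#' Movement analysis for colonial central-place foragers: trip segmentation,
#' hidden Markov behavioural classification, a randomization-based
#' site-fidelity index, boldness scoring and repeatability comparison,
#' together with a synthetic-data generator with known ground truth.
#'
#' @useDynLib boldforage, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @keywords internal
"_PACKAGE"

#' Wrap angles to (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return angles wrapped to the half-open interval (-pi, pi].
#' @export
wrap_angle <- function(x) {
  w <- ((-x + pi) %% (2 * pi))
  pi - w
}

# stop() with sprintf-style formatting
abort_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_prob <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0 & x <= 1)

# quantile-type-7 based empirical interval
quantile_ci <- function(x, level) {
  a <- (1 - level) / 2
  stats::quantile(x, c(a, 1 - a), names = FALSE, na.rm = TRUE)
}
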