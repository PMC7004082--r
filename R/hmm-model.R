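#' Construct a movement hidden Markov model
#'
#' Defines an N-state HMM for animal movement in which each state emits a
#' step length from a gamma distribution (parameterized by mean and standard
#' deviation) and a turning angle from a von Mises distribution (mean
#' direction `mu`, concentration `kappa`). This is the standard behavioural
#' decomposition used in biologging studies, where states are interpreted
#' post hoc as e.g. travelling, resting and foraging (area-restricted
#' search).
#'
#' Internally the gamma distribution uses shape `mean^2/sd^2` and scale
#' `sd^2/mean`.
#'
#' @param delta initial state distribution (length N, sums to 1).
#' @param Gamma N x N transition probability matrix, rows summing to 1.
#' @param step_mean,step_sd per-state gamma step-length mean and sd (same
#'   units as the step observations, typically metres per fix interval).
#' @param angle_mu per-state von Mises mean turning angle in (-pi, pi].
#' @param angle_kappa per-state von Mises concentration, >= 0.
#' @return an object of class `movement_hmm`.
#' @examples
#' m <- movement_hmm(
#'   delta = c(1, 0, 0) / 1,
#'   Gamma = matrix(1 / 3, 3, 3),
#'   step_mean = c(5000, 500, 100), step_sd = c(5000, 400, 80),
#'   angle_mu = c(0, pi, 0), angle_kappa = c(8, 0.7, 2)
#' )
#' @export
movement_hmm <- function(delta, Gamma, step_mean, step_sd, angle_mu, angle_kappa) {
  n <- length(delta)
  Gamma <- as.matrix(Gamma)
  if (!is_prob(delta) || abs(sum(delta) - 1) > 1e-8)
    abort_fmt("`delta` must be a probability vector summing to 1")
  if (nrow(Gamma) != n || ncol(Gamma) != n)
    abort_fmt("`Gamma` must be %d x %d", n, n)
  if (!is_prob(c(Gamma)) || any(abs(rowSums(Gamma) - 1) > 1e-8))
    abort_fmt("`Gamma` rows must be probability vectors summing to 1 (row-stochastic)")
  if (length(step_mean) != n || length(step_sd) != n ||
      length(angle_mu) != n || length(angle_kappa) != n)
    abort_fmt("emission parameter vectors must all have length %d", n)
  if (any(step_mean <= 0) || any(step_sd <= 0))
    abort_fmt("gamma step mean and sd must be positive")
  if (any(angle_kappa < 0)) abort_fmt("von Mises kappa must be >= 0")
  structure(list(
    n_states = n,
    delta = as.numeric(delta),
    Gamma = Gamma,
    step_mean = as.numeric(step_mean),
    step_sd = as.numeric(step_sd),
    angle_mu = wrap_angle(as.numeric(angle_mu)),
    angle_kappa = as.numeric(angle_kappa)
  ), class = "movement_hmm")
}

#' @export
print.movement_hmm <- function(x, ...) {
  cat(sprintf("movement HMM with %d states\n", x$n_states))
  cat("step length (gamma): mean =", signif(x$step_mean, 4),
      " sd =", signif(x$step_sd, 4), "\n")
  cat("turning angle (von Mises): mu =", signif(x$angle_mu, 3),
      " kappa =", signif(x$angle_kappa, 3), "\n")
  cat("transition matrix:\n")
  print(round(x$Gamma, 3))
  invisible(x)
}

#' Von Mises density
#'
#' Density of the von Mises circular distribution, evaluated stably for
#' large concentration via the exponentially scaled Bessel function.
#'
#' @param x angles in radians.
#' @param mu mean direction.
#' @param kappa concentration (>= 0).
#' @param log return log density?
#' @return density (or log density) values.
#' @export
dvonmises <- function(x, mu, kappa, log = FALSE) {
  ld <- kappa * (cos(x - mu) - 1) - log(2 * pi) -
    log(besselI(kappa, 0, expon.scaled = TRUE))
  if (log) ld else exp(ld)
}

#' Von Mises random deviates
#'
#' Rejection sampler of Best & Fisher (1979). Draws from the session RNG
#' stream so results are reproducible under `set.seed()`.
#'
#' @param n number of deviates.
#' @inheritParams dvonmises
#' @return angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(wrap_angle(stats::runif(n, -pi, pi) + mu))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  wrap_angle(out + mu)
}

# gamma mean/sd -> shape/scale
gamma_shape_scale <- function(mean, sd) {
  list(shape = mean^2 / sd^2, scale = sd^2 / mean)
}

# Steps are floored at this value before gamma evaluation so that
# stationary (zero-length) steps keep the likelihood finite without a
# zero-inflation component.
STEP_FLOOR_M <- 0.1

# T x N matrix of per-observation emission log densities; NA angles (the
# undefined first turning angle of each track) contribute step density only.
emission_logdens <- function(model, step, angle) {
  n <- model$n_states
  step <- pmax(step, STEP_FLOOR_M)
  out <- matrix(0, length(step), n)
  for (j in seq_len(n)) {
    gp <- gamma_shape_scale(model$step_mean[j], model$step_sd[j])
    out[, j] <- suppressWarnings(
      stats::dgamma(step, shape = gp$shape, scale = gp$scale, log = TRUE))
    ok <- !is.na(angle)
    out[ok, j] <- out[ok, j] +
      dvonmises(angle[ok], model$angle_mu[j], model$angle_kappa[j], log = TRUE)
  }
  out[is.nan(out)] <- -Inf
  out
}

#' Simulate step/turning-angle observations from a movement HMM
#'
#' Generates one or more independent observation chains directly from the
#' state process and emission distributions. The first turning angle of
#' each chain is `NA` (a turning angle needs two preceding steps).
#'
#' @param model a [movement_hmm()].
#' @param n_steps steps per chain.
#' @param n_chains number of independent chains (e.g. trips).
#' @return a data frame with columns `trip_id`, `index`, `step_m`,
#'   `angle_rad` and the generating `state` (ground truth).
#' @export
simulate_hmm_obs <- function(model, n_steps, n_chains = 1) {
  res <- vector("list", n_chains)
  for (k in seq_len(n_chains)) {
    s <- integer(n_steps)
    s[1] <- sample.int(model$n_states, 1, prob = model$delta)
    for (t in seq_len(n_steps)[-1])
      s[t] <- sample.int(model$n_states, 1, prob = model$Gamma[s[t - 1], ])
    gp <- gamma_shape_scale(model$step_mean[s], model$step_sd[s])
    step <- stats::rgamma(n_steps, shape = gp$shape, scale = gp$scale)
    ang <- vapply(s, function(j) rvonmises(1, model$angle_mu[j], model$angle_kappa[j]),
                  numeric(1))
    ang[1] <- NA_real_
    res[[k]] <- data.frame(
      trip_id = sprintf("chain%03d", k), index = seq_len(n_steps),
      step_m = step, angle_rad = ang, state = s
    )
  }
  do.call(rbind, res)
}
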