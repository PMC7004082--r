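# --- working-scale parameterization -----------------------------------------
# delta via multinomial logit anchored at state 1; transition matrix via
# row-wise multinomial logit anchored at the diagonal; positives via log;
# von Mises mean unconstrained and wrapped on the natural scale.

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

tpm_from_eta <- function(eta, n) {
  G <- diag(n)
  G[row(G) != col(G)] <- exp(eta)
  G / rowSums(G)
}

eta_from_tpm <- function(G) {
  n <- nrow(G)
  G <- pmax(G, 1e-12)
  w <- log(G / diag(G))
  w[row(w) != col(w)]
}

pack_hmm_par <- function(model) {
  n <- model$n_states
  if (n == 1) {
    return(c(log(model$step_mean), log(model$step_sd),
             model$angle_mu, log(pmax(model$angle_kappa, 1e-8))))
  }
  c(log(pmax(model$delta[-1], 1e-12) / pmax(model$delta[1], 1e-12)),
    eta_from_tpm(model$Gamma),
    log(model$step_mean), log(model$step_sd),
    model$angle_mu, log(pmax(model$angle_kappa, 1e-8)))
}

unpack_hmm_par <- function(par, n) {
  if (n == 1) {
    return(movement_hmm(1, matrix(1, 1, 1), exp(par[1]), exp(par[2]),
                        wrap_angle(par[3]), exp(par[4])))
  }
  i <- 0L
  take <- function(k) {
    out <- par[(i + 1L):(i + k)]
    i <<- i + k
    out
  }
  delta <- softmax(c(0, take(n - 1L)))
  Gamma <- tpm_from_eta(take(n * (n - 1L)), n)
  movement_hmm(delta, Gamma,
               step_mean = exp(take(n)), step_sd = exp(take(n)),
               angle_mu = wrap_angle(take(n)), angle_kappa = exp(take(n)))
}

n_hmm_par <- function(n) as.integer(if (n == 1) 4 else (n - 1) + n * (n - 1) + 4 * n)

obs_chain_lengths <- function(obs) {
  r <- rle(as.character(obs$trip_id))
  as.integer(r$lengths)
}

check_obs <- function(obs) {
  if (!is.data.frame(obs) || !all(c("step_m", "angle_rad") %in% names(obs)))
    abort_fmt("`obs` must be a data frame with columns step_m and angle_rad")
  if (nrow(obs) == 0) abort_fmt("`obs` is empty")
  if (is.null(obs$trip_id)) obs$trip_id <- "chain001"
  obs
}

#' Forward-algorithm log likelihood of a movement HMM
#'
#' Computes the log marginal likelihood of pooled step/turning-angle
#' observations under an HMM, treating each `trip_id` as an independent
#' chain sharing the same parameters. Per-step scaling keeps the recursion
#' stable over long tracks; missing turning angles (the first observation
#' of every chain) contribute their step density only.
#'
#' @param model a [movement_hmm()].
#' @param obs data frame with columns `step_m`, `angle_rad` (NA allowed)
#'   and optionally `trip_id` (defaults to a single chain).
#' @return the log likelihood (scalar).
#' @export
hmm_loglik <- function(model, obs) {
  obs <- check_obs(obs)
  ld <- emission_logdens(model, obs$step_m, obs$angle_rad)
  forward_loglik_cpp(ld, model$delta, model$Gamma, obs_chain_lengths(obs))
}

#' Most probable state path (Viterbi decoding)
#'
#' Returns the jointly most probable hidden-state sequence for pooled
#' observations, decoding each `trip_id` chain independently under the
#' shared model.
#'
#' @inheritParams hmm_loglik
#' @return integer vector of state indices (1..n_states), one per
#'   observation row.
#' @export
viterbi <- function(model, obs) {
  obs <- check_obs(obs)
  ld <- emission_logdens(model, obs$step_m, obs$angle_rad)
  as.integer(viterbi_cpp(ld, model$delta, model$Gamma, obs_chain_lengths(obs)))
}

# Data-driven default starting model: step means at spread quantiles of the
# observed step lengths, sds equal to means, turning angles mildly
# concentrated at zero, sticky transition matrix.
default_hmm_start <- function(obs, n_states) {
  qs <- stats::quantile(pmax(obs$step_m, STEP_FLOOR_M),
                        probs = seq(0.15, 0.85, length.out = n_states),
                        names = FALSE)
  qs <- sort(unique(pmax(qs, STEP_FLOOR_M * 2)))
  if (length(qs) < n_states) qs <- qs[1] * 2^(seq_len(n_states) - 1)
  G <- matrix(0.1 / max(n_states - 1, 1), n_states, n_states)
  diag(G) <- if (n_states == 1) 1 else 0.9
  movement_hmm(rep(1 / n_states, n_states), G,
               step_mean = qs, step_sd = qs,
               angle_mu = rep(0, n_states),
               angle_kappa = rep(1, n_states))
}

jitter_start <- function(model, sd = 0.25) {
  n <- model$n_states
  movement_hmm(
    delta = softmax(log(pmax(model$delta, 1e-8)) + stats::rnorm(n, 0, sd)),
    Gamma = {
      if (n == 1) matrix(1, 1, 1)
      else tpm_from_eta(eta_from_tpm(model$Gamma) + stats::rnorm(n * (n - 1), 0, sd), n)
    },
    step_mean = model$step_mean * exp(stats::rnorm(n, 0, sd)),
    step_sd = model$step_sd * exp(stats::rnorm(n, 0, sd)),
    angle_mu = wrap_angle(model$angle_mu + stats::rnorm(n, 0, sd)),
    angle_kappa = pmax(model$angle_kappa * exp(stats::rnorm(n, 0, sd)), 1e-4)
  )
}

#' Fit a movement HMM by direct likelihood maximization
#'
#' Maximizes the pooled forward log likelihood over all chains with
#' quasi-Newton optimization on a working scale (log for positive
#' parameters, multinomial logit for the initial distribution and
#' transition-matrix rows), restarting from jittered starting values and
#' keeping the best solution.
#'
#' @inheritParams hmm_loglik
#' @param n_states number of hidden states.
#' @param start optional [movement_hmm()] giving starting values; by
#'   default starting step means are placed at spread quantiles of the
#'   observed step lengths.
#' @param n_restarts number of jittered restarts (the first uses `start`
#'   unperturbed).
#' @param maxit maximum optimizer iterations per restart.
#' @return the fitted [movement_hmm()] with attributes `loglik`, `AIC`,
#'   `n_obs`, `n_par` and `convergence`.
#' @export
fit_hmm <- function(obs, n_states = 3, start = NULL, n_restarts = 5, maxit = 500) {
  obs <- check_obs(obs)
  if (is.null(start)) start <- default_hmm_start(obs, n_states)
  if (start$n_states != n_states)
    abort_fmt("`start` has %d states but n_states = %d", start$n_states, n_states)
  chain_len <- obs_chain_lengths(obs)
  step <- obs$step_m
  angle <- obs$angle_rad

  nll <- function(par) {
    m <- try(unpack_hmm_par(par, n_states), silent = TRUE)
    if (inherits(m, "try-error")) return(1e12)
    ll <- forward_loglik_cpp(emission_logdens(m, step, angle),
                             m$delta, m$Gamma, chain_len)
    if (!is.finite(ll)) return(1e12) else -ll
  }

  best <- NULL
  diagnostics <- character(0)
  for (r in seq_len(n_restarts)) {
    s <- if (r == 1) start else jitter_start(start)
    fit <- try(stats::optim(pack_hmm_par(s), nll, method = "BFGS",
                            control = list(maxit = maxit, reltol = 1e-10)),
               silent = TRUE)
    if (inherits(fit, "try-error")) {
      diagnostics <- c(diagnostics, sprintf("restart %d: %s", r, attr(fit, "condition")$message))
      next
    }
    if (!is.finite(fit$value) || fit$value >= 1e12) {
      diagnostics <- c(diagnostics, sprintf("restart %d: non-finite likelihood", r))
      next
    }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    abort_fmt("HMM fit failed in all %d restarts:\n%s", n_restarts,
              paste(diagnostics, collapse = "\n"))
  model <- unpack_hmm_par(best$par, n_states)
  attr(model, "loglik") <- -best$value
  attr(model, "n_par") <- n_hmm_par(n_states)
  attr(model, "AIC") <- 2 * n_hmm_par(n_states) + 2 * best$value
  attr(model, "n_obs") <- nrow(obs)
  attr(model, "convergence") <- best$convergence
  model
}

#' Select the number of HMM states by AIC
#'
#' Fits an HMM for each candidate state count and returns the count with
#' the smallest AIC, `AIC = 2k - 2 logL` with
#' `k = (n - 1) + n(n - 1) + 4n` free parameters.
#'
#' @inheritParams fit_hmm
#' @param candidates integer vector of state counts to compare.
#' @param ... passed to [fit_hmm()].
#' @return the selected state count, with attribute `aic_table` (data
#'   frame of candidate fits) and `fits` (the fitted models).
#' @export
select_n_states <- function(obs, candidates = c(2, 3), ...) {
  fits <- lapply(candidates, function(n) fit_hmm(obs, n_states = n, ...))
  aic <- vapply(fits, attr, numeric(1), which = "AIC")
  out <- candidates[which.min(aic)]
  attr(out, "aic_table") <- data.frame(
    n_states = candidates,
    n_par = vapply(candidates, n_hmm_par, integer(1)),
    loglik = vapply(fits, attr, numeric(1), which = "loglik"),
    AIC = aic
  )
  attr(out, "fits") <- fits
  out
}

#' Map fitted HMM states to behavioural labels
#'
#' Behavioural interpretation follows the usual movement-ecology reading:
#' travelling is the state with the largest mean step length; foraging
#' (area-restricted search) is, among the remaining states, the one whose
#' turning-angle distribution is least concentrated at zero (preferring
#' states that also take short steps); everything else is resting.
#' Concentration at zero is scored as `kappa * cos(mu)`.
#'
#' @param model a fitted [movement_hmm()].
#' @return character vector of labels ("travelling", "foraging",
#'   "resting"), one per state index.
#' @export
label_states <- function(model) {
  n <- model$n_states
  labels <- rep("resting", n)
  travelling <- which.max(model$step_mean)
  labels[travelling] <- "travelling"
  rest <- setdiff(seq_len(n), travelling)
  if (length(rest) == 1) {
    labels[rest] <- "foraging"
  } else if (length(rest) > 1) {
    straightness <- model$angle_kappa[rest] * cos(model$angle_mu[rest])
    turny <- rest[straightness < 0.5]
    if (length(turny) == 0) turny <- rest[which.min(straightness)]
    labels[turny[which.min(model$step_mean[turny])]] <- "foraging"
  }
  labels
}

#' Aggregate decoded foraging runs into foraging sites
#'
#' Each maximal run of consecutive foraging-state fixes in a decoded trip
#' becomes one foraging site, represented by the arithmetic mean of its
#' member fixes' coordinates and the midpoint of its time span. States are
#' decoded per step (fix i to fix i+1); fix i inherits the state of step i
#' and the final fix inherits the final step's state.
#'
#' @param trip data frame of the trip's fixes with columns `bird_id`,
#'   `trip_id`, `t` (POSIXct), `lat`, `lon` (and optionally `stage`).
#' @param states integer state path from [viterbi()], one per step
#'   (`nrow(trip) - 1` values).
#' @param label_map character labels per state index from
#'   [label_states()].
#' @return data frame of sites (`site_id`, `bird_id`, `trip_id`, `lat_c`,
#'   `lon_c`, `t_mid`, `n_fixes`), zero rows if the trip contains no
#'   foraging-state fix.
#' @export
extract_sites <- function(trip, states, label_map) {
  if (length(states) != nrow(trip) - 1)
    abort_fmt("decoded path length (%d) must equal n_fixes - 1 (%d)",
              length(states), nrow(trip) - 1)
  fix_state <- c(states, states[length(states)])
  is_forage <- label_map[fix_state] == "foraging"
  r <- rle(is_forage)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  if (length(keep) == 0) {
    return(data.frame(site_id = character(0), bird_id = character(0),
                      trip_id = character(0), lat_c = numeric(0),
                      lon_c = numeric(0),
                      t_mid = as.POSIXct(character(0), tz = "UTC"),
                      n_fixes = integer(0), stringsAsFactors = FALSE))
  }
  out <- lapply(seq_along(keep), function(k) {
    idx <- starts[keep[k]]:ends[keep[k]]
    data.frame(
      site_id = sprintf("%s_s%02d", trip$trip_id[1], k),
      bird_id = trip$bird_id[1],
      trip_id = trip$trip_id[1],
      lat_c = mean(trip$lat[idx]),
      lon_c = mean(trip$lon[idx]),
      t_mid = trip$t[idx[1]] + (trip$t[idx[length(idx)]] - trip$t[idx[1]]) / 2,
      n_fixes = length(idx),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
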