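# Independent oracles and small constructed fixtures. The oracle density,
# forward and Viterbi computations here are written from the model
# definitions directly (gamma in shape/scale, von Mises via the Bessel
# normalizer, exhaustive path enumeration) and share no code with the
# package's recursions.

oracle_logdens <- function(model, step, angle) {
  sapply(seq_len(model$n_states), function(j) {
    sh <- model$step_mean[j]^2 / model$step_sd[j]^2
    sc <- model$step_sd[j]^2 / model$step_mean[j]
    d <- dgamma(pmax(step, 0.1), shape = sh, scale = sc, log = TRUE)
    va <- ifelse(is.na(angle), 0,
                 model$angle_kappa[j] * cos(angle - model$angle_mu[j]) -
                   log(2 * pi * besselI(model$angle_kappa[j], 0)))
    d + va
  })
}

enumerate_paths <- function(n_states, T) {
  as.matrix(expand.grid(rep(list(seq_len(n_states)), T)))
}

# log joint probability of each complete state path
oracle_path_logjoint <- function(model, obs) {
  ld <- oracle_logdens(model, obs$step_m, obs$angle_rad)
  T <- nrow(obs)
  paths <- enumerate_paths(model$n_states, T)
  apply(paths, 1, function(s) {
    lp <- log(model$delta[s[1]]) + ld[1, s[1]]
    for (t in 2:T) lp <- lp + log(model$Gamma[s[t - 1], s[t]]) + ld[t, s[t]]
    lp
  })
}

oracle_loglik <- function(model, obs) {
  lp <- oracle_path_logjoint(model, obs)
  m <- max(lp)
  log(sum(exp(lp - m))) + m
}

oracle_viterbi <- function(model, obs) {
  lp <- oracle_path_logjoint(model, obs)
  paths <- enumerate_paths(model$n_states, nrow(obs))
  as.integer(paths[which.max(lp), ])
}

toy_hmm3 <- function() {
  movement_hmm(
    delta = c(0.5, 0.3, 0.2),
    Gamma = matrix(c(0.8, 0.1, 0.1,
                     0.2, 0.6, 0.2,
                     0.3, 0.3, 0.4), 3, 3, byrow = TRUE),
    step_mean = c(500, 100, 20), step_sd = c(400, 80, 15),
    angle_mu = c(0, pi, 0), angle_kappa = c(4, 0.5, 1)
  )
}

# fixes along a meridian: colony at (lat0, lon0), out-and-back is built by
# mirroring the outbound latitudes
meridian_fixes <- function(lat_off_deg, lat0 = 70, lon0 = 12,
                           t0 = as.POSIXct("2017-06-20 06:00:00", tz = "UTC"),
                           step_min = 10, bird_id = "b1") {
  data.frame(
    bird_id = bird_id, colony_id = "colony1", stage = "incubation",
    t = t0 + seq_along(lat_off_deg) * step_min * 60 - step_min * 60,
    lat = lat0 + lat_off_deg, lon = lon0,
    stringsAsFactors = FALSE
  )
}

METER_PER_DEG <- pi * 6371000 / 180  # one degree of meridian arc

# exhaustive expectation of the raw similarity proportion per bird for a
# toy site table (uniform within-candidate and donor-site draws)
oracle_fidelity_expectation <- function(sites) {
  birds <- unique(sites$bird_id)
  eligible <- birds[sapply(birds, function(b)
    length(unique(sites$trip_id[sites$bird_id == b])) >= 2)]
  dist <- function(i, j) haversine_m(c(sites$lat_c[i], sites$lon_c[i]),
                                     c(sites$lat_c[j], sites$lon_c[j]))
  out <- sapply(eligible, function(b) {
    f_idx <- which(sites$bird_id == b)
    probs <- c()
    for (f in f_idx) {
      wc <- which(sites$bird_id == b & sites$trip_id != sites$trip_id[f])
      others <- setdiff(unique(sites$bird_id[sites$colony_id == sites$colony_id[f]]), b)
      for (ob in others) {
        os <- which(sites$bird_id == ob)
        p <- mean(outer(wc, os, Vectorize(function(w, s) dist(f, w) < dist(f, s))))
        probs <- c(probs, p)
      }
    }
    mean(probs)
  })
  names(out) <- eligible
  out
}
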