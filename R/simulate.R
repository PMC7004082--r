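# Local tangent-plane geometry around a colony: x east, y north, metres.
# Adequate well below ~300 km ranges; the generator stays inside 60 km.
M_PER_DEG <- pi * 6371000 / 180

tangent_to_latlon <- function(x, y, origin) {
  lat <- origin[1] + y / M_PER_DEG
  # east-west scaling at the point's own latitude keeps local distances
  # nearly isometric over the whole annulus
  lon <- origin[2] + x / (M_PER_DEG * cos(lat * pi / 180))
  cbind(lat = lat, lon = lon)
}

latlon_to_tangent <- function(lat, lon, origin) {
  y <- (lat - origin[1]) * M_PER_DEG
  x <- (lon - origin[2]) * M_PER_DEG * cos(lat * pi / 180)
  c(x, y)
}

#' Default ground-truth movement HMM for the generator
#'
#' Three behavioural states scaled to the fix interval: travelling (long,
#' directed steps), foraging/area-restricted search (short steps, wide
#' turns) and resting (very short, weakly directed steps). Step means are
#' expressed in metres per fix interval; the defaults correspond to
#' roughly 30 km/h travel, 3 km/h search and drift at a 10-min interval.
#'
#' @param fix_interval_min fix interval in minutes.
#' @return a [movement_hmm()]; state order travelling, foraging, resting.
#' @export
default_true_hmm <- function(fix_interval_min = 10) {
  f <- fix_interval_min / 10
  movement_hmm(
    delta = c(1, 0, 0),
    Gamma = matrix(c(
      0.85, 0.10, 0.05,
      0.10, 0.80, 0.10,
      0.05, 0.15, 0.80
    ), 3, 3, byrow = TRUE),
    step_mean = c(5000, 500, 100) * f,
    step_sd = c(2500, 400, 80) * f,
    angle_mu = c(0, pi, 0),
    angle_kappa = c(8, 0.7, 2)
  )
}

#' Configuration for the synthetic study generator
#'
#' Describes a multi-colony central-place foraging study with known ground
#' truth: per-bird latent boldness (with a chosen repeatability of the
#' personality score), per-bird site-fidelity level optionally coupled to
#' boldness, and a known movement HMM generating the tracks. Per-bird
#' quantities (latent boldness, sex, fidelity level, preferred foraging
#' site) are drawn here, once, from `rng_seed`, so that tracks and
#' personality tests share the same birds.
#'
#' @param n_colonies number of colonies.
#' @param colony_coords list of `c(lat, lon)` per colony; defaults to
#'   west-Svalbard-like positions.
#' @param n_birds_per_colony birds per colony.
#' @param n_trips_per_bird foraging trips per bird.
#' @param stage breeding stage, `"incubation"` or `"chick_rearing"`.
#' @param fix_interval_min GPS fix interval in minutes (10 during
#'   incubation, 2 during chick rearing in the emulated design).
#' @param true_hmm generating [movement_hmm()]; state order travelling,
#'   foraging, resting.
#' @param fidelity_base baseline probability that a trip targets the
#'   bird's preferred site rather than a fresh random site.
#' @param boldness_fidelity_slope logit-scale effect of latent boldness on
#'   the per-bird fidelity level (0 = no coupling).
#' @param boldness_repeatability between-bird share of personality-score
#'   variance in (0, 1]; default 0.678.
#' @param fidelity_level optional explicit per-bird fidelity levels
#'   (recycled), overriding the boldness coupling.
#' @param annulus_km preferred/random foraging sites are drawn uniformly
#'   in this distance annulus around the colony.
#' @param start_date first day of the emulated field season (UTC).
#' @param rng_seed integer seed; all generator randomness derives from it.
#' @return a `sim_config` list, including the realized per-bird table
#'   `$birds` (bird_id, colony_id, sex, boldness, fidelity_level and the
#'   preferred site coordinates).
#' @export
sim_config <- function(n_colonies = 2,
                       colony_coords = list(c(78.92, 12.10), c(78.17, 15.10)),
                       n_birds_per_colony = 10,
                       n_trips_per_bird = 4,
                       stage = c("incubation", "chick_rearing"),
                       fix_interval_min = 10,
                       true_hmm = default_true_hmm(fix_interval_min),
                       fidelity_base = 0.7,
                       boldness_fidelity_slope = 0,
                       boldness_repeatability = 0.678,
                       fidelity_level = NULL,
                       annulus_km = c(5, 60),
                       start_date = as.POSIXct("2017-06-15 00:00:00", tz = "UTC"),
                       rng_seed = 1) {
  stage <- match.arg(stage)
  stopifnot(n_colonies >= 1, length(colony_coords) >= n_colonies,
            n_birds_per_colony >= 0, n_trips_per_bird >= 0,
            fix_interval_min > 0)
  if (!is_prob(fidelity_base) || !is_prob(boldness_repeatability))
    abort_fmt("fidelity_base and boldness_repeatability must lie in [0, 1]")
  if (!inherits(true_hmm, "movement_hmm"))
    abort_fmt("true_hmm must be a movement_hmm")
  for (cc in colony_coords[seq_len(n_colonies)])
    if (abs(cc[1]) > 90 || abs(cc[2]) > 180) abort_fmt("invalid colony coordinates")

  n_birds <- n_colonies * n_birds_per_colony
  set.seed(rng_seed)
  birds <- NULL
  if (n_birds > 0) {
    colony_id <- rep(sprintf("colony%d", seq_len(n_colonies)), each = n_birds_per_colony)
    boldness <- stats::rnorm(n_birds, 0, sqrt(boldness_repeatability))
    fl <- if (is.null(fidelity_level)) {
      stats::plogis(stats::qlogis(pmin(pmax(fidelity_base, 1e-6), 1 - 1e-6)) +
                      boldness_fidelity_slope * boldness)
    } else rep_len(fidelity_level, n_birds)
    # preferred foraging site, uniform in the annulus around the home colony
    rr <- sqrt(stats::runif(n_birds, annulus_km[1]^2, annulus_km[2]^2)) * 1000
    th <- stats::runif(n_birds, 0, 2 * pi)
    pref <- t(vapply(seq_len(n_birds), function(i) {
      origin <- colony_coords[[match(colony_id[i], sprintf("colony%d", seq_len(n_colonies)))]]
      tangent_to_latlon(rr[i] * cos(th[i]), rr[i] * sin(th[i]), origin)[1, ]
    }, numeric(2)))
    birds <- data.frame(
      bird_id = sprintf("bird%03d", seq_len(n_birds)),
      colony_id = colony_id,
      sex = sample(c("F", "M"), n_birds, replace = TRUE),
      boldness = boldness,
      fidelity_level = fl,
      pref_lat = pref[, 1], pref_lon = pref[, 2],
      stringsAsFactors = FALSE
    )
  }
  structure(list(
    n_colonies = n_colonies, colony_coords = colony_coords[seq_len(n_colonies)],
    n_birds_per_colony = n_birds_per_colony, n_trips_per_bird = n_trips_per_bird,
    stage = stage, fix_interval_min = fix_interval_min, true_hmm = true_hmm,
    fidelity_base = fidelity_base,
    boldness_fidelity_slope = boldness_fidelity_slope,
    boldness_repeatability = boldness_repeatability,
    annulus_km = annulus_km, start_date = start_date, rng_seed = rng_seed,
    birds = birds
  ), class = "sim_config")
}

# draw a trip target: preferred site with probability fidelity_level,
# otherwise a fresh uniform draw from the annulus (tangent-plane metres)
draw_target_xy <- function(pref_xy, fidelity_level, annulus_m) {
  if (stats::runif(1) < fidelity_level) return(pref_xy)
  r <- sqrt(stats::runif(1, annulus_m[1]^2, annulus_m[2]^2))
  th <- stats::runif(1, 0, 2 * pi)
  c(r * cos(th), r * sin(th))
}

#' Simulate GPS tracks from the generating HMM
#'
#' Produces per-bird fix sequences with the emulated sampling design:
#' equally spaced timestamps, trips that leave the colony buffer, travel
#' to a target site (the bird's preferred site with probability
#' `fidelity_level`, else a fresh random site), dwell there in a
#' foraging/resting mixture governed by the true HMM's transition
#' probabilities, and return. Step lengths and turning angles within each
#' behavioural phase are emitted from the true HMM's state distributions;
#' out-/return-leg headings are steered toward the target with von Mises
#' noise so trips are central-place round trips.
#'
#' @param config a [sim_config()].
#' @param buffer_m colony buffer radius used to anchor trip boundaries.
#' @param dwell_steps range (min, max) of dwell steps per trip, sampled
#'   uniformly.
#' @return data frame of fixes (`bird_id`, `colony_id`, `stage`, `t`,
#'   `lat`, `lon`, `true_state`); `true_state` is the HMM state that
#'   generated the outgoing step of each fix (NA at colony fixes and for
#'   boundary-adjusted steps). Zero birds or zero trips give a zero-row
#'   data frame.
#' @export
simulate_tracks <- function(config, buffer_m = 300, dwell_steps = c(20, 60)) {
  stopifnot(inherits(config, "sim_config"))
  empty <- data.frame(bird_id = character(0), colony_id = character(0),
                      stage = character(0),
                      t = as.POSIXct(character(0), tz = "UTC"),
                      lat = numeric(0), lon = numeric(0),
                      true_state = integer(0), stringsAsFactors = FALSE)
  if (is.null(config$birds) || config$n_trips_per_bird == 0) return(empty)
  set.seed(config$rng_seed + 1L)
  hmm <- config$true_hmm
  annulus_m <- config$annulus_km * 1000
  dt <- config$fix_interval_min * 60
  TRAVEL <- 1L; FORAGE <- 2L; REST <- 3L

  draw_step <- function(state) {
    gp <- gamma_shape_scale(hmm$step_mean[state], hmm$step_sd[state])
    stats::rgamma(1, shape = gp$shape, scale = gp$scale)
  }
  # travel steps drawn closer to the goal than this are length-censored by
  # the arrival; flag them so ground-truth emission checks use only
  # unconditioned draws
  gp_t <- gamma_shape_scale(hmm$step_mean[TRAVEL], hmm$step_sd[TRAVEL])
  travel_censor_m <- stats::qgamma(0.995, shape = gp_t$shape, scale = gp_t$scale)

  out <- vector("list", nrow(config$birds))
  for (bi in seq_len(nrow(config$birds))) {
    bird <- config$birds[bi, ]
    origin <- config$colony_coords[[match(bird$colony_id,
                                          sprintf("colony%d", seq_len(config$n_colonies)))]]
    pref_xy <- latlon_to_tangent(bird$pref_lat, bird$pref_lon, origin)
    xs <- ys <- numeric(0)
    st <- integer(0)
    add <- function(x, y, state) {
      xs <<- c(xs, x); ys <<- c(ys, y); st <<- c(st, state)
    }
    for (tr in seq_len(config$n_trips_per_bird)) {
      # pre-trip colony fixes (inside buffer)
      for (k in 1:2) add(0, 0, NA_integer_)
      target <- draw_target_xy(pref_xy, bird$fidelity_level, annulus_m)
      pos <- c(0, 0)
      # out-leg: travel state, heading steered at the target; the final
      # approach step is truncated so the dwell starts at the target
      guard <- 0L
      while (sqrt(sum((pos - target)^2)) > 300 && guard < 500L) {
        guard <- guard + 1L
        dist_left <- sqrt(sum((pos - target)^2))
        head_to <- atan2(target[2] - pos[2], target[1] - pos[1])
        theta <- head_to + rvonmises(1, 0, hmm$angle_kappa[TRAVEL])
        L <- draw_step(TRAVEL)
        adjusted <- dist_left < travel_censor_m
        if (L > dist_left) {  # do not overshoot the target
          L <- dist_left
          adjusted <- TRUE
        }
        cand <- pos + L * c(cos(theta), sin(theta))
        if (sqrt(sum(cand^2)) <= buffer_m + 50) {
          cand <- cand * (buffer_m + 100) / max(sqrt(sum(cand^2)), 1)
          adjusted <- TRUE
        }
        add(cand[1], cand[2], if (adjusted) NA_integer_ else TRAVEL)
        pos <- cand
      }
      # dwell: foraging/resting chain restricted to those two states
      nd <- sample(dwell_steps[1]:dwell_steps[2], 1)
      state <- FORAGE
      theta <- stats::runif(1, -pi, pi)
      for (k in seq_len(nd)) {
        if (sqrt(sum((pos - target)^2)) > 2000) {
          # beyond the dwell radius: head straight back at the target
          # (step lengths stay state-distributed, only the heading is
          # steered)
          theta <- atan2(target[2] - pos[2], target[1] - pos[1])
        } else {
          theta <- theta + rvonmises(1, hmm$angle_mu[state], hmm$angle_kappa[state])
        }
        L <- draw_step(state)
        cand <- pos + L * c(cos(theta), sin(theta))
        adjusted <- FALSE
        if (sqrt(sum(cand^2)) <= buffer_m + 50) {
          cand <- cand * (buffer_m + 100) / max(sqrt(sum(cand^2)), 1)
          adjusted <- TRUE
        }
        add(cand[1], cand[2], if (adjusted) NA_integer_ else state)
        pos <- cand
        p2 <- hmm$Gamma[state, c(FORAGE, REST)]
        state <- c(FORAGE, REST)[sample.int(2, 1, prob = p2 / sum(p2))]
      }
      # return-leg: travel state steered at the colony
      guard <- 0L
      while (sqrt(sum(pos^2)) > buffer_m + 200 && guard < 500L) {
        guard <- guard + 1L
        head_to <- atan2(-pos[2], -pos[1])
        theta <- head_to + rvonmises(1, 0, hmm$angle_kappa[TRAVEL])
        L <- draw_step(TRAVEL)
        adjusted <- sqrt(sum(pos^2)) < travel_censor_m
        if (L >= sqrt(sum(pos^2))) {  # final step: snap to the colony
          L <- sqrt(sum(pos^2))
          adjusted <- TRUE
        }
        cand <- pos + L * c(cos(theta), sin(theta))
        add(cand[1], cand[2], if (adjusted) NA_integer_ else TRAVEL)
        pos <- cand
      }
      add(0, 0, NA_integer_)
    }
    ll <- tangent_to_latlon(xs, ys, origin)
    n <- length(xs)
    # the recorded true state belongs to the outgoing step: shift by one
    state_out <- c(st[-1], NA_integer_)
    out[[bi]] <- data.frame(
      bird_id = bird$bird_id, colony_id = bird$colony_id, stage = config$stage,
      t = config$start_date + (bi - 1) * 60 + dt * (seq_len(n) - 1),
      lat = ll[, 1], lon = ll[, 2], true_state = state_out,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Simulate repeated novel-object personality tests
#'
#' Each bird receives 1-4 tests (frequencies matching a typical colonial
#' field season: most birds tested once, a tail tested repeatedly). A
#' latent per-bird value with between-bird variance share equal to
#' `boldness_repeatability` drives a sitting-versus-leaving gradient in
#' the five behaviour-state proportions of the 60-s test; a small
#' compositional measurement noise is added and each row renormalized so
#' proportions sum to one exactly.
#'
#' @param config a [sim_config()].
#' @param n_tests optional explicit number of tests per bird (recycled).
#' @return data frame of tests: `bird_id`, `date`, `stage`, `observer`,
#'   `test_number`, `p_sit`, `p_raised`, `p_stand`, `p_off_nest`,
#'   `p_off_ledge`, plus the generating `latent` value.
#' @export
simulate_personality <- function(config, n_tests = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$birds)) {
    return(data.frame(bird_id = character(0)))
  }
  set.seed(config$rng_seed + 2L)
  birds <- config$birds
  nb <- nrow(birds)
  k <- if (is.null(n_tests)) {
    sample(1:4, nb, replace = TRUE, prob = c(0.60, 0.22, 0.11, 0.07))
  } else rep_len(n_tests, nb)
  R <- config$boldness_repeatability
  mean_profile <- c(0.32, 0.15, 0.18, 0.10, 0.25)
  gradient <- c(0.55, 0.02, -0.02, -0.05, -0.50)  # sums to zero
  # measurement noise spans the compositional directions orthogonal to both
  # the simplex constraint and the boldness gradient, so the latent
  # repeatability carries onto the score axis undiluted while the
  # non-leading components receive realistic variance
  basis <- qr.Q(qr(cbind(rep(1, 5) / sqrt(5),
                         gradient / sqrt(sum(gradient^2)),
                         diag(5)[, 1:3])))[, 3:5]
  noise_sd <- c(0.06, 0.05, 0.03)
  rows <- vector("list", nb)
  for (i in seq_len(nb)) {
    z <- birds$boldness[i] + stats::rnorm(k[i], 0, sqrt(max(1 - R, 1e-12)))
    u <- pmin(pmax(0.5 + 0.15 * z, 0), 1)
    P <- t(vapply(u, function(uu) {
      p <- mean_profile + (uu - 0.5) * gradient +
        as.numeric(basis %*% (stats::rnorm(3) * noise_sd))
      p <- pmax(p, 1e-6)
      p / sum(p)
    }, numeric(5)))
    rows[[i]] <- data.frame(
      bird_id = birds$bird_id[i],
      date = as.Date(config$start_date) + sample(0:30, k[i], replace = TRUE),
      stage = config$stage,
      observer = ifelse(birds$colony_id[i] == "colony1", "obs1", "obs2"),
      test_number = seq_len(k[i]),
      p_sit = P[, 1], p_raised = P[, 2], p_stand = P[, 3],
      p_off_nest = P[, 4], p_off_ledge = P[, 5],
      latent = z,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Simulate foraging sites directly (site-level generator)
#'
#' Skips GPS simulation and HMM decoding: for each bird and trip, sites
#' are placed at the bird's preferred location with probability
#' `fidelity_level` (else at a fresh uniform draw from the annulus), with
#' isotropic scatter. Useful for exercising the fidelity randomization at
#' known ground truth.
#'
#' @param config a [sim_config()].
#' @param sites_per_trip number of foraging sites per trip.
#' @param scatter_km sd of the isotropic site scatter around the target.
#' @return data frame of sites (`site_id`, `bird_id`, `trip_id`,
#'   `colony_id`, `stage`, `lat_c`, `lon_c`, `t_mid`, `n_fixes`).
#' @export
simulate_sites <- function(config, sites_per_trip = 2, scatter_km = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$birds) || config$n_trips_per_bird == 0) {
    return(data.frame(site_id = character(0)))
  }
  set.seed(config$rng_seed + 3L)
  annulus_m <- config$annulus_km * 1000
  rows <- list()
  for (bi in seq_len(nrow(config$birds))) {
    bird <- config$birds[bi, ]
    origin <- config$colony_coords[[match(bird$colony_id,
                                          sprintf("colony%d", seq_len(config$n_colonies)))]]
    pref_xy <- latlon_to_tangent(bird$pref_lat, bird$pref_lon, origin)
    for (tr in seq_len(config$n_trips_per_bird)) {
      target <- draw_target_xy(pref_xy, bird$fidelity_level, annulus_m)
      for (s in seq_len(sites_per_trip)) {
        xy <- target + stats::rnorm(2, 0, scatter_km * 1000)
        ll <- tangent_to_latlon(xy[1], xy[2], origin)
        rows[[length(rows) + 1L]] <- data.frame(
          site_id = sprintf("%s_t%02d_s%02d", bird$bird_id, tr, s),
          bird_id = bird$bird_id,
          trip_id = sprintf("%s_t%02d", bird$bird_id, tr),
          colony_id = bird$colony_id, stage = config$stage,
          lat_c = ll[1, 1], lon_c = ll[1, 2],
          t_mid = config$start_date + (tr - 1) * 86400 + s * 3600,
          n_fixes = 1L, stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Write a simulated study to delimited-text files
#'
#' Writes `fixes.csv`, `personality.csv`, `colonies.csv` and
#' `truth.json` (the generator's ground-truth parameters) in the formats
#' the pipeline reads.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @param fixes,tests optionally precomputed outputs of
#'   [simulate_tracks()] / [simulate_personality()].
#' @return `dir`, invisibly.
#' @export
write_sim_data <- function(config, dir, fixes = NULL, tests = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(fixes)) fixes <- simulate_tracks(config)
  if (is.null(tests)) tests <- simulate_personality(config)
  fx <- fixes
  fx$timestamp <- format(fx$t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(fx[, c("bird_id", "colony_id", "stage", "timestamp", "lat", "lon")],
                   file.path(dir, "fixes.csv"), row.names = FALSE)
  utils::write.csv(tests[, setdiff(names(tests), "latent")],
                   file.path(dir, "personality.csv"), row.names = FALSE)
  colonies <- data.frame(
    colony_id = sprintf("colony%d", seq_len(config$n_colonies)),
    lat = vapply(config$colony_coords, `[`, numeric(1), 1),
    lon = vapply(config$colony_coords, `[`, numeric(1), 2)
  )
  utils::write.csv(colonies, file.path(dir, "colonies.csv"), row.names = FALSE)
  truth <- list(
    rng_seed = config$rng_seed, stage = config$stage,
    fix_interval_min = config$fix_interval_min,
    boldness_repeatability = config$boldness_repeatability,
    boldness_fidelity_slope = config$boldness_fidelity_slope,
    hmm = config$true_hmm[c("delta", "Gamma", "step_mean", "step_sd",
                            "angle_mu", "angle_kappa")],
    birds = config$birds
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
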