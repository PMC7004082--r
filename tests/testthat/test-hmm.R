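test_that("forward log likelihood matches independent oracles", {
  m <- toy_hmm3()
  set.seed(3)
  obs <- simulate_hmm_obs(m, 8)

  # exhaustive enumeration over all 3^8 paths
  expect_equal(hmm_loglik(m, obs), oracle_loglik(m, obs), tolerance = 1e-10)

  # one state: independent emission densities
  m1 <- movement_hmm(1, matrix(1, 1, 1), 300, 250, 0.3, 2)
  obs1 <- simulate_hmm_obs(m1, 50)
  expect_equal(hmm_loglik(m1, obs1),
               sum(oracle_logdens(m1, obs1$step_m, obs1$angle_rad)),
               tolerance = 1e-10)

  # several chains are independent: loglik adds over trips
  obs2 <- simulate_hmm_obs(m, 6, n_chains = 2)
  split_ll <- sum(sapply(split(obs2, obs2$trip_id), function(d) hmm_loglik(m, d)))
  expect_equal(hmm_loglik(m, obs2), split_ll, tolerance = 1e-10)
})

test_that("likelihood and decoding are invariant under state relabelling", {
  m <- toy_hmm3()
  set.seed(4)
  obs <- simulate_hmm_obs(m, 40)
  perm <- c(3, 1, 2)
  mp <- movement_hmm(m$delta[perm], m$Gamma[perm, perm],
                     m$step_mean[perm], m$step_sd[perm],
                     m$angle_mu[perm], m$angle_kappa[perm])
  expect_equal(hmm_loglik(mp, obs), hmm_loglik(m, obs), tolerance = 1e-10)
  expect_equal(perm[viterbi(mp, obs)], viterbi(m, obs))

  # two identical states behave like one state
  m2 <- movement_hmm(c(0.5, 0.5), matrix(0.5, 2, 2), c(300, 300), c(250, 250),
                     c(0.3, 0.3), c(2, 2))
  m1 <- movement_hmm(1, matrix(1, 1, 1), 300, 250, 0.3, 2)
  obs1 <- simulate_hmm_obs(m1, 30)
  expect_equal(hmm_loglik(m2, obs1), hmm_loglik(m1, obs1), tolerance = 1e-10)
})

test_that("Viterbi equals the exhaustive argmax and respects persistence", {
  m <- toy_hmm3()
  for (s in 1:3) {
    set.seed(100 + s)
    obs <- simulate_hmm_obs(m, 8)
    expect_equal(viterbi(m, obs), oracle_viterbi(m, obs))
  }

  m1 <- movement_hmm(1, matrix(1, 1, 1), 300, 250, 0, 2)
  obs1 <- simulate_hmm_obs(m1, 25)
  expect_equal(viterbi(m1, obs1), rep(1L, 25))

  # sticky transition matrix decodes fewer switches than a uniform one
  set.seed(11)
  obs <- simulate_hmm_obs(m, 200)
  sticky <- movement_hmm(m$delta, diag(3) * 0.998 + (1 - diag(3)) * 0.001,
                         m$step_mean, m$step_sd, m$angle_mu, m$angle_kappa)
  uniform <- movement_hmm(m$delta, matrix(1 / 3, 3, 3),
                          m$step_mean, m$step_sd, m$angle_mu, m$angle_kappa)
  n_switch <- function(p) sum(diff(p) != 0)
  expect_lt(n_switch(viterbi(sticky, obs)), n_switch(viterbi(uniform, obs)))
})

test_that("fitting attains at least the truth's likelihood and the MLE basics", {
  m <- toy_hmm3()
  set.seed(21)
  obs <- simulate_hmm_obs(m, 250, n_chains = 4)
  fit <- fit_hmm(obs, n_states = 3, n_restarts = 2)
  expect_gte(attr(fit, "loglik"), hmm_loglik(m, obs) - 1e-6)
  expect_equal(rowSums(fit$Gamma), rep(1, 3), tolerance = 1e-10)
  expect_true(all(fit$step_mean > 0 & fit$step_sd > 0 & fit$angle_kappa >= 0))

  # one state: gamma MLE forces the fitted mean to the sample mean
  m1 <- movement_hmm(1, matrix(1, 1, 1), 300, 250, 0.3, 2)
  set.seed(22)
  obs1 <- simulate_hmm_obs(m1, 400)
  fit1 <- fit_hmm(obs1, n_states = 1, n_restarts = 2)
  expect_equal(fit1$step_mean, mean(pmax(obs1$step_m, 0.1)), tolerance = 1e-3)
  expect_equal(attr(fit1, "AIC"),
               2 * 4 - 2 * attr(fit1, "loglik"), tolerance = 1e-10)
})

test_that("AIC model selection distinguishes well-separated state counts", {
  set.seed(31)
  obs <- simulate_hmm_obs(default_true_hmm(), 300, n_chains = 4)
  sel <- select_n_states(obs, candidates = c(2, 3), n_restarts = 2)
  expect_equal(as.integer(sel), 3L)
  tab <- attr(sel, "aic_table")
  expect_equal(tab$AIC, 2 * tab$n_par - 2 * tab$loglik)
})

test_that("state labelling identifies travelling, foraging and resting", {
  m <- default_true_hmm()
  expect_equal(label_states(m), c("travelling", "foraging", "resting"))
  perm <- c(2, 3, 1)
  mp <- movement_hmm(m$delta[perm], m$Gamma[perm, perm],
                     m$step_mean[perm], m$step_sd[perm],
                     m$angle_mu[perm], m$angle_kappa[perm])
  expect_equal(label_states(mp), c("travelling", "foraging", "resting")[perm])
})

test_that("foraging sites aggregate maximal decoded runs", {
  trip <- data.frame(
    bird_id = "b1", trip_id = "b1_t01",
    t = as.POSIXct("2017-06-20", tz = "UTC") + (0:9) * 600,
    lat = 70 + (0:9) * 0.01, lon = 12 + (0:9) * 0.005
  )
  labels <- c("travelling", "foraging", "resting")
  # fix i inherits the state of its outgoing step, the last fix carries
  # over: fix states 1 2 2 2 2 2 1 1 1 1 -> one run of 5 foraging fixes
  states <- c(1, 2, 2, 2, 2, 2, 1, 1, 1)
  s <- extract_sites(trip, states, labels)
  expect_equal(nrow(s), 1)
  expect_equal(s$n_fixes, 5)
  expect_equal(s$lat_c, mean(trip$lat[2:6]))
  expect_equal(s$lon_c, mean(trip$lon[2:6]))
  expect_equal(s$t_mid, trip$t[2] + (trip$t[6] - trip$t[2]) / 2)

  # foraging - travel - foraging -> two sites
  states2 <- c(2, 2, 1, 1, 1, 1, 2, 2, 2)
  s2 <- extract_sites(trip, states2, labels)
  expect_equal(nrow(s2), 2)

  # no foraging fixes -> empty (trip is then dropped by ARS screening)
  s0 <- extract_sites(trip, rep(1, 9), labels)
  expect_equal(nrow(s0), 0)

  # site count equals the number of foraging runs, over random paths
  set.seed(41)
  for (k in 1:20) {
    p <- sample(1:3, 9, replace = TRUE)
    fix_state <- c(p, p[9])
    runs <- rle(labels[fix_state] == "foraging")
    expect_equal(nrow(extract_sites(trip, p, labels)),
                 sum(runs$values))
  }
})
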