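# toy site tables built in tangent-plane kilometres north of a reference
# point, all in one colony unless stated
toy_sites <- function(km_north, bird_id, trip_id, colony_id = "colony1",
                      t_mid = NULL) {
  n <- length(km_north)
  if (is.null(t_mid))
    t_mid <- as.POSIXct("2017-06-20", tz = "UTC") + seq_len(n) * 3600
  data.frame(
    site_id = sprintf("s%02d", seq_len(n)),
    bird_id = bird_id, trip_id = trip_id, colony_id = colony_id,
    lat_c = 70 + km_north * 1000 / METER_PER_DEG, lon_c = 12,
    t_mid = t_mid, stringsAsFactors = FALSE
  )
}

test_that("pair draws respect trip and colony structure", {
  s <- toy_sites(c(0, 2, 5, 9), bird_id = c("A", "A", "B", "B"),
                 trip_id = c("A1", "A2", "B1", "B2"))
  set.seed(1)
  p <- draw_pairs(s, "s01")
  expect_equal(length(p$between_site_ids), 1)  # one other bird -> one pair
  expect_equal(p$within_site_id, "s02")        # forced draw from trip A2
  expect_true(p$between_site_ids %in% c("s03", "s04"))

  # single-trip focal bird rejected; donor colony needs >= 2 birds
  s2 <- toy_sites(c(0, 2), bird_id = c("A", "B"), trip_id = c("A1", "B1"))
  expect_error(draw_pairs(s2, "s01"), "single-trip")
  s3 <- toy_sites(c(0, 2), bird_id = c("A", "A"), trip_id = c("A1", "A2"))
  expect_error(draw_pairs(s3, "s01"), "fewer than 2 birds")
})

test_that("pair draws are uniform over eligible candidates", {
  # focal bird A with 3 within-candidates on other trips
  s <- toy_sites(c(0, 1, 2, 3, 8), bird_id = c("A", "A", "A", "A", "B"),
                 trip_id = c("A1", "A2", "A2", "A3", "B1"))
  set.seed(2)
  draws <- replicate(4000, draw_pairs(s, "s01")$within_site_id)
  freq <- table(factor(draws, levels = c("s02", "s03", "s04"))) / 4000
  se <- sqrt((1 / 3) * (2 / 3) / 4000)
  expect_true(all(abs(freq - 1 / 3) < 3 * se + 1e-9))
})

test_that("similarity outcomes implement the inverted index with strict ties", {
  # within at 2 km, betweens at 1 km and 3 km -> outcomes (0, 1)
  s <- toy_sites(c(0, 2, 1, 3), bird_id = c("A", "A", "B", "C"),
                 trip_id = c("A1", "A2", "B1", "C1"))
  p <- list(focal_site_id = "s01", within_site_id = "s02",
            between_site_ids = c(B = "s03", C = "s04"))
  so <- similarity_outcomes(p, s)
  expect_equal(unname(so$outcomes), c(0L, 1L))
  expect_equal(mean(so$outcomes), 0.5)

  # within at distance zero beats any distinct between site
  s0 <- s; s0$lat_c[2] <- s0$lat_c[1]
  expect_equal(unname(similarity_outcomes(p, s0)$outcomes), c(1L, 1L))

  # within farther than every between site -> all zeros
  sf <- s; sf$lat_c[2] <- 70 + 9 * 1000 / METER_PER_DEG
  expect_equal(unname(similarity_outcomes(p, sf)$outcomes), c(0L, 0L))

  # exact tie scores 0 (not closer)
  st <- s; st$lat_c[3] <- st$lat_c[2]
  expect_equal(unname(similarity_outcomes(p, st)$outcomes)[1], 0L)

  # the time-difference covariate is the focal/within gap in days
  expect_equal(so$timediff_days, 1 / 24)
})

test_that("a fidelity iteration reduces to raw proportions without covariates", {
  # two birds, two trips each, deterministic geometry
  s <- toy_sites(c(0, 0.1, 30, 30.1), bird_id = c("A", "A", "B", "B"),
                 trip_id = c("A1", "A2", "B1", "B2"))
  set.seed(3)
  est <- fidelity_iteration(s, include_timediff = FALSE)
  # A's own sites are always closer than B's and vice versa: separation,
  # clamped at 1 - 1/(2m) and flagged
  expect_true(all(est$separated))
  expect_equal(est$fidelity, 1 - 1 / (2 * est$n_outcomes))

  # mixed geometry: estimates equal each bird's outcome proportion
  s2 <- toy_sites(c(0, 5, 2, 40, 3, 41), bird_id = c("A", "A", "B", "B", "C", "C"),
                  trip_id = c("A1", "A2", "B1", "B2", "C1", "C2"))
  set.seed(4)
  prep <- boldforage:::fidelity_randomization_prep(s2)
  est2 <- fidelity_iteration(s2, include_timediff = FALSE, prep = prep)
  expect_true(all(est2$fidelity >= 0 & est2$fidelity <= 1))
})

test_that("Monte-Carlo fidelity converges to the exhaustive-pairing expectation", {
  # 3 birds, mixed trip counts, no time-difference covariate
  s <- toy_sites(c(0, 4, 1, 7, 2.5, 11, 6),
                 bird_id = c("A", "A", "B", "B", "C", "C", "C"),
                 trip_id = c("A1", "A2", "B1", "B2", "C1", "C2", "C2"))
  exact <- oracle_fidelity_expectation(s)
  est <- run_fidelity_randomization(s, n_iter = 1000, seed = 5,
                                    include_timediff = FALSE)
  # undo the separation clamp to recover the raw per-iteration proportion
  raw <- ifelse(est$separated, round(est$fidelity), est$fidelity)
  got <- tapply(raw, est$bird_id, mean)[names(exact)]
  expect_true(all(abs(got - exact) < 0.02))
  expect_true(all(est$fidelity >= 0 & est$fidelity <= 1))
})

test_that("the randomization is deterministic under a seed", {
  cfg <- sim_config(n_colonies = 1, n_birds_per_colony = 5,
                    n_trips_per_bird = 3, rng_seed = 6)
  s <- simulate_sites(cfg)
  a <- run_fidelity_randomization(s, n_iter = 5, seed = 42)
  b <- run_fidelity_randomization(s, n_iter = 5, seed = 42)
  expect_identical(a, b)
  one <- run_fidelity_randomization(s, n_iter = 1, seed = 1)
  expect_equal(nrow(one), length(unique(one$bird_id)))
})

test_that("planted fidelity levels order the estimated index", {
  ok <- sapply(1:20, function(seed) {
    cfg <- sim_config(n_colonies = 1, n_birds_per_colony = 6,
                      n_trips_per_bird = 3,
                      fidelity_level = c(1, 1, 1, 0, 0, 0),
                      rng_seed = seed)
    s <- simulate_sites(cfg, sites_per_trip = 1, scatter_km = 0.3)
    smry <- attr(run_fidelity_randomization(s, n_iter = 40, seed = seed), "summary")
    m <- merge(smry, cfg$birds, by = "bird_id")
    mean(m$fidelity_mean[m$fidelity_level == 1]) >
      mean(m$fidelity_mean[m$fidelity_level == 0])
  })
  expect_equal(sum(ok), 20)
})

test_that("the boldness model recovers exact and planted relationships", {
  # exact linear relation, single iteration: slope recovered to 1e-10
  birds <- data.frame(bird_id = sprintf("b%02d", 1:12),
                      boldness = seq(-1, 1, length.out = 12))
  est <- data.frame(bird_id = birds$bird_id, iteration = 1,
                    fidelity = 0.5 + 0.12 * birds$boldness)
  fit <- boldness_fidelity_model(est, birds)
  b <- fit$coefficients[fit$coefficients$term == "boldness", ]
  expect_equal(b$mean, 0.12, tolerance = 1e-10)

  # planted positive coupling across iterations: positive mean, CI > 0
  set.seed(9)
  nb <- 40
  birds2 <- data.frame(bird_id = sprintf("b%02d", 1:nb), boldness = rnorm(nb),
                       sex = sample(c("F", "M"), nb, TRUE))
  its <- do.call(rbind, lapply(1:50, function(i) data.frame(
    bird_id = birds2$bird_id, iteration = i,
    fidelity = pmin(pmax(0.5 + 0.1 * birds2$boldness + rnorm(nb, 0, 0.03), 0), 1)
  )))
  fit2 <- boldness_fidelity_model(its, birds2)
  b2 <- fit2$coefficients[fit2$coefficients$term == "boldness", ]
  expect_gt(b2$mean, 0)
  expect_gt(b2$ci_lower, 0)
  expect_true(all(fit2$coefficients$iter_lower <= fit2$coefficients$mean &
                    fit2$coefficients$mean <= fit2$coefficients$iter_upper))
})

test_that("a null boldness effect is covered by the iteration interval", {
  covered <- sapply(1:20, function(seed) {
    set.seed(seed)
    nb <- 30
    birds <- data.frame(bird_id = sprintf("b%02d", 1:nb), boldness = rnorm(nb))
    its <- do.call(rbind, lapply(1:60, function(i) data.frame(
      bird_id = birds$bird_id, iteration = i,
      fidelity = pmin(pmax(0.55 + rnorm(nb, 0, 0.08), 0), 1)
    )))
    fit <- boldness_fidelity_model(its, birds)
    b <- fit$coefficients[fit$coefficients$term == "boldness", ]
    b$iter_lower <= 0 && 0 <= b$iter_upper
  })
  expect_gte(mean(covered), 0.9)
})
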