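test_that("haversine distance is zero at identity, exact on a meridian arc, symmetric", {
  expect_equal(haversine_m(c(78, 12), c(78, 12)), 0)
  # one degree of meridian arc = pi * R / 180
  expect_equal(haversine_m(c(78, 12), c(79, 12)), METER_PER_DEG, tolerance = 1e-6)
  set.seed(1)
  a <- cbind(runif(200, -89, 89), runif(200, -179, 179))
  b <- cbind(runif(200, -89, 89), runif(200, -179, 179))
  expect_equal(haversine_m(a, b), haversine_m(b, a))
  expect_true(all(haversine_m(a, b) >= 0))
  expect_error(haversine_m(c(95, 0), c(0, 0)), "lat")
})

test_that("trip segmentation applies the buffer and minimum-duration rules", {
  colony <- c(70, 12)
  # everything inside the 300 m buffer
  near <- meridian_fixes(rep(0.001, 10))  # ~111 m from colony
  expect_length(segment_trips(near, colony), 0)

  # a 30-minute excursion is below the 1 hr rule
  short <- meridian_fixes(c(0, 0.1, 0.1, 0.1, 0.1, 0))  # 30 min outside
  expect_length(segment_trips(short, colony), 0)

  # two excursions (2 hr and 5 hr) separated by a colony visit
  off <- c(0, rep(0.2, 13), 0, 0, rep(0.3, 31), 0)
  trips <- segment_trips(meridian_fixes(off), colony)
  expect_length(trips, 2)
  durs <- sapply(trips, function(tr)
    as.numeric(difftime(tr$t[nrow(tr)], tr$t[1], units = "hours")))
  expect_equal(durs, c(2, 5))
  expect_true(all(sapply(trips, function(tr) isTRUE(attr(tr, "complete")))))
  # every fix inside a reported trip is outside the buffer
  for (tr in trips)
    expect_true(all(haversine_m(cbind(tr$lat, tr$lon), matrix(colony, 1)) > 300))
})

test_that("trips touching the recording edge are flagged incomplete", {
  colony <- c(70, 12)
  ends_out <- meridian_fixes(c(0, rep(0.2, 15)))
  trips <- segment_trips(ends_out, colony)
  expect_length(trips, 1)
  expect_false(attr(trips[[1]], "complete"))
})

test_that("interpolation is idempotent on-grid, linear, and grid-anchored", {
  colony <- c(70, 12)
  tr <- segment_trips(meridian_fixes(c(0, rep(seq(0.1, 0.8, length.out = 12), 1), 0)),
                      colony)[[1]]
  expect_equal(interpolate_trip(tr, 10)[, c("t", "lat", "lon")],
               tr[, c("t", "lat", "lon")])

  # two fixes 20 min apart -> inserted coordinate midpoint
  two <- tr[1:2, ]
  two$t <- two$t[1] + c(0, 1200)
  out <- interpolate_trip(two, 10)
  expect_equal(nrow(out), 3)
  expect_equal(out$lat[2], mean(two$lat))
  expect_equal(out$lon[2], mean(two$lon))

  # 47-min gap -> grid at 10,20,30,40 plus the preserved end fix; collinear
  two$t <- two$t[1] + c(0, 47 * 60)
  two$lon <- c(12, 13)
  out <- interpolate_trip(two, 10)
  expect_equal(as.numeric(difftime(out$t, out$t[1], units = "mins")),
               c(0, 10, 20, 30, 40, 47))
  # linear in time for both coordinates => collinear in (lat, lon)
  expect_equal(cor(out$lat, out$lon), 1, tolerance = 1e-12)

  expect_error(interpolate_trip(two[1, ], 10), "2 fixes")
})

test_that("interpolation never lengthens the path", {
  set.seed(7)
  lat_off <- cumsum(c(0.05, runif(20, -0.02, 0.06)))
  fx <- meridian_fixes(c(0, lat_off, 0))
  fx$lon <- fx$lon + c(0, cumsum(runif(21, -0.01, 0.01)), 0)
  # irregular sampling: drop some rows
  tr <- segment_trips(fx[-c(5, 9, 14), ], c(70, 12))[[1]]
  path_len <- function(tr) sum(steps_and_angles(tr)$step_m)
  # linear interpolation in (lat, lon) can exceed the great-circle chord
  # by a sub-millimetre amount; allow that spherical slack
  expect_lte(path_len(interpolate_trip(tr, 10)), path_len(tr) + 1e-3)
})

test_that("trip metrics follow the completeness and 75% return rules", {
  colony <- c(70, 12)
  # out-and-back along a meridian to 10 km
  off_deg <- 10000 / METER_PER_DEG
  prof <- c(0, seq(0.2, 0.8, by = 0.2), 1, seq(0.8, 0.2, by = -0.2), 0) * off_deg
  tr <- segment_trips(meridian_fixes(c(0, prof[-c(1, length(prof))], 0)), colony)[[1]]
  m <- trip_metrics(tr, colony)
  expect_equal(m$max_range_km, 10, tolerance = 1e-6)
  expect_equal(m$distance_km, 2 * (10 - 0.2 * 10), tolerance = 1e-6)
  expect_true(m$complete)

  # incomplete, ends at 90% of max colony distance -> no metrics at all
  out90 <- c(0.2, 0.4, 0.6, 0.8, 1, 0.95, 0.9, 0.9) * off_deg
  tr90 <- segment_trips(meridian_fixes(c(0, out90)), colony)[[1]]
  m90 <- trip_metrics(tr90, colony)
  expect_false(m90$complete)
  expect_true(all(is.na(c(m90$distance_km, m90$duration_hr, m90$max_range_km))))

  # incomplete, ends at 50% of max -> max range only
  out50 <- c(0.2, 0.4, 0.6, 0.8, 1, 0.8, 0.65, 0.5) * off_deg
  tr50 <- segment_trips(meridian_fixes(c(0, out50)), colony)[[1]]
  m50 <- trip_metrics(tr50, colony)
  expect_true(is.na(m50$distance_km) && is.na(m50$duration_hr))
  expect_equal(m50$max_range_km, 10, tolerance = 1e-6)
})

test_that("metrics are unchanged by colony-buffer fixes before and after the trip", {
  colony <- c(70, 12)
  core <- c(rep(0.2, 8), 0.3, rep(0.2, 5))
  t1 <- segment_trips(meridian_fixes(c(0, core, 0)), colony)[[1]]
  t2 <- segment_trips(meridian_fixes(c(0, 0.0005, 0, core, 0, 0.001, 0)), colony)[[1]]
  m1 <- trip_metrics(t1, colony)
  m2 <- trip_metrics(t2, colony)
  expect_equal(m1[, c("distance_km", "duration_hr", "max_range_km")],
               m2[, c("distance_km", "duration_hr", "max_range_km")])
})

test_that("steps and turning angles follow the counting and sign conventions", {
  colony <- c(70, 12)
  tr <- segment_trips(meridian_fixes(c(0, seq(0.1, 1, by = 0.1), 0)), colony)[[1]]
  sa <- steps_and_angles(tr)
  n <- nrow(tr)
  expect_equal(nrow(sa), n - 1)
  expect_equal(sum(is.na(sa$angle_rad)), 1)
  # straight meridian: no turning
  expect_true(all(abs(sa$angle_rad[-1]) < 1e-6))

  # heading north then turning east (clockwise) => negative angle ~ -pi/2
  turn <- data.frame(
    bird_id = "b1", trip_id = "b1_t01",
    t = as.POSIXct("2017-06-20", tz = "UTC") + (0:2) * 600,
    lat = c(0, 0.01, 0.01), lon = c(12, 12, 12.01)
  )
  a <- steps_and_angles(turn)$angle_rad[2]
  expect_equal(a, -pi / 2, tolerance = 0.01)
  # and the mirror turn west is +pi/2
  turn$lon <- c(12, 12, 11.99)
  expect_equal(steps_and_angles(turn)$angle_rad[2], pi / 2, tolerance = 0.01)
})
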