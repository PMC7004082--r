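#' Great-circle distance in metres
#'
#' Haversine distance on a sphere of radius 6,371,000 m. Coordinates are
#' given latitude-first in decimal degrees (WGS84); the spherical
#' approximation errs by well under 0.5% at foraging-trip ranges.
#'
#' @param a,b coordinates as `c(lat, lon)` vectors or two-column
#'   (lat, lon) matrices; recycled row-wise.
#' @return distance(s) in metres.
#' @export
haversine_m <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = 2)
  b <- matrix(as.numeric(b), ncol = 2)
  if (any(abs(a[, 1]) > 90) || any(abs(b[, 1]) > 90) ||
      any(abs(a[, 2]) > 180) || any(abs(b[, 2]) > 180))
    abort_fmt("coordinates must be (lat, lon) with |lat| <= 90, |lon| <= 180")
  # geosphere expects (lon, lat)
  geosphere::distHaversine(a[, 2:1, drop = FALSE], b[, 2:1, drop = FALSE],
                           r = 6371000)
}

# initial bearing (degrees clockwise from north), lat-first interface
bearing_deg <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = 2)
  b <- matrix(as.numeric(b), ncol = 2)
  geosphere::bearing(a[, 2:1, drop = FALSE], b[, 2:1, drop = FALSE])
}

check_fixes <- function(fixes) {
  need <- c("bird_id", "t", "lat", "lon")
  if (!is.data.frame(fixes) || !all(need %in% names(fixes)))
    abort_fmt("fixes must be a data frame with columns %s", paste(need, collapse = ", "))
  if (!inherits(fixes$t, "POSIXct"))
    abort_fmt("fixes$t must be POSIXct (UTC)")
  if (any(abs(fixes$lat) > 90) || any(abs(fixes$lon) > 180))
    abort_fmt("invalid coordinates in fixes")
  fixes
}

#' Segment a bird's fixes into foraging trips
#'
#' A foraging trip is a maximal run of consecutive fixes farther than
#' `buffer_m` from the colony whose elapsed time (last minus first fix of
#' the run) exceeds `min_duration_hr`. Runs touching the start or end of
#' the recording without a return inside the buffer are flagged
#' incomplete (`complete = FALSE`), the operational proxy for logger
#' failure. The trip consists of the outside-buffer fixes only.
#'
#' @param fixes data frame of one bird's fixes (`bird_id`, `t` POSIXct,
#'   `lat`, `lon`, optionally `stage`), time-ordered.
#' @param colony colony coordinates `c(lat, lon)`.
#' @param buffer_m colony buffer radius in metres (default 300).
#' @param min_duration_hr minimum trip duration in hours (default 1).
#' @return list of trips; each element is the trip's fix data frame with
#'   attributes `trip_id` and `complete`, plus columns `trip_id` and
#'   `complete`.
#' @export
segment_trips <- function(fixes, colony, buffer_m = 300, min_duration_hr = 1) {
  if (nrow(fixes) == 0) return(list())
  fixes <- check_fixes(fixes)
  if (is.unsorted(fixes$t, strictly = FALSE))
    abort_fmt("fixes must be ordered in time")
  d <- haversine_m(cbind(fixes$lat, fixes$lon), matrix(colony, 1))
  outside <- d > buffer_m
  if (!any(outside)) return(list())
  r <- rle(outside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  trips <- list()
  k <- 0L
  for (i in runs) {
    idx <- starts[i]:ends[i]
    dur_hr <- as.numeric(difftime(fixes$t[idx[length(idx)]], fixes$t[idx[1]],
                                  units = "hours"))
    if (dur_hr <= min_duration_hr) next
    k <- k + 1L
    trip <- fixes[idx, , drop = FALSE]
    complete <- !(starts[i] == 1 || ends[i] == nrow(fixes))
    trip$trip_id <- sprintf("%s_t%02d", trip$bird_id[1], k)
    trip$complete <- complete
    rownames(trip) <- NULL
    attr(trip, "trip_id") <- trip$trip_id[1]
    attr(trip, "complete") <- complete
    trips[[k]] <- trip
  }
  trips
}

#' Linearly interpolate a trip to a regular time grid
#'
#' Standardizes fix resolution: output timestamps form an arithmetic grid
#' anchored at the trip's first fix with spacing `interval_min`; latitude
#' and longitude are interpolated linearly in time between bracketing
#' original fixes. The last original fix is appended if it falls off the
#' grid, so the trip's endpoints are always preserved.
#'
#' @param trip a trip data frame from [segment_trips()] (>= 2 fixes).
#' @param interval_min grid spacing in minutes.
#' @return the interpolated trip data frame (same columns).
#' @export
interpolate_trip <- function(trip, interval_min) {
  if (nrow(trip) < 2) abort_fmt("cannot interpolate a trip with < 2 fixes")
  t0 <- trip$t[1]
  tn <- trip$t[nrow(trip)]
  tt <- as.numeric(difftime(trip$t, t0, units = "secs"))
  grid <- seq(0, tt[length(tt)], by = interval_min * 60)
  if (grid[length(grid)] < tt[length(tt)]) grid <- c(grid, tt[length(tt)])
  lat <- stats::approx(tt, trip$lat, xout = grid, ties = "ordered")$y
  lon <- stats::approx(tt, trip$lon, xout = grid, ties = "ordered")$y
  out <- trip[rep(1, length(grid)), , drop = FALSE]
  out$t <- t0 + grid
  out$lat <- lat
  out$lon <- lon
  rownames(out) <- NULL
  attr(out, "trip_id") <- attr(trip, "trip_id")
  attr(out, "complete") <- attr(trip, "complete")
  out
}

#' Summary metrics of a foraging trip
#'
#' Complete trips yield cumulative path distance (km), duration (hr) and
#' maximum range from the colony (km). Incomplete trips (logger failed
#' before the return) are excluded from distance and duration; their
#' maximum range is reported only if the bird had returned to within 75%
#' of its maximum colony distance by the final recorded fix.
#'
#' @param trip a trip data frame from [segment_trips()].
#' @param colony colony coordinates `c(lat, lon)`.
#' @return one-row data frame with `trip_id`, `bird_id`, `complete`,
#'   `distance_km`, `duration_hr`, `max_range_km` (NA where undefined).
#' @export
trip_metrics <- function(trip, colony) {
  p <- cbind(trip$lat, trip$lon)
  dcol <- haversine_m(p, matrix(colony, 1))
  max_range <- max(dcol) / 1000
  complete <- isTRUE(attr(trip, "complete")) ||
    (is.null(attr(trip, "complete")) && isTRUE(trip$complete[1]))
  if (complete) {
    steps <- haversine_m(p[-nrow(p), , drop = FALSE], p[-1, , drop = FALSE])
    distance <- sum(steps) / 1000
    duration <- as.numeric(difftime(trip$t[nrow(trip)], trip$t[1], units = "hours"))
  } else {
    distance <- NA_real_
    duration <- NA_real_
    if (dcol[length(dcol)] > 0.75 * max(dcol)) max_range <- NA_real_
  }
  data.frame(
    trip_id = trip$trip_id[1], bird_id = trip$bird_id[1],
    complete = complete,
    distance_km = distance, duration_hr = duration, max_range_km = max_range,
    stringsAsFactors = FALSE
  )
}

#' Step lengths and turning angles of a trip
#'
#' Step i is the haversine distance between fixes i and i+1; the turning
#' angle at step i (defined from the second step onward) is the signed
#' change in bearing between steps i-1 and i, wrapped to (-pi, pi] with
#' counter-clockwise turns positive. The first angle is `NA`.
#'
#' @param trip a trip data frame, normally interpolated to a regular grid.
#' @return data frame of step observations (`trip_id`, `index`, `step_m`,
#'   `angle_rad`); `nrow(trip) - 1` rows.
#' @export
steps_and_angles <- function(trip) {
  n <- nrow(trip)
  if (n < 2) abort_fmt("need at least 2 fixes for steps")
  p <- cbind(trip$lat, trip$lon)
  a <- p[-n, , drop = FALSE]
  b <- p[-1, , drop = FALSE]
  step <- haversine_m(a, b)
  brg <- bearing_deg(a, b) * pi / 180
  angle <- rep(NA_real_, n - 1)
  if (n >= 3) {
    # bearings are clockwise-positive; negate for counter-clockwise-positive
    angle[-1] <- wrap_angle(-(brg[-1] - brg[-(n - 1)]))
  }
  data.frame(
    trip_id = trip$trip_id[1], index = seq_len(n - 1),
    step_m = step, angle_rad = angle, stringsAsFactors = FALSE
  )
}
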