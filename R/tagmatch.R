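# Glider-track vs satellite-tag matching: the distance/accuracy encounter
# rule, hypothetical whale dive-profile reconstruction, and
# recording-overlap computation.

#' Great-circle distance (haversine)
#'
#' Haversine distance on a sphere of radius 6371 km. Vectorised over equal
#' length coordinate vectors.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (WGS-84).
#' @return distance in km.
#' @examples
#' haversine_km(0, 0, 0, 1)  # 111.19 km, one degree of longitude at the equator
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 360))
    stop("latitude/longitude out of range")
  r <- pi / 180
  a <- sin((lat2 - lat1) * r / 2)^2 +
    cos(lat1 * r) * cos(lat2 * r) * sin((lon2 - lon1) * r / 2)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}

#' Cuvier's-beaked-whale-like dive cycle parameters
#'
#' Mean deep-dive cycle values used to reconstruct a hypothetical dive
#' profile; defaults follow published tagging means for Cuvier's beaked
#' whales (deep dive ~58 min, ~2 min at the surface, vocal below ~400 m,
#' descent/ascent ~1.1/0.8 m/s). These are configuration values carried as
#' a convention, not measurements of this package.
#'
#' @param deep_dive_duration_s,surface_duration_s cycle durations (s).
#' @param vocal_onset_depth_m depth below which the whale echolocates (m).
#' @param descent_rate_m_s,ascent_rate_m_s vertical speeds (m/s).
#' @param max_depth_m depth ceiling of the reconstructed dives (m).
#' @return list of class `dive_cycle_params`.
#' @export
dive_cycle_params <- function(deep_dive_duration_s = 58 * 60,
                              surface_duration_s = 2 * 60,
                              vocal_onset_depth_m = 400,
                              descent_rate_m_s = 1.1,
                              ascent_rate_m_s = 0.8,
                              max_depth_m = 1200) {
  stopifnot(deep_dive_duration_s > 0, surface_duration_s > 0,
            vocal_onset_depth_m > 0, descent_rate_m_s > 0,
            ascent_rate_m_s > 0)
  structure(list(deep_dive_duration_s = deep_dive_duration_s,
                 surface_duration_s = surface_duration_s,
                 vocal_onset_depth_m = vocal_onset_depth_m,
                 descent_rate_m_s = descent_rate_m_s,
                 ascent_rate_m_s = ascent_rate_m_s,
                 max_depth_m = max_depth_m),
            class = "dive_cycle_params")
}

#' Match a glider track against tag surfacing fixes
#'
#' A fix qualifies as a potential encounter when (a) its reported accuracy
#' radius is at most `max_acc_km` and (b) the glider-whale distance at the
#' fix time is at most `max_km`. The glider position at a fix time is
#' linearly interpolated along the track (or taken from the nearest track
#' sample with `position = "nearest"`). Qualifying fixes of one tag
#' deployment merge into one potential encounter (grouped by a
#' `deployment_id` column when present, otherwise all fixes form one
#' deployment).
#'
#' @param track data.frame with `t_utc` (POSIXct, strictly increasing),
#'   `lat`, `lon`.
#' @param fixes data.frame with `t_utc`, `lat`, `lon`,
#'   `accuracy_radius_km`, optionally `deployment_id`.
#' @param max_km distance rule (default 6 km).
#' @param max_acc_km fix accuracy gate (default 1.5 km).
#' @param position `"interpolate"` or `"nearest"` glider positioning.
#' @return list with `fixes` (input plus `glider_lat`, `glider_lon`,
#'   `distance_km`, `qualifies`) and `encounters` (one row per potential
#'   encounter: `deployment_id`, `start_utc`, `end_utc`, `n_fixes`,
#'   `min_distance_km`).
#' @export
find_potential_encounters <- function(track, fixes, max_km = 6,
                                      max_acc_km = 1.5,
                                      position = c("interpolate", "nearest")) {
  position <- match.arg(position)
  stopifnot(nrow(track) > 1, all(diff(as.numeric(track$t_utc)) > 0))
  tt <- as.numeric(track$t_utc)
  ft <- as.numeric(fixes$t_utc)
  in_span <- ft >= tt[1] & ft <= tt[length(tt)]
  if (any(!in_span))
    warning(sum(!in_span), " fix(es) outside the track time span skipped")
  glat <- glon <- dist <- rep(NA_real_, nrow(fixes))
  if (any(in_span)) {
    if (position == "interpolate") {
      glat[in_span] <- approx(tt, track$lat, ft[in_span])$y
      glon[in_span] <- approx(tt, track$lon, ft[in_span])$y
    } else {
      idx <- vapply(ft[in_span], function(x) which.min(abs(tt - x)),
                    integer(1))
      glat[in_span] <- track$lat[idx]
      glon[in_span] <- track$lon[idx]
    }
    dist[in_span] <- haversine_km(fixes$lat[in_span], fixes$lon[in_span],
                                  glat[in_span], glon[in_span])
  }
  qual <- in_span & fixes$accuracy_radius_km <= max_acc_km &
    !is.na(dist) & dist <= max_km
  fixes$glider_lat <- glat
  fixes$glider_lon <- glon
  fixes$distance_km <- dist
  fixes$qualifies <- qual
  dep <- if ("deployment_id" %in% names(fixes)) fixes$deployment_id
    else rep("tag1", nrow(fixes))
  q <- fixes[qual, , drop = FALSE]
  qdep <- dep[qual]
  enc <- if (nrow(q) == 0) {
    data.frame(deployment_id = character(0),
               start_utc = q$t_utc[0], end_utc = q$t_utc[0],
               n_fixes = integer(0), min_distance_km = numeric(0))
  } else {
    do.call(rbind, lapply(split(q, qdep), function(d)
      data.frame(deployment_id = dep[qual][match(d$t_utc[1], q$t_utc)],
                 start_utc = min(d$t_utc), end_utc = max(d$t_utc),
                 n_fixes = nrow(d), min_distance_km = min(d$distance_km))))
  }
  rownames(enc) <- NULL
  list(fixes = fixes, encounters = enc)
}

#' Reconstruct a hypothetical deep-dive profile from tag fixes
#'
#' Builds a u-shaped deep-dive/surface cycle series between tag surfacing
#' fixes, with each surface interval centred on its fix time (a satellite
#' fix can only be transmitted at the surface). Gaps long enough for
#' several dive cycles are filled with equal-length dives separated by
#' surface intervals; the profile is limited to deep dives (shallow silent
#' dives are not modelled). The vocal intervals are the portions of each
#' dive deeper than `params$vocal_onset_depth_m`.
#'
#' @param fix_times POSIXct (or numeric seconds) surfacing-fix times,
#'   sorted.
#' @param params a [dive_cycle_params()].
#' @return list with `profile` (data.frame `time`, `depth_m`; piecewise
#'   linear breakpoints), `dives` (`start`, `end`, `max_depth_m`) and
#'   `vocal_intervals` (`start`, `end`).
#' @export
hypothetical_dive_profile <- function(fix_times, params = dive_cycle_params()) {
  stopifnot(length(fix_times) >= 1)
  is_posix <- inherits(fix_times, "POSIXct")
  ft <- sort(as.numeric(fix_times))
  s <- params$surface_duration_s
  dr <- params$descent_rate_m_s
  ar <- params$ascent_rate_m_s
  surf <- data.frame(start = ft - s / 2, end = ft + s / 2)
  pts_t <- c(surf$start[1], surf$end[1])
  pts_d <- c(0, 0)
  dives <- vocal <- data.frame(start = numeric(0), end = numeric(0))
  dives$max_depth_m <- numeric(0)
  if (length(ft) > 1) {
    for (i in seq_len(length(ft) - 1)) {
      a <- surf$end[i]
      b <- surf$start[i + 1]
      gap <- b - a
      if (gap < 0.5 * params$deep_dive_duration_s)
        stop("fixes closer together than one dive cycle")
      k <- max(1L, round((gap + s) / (params$deep_dive_duration_s + s)))
      dive_len <- (gap - (k - 1) * s) / k
      for (j in seq_len(k)) {
        d0 <- a + (j - 1) * (dive_len + s)
        d1 <- d0 + dive_len
        depth <- min(params$max_depth_m, dive_len / (1 / dr + 1 / ar))
        t_bot0 <- d0 + depth / dr
        t_bot1 <- d1 - depth / ar
        pts_t <- c(pts_t, d0, t_bot0, t_bot1, d1)
        pts_d <- c(pts_d, 0, depth, depth, 0)
        dives <- rbind(dives, data.frame(start = d0, end = d1,
                                         max_depth_m = depth))
        v <- params$vocal_onset_depth_m
        if (depth > v)
          vocal <- rbind(vocal, data.frame(start = d0 + v / dr,
                                           end = d1 - v / ar))
        if (j < k) {
          pts_t <- c(pts_t, d1 + s)
          pts_d <- c(pts_d, 0)
        }
      }
      pts_t <- c(pts_t, surf$end[i + 1])
      pts_d <- c(pts_d, 0)
    }
  }
  back <- function(x) if (is_posix) as.POSIXct(x, origin = "1970-01-01",
                                               tz = "UTC") else x
  list(profile = data.frame(time = back(pts_t), depth_m = pts_d),
       dives = if (nrow(dives)) transform(dives, start = back(start),
                                          end = back(end)) else dives,
       vocal_intervals = if (nrow(vocal)) transform(vocal,
                                                    start = back(start),
                                                    end = back(end)) else vocal)
}

#' Intersect whale-vocal and glider-recording intervals
#'
#' Standard interval intersection: the periods during which the whale was
#' presumably vocal *and* the glider's acoustic system was recording.
#'
#' @param vocal,recording data.frames with `start` and `end` columns
#'   (POSIXct or numeric seconds), sorted.
#' @return list with `overlap` (data.frame `start`, `end`) and `total_s`.
#' @export
recording_overlap <- function(vocal, recording) {
  if (nrow(vocal) == 0 || nrow(recording) == 0)
    return(list(overlap = data.frame(start = numeric(0), end = numeric(0)),
                total_s = 0))
  is_posix <- inherits(vocal$start, "POSIXct") ||
    inherits(recording$start, "POSIXct")
  v0 <- as.numeric(vocal$start); v1 <- as.numeric(vocal$end)
  r0 <- as.numeric(recording$start); r1 <- as.numeric(recording$end)
  s0 <- s1 <- numeric(0)
  for (i in seq_along(v0)) {
    lo <- pmax(v0[i], r0)
    hi <- pmin(v1[i], r1)
    ok <- hi > lo
    s0 <- c(s0, lo[ok]); s1 <- c(s1, hi[ok])
  }
  o <- order(s0)
  s0 <- s0[o]; s1 <- s1[o]
  back <- function(x) if (is_posix) as.POSIXct(x, origin = "1970-01-01",
                                               tz = "UTC") else x
  list(overlap = data.frame(start = back(s0), end = back(s1)),
       total_s = sum(s1 - s0))
}

#' Glider recording intervals from a dive track
#'
#' Collapses runs of consecutive track samples with `recording == TRUE`
#' into intervals.
#'
#' @param track data.frame with `t_utc` and logical `recording`.
#' @return data.frame with `start`, `end`.
#' @export
recording_intervals <- function(track) {
  stopifnot(all(c("t_utc", "recording") %in% names(track)))
  r <- rle(track$recording)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(start = track$t_utc[starts[keep]],
             end = track$t_utc[ends[keep]])
}
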