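# Simulated satellite-tag track: a whale performing deep-dive cycles with
# one ARGOS fix per surfacing, centred on the surface interval, plus the
# true continuous track for validation.

#' Simulate a tagged whale's surfacing fixes and true track
#'
#' The whale alternates deep dives and surface intervals (deep dives only —
#' shallow silent dives are not modelled) while drifting on a straight
#' course. One tag fix is produced per surfacing, timed at the centre of
#' the surface interval, with position error drawn per axis from a normal
#' distribution scaled to the ARGOS accuracy radius (`accuracy_km = 0`
#' gives error-free fixes).
#'
#' @param n_deep_dives number of dive cycles (one fix per following
#'   surfacing).
#' @param dive_params a [dive_cycle_params()].
#' @param start_utc time the first dive starts (POSIXct, UTC).
#' @param start_lat,start_lon start position (decimal degrees).
#' @param speed_km_h,heading_deg drift speed and course.
#' @param accuracy_km ARGOS accuracy radius of the fixes (km); scalar or
#'   one value per fix.
#' @param seed optional integer seed.
#' @return list with `fixes` (`t_utc`, `lat`, `lon`, `accuracy_radius_km`),
#'   `surfacings` (true surfacing positions and intervals) and `track`
#'   (true continuous position at 60 s steps).
#' @export
make_tag_track <- function(n_deep_dives = 4,
                           dive_params = dive_cycle_params(),
                           start_utc = as.POSIXct("2009-11-03 00:00:00",
                                                  tz = "UTC"),
                           start_lat = 19.75, start_lon = -156.25,
                           speed_km_h = 2, heading_deg = 90,
                           accuracy_km = 1.0, seed = NULL) {
  stopifnot(n_deep_dives >= 1)
  if (!is.null(seed)) set.seed(seed)
  cycle <- dive_params$deep_dive_duration_s + dive_params$surface_duration_s
  fix_t <- (seq_len(n_deep_dives) - 1) * cycle +
    dive_params$deep_dive_duration_s + dive_params$surface_duration_s / 2
  pos_at <- function(t_s) {
    km <- speed_km_h * t_s / 3600
    th <- heading_deg * pi / 180
    list(lat = start_lat + km * cos(th) / 111.195,
         lon = start_lon + km * sin(th) /
           (111.195 * cos(start_lat * pi / 180)))
  }
  true_pos <- pos_at(fix_t)
  acc <- rep_len(accuracy_km, n_deep_dives)
  err_lat_km <- rnorm(n_deep_dives, 0, acc / 2)
  err_lon_km <- rnorm(n_deep_dives, 0, acc / 2)
  fixes <- data.frame(
    t_utc = start_utc + fix_t,
    lat = true_pos$lat + err_lat_km / 111.195,
    lon = true_pos$lon + err_lon_km /
      (111.195 * cos(start_lat * pi / 180)),
    accuracy_radius_km = acc)
  tt <- seq(0, n_deep_dives * cycle, by = 60)
  tp <- pos_at(tt)
  list(fixes = fixes,
       surfacings = data.frame(
         t_utc = start_utc + fix_t,
         lat = true_pos$lat, lon = true_pos$lon,
         start = start_utc + fix_t - dive_params$surface_duration_s / 2,
         end = start_utc + fix_t + dive_params$surface_duration_s / 2),
       track = data.frame(t_utc = start_utc + tt, lat = tp$lat,
                          lon = tp$lon))
}
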