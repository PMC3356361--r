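# Whole-mission simulation: a sequence of dives, each recording a block of
# fixed-duration files while the glider is deep, with per-class click-train
# prevalences (optionally modulated by a diel profile) and ground truth.

#' Describe a simulated mission
#'
#' Defaults emulate the reference survey scale: 85 dives recording 1-minute
#' files at 194 kHz with the recorder on only during the deep portion of
#' each dive, and the four target classes present at their mission-level
#' file prevalences (beaked whale 1%, delphinid 50.4%, sperm whale 11.8%,
#' echosounder 6.5%).
#'
#' @param n_dives number of glider dives.
#' @param files_per_dive recorded files per dive.
#' @param file_duration_s duration of one file in seconds (60 in the field;
#'   simulations may scale this down).
#' @param sample_rate_hz audio sampling rate.
#' @param prevalence named per-class probabilities that a file contains the
#'   class; names are `beaked_whale`, `delphinid`, `sperm_whale`,
#'   `echosounder`.
#' @param diel_profile optional length-24 vector of per-local-hour
#'   prevalence multipliers (index 1 = hour 0); `NULL` for no diel
#'   modulation. Applied per class via `diel_classes`.
#' @param diel_classes classes the diel profile applies to.
#' @param class_presets mapping from class to [click_presets()] name.
#' @param clicks_per_train named per-class click counts per inserted train.
#' @param noise_sigma,noise_slope_db_per_octave background noise RMS and
#'   spectral slope.
#' @param start_utc mission start (POSIXct, UTC).
#' @param utc_offset_h local-time offset (Hawai'i: -10).
#' @param descent_s,surface_s silent descent/ascent time and surface time
#'   per dive (sets the file timestamps; ascent is assumed equal to
#'   descent).
#' @return list of class `mission_scenario`.
#' @export
mission_scenario <- function(n_dives = 85, files_per_dive = 137,
                             file_duration_s = 60, sample_rate_hz = 194000,
                             prevalence = c(beaked_whale = 0.01,
                                            delphinid = 0.504,
                                            sperm_whale = 0.118,
                                            echosounder = 0.065),
                             diel_profile = NULL,
                             diel_classes = c("delphinid", "echosounder"),
                             class_presets = c(beaked_whale = "blainville",
                                               delphinid = "delphinid",
                                               sperm_whale = "sperm",
                                               echosounder = "echosounder"),
                             clicks_per_train = c(beaked_whale = 8,
                                                  delphinid = 12,
                                                  sperm_whale = 4,
                                                  echosounder = 4),
                             noise_sigma = 0.05,
                             noise_slope_db_per_octave = 0,
                             start_utc = as.POSIXct("2009-10-27 00:00:00",
                                                    tz = "UTC"),
                             utc_offset_h = -10,
                             descent_s = 4500, surface_s = 970) {
  stopifnot(all(prevalence >= 0), all(prevalence <= 1),
            n_dives >= 1, files_per_dive >= 1, file_duration_s > 0)
  if (!is.null(diel_profile)) stopifnot(length(diel_profile) == 24,
                                        all(diel_profile >= 0))
  structure(
    list(n_dives = as.integer(n_dives),
         files_per_dive = as.integer(files_per_dive),
         file_duration_s = file_duration_s,
         sample_rate_hz = sample_rate_hz, prevalence = prevalence,
         diel_profile = diel_profile, diel_classes = diel_classes,
         class_presets = class_presets,
         clicks_per_train = clicks_per_train, noise_sigma = noise_sigma,
         noise_slope_db_per_octave = noise_slope_db_per_octave,
         start_utc = start_utc, utc_offset_h = utc_offset_h,
         descent_s = descent_s, surface_s = surface_s),
    class = "mission_scenario")
}

# File index (ids, dive ids, timestamps) implied by a scenario.
mission_file_index <- function(scenario) {
  cycle_s <- 2 * scenario$descent_s +
    scenario$files_per_dive * scenario$file_duration_s + scenario$surface_s
  dive <- rep(seq_len(scenario$n_dives), each = scenario$files_per_dive)
  j <- rep(seq_len(scenario$files_per_dive), scenario$n_dives)
  t_utc <- scenario$start_utc + (dive - 1) * cycle_s + scenario$descent_s +
    (j - 1) * scenario$file_duration_s
  data.frame(
    file_id = sprintf("pam%04d_DIVE%02d_%s.wav",
                      seq_along(dive), dive,
                      format(t_utc, "%Y%m%d-%H%M%S", tz = "UTC")),
    dive_id = dive, t_utc = t_utc)
}

# Bernoulli per-class presence draws with optional diel modulation.
draw_file_classes <- function(index, scenario) {
  hr <- (as.integer(format(index$t_utc, "%H", tz = "UTC")) +
           scenario$utc_offset_h) %% 24
  for (cl in names(scenario$prevalence)) {
    p <- rep(scenario$prevalence[[cl]], nrow(index))
    if (!is.null(scenario$diel_profile) && cl %in% scenario$diel_classes)
      p <- pmin(1, p * scenario$diel_profile[hr + 1L])
    index[[cl]] <- runif(nrow(index)) < p
  }
  index
}

# Synthesise the audio of one file given its class presences. Returns the
# wave plus per-click truth rows. `cal` caches per-preset band calibration.
synth_mission_file <- function(present, scenario, presets, cal) {
  fs <- scenario$sample_rate_hz
  n <- as.integer(round(scenario$file_duration_s * fs))
  wave <- make_noise(n, fs, scenario$noise_sigma,
                     scenario$noise_slope_db_per_octave)
  clicks <- NULL
  emitted <- character(0)
  for (cl in present) {
    pre <- scenario$class_presets[[cl]]
    spec <- presets[[pre]]
    cc <- cal[[pre]]
    amp <- 10^(spec$snr_db / 20) * cc$sigma_b / cc$peak_b
    nk <- scenario$clicks_per_train[[cl]]
    icis <- if (nk > 1) draw_icis(spec, nk - 1) else numeric(0)
    span <- sum(icis) + length(cc$w) / fs
    margin <- min(0.2, 0.05 * scenario$file_duration_s)
    avail <- scenario$file_duration_s - 2 * margin - span
    if (avail <= 0) next   # train does not fit; class stays absent in audio
    emitted <- c(emitted, cl)
    t0 <- margin + runif(1) * avail
    onsets <- t0 + cumsum(c(0, icis))
    wv <- amp * cc$w
    for (on in onsets) {
      i0 <- as.integer(round(on * fs)) + 1L
      wave[i0:(i0 + length(wv) - 1L)] <- wave[i0:(i0 + length(wv) - 1L)] + wv
    }
    clicks <- rbind(clicks, data.frame(class = cl, preset = pre,
                                       onset_s = onsets,
                                       time_s = onsets + cc$t_peak))
  }
  list(wave = wave, clicks = clicks, emitted = emitted)
}

# Per-preset waveform/calibration cache shared across files: unit click,
# its band-limited peak, and the band RMS of unit-variance noise.
mission_calibration <- function(scenario, presets) {
  fs <- scenario$sample_rate_hz
  for (pre in scenario$class_presets)
    if (fs < 2 * presets[[pre]]$f_end_hz)
      stop("sample_rate_hz below Nyquist for preset ", pre)
  ref <- make_noise(as.integer(fs / 2), fs, 1,
                    scenario$noise_slope_db_per_octave)
  cal <- list()
  pad <- numeric(512)
  for (pre in unique(scenario$class_presets)) {
    spec <- presets[[pre]]
    band <- snr_cal_band(spec, fs)
    w <- make_click_waveform(spec, fs)
    cal[[pre]] <- list(
      w = as.numeric(w), t_peak = attr(w, "t_peak_s"),
      peak_b = max(abs(band_filter(c(pad, as.numeric(w), pad), fs, band))),
      sigma_b = rms(band_filter(ref, fs, band)) * scenario$noise_sigma)
  }
  cal
}

#' Simulate a recording mission
#'
#' Draws per-file class presences from the scenario prevalences (and diel
#' profile), optionally synthesises the audio of every file, and returns
#' the ground truth.
#'
#' @param scenario a [mission_scenario()].
#' @param presets click presets (see [click_presets()]).
#' @param audio `"none"` (presence truth only — fast), `"memory"` (waves
#'   returned in a list; use only for small missions), or `"wav"` (files
#'   written to `out_dir`).
#' @param out_dir output directory for `audio = "wav"`.
#' @param seed optional integer seed (bit-reproducible output).
#' @return list with `files` (per-file truth flags: `file_id`, `dive_id`,
#'   `t_utc`, one logical column per class), `clicks` (per-click truth:
#'   `file_id`, `class`, `onset_s`, `time_s`; `NULL` when `audio = "none"`),
#'   `waves` (list or `NULL`), `paths` (for `audio = "wav"`), and
#'   `scenario`.
#' @export
make_mission <- function(scenario, presets = click_presets(),
                         audio = c("none", "memory", "wav"),
                         out_dir = NULL, seed = NULL) {
  audio <- match.arg(audio)
  stopifnot(inherits(scenario, "mission_scenario"))
  if (!is.null(seed)) set.seed(seed)
  index <- mission_file_index(scenario)
  files <- draw_file_classes(index, scenario)
  if (audio == "none")
    return(list(files = files, clicks = NULL, waves = NULL, paths = NULL,
                scenario = scenario))
  if (audio == "wav") {
    stopifnot(!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  }
  cal <- mission_calibration(scenario, presets)
  classes <- names(scenario$prevalence)
  waves <- if (audio == "memory") vector("list", nrow(files)) else NULL
  paths <- if (audio == "wav") character(nrow(files)) else NULL
  clicks <- vector("list", nrow(files))
  for (i in seq_len(nrow(files))) {
    present <- classes[unlist(files[i, classes])]
    sf <- synth_mission_file(present, scenario, presets, cal)
    for (cl in setdiff(present, sf$emitted)) files[[cl]][i] <- FALSE
    if (!is.null(sf$clicks)) {
      sf$clicks$file_id <- files$file_id[i]
      clicks[[i]] <- sf$clicks
    }
    if (audio == "memory") waves[[i]] <- sf$wave
    if (audio == "wav") {
      paths[i] <- file.path(out_dir, files$file_id[i])
      write_wav(sf$wave, scenario$sample_rate_hz, paths[i])
    }
  }
  list(files = files, clicks = do.call(rbind, clicks), waves = waves,
       paths = paths, scenario = scenario)
}

#' Simulate a glider dive track
#'
#' A sawtooth depth profile along a straight course, with the acoustic
#' system recording only below `recording_depth_m` (the glider records on
#' the deep portion of each dive).
#'
#' @param n_dives number of dives.
#' @param dive_duration_s full dive duration (surface to surface, s).
#' @param surface_duration_s time at the surface between dives (s).
#' @param max_depth_m dive target depth.
#' @param recording_depth_m depth below which the recorder runs.
#' @param start_utc track start (POSIXct, UTC).
#' @param start_lat,start_lon start position (decimal degrees).
#' @param speed_km_h horizontal speed along the course.
#' @param heading_deg course over ground (0 = north).
#' @param step_s track sampling interval.
#' @return data.frame of `GliderSample` rows: `t_utc`, `lat`, `lon`,
#'   `depth_m`, `recording`.
#' @export
make_glider_track <- function(n_dives = 4, dive_duration_s = 4.3 * 3600,
                              surface_duration_s = 970, max_depth_m = 1000,
                              recording_depth_m = 500,
                              start_utc = as.POSIXct("2009-11-03 00:00:00",
                                                     tz = "UTC"),
                              start_lat = 19.7, start_lon = -156.3,
                              speed_km_h = 0.9, heading_deg = 340,
                              step_s = 60) {
  cycle <- dive_duration_s + surface_duration_s
  t <- seq(0, n_dives * cycle, by = step_s)
  phase <- t %% cycle
  half <- dive_duration_s / 2
  depth <- ifelse(phase >= dive_duration_s, 0,
                  ifelse(phase <= half, max_depth_m * phase / half,
                         max_depth_m * (dive_duration_s - phase) / half))
  km <- speed_km_h * t / 3600
  th <- heading_deg * pi / 180
  lat <- start_lat + km * cos(th) / 111.195
  lon <- start_lon + km * sin(th) / (111.195 * cos(start_lat * pi / 180))
  data.frame(t_utc = start_utc + t, lat = lat, lon = lon, depth_m = depth,
             recording = depth >= recording_depth_m)
}
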