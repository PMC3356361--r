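# End-to-end screening: detection -> feature measurement -> classification
# -> per-file presence flags, on one recording or a whole simulated
# mission.

#' Detector configurations for full-band screening
#'
#' Three band-energy-ratio configurations sharing one spectrogram pass: the
#' beaked-whale config (signal 24–48 kHz vs guard 5–20 kHz, as
#' [detector_config()]), a mid/high-frequency config for delphinid clicks
#' and echosounder pings (signal 40–90 kHz vs guard 5–18 kHz), and a
#' low-frequency config for sperm-whale clicks (signal 6–18 kHz vs guard
#' 30–90 kHz). A single signal/guard pair cannot see all classes, since
#' each group's band is another group's guard.
#'
#' @param threshold_db detection threshold applied to all configs.
#' @return named list of three [detector_config()]s.
#' @export
screening_configs <- function(threshold_db = 8) {
  list(bw = detector_config(ratio_threshold_db = threshold_db),
       mf = detector_config(signal_band_hz = c(40e3, 90e3),
                            guard_band_hz = c(5e3, 18e3),
                            ratio_threshold_db = threshold_db),
       lf = detector_config(signal_band_hz = c(6e3, 18e3),
                            guard_band_hz = c(30e3, 90e3),
                            ratio_threshold_db = threshold_db))
}

#' Screen one recording
#'
#' Runs detection, groups events into trains, measures train features,
#' classifies each train, and reports the per-class presence of the file.
#'
#' @param samples numeric samples, or a WAV path.
#' @param sample_rate sampling rate in Hz (ignored for a path).
#' @param file_id file identifier.
#' @param spec_cfg spectrogram framing; defaults to [sg_config_detector()].
#' @param det_cfg one or a list of [detector_config()]s; defaults to
#'   [screening_configs()].
#' @param rules a [rule_set()].
#' @param feature_highpass_hz high-pass for feature measurement (2 kHz so
#'   sperm-whale clicks remain measurable).
#' @return list with `events`, `trains` (features + `label`), and `flags`
#'   (one-row data.frame of per-class logicals + `bw_detail`).
#' @export
screen_recording <- function(samples, sample_rate = NULL,
                             file_id = "file1", spec_cfg = NULL,
                             det_cfg = screening_configs(),
                             rules = rule_set(),
                             feature_highpass_hz = 2000) {
  if (is.character(samples)) {
    wav <- read_wav(samples)
    if (missing(file_id)) file_id <- basename(samples)
    sample_rate <- wav$sample_rate
    samples <- wav$samples
  }
  if (is.null(spec_cfg)) spec_cfg <- sg_config_detector(sample_rate)
  gcfg <- if (inherits(det_cfg, "detector_config")) det_cfg else det_cfg[[1]]
  ev <- detect_clicks(samples, sample_rate, spec_cfg, det_cfg, file_id)
  tr <- group_into_trains(ev, gcfg)
  tf <- train_features(tr, samples, sample_rate,
                       highpass_hz = feature_highpass_hz)
  tf <- classify_trains(tf, rules)
  flags <- flag_files(tf, data.frame(file_id = file_id))
  list(events = ev, trains = tf, flags = flags)
}

#' Simulate a mission and screen every file
#'
#' Streams through a simulated mission file by file (audio is synthesised,
#' screened and discarded), accumulating truth flags, detector flags and
#' labelled trains. This is the package's end-to-end closed loop:
#' generator -> detector -> features -> classifier -> mission statistics.
#'
#' @param scenario a [mission_scenario()].
#' @param presets click presets.
#' @param det_cfg detector config(s) for screening.
#' @param rules classification rules.
#' @param spec_cfg spectrogram framing (default [sg_config_detector()]).
#' @param seed optional integer seed.
#' @param progress print a dot every 100 files.
#' @return list with `truth` (per-file truth flags), `flags` (per-file
#'   detected flags, same columns), and `trains` (all labelled trains).
#' @export
simulate_and_screen <- function(scenario, presets = click_presets(),
                                det_cfg = screening_configs(),
                                rules = rule_set(), spec_cfg = NULL,
                                seed = NULL, progress = FALSE) {
  stopifnot(inherits(scenario, "mission_scenario"))
  if (!is.null(seed)) set.seed(seed)
  fs <- scenario$sample_rate_hz
  if (is.null(spec_cfg)) spec_cfg <- sg_config_detector(fs)
  index <- mission_file_index(scenario)
  truth <- draw_file_classes(index, scenario)
  cal <- mission_calibration(scenario, presets)
  classes <- names(scenario$prevalence)
  gcfg <- if (inherits(det_cfg, "detector_config")) det_cfg else det_cfg[[1]]
  flag_rows <- vector("list", nrow(truth))
  train_rows <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    present <- classes[unlist(truth[i, classes])]
    sf <- synth_mission_file(present, scenario, presets, cal)
    for (cl in setdiff(present, sf$emitted)) truth[[cl]][i] <- FALSE
    ev <- detect_clicks(sf$wave, fs, spec_cfg, det_cfg, truth$file_id[i])
    tr <- group_into_trains(ev, gcfg)
    tf <- train_features(tr, sf$wave, fs)
    tf <- classify_trains(tf, rules)
    flag_rows[[i]] <- flag_files(tf, data.frame(file_id = truth$file_id[i]))
    if (nrow(tf) > 0) train_rows[[i]] <- tf
    if (progress && i %% 100 == 0) cat(".")
  }
  if (progress) cat("\n")
  flags <- do.call(rbind, flag_rows)
  flags$dive_id <- truth$dive_id
  flags$t_utc <- truth$t_utc
  list(truth = truth, flags = flags,
       trains = do.call(rbind, train_rows))
}
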