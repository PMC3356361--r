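# Shared fixtures: everything is generated in code at test time.

FS <- 194000                      # survey sampling rate (Hz)
PRESETS <- click_presets()

# A click train plus its detections, at a given SNR.
detect_train <- function(preset, n_clicks, snr_db, duration_s = 2.5,
                         seed = NULL, det_cfg = detector_config()) {
  tr <- make_click_train(PRESETS[[preset]], n_clicks, duration_s, FS,
                         snr_db = snr_db, seed = seed)
  tr$events <- detect_clicks(tr$wave, FS, det_cfg = det_cfg)
  tr
}

# How many truth clicks have a detected event within tol seconds.
matched_clicks <- function(tr, tol = 0.0015) {
  sum(vapply(tr$truth$time_s, function(tt)
    any(abs(tr$events$onset_s - tt) < tol), logical(1)))
}

# Flag tables for detector-performance arithmetic: n files over n_dives
# dives, with given truth-positive and detected-positive file indices.
make_flag_tables <- function(n, n_dives, truth_pos, det_pos) {
  base <- data.frame(file_id = sprintf("f%05d", seq_len(n)),
                     dive_id = rep(seq_len(n_dives), length.out = n))
  truth <- det <- base
  truth$bw <- seq_len(n) %in% truth_pos
  det$bw <- seq_len(n) %in% det_pos
  list(truth = truth, det = det)
}
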