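test_that("spectrogram localises a pure tone", {
  x <- sin(2 * pi * 30000 * (0:(0.03 * FS)) / FS)
  cfg <- spectrogram_config(FS, 2048, 2048, 0.5, highpass_hz = 0)
  sg <- spectrogram(x, cfg)
  expect_equal(sg$freq_hz[which.max(sg$mag[, 1])], 30000,
               tolerance = FS / 2048 / 30000)
})

test_that("all-zero input gives an all-zero magnitude matrix", {
  cfg <- spectrogram_config(FS, 256, 256, 0.5, highpass_hz = 0)
  sg <- spectrogram(numeric(1000), cfg)
  expect_true(all(sg$mag == 0))
})

test_that("spectrogram rejects inputs shorter than one frame", {
  cfg <- spectrogram_config(FS, 2048, 2048, 0.5)
  expect_error(spectrogram(numeric(100), cfg), "frame")
})

test_that("frame counts follow floor((N - frame)/hop) + 1", {
  cfg <- sg_config_analyst(FS)
  # integer-arithmetic oracle, computed independently here
  oracle <- function(n) floor((n - 2048) / 1024) + 1
  for (n in c(2048, 5000, 194000, 60 * FS)) {
    expect_equal(spectrogram_n_frames(n, cfg), oracle(n))
  }
  expect_equal(spectrogram_n_frames(60 * FS, cfg), 11366L)
  x <- rnorm(10000)
  expect_equal(ncol(spectrogram(x, cfg)$mag), oracle(10000))
})

test_that("reported bandwidth scales exactly with the frame-size ratio", {
  coarse <- sg_config_analyst(FS)   # 2048-sample frames
  fine <- sg_config_fine(FS)        # 32-sample frames
  expect_identical(fine$reported_bandwidth_hz / coarse$reported_bandwidth_hz,
                   2048 / 32)
  # the pair printed for these configurations: ~385 Hz and ~24.6 kHz
  expect_equal(coarse$reported_bandwidth_hz, 378.9, tolerance = 0.001)
  expect_equal(fine$reported_bandwidth_hz, 24250, tolerance = 0.001)
})

test_that("band energy ratio is 0 dB for equal flat power and +Inf on a dead guard band", {
  freq <- seq(0, FS / 2, by = 1000)
  cfg <- detector_config()
  expect_equal(band_energy_ratio(rep(1, length(freq)), freq, cfg), 0)
  col <- rep(1, length(freq))
  col[freq >= 5000 & freq <= 20000] <- 0
  expect_identical(band_energy_ratio(col, freq, cfg), Inf)
  expect_error(band_energy_ratio(col, freq / 10, cfg), "Nyquist")
})

test_that("a beaked-whale click column scores above threshold (direct FFT oracle)", {
  w <- as.numeric(make_click_waveform(PRESETS$blainville, FS))
  x <- c(rnorm(2000, 0, 1e-3), w, rnorm(2000, 0, 1e-3))
  cfg <- sg_config_detector(FS)
  sg <- spectrogram(x, cfg)
  j <- which.max(colSums(sg$mag^2))
  dc <- detector_config()
  r_pkg <- band_energy_ratio(sg$mag[, j], sg$freq_hz, dc)
  # oracle: integrate band powers of the same frame by direct FFT
  i0 <- (j - 1) * cfg$hop_samples + 1
  fr <- x[i0:(i0 + 63)] * (0.54 - 0.46 * cos(2 * pi * (0:63) / 64))
  P <- Mod(fft(fr))[1:33]^2
  f <- (0:32) * FS / 64
  r_oracle <- 10 * log10(mean(P[f >= 24000 & f <= 48000]) /
                           mean(P[f >= 5000 & f <= 20000]))
  expect_equal(r_pkg, r_oracle, tolerance = 1e-10)
  expect_gt(r_pkg, dc$ratio_threshold_db)
})

test_that("white-noise band ratio averages near 0 dB (Monte-Carlo check)", {
  set.seed(101)
  x <- rnorm(FS)                       # 1 s of white noise
  cfg <- sg_config_analyst(FS)
  cfg$highpass_hz <- 0
  sg <- spectrogram(x, cfg)
  dc <- detector_config()
  r <- apply(sg$mag, 2, band_energy_ratio, freq_hz = sg$freq_hz, cfg = dc)
  expect_lt(abs(mean(r)), 3 * sd(r) / sqrt(length(r)))
})

test_that("a noise-only file yields (almost) no events at the default threshold", {
  set.seed(5)
  nz <- make_noise(10 * FS, FS, 0.05)
  ev <- detect_clicks(nz, FS)
  expect_lte(nrow(ev), 2)
})

test_that("an 11-click train is recovered at the truth onsets", {
  tr <- detect_train("unknown_bw", 11, snr_db = 15, seed = 21)
  expect_equal(nrow(tr$events), 11)
  expect_equal(matched_clicks(tr), 11)
  # at lower SNR most clicks are still recovered
  tr10 <- detect_train("unknown_bw", 11, snr_db = 10, seed = 21)
  expect_gte(matched_clicks(tr10), 9)
})

test_that("a file with exactly one click yields exactly one event", {
  tr <- detect_train("unknown_bw", 1, snr_db = 20, duration_s = 1.5,
                     seed = 4)
  expect_equal(nrow(tr$events), 1)
})

test_that("detection tolerates a one-hop translation of the input", {
  tr <- make_click_train(PRESETS$unknown_bw, 3, 1.5, FS, snr_db = 20,
                         seed = 13)
  cfg <- sg_config_detector(FS)
  ev1 <- detect_clicks(tr$wave, FS)
  ev2 <- detect_clicks(c(numeric(cfg$hop_samples), tr$wave), FS)
  expect_equal(nrow(ev1), nrow(ev2))
  shift <- cfg$hop_samples / FS
  frame_s <- cfg$frame_size_samples / FS
  expect_true(all(abs(ev2$onset_s - ev1$onset_s - shift) <= frame_s + 1e-9))
})

test_that("events group into trains by the maximum allowed gap", {
  ev <- data.frame(file_id = "f", onset_s = cumsum(c(1, rep(0.12, 10))),
                   ratio_db = 12)
  tr <- group_into_trains(ev, detector_config(max_ici_s = 0.5))
  expect_equal(unique(tr$train_id), 1L)
  expect_equal(nrow(tr), 11)

  ev2 <- data.frame(file_id = "f",
                    onset_s = cumsum(c(1, 0.3, 0.3, 5.0, 0.3)),
                    ratio_db = 12)
  tr2 <- group_into_trains(ev2, detector_config(max_ici_s = 0.5,
                                                min_clicks_per_train = 2))
  expect_equal(as.integer(table(tr2$train_id)), c(3L, 2L))
  # the default minimum train size discards the 2-click fragment
  tr3 <- group_into_trains(ev2, detector_config(max_ici_s = 0.5))
  expect_equal(nrow(tr3), 3)
})

test_that("an empty event list gives an empty train list", {
  ev <- data.frame(file_id = character(0), onset_s = numeric(0),
                   ratio_db = numeric(0))
  expect_equal(nrow(group_into_trains(ev)), 0)
})

test_that("detect_clicks reads WAV files and errors usefully otherwise", {
  tr <- make_click_train(PRESETS$unknown_bw, 3, 1.2, FS, snr_db = 20,
                         seed = 2)
  p <- withr::local_tempfile(fileext = ".wav")
  write_wav(tr$wave, FS, p)
  ev <- detect_clicks(p)
  expect_equal(nrow(ev), 3)
  expect_equal(ev$file_id[1], basename(p))
  expect_error(detect_clicks("no-such-file.wav"), "no-such-file.wav")
})
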