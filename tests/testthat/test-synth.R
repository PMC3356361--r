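test_that("click waveforms round-trip their design features", {
  for (nm in c("blainville", "cuvier", "unknown_bw", "sperm", "echosounder")) {
    sp <- PRESETS[[nm]]
    w <- as.numeric(make_click_waveform(sp, FS))
    w <- c(numeric(291), w, numeric(291))          # measurement margins
    hp <- if (sp$f_start_hz < 12e3) 2000 else 10000
    d <- measure_duration(w, FS, highpass_hz = hp)
    expect_lt(abs(d - sp$duration_us) / sp$duration_us, 0.10)
    spec <- click_spectrum(w, FS)
    pk <- spec$freq_hz[which.max(spec$power)]
    expect_lt(abs(pk - sp$peak_freq_hz), 2500)
  }
})

test_that("Blainville's and Cuvier's presets reproduce the published features", {
  wb <- c(numeric(291), as.numeric(make_click_waveform(PRESETS$blainville, FS)),
          numeric(291))
  expect_lt(abs(measure_duration(wb, FS) - 250), 25)
  expect_lt(abs(lf_rolloff(click_spectrum(wb, FS)) - 25000), 3000)
  wc <- c(numeric(291), as.numeric(make_click_waveform(PRESETS$cuvier, FS)),
          numeric(291))
  expect_lt(abs(measure_duration(wc, FS) - 175), 18)
  expect_lt(abs(lf_rolloff(click_spectrum(wc, FS)) - 20000), 3000)
})

test_that("unknown-species preset lands on the reported click measurements", {
  w <- c(numeric(291), as.numeric(make_click_waveform(PRESETS$unknown_bw, FS)),
         numeric(291))
  d <- measure_duration(w, FS)
  expect_gt(d, 530 - 95)
  expect_lt(d, 530 + 95)
  sp <- click_spectrum(w, FS)
  expect_lt(abs(sp$freq_hz[which.max(sp$power)] - 30000), 2000)
})

test_that("zero amplitude scale gives an all-zero waveform", {
  expect_true(all(make_click_waveform(PRESETS$blainville, FS, amp = 0) == 0))
})

test_that("a sample rate below Nyquist is rejected with the limit named", {
  expect_error(make_click_waveform(PRESETS$blainville, 60000), "Nyquist")
})

test_that("sweep-click energy is confined to the design band", {
  for (nm in c("blainville", "cuvier", "unknown_bw", "sperm", "echosounder")) {
    sp <- PRESETS[[nm]]
    w <- as.numeric(make_click_waveform(sp, FS))
    n <- 2^ceiling(log2(length(w)))
    P <- Mod(fft(c(w, numeric(n - length(w)))))[1:(n / 2 + 1)]^2
    f <- (0:(n / 2)) * FS / n
    out <- f < sp$f_start_hz - 5000 | f > sp$f_end_hz + 10000
    expect_lt(10 * log10(max(P[out]) / max(P)), -40)
  }
  # the delphinid tone burst's bandwidth is set by its 50 us duration, so
  # confinement is checked against its nominal broadband extent
  w <- as.numeric(make_click_waveform(PRESETS$delphinid, FS))
  n <- 2^ceiling(log2(max(1024, length(w))))
  P <- Mod(fft(c(w, numeric(n - length(w)))))[1:(n / 2 + 1)]^2
  f <- (0:(n / 2)) * FS / n
  out <- f < 15000 | f > 95000
  expect_lt(10 * log10(max(P[out]) / max(P)), -40)
})

test_that("double-click replica appears at the configured lag", {
  sp <- PRESETS$unknown_bw
  sp$double_click_delay_us <- 300
  w <- as.numeric(make_click_waveform(sp, FS))
  w0 <- as.numeric(make_click_waveform(PRESETS$unknown_bw, FS))
  lag <- round(300e-6 * FS)
  expect_equal(length(w), length(w0) + lag)
  expect_equal(w[seq_len(lag)], w0[seq_len(lag)])
  n0 <- length(w0)
  expect_equal(w[lag + seq_len(n0 - lag)],
               w0[(lag + 1):n0] + 10^(-6 / 20) * w0[seq_len(n0 - lag)])
})

test_that("click trains place clicks at the requested ICI statistics", {
  tr <- make_click_train(PRESETS$unknown_bw, 11, 2.5, FS, snr_db = 15,
                         seed = 42)
  ici <- diff(tr$truth$time_s)
  expect_length(ici, 10)
  expect_lt(abs(mean(ici) - 0.12), 0.01)
})

test_that("a single click has an empty ICI series", {
  tr <- make_click_train(PRESETS$blainville, 1, 1, FS, noise_sigma = 0,
                         seed = 1)
  expect_equal(nrow(tr$truth), 1)
  expect_length(ici_series(tr$truth$time_s)$ici_s, 0)
})

test_that("the same seed reproduces the waveform bit for bit", {
  a <- make_click_train(PRESETS$unknown_bw, 5, 1.5, FS, seed = 7)
  b <- make_click_train(PRESETS$unknown_bw, 5, 1.5, FS, seed = 7)
  expect_identical(a$wave, b$wave)
  expect_identical(a$truth, b$truth)
})

test_that("a train that cannot fit the recording is rejected", {
  expect_error(make_click_train(PRESETS$sperm, 10, 2, FS, seed = 1),
               "does not fit")
})

test_that("generated click SNR matches the target", {
  tr <- make_click_train(PRESETS$unknown_bw, 11, 2.5, FS, snr_db = 15,
                         seed = 3)
  p <- vapply(tr$truth$time_s, function(tt) {
    w <- extract_click_window(tr$wave, FS, tt)
    n0 <- round((tt - 0.0095) * FS)
    n1 <- round((tt - 0.0045) * FS)
    10^(snr0p(w, tr$wave[n0:n1], FS) / 10)
  }, numeric(1))
  expect_lt(abs(10 * log10(mean(p)) - 15), 1)
})

test_that("mission truth respects prevalences (exact binomial oracle)", {
  sc <- mission_scenario(n_dives = 10, files_per_dive = 20,
                         prevalence = c(delphinid = 0.5))
  m <- make_mission(sc, audio = "none", seed = 11)
  count <- sum(m$files$delphinid)
  bounds <- qbinom(c(pnorm(-3), pnorm(3)), 200, 0.5)
  expect_gte(count, bounds[1])
  expect_lte(count, bounds[2])
})

test_that("all-zero prevalences give noise-only files and all-false truth", {
  sc <- mission_scenario(n_dives = 2, files_per_dive = 2, file_duration_s = 1,
                         prevalence = c(delphinid = 0, sperm_whale = 0))
  m <- make_mission(sc, audio = "memory", seed = 2)
  expect_false(any(m$files$delphinid))
  expect_null(m$clicks)
  expect_true(all(vapply(m$waves, function(w)
    max(abs(w)) < 6 * sc$noise_sigma, logical(1))))
})

test_that("the default scenario matches the survey recording scale", {
  sc <- mission_scenario()
  expect_equal(sc$n_dives * sc$files_per_dive, 85 * 137)  # ~11,600 files
  idx <- gliderpam:::mission_file_index(sc)
  expect_equal(nrow(idx), 85 * 137)
  expect_true(all(grepl("^pam\\d{4,}_DIVE\\d{2}_\\d{8}-\\d{6}\\.wav$",
                        idx$file_id)))
})

test_that("mission audio is reproducible under a fixed seed", {
  sc <- mission_scenario(n_dives = 1, files_per_dive = 2, file_duration_s = 2,
                         prevalence = c(delphinid = 1),
                         clicks_per_train = c(delphinid = 5))
  a <- make_mission(sc, audio = "memory", seed = 9)
  b <- make_mission(sc, audio = "memory", seed = 9)
  expect_identical(a$waves, b$waves)
  expect_identical(a$clicks, b$clicks)
})

test_that("tag fixes sit at surface-interval centres with class-scaled error", {
  dp <- dive_cycle_params()
  tt <- make_tag_track(3, dp, accuracy_km = 0, seed = 5)
  expect_equal(tt$fixes$lat, tt$surfacings$lat)
  expect_equal(tt$fixes$lon, tt$surfacings$lon)
  gaps <- diff(as.numeric(tt$fixes$t_utc))
  expect_equal(gaps, rep(dp$deep_dive_duration_s + dp$surface_duration_s, 2))
  expect_equal(as.numeric(tt$fixes$t_utc),
               as.numeric(tt$surfacings$start) + dp$surface_duration_s / 2)
})

test_that("WAV files survive a write/read round trip", {
  x <- sin(2 * pi * 1000 * seq(0, 0.01, by = 1 / 48000)) * 0.5
  p <- withr::local_tempfile(fileext = ".wav")
  write_wav(x, 48000, p)
  back <- read_wav(p)
  expect_equal(back$sample_rate, 48000)
  expect_equal(back$samples, x, tolerance = 1e-4)
})
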