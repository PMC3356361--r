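# Per-click and per-train feature measurement: duration, -20 dB
# low-frequency roll-off, peak frequency, upsweep, band-limited zero-to-peak
# SNR, and the inter-click-interval series.
#
# All spectral/temporal measures are noise-compensated: the noise floor
# estimated from a click-free window (or from the window edges) is
# subtracted in the power domain before quantiles/thresholds are applied.
# Without this, the -20 dB roll-off is unmeasurable at the low SNRs typical
# of glider recordings.

moving_avg <- function(x, k) {
  if (k <= 1) return(x)
  as.numeric(stats::filter(x, rep(1 / k, k), sides = 2, circular = FALSE)) |>
    (\(y) { y[is.na(y)] <- x[is.na(y)]; y })()
}

#' Measure click duration
#'
#' Duration is the interval containing 95% of the above-noise-floor energy
#' of the high-pass-filtered window (central 2.5%–97.5% energy quantiles of
#' the smoothed, noise-subtracted instantaneous energy). When a noise floor
#' is present, the measurement is restricted to the contiguous region
#' around the energy peak where the smoothed energy exceeds
#' `region_gate` times the noise power, so that noise elsewhere in the
#' window cannot inflate the energy quantiles.
#'
#' @param window waveform window containing the click (roughly centred).
#' @param sample_rate sampling rate in Hz.
#' @param highpass_hz high-pass cutoff applied before measuring (default
#'   10 kHz, the beaked-whale convention; use a lower cutoff for
#'   low-frequency clicks). 0 disables.
#' @param fraction energy fraction defining the duration (default 0.95).
#' @param noise_rms RMS of the noise floor in the same band; estimated from
#'   the window edges when `NULL`.
#' @param smooth_us smoothing length of the energy envelope in microseconds.
#' @param region_gate factor over the noise power defining the contiguous
#'   click region around the energy peak.
#' @return duration in microseconds.
#' @export
measure_duration <- function(window, sample_rate, highpass_hz = 10000,
                             fraction = 0.95, noise_rms = NULL,
                             smooth_us = 40, region_gate = 1.2) {
  stopifnot(length(window) > 8)
  if (all(window == 0)) stop("all-zero window: no click to measure")
  x <- if (highpass_hz > 0) band_filter(window, sample_rate,
                                        c(highpass_hz, Inf)) else window
  k <- max(1L, as.integer(round(smooth_us * 1e-6 * sample_rate)))
  e <- moving_avg(x^2, k)
  np <- if (is.null(noise_rms)) {
    m <- max(3L, as.integer(round(0.15 * length(e))))
    median(c(e[seq_len(m)], e[(length(e) - m + 1):length(e)]))
  } else noise_rms^2
  idx <- seq_along(e)
  if (np > 0) {
    above <- e > region_gate * np
    ipk <- which.max(e)
    if (!above[ipk]) stop("window energy does not exceed the noise floor")
    lo <- hi <- ipk
    while (lo > 1 && above[lo - 1]) lo <- lo - 1
    while (hi < length(e) && above[hi + 1]) hi <- hi + 1
    idx <- lo:hi
  }
  e2 <- pmax(e[idx] - np, 0)
  if (sum(e2) == 0) stop("window energy does not exceed the noise floor")
  cume <- cumsum(e2) / sum(e2)
  a <- (1 - fraction) / 2
  lo <- which(cume >= a)[1]
  hi <- which(cume >= 1 - a)[1]
  (hi - lo + 1) / sample_rate * 1e6
}

#' Noise-compensated click power spectrum
#'
#' Hamming-windowed, zero-padded periodogram of a click window; when a
#' click-free `noise_window` is supplied, its Welch-averaged spectrum is
#' subtracted in the power domain (floored at zero). Both spectra are
#' lightly smoothed across bins.
#'
#' @param window click waveform window.
#' @param sample_rate sampling rate in Hz.
#' @param noise_window optional click-free waveform for noise-floor
#'   estimation.
#' @param n_fft FFT length (>= window length; default next power of two,
#'   minimum 256).
#' @param smooth_bins width of the spectral smoothing moving average.
#' @return data.frame with `freq_hz`, `power` (smoothed, noise-subtracted),
#'   `db` (relative to the spectrum peak), and — when a noise window was
#'   given — `noise_db`, the smoothed noise floor relative to the same
#'   peak (used by [lf_rolloff()] to limit its dynamic range).
#' @export
click_spectrum <- function(window, sample_rate, noise_window = NULL,
                           n_fft = NULL, smooth_bins = 5) {
  n <- length(window)
  if (is.null(n_fft)) n_fft <- max(256L, 2^ceiling(log2(n)))
  stopifnot(n_fft >= n)
  win <- hamming_window(n)
  pad <- function(x) c(x * win, numeric(n_fft - n))
  P <- Mod(fft(pad(window)))[seq_len(n_fft %/% 2 + 1)]^2
  P <- moving_avg(P, smooth_bins)
  Pn <- NULL
  if (!is.null(noise_window) && length(noise_window) >= n) {
    starts <- seq(1L, length(noise_window) - n + 1L, by = max(1L, n %/% 2))
    Pn <- rowMeans(vapply(starts, function(s) {
      Mod(fft(pad(noise_window[s:(s + n - 1L)])))[seq_len(n_fft %/% 2 + 1)]^2
    }, numeric(n_fft %/% 2 + 1)))
    Pn <- moving_avg(Pn, smooth_bins)
    P <- pmax(P - Pn, 0)
  }
  pk <- max(P)
  out <- data.frame(freq_hz = (0:(n_fft %/% 2)) * sample_rate / n_fft,
                    power = P,
                    db = 10 * log10(pmax(P, pk * 1e-12) / pk))
  if (!is.null(Pn))
    out$noise_db <- 10 * log10(pmax(Pn, pk * 1e-12) / pk)
  out
}

#' -20 dB low-frequency roll-off
#'
#' The lowest frequency below the spectral peak still within `db_down` dB
#' of the peak level, found by walking downward in frequency from the peak
#' until the level drops below the criterion and stays below it for
#' `sustain_bins` consecutive bins (equivalently, the frequency at which
#' the spectrum first rises to within `db_down` of its peak when scanning
#' upward across a unimodal spectrum, but robust to isolated noise spikes
#' below the click band). When the spectrum carries a measured noise floor
#' (`noise_db` from [click_spectrum()]), the criterion is limited to the
#' available dynamic range (floor + `floor_margin_db`); for clicks with
#' steep spectral skirts this changes the estimate only slightly, and it
#' prevents the scan from descending into the noise floor at low SNR.
#'
#' @param spec a data.frame from [click_spectrum()].
#' @param db_down level below peak defining the roll-off (default 20 dB).
#' @param sustain_bins consecutive below-criterion bins that terminate the
#'   walk, guarding against isolated noise spikes.
#' @param min_freq_hz ignore bins below this frequency.
#' @param floor_margin_db margin above the measured noise floor kept inside
#'   the usable dynamic range.
#' @return roll-off frequency in Hz (always `<=` the peak frequency), or
#'   `NA` if the spectrum carries no finite level.
#' @export
lf_rolloff <- function(spec, db_down = 20, sustain_bins = 3,
                       min_freq_hz = 0, floor_margin_db = 6) {
  use <- spec$freq_hz >= min_freq_hz
  f <- spec$freq_hz[use]
  db <- spec$db[use]
  if (!any(is.finite(db))) return(NA_real_)
  ipk <- which.max(db)
  eff <- db_down
  if (!is.null(spec$noise_db)) {
    dr <- -stats::median(spec$noise_db[use], na.rm = TRUE) - floor_margin_db
    eff <- max(6, min(db_down, dr))
  }
  lim <- db[ipk] - eff
  lo <- ipk
  gap <- 0L
  j <- ipk
  while (j > 1) {
    j <- j - 1L
    if (db[j] >= lim) {
      lo <- j
      gap <- 0L
    } else {
      gap <- gap + 1L
      if (gap >= sustain_bins) break
    }
  }
  f[lo]
}

#' Test a click for a rising FM contour (upsweep)
#'
#' Computes the fine-resolution spectrogram of the click window, keeps the
#' frames whose total power is within `gate_db` of the loudest frame (the
#' frames actually containing the click), takes the per-frame peak-frequency
#' ridge and fits its least-squares slope against time.
#'
#' @param window click waveform window.
#' @param sample_rate sampling rate in Hz.
#' @param fine_cfg spectrogram configuration; defaults to
#'   [sg_config_fine()].
#' @param min_slope_khz_per_ms minimum positive slope to call an upsweep
#'   (guards against sign-flipping noise on non-FM clicks; set to 0 for a
#'   pure sign test).
#' @param gate_db frame-power gate relative to the loudest frame; only the
#'   contiguous run of frames around the loudest one that stay within this
#'   gate contributes to the ridge, so noise frames elsewhere in the
#'   window are excluded.
#' @return list with `upsweep` (logical, `NA` when fewer than 3 ridge
#'   frames are available), `slope_khz_per_ms`, and `n_cols`.
#' @export
upsweep_test <- function(window, sample_rate, fine_cfg = NULL,
                         min_slope_khz_per_ms = 15, gate_db = 6) {
  if (is.null(fine_cfg)) fine_cfg <- sg_config_fine(sample_rate)
  if (length(window) < fine_cfg$frame_size_samples)
    return(list(upsweep = NA, slope_khz_per_ms = NA_real_, n_cols = 0L))
  sg <- spectrogram(window, fine_cfg)
  colp <- colSums(sg$mag^2)
  strong <- colp > max(colp) / 10^(gate_db / 10)
  ipk <- which.max(colp)
  lo <- hi <- ipk
  while (lo > 1 && strong[lo - 1]) lo <- lo - 1
  while (hi < length(colp) && strong[hi + 1]) hi <- hi + 1
  sel <- lo:hi
  if (length(sel) < 3)
    return(list(upsweep = NA, slope_khz_per_ms = NA_real_,
                n_cols = length(sel)))
  ridge <- sg$freq_hz[apply(sg$mag[, sel, drop = FALSE], 2, which.max)]
  tt <- sg$time_s[sel]
  slope <- unname(coef(lm(ridge ~ tt))[2]) / 1e6   # Hz/s -> kHz/ms
  list(upsweep = slope > min_slope_khz_per_ms,
       slope_khz_per_ms = slope, n_cols = length(sel))
}

# Analytic-signal (Hilbert) envelope via the frequency domain.
analytic_env <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else h[2:((n + 1) / 2)] <- 2
  Mod(fft(X * h, inverse = TRUE)) / n
}

#' Band-limited zero-to-peak SNR
#'
#' Peak click amplitude over noise RMS, in dB, with both windows band-pass
#' filtered to `band` (default 15–90 kHz, the reporting convention for
#' beaked-whale clicks). The peak amplitude is read from the analytic
#' (Hilbert) envelope at the window centre — the click must be centred, as
#' it is when the window is cut at a detected or known click time — and the
#' envelope power is reduced by the expected noise contribution before the
#' ratio is formed. Near-unity SNR cannot be measured from the raw window
#' maximum: the maximum of band-limited noise alone exceeds its RMS by
#' ~10 dB, which would floor the estimate.
#'
#' @param click_window waveform window with the click centred.
#' @param noise_window click-free waveform window.
#' @param sample_rate sampling rate in Hz.
#' @param band band limits in Hz.
#' @param peak_region_s half-width (s) of the envelope-peak search region
#'   around the window centre; 0 reads the centre sample only.
#' @param noise_correct subtract the expected noise contribution from the
#'   envelope power (recommended for clicks embedded in noise; disable for
#'   the textbook peak-over-RMS definition on clean windows).
#' @return SNR in dB.
#' @export
snr0p <- function(click_window, noise_window, sample_rate,
                  band = c(15e3, 90e3), peak_region_s = 0,
                  noise_correct = TRUE) {
  if (all(noise_window == 0)) stop("silent noise window: SNR undefined")
  band[2] <- min(band[2], 0.47 * sample_rate)
  bc <- band_filter(click_window, sample_rate, band)
  bn <- band_filter(noise_window, sample_rate, band)
  env <- analytic_env(bc)
  mid <- as.integer((length(bc) + 1) / 2)
  r <- as.integer(round(peak_region_s * sample_rate))
  idx <- max(1, mid - r):min(length(bc), mid + r)
  pk2 <- max(env[idx])^2
  n2 <- mean(bn^2)
  # envelope of pure noise has mean square 2 * noise power; subtract it
  # unless the window is essentially noise-free at the peak
  corr <- if (noise_correct) min(2 * n2, 0.75 * pk2) else 0
  10 * log10((pk2 - corr) / n2)
}

#' Inter-click-interval series
#'
#' Successive differences of (sorted) click onset times.
#'
#' @param onsets_s numeric vector of click times in seconds.
#' @return list with `ici_s` (length `n - 1`), `mean_s` and `sd_s`
#'   (`NA` for fewer than 2 clicks; `sd_s` is `NA` for fewer than 3).
#' @export
ici_series <- function(onsets_s) {
  onsets_s <- sort(onsets_s)
  if (length(onsets_s) < 2)
    return(list(ici_s = numeric(0), mean_s = NA_real_, sd_s = NA_real_))
  ici <- diff(onsets_s)
  list(ici_s = ici, mean_s = mean(ici),
       sd_s = if (length(ici) > 1) sd(ici) else NA_real_)
}

#' Measure all features of one click
#'
#' @param window click waveform window (click roughly centred).
#' @param noise_window click-free window for noise compensation, or `NULL`.
#' @param sample_rate sampling rate in Hz.
#' @param highpass_hz high-pass cutoff for the duration measure and the
#'   lower limit of the spectral peak search.
#' @param snr_band band for [snr0p()].
#' @param min_slope_khz_per_ms upsweep slope gate (see [upsweep_test()]).
#' @return one-row data.frame: `duration_us`, `peak_freq_hz`,
#'   `lf_rolloff_hz`, `upsweep`, `upsweep_slope_khz_per_ms`, `snr0p_db`.
#' @export
click_features <- function(window, noise_window, sample_rate,
                           highpass_hz = 10000, snr_band = c(15e3, 90e3),
                           min_slope_khz_per_ms = 15) {
  nr <- if (!is.null(noise_window)) {
    if (highpass_hz > 0)
      rms(band_filter(noise_window, sample_rate, c(highpass_hz, Inf)))
    else rms(noise_window)
  } else NULL
  dur <- tryCatch(
    measure_duration(window, sample_rate, highpass_hz, noise_rms = nr),
    error = function(e) NA_real_)
  sp <- click_spectrum(window, sample_rate, noise_window)
  use <- sp$freq_hz >= max(highpass_hz, 2000) &
    sp$freq_hz <= 0.47 * sample_rate
  pk <- sp$freq_hz[use][which.max(sp$power[use])]
  ro <- lf_rolloff(sp, min_freq_hz = max(highpass_hz, 2000))
  fine <- spectrogram_config(sample_rate, 32, 128, 0.94,
                             highpass_hz = max(highpass_hz, 2000))
  up <- upsweep_test(window, sample_rate, fine_cfg = fine,
                     min_slope_khz_per_ms = min_slope_khz_per_ms)
  snr <- if (!is.null(noise_window))
    tryCatch(snr0p(window, noise_window, sample_rate, snr_band),
             error = function(e) NA_real_) else NA_real_
  data.frame(duration_us = dur, peak_freq_hz = pk, lf_rolloff_hz = ro,
             upsweep = up$upsweep,
             upsweep_slope_khz_per_ms = up$slope_khz_per_ms,
             snr0p_db = snr)
}

# Average the (Hamming-windowed, padded) power spectra of several click
# windows and of their noise windows, then noise-subtract. Averaging across
# the train shrinks the noise residual, which is what makes the -20 dB
# roll-off measurable at single-digit per-click SNR.
train_spectrum <- function(windows, noise_windows, sample_rate,
                           smooth_bins = 5) {
  L <- min(vapply(windows, length, integer(1)))
  n_fft <- max(256L, 2^ceiling(log2(L)))
  win <- hamming_window(L)
  pad <- function(x) c(x[seq_len(L)] * win, numeric(n_fft - L))
  pspec <- function(x) Mod(fft(pad(x)))[seq_len(n_fft %/% 2 + 1)]^2
  P <- rowMeans(vapply(windows, pspec, numeric(n_fft %/% 2 + 1)))
  Pn <- rowMeans(vapply(noise_windows, function(nw) {
    if (length(nw) < L) return(rep(NA_real_, n_fft %/% 2 + 1))
    starts <- seq(1L, length(nw) - L + 1L, by = max(1L, L %/% 2))
    rowMeans(vapply(starts, function(s0) pspec(nw[s0:(s0 + L - 1L)]),
                    numeric(n_fft %/% 2 + 1)))
  }, numeric(n_fft %/% 2 + 1)), na.rm = TRUE)
  P <- moving_avg(P, smooth_bins)
  Pn <- moving_avg(Pn, smooth_bins)
  Ps <- pmax(P - Pn, 0)
  pk <- max(Ps)
  out <- data.frame(freq_hz = (0:(n_fft %/% 2)) * sample_rate / n_fft,
                    power = Ps,
                    db = 10 * log10(pmax(Ps, pk * 1e-12) / pk))
  out$noise_db <- 10 * log10(pmax(Pn, pk * 1e-12) / pk)
  out
}

#' Per-train feature summary
#'
#' Extracts a window around every detected click, measures per-click
#' features ([click_features()]), and summarises each train by its median
#' features, upsweep fraction and ICI statistics. The noise window for each
#' click is taken immediately before the click onset.
#'
#' @param events data.frame from [group_into_trains()] (one file).
#' @param samples the file's samples.
#' @param sample_rate sampling rate in Hz.
#' @param highpass_hz feature measurement high-pass (2 kHz default so
#'   low-frequency sperm-whale clicks remain measurable).
#' @param pre_s,post_s click window extent around the onset.
#' @param noise_dur_s,noise_gap_s length of, and gap before, the pre-click
#'   noise window.
#' @param min_slope_khz_per_ms upsweep slope gate.
#' @return data.frame, one row per train: `train_id`, `file_id`, `n_clicks`,
#'   `t_start_s`, `t_end_s`, `ici_mean_s`, `ici_sd_s`, `duration_us_med`,
#'   `peak_freq_hz_med`, `lf_rolloff_hz_med` (measured on the train-averaged
#'   noise-subtracted spectrum), `upsweep_frac`, `upsweep`, `snr_db_med`.
#' @export
train_features <- function(events, samples, sample_rate,
                           highpass_hz = 2000, pre_s = 0.0015,
                           post_s = 0.0015, noise_dur_s = 0.005,
                           noise_gap_s = 0.0015,
                           min_slope_khz_per_ms = 15) {
  if (nrow(events) == 0) return(empty_train_features())
  out <- lapply(split(events, events$train_id), function(tr) {
    wins <- list()
    noises <- list()
    feats <- lapply(seq_along(tr$onset_s), function(i) {
      on <- tr$onset_s[i]
      w <- extract_click_window(samples, sample_rate, on, pre_s, post_s)
      n0 <- max(1L, as.integer(round((on - pre_s - noise_gap_s - noise_dur_s) *
                                       sample_rate)))
      n1 <- max(1L, as.integer(round((on - pre_s - noise_gap_s) * sample_rate)))
      nw <- if (n1 - n0 > 64) samples[n0:n1] else
        samples[seq_len(min(length(samples), as.integer(noise_dur_s * sample_rate)))]
      wins[[i]] <<- w
      noises[[i]] <<- nw
      click_features(w, nw, sample_rate, highpass_hz,
                     min_slope_khz_per_ms = min_slope_khz_per_ms)
    })
    f <- do.call(rbind, feats)
    ici <- ici_series(tr$onset_s)
    up_frac <- mean(f$upsweep, na.rm = TRUE)
      tsp <- train_spectrum(wins, noises, sample_rate)
    tsp$noise_db <- NULL   # averaged spectrum: scan the full 20 dB range
    ro_train <- lf_rolloff(tsp, min_freq_hz = max(highpass_hz, 2000))
    data.frame(
      train_id = tr$train_id[1], file_id = tr$file_id[1],
      n_clicks = nrow(tr),
      t_start_s = min(tr$onset_s), t_end_s = max(tr$onset_s),
      ici_mean_s = ici$mean_s, ici_sd_s = ici$sd_s,
      duration_us_med = median(f$duration_us, na.rm = TRUE),
      peak_freq_hz_med = median(f$peak_freq_hz, na.rm = TRUE),
      lf_rolloff_hz_med = ro_train,
      upsweep_frac = if (is.nan(up_frac)) NA_real_ else up_frac,
      upsweep = !is.nan(up_frac) && !is.na(up_frac) && up_frac > 0.5,
      snr_db_med = median(f$snr0p_db, na.rm = TRUE))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_train_features <- function() {
  data.frame(train_id = integer(0), file_id = character(0),
             n_clicks = integer(0), t_start_s = numeric(0),
             t_end_s = numeric(0), ici_mean_s = numeric(0),
             ici_sd_s = numeric(0), duration_us_med = numeric(0),
             peak_freq_hz_med = numeric(0), lf_rolloff_hz_med = numeric(0),
             upsweep_frac = numeric(0), upsweep = logical(0),
             snr_db_med = numeric(0))
}
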