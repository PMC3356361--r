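# Click, noise and click-train synthesis.
#
# Clicks are modelled as FM chirps (linear sweep) under a smooth asymmetric
# envelope. The model is deliberately minimal: it is parameterised directly
# in the aggregate features the analysis chain measures (duration, sweep
# band, spectral peak, upsweep), not in any physiological source model.

# Beta-shaped window on u in (0,1): u^p (1-u)^q, maximum at p/(p+q).
# Used both as the amplitude-spectrum shape of sweep clicks (maximum placed
# at the requested peak frequency) and as the time envelope of
# constant-frequency pings.
click_env_shape <- function(spec) {
  xpk <- if (spec$f_end_hz > spec$f_start_hz) {
    (spec$peak_freq_hz - spec$f_start_hz) / (spec$f_end_hz - spec$f_start_hz)
  } else 0.5
  s <- spec$env_sharpness
  list(p = max(1.05, s * xpk), q = max(1.05, s * (1 - xpk)))
}

click_env <- function(u, p, q) {
  upk <- p / (p + q)
  emax <- exp(p * log(upk) + q * log(1 - upk))
  out <- numeric(length(u))
  ok <- u > 0 & u < 1
  out[ok] <- exp(p * log(u[ok]) + q * log(1 - u[ok])) / emax
  out
}

# Fraction of the envelope support spanned by the central 95%-energy
# interval; used to scale the support so the *measured* duration equals the
# requested one.
click_env_efrac <- function(p, q, fraction = 0.95) {
  u <- seq(0, 1, length.out = 4096)
  e <- click_env(u, p, q)^2
  cume <- cumsum(e) / sum(e)
  lo <- u[which(cume >= (1 - fraction) / 2)[1]]
  hi <- u[which(cume >= 1 - (1 - fraction) / 2)[1]]
  hi - lo
}

# Frequency-domain synthesis of an FM sweep click: the one-sided amplitude
# spectrum is beta-shaped over [f_start, f_end] with its maximum at the
# requested peak frequency, and a linear group delay across the band makes
# the low frequencies arrive first (upsweep). The sweep time is iterated so
# the measured 95%-energy duration matches the requested duration. Direct
# spectral shaping is used because a time-windowed chirp of this small
# time-bandwidth product smears its spectrum by ~sqrt(bandwidth/duration)
# (several kHz), displacing the spectral peak and roll-off from the design
# values.
synth_sweep_click <- function(spec, sample_rate) {
  sh <- click_env_shape(spec)
  B <- spec$f_end_hz - spec$f_start_hz
  sweep_s <- spec$duration_us * 1e-6
  for (iter in 1:4) {
    n <- max(1024L, 2^ceiling(log2(4 * sweep_s * sample_rate)))
    f <- (0:(n / 2)) * sample_rate / n
    u <- (f - spec$f_start_hz) / B
    A <- click_env(u, sh$p, sh$q)
    uc <- pmin(pmax(u, 0), 1)
    # Rising group delay gives the beaked-whale upsweep; a symmetric
    # vee-shaped delay (spectral peak first, band edges trailing) gives a
    # broadband transient with no net FM contour (delphinid-like).
    tau <- 0.1 * sweep_s +
      if (spec$upsweep) uc * sweep_s else abs(2 * uc - 1) * sweep_s
    df <- sample_rate / n
    phi <- -2 * pi * cumsum(tau) * df
    X <- complex(modulus = A, argument = phi)
    Xfull <- c(X, Conj(rev(X[2:(n / 2)])))
    x <- Re(fft(Xfull, inverse = TRUE))
    e <- cumsum(x^2) / sum(x^2)
    lo <- which(e >= 0.025)[1]
    hi <- which(e >= 0.975)[1]
    meas_s <- (hi - lo + 1) / sample_rate
    if (abs(meas_s - spec$duration_us * 1e-6) < 2 / sample_rate) break
    sweep_s <- sweep_s * spec$duration_us * 1e-6 / meas_s
    sweep_s <- min(sweep_s, n / sample_rate / 3)   # keep inside the buffer
  }
  i0 <- which(e >= 1e-4)[1]
  i1 <- which(e >= 1 - 1e-4)[1]
  x <- x[i0:i1]
  x / max(abs(x))
}

#' Synthesise one echolocation click waveform
#'
#' Sweep clicks (`f_start_hz < f_end_hz`) are built in the frequency
#' domain: a smooth beta-shaped amplitude spectrum over the sweep band with
#' its maximum at `spec$peak_freq_hz`, and a linear group delay across the
#' band producing the rising FM contour. Constant-frequency pings
#' (`f_start_hz == f_end_hz`) are tone bursts under a beta-shaped time
#' envelope. In both cases the time scale is calibrated so the interval
#' containing 95% of the waveform energy matches `spec$duration_us` (the
#' duration convention of [measure_duration()]). If
#' `spec$double_click_delay_us` is set, an attenuated replica is appended at
#' that lag.
#'
#' @param spec a [click_spec()].
#' @param sample_rate sampling rate in Hz; must be at least `2 * f_end_hz`.
#' @param amp peak amplitude scale (0 gives an all-zero waveform).
#' @return numeric waveform with attributes `sample_rate`, `t_peak_s` (time
#'   of the energy-envelope maximum from waveform start) and `spec`.
#' @examples
#' w <- make_click_waveform(click_presets()$blainville, 194000)
#' length(w) / 194000 * 1e6  # support somewhat longer than the 250 us core
#' @export
make_click_waveform <- function(spec, sample_rate, amp = 1) {
  stopifnot(inherits(spec, "click_spec"))
  if (sample_rate < 2 * spec$f_end_hz)
    stop(sprintf(
      "sample rate %g Hz is below the Nyquist requirement %g Hz for a sweep ending at %g Hz",
      sample_rate, 2 * spec$f_end_hz, spec$f_end_hz))
  if (spec$f_end_hz > spec$f_start_hz) {
    x <- amp * synth_sweep_click(spec, sample_rate)
  } else {
    sh <- click_env_shape(spec)
    efrac <- click_env_efrac(sh$p, sh$q)
    support_s <- spec$duration_us * 1e-6 / efrac
    n <- max(8L, as.integer(round(support_s * sample_rate)))
    t <- (seq_len(n) - 0.5) / sample_rate
    env <- click_env(t / support_s, sh$p, sh$q)
    x <- amp * env * sin(2 * pi * spec$peak_freq_hz * t)
  }
  esm <- moving_avg(x^2, max(3L, as.integer(20e-6 * sample_rate)))
  t_peak <- (which.max(esm) - 1) / sample_rate
  if (is.finite(spec$double_click_delay_us)) {
    n <- length(x)
    lag <- as.integer(round(spec$double_click_delay_us * 1e-6 * sample_rate))
    out <- numeric(n + lag)
    out[seq_len(n)] <- x
    out[lag + seq_len(n)] <- out[lag + seq_len(n)] +
      x * 10^(-spec$double_click_atten_db / 20)
    x <- out
  }
  structure(x, sample_rate = sample_rate, t_peak_s = t_peak, spec = spec)
}

#' Synthesise background noise
#'
#' Gaussian noise, either white or with a constant spectral slope in
#' dB/octave (negative values give "pinkish" noise with more low-frequency
#' energy, a crude match to deep-water ambient spectra).
#'
#' @param n number of samples.
#' @param sample_rate sampling rate in Hz.
#' @param sigma target RMS amplitude.
#' @param slope_db_per_octave spectral slope; 0 = white.
#' @return numeric vector of length `n`.
#' @export
make_noise <- function(n, sample_rate, sigma = 1, slope_db_per_octave = 0) {
  if (slope_db_per_octave == 0) return(rnorm(n, 0, sigma))
  x <- rnorm(n)
  X <- fft(x)
  f <- seq(0, sample_rate, length.out = n + 1)[seq_len(n)]
  f <- pmin(f, sample_rate - f)            # two-sided bin frequencies
  gain <- 10^(slope_db_per_octave * log2(pmax(f, 20) / 1000) / 20)
  y <- Re(fft(X * gain, inverse = TRUE)) / n
  y * sigma / sd(y)
}

# Zero-phase Butterworth band-pass (order 4). Degrades gracefully to a
# high-pass when the upper edge is at or above ~Nyquist.
band_filter <- function(x, sample_rate, band) {
  nyq <- sample_rate / 2
  lo <- max(band[1], 0) / nyq
  hi <- min(band[2], 0.985 * nyq) / nyq
  bf <- if (lo <= 0) {
    signal::butter(4, hi, type = "low")
  } else if (hi >= 0.985) {
    signal::butter(4, lo, type = "high")
  } else {
    signal::butter(2, c(lo, hi), type = "pass")
  }
  as.numeric(signal::filtfilt(bf, x))
}

rms <- function(x) sqrt(mean(x^2))

# SNR calibration band: the 15-90 kHz reporting convention where the click
# band allows it; clicks lying (partly) below 15 kHz (sperm-whale-like) use
# a band adapted to their own energy, since calibrating against a band that
# excludes the click would be meaningless.
snr_cal_band <- function(spec, sample_rate) {
  hi <- min(90e3, 0.47 * sample_rate)
  if (spec$f_start_hz >= 15e3) c(15e3, hi)
  else c(max(2e3, 0.6 * spec$f_start_hz), min(hi, 1.5 * spec$f_end_hz))
}

#' Synthesise a click train embedded in noise
#'
#' Places `n_clicks` copies of the click described by `spec` in a noise
#' recording of `duration_s` seconds. Inter-click intervals are drawn from
#' the spec's ICI distribution (truncated-positive normal, or lognormal for
#' irregular delphinid-like trains). Click amplitudes are calibrated so the
#' band-limited (15–90 kHz) zero-to-peak SNR of the emitted clicks over the
#' generated noise RMS equals `snr_db`.
#'
#' @param spec a [click_spec()].
#' @param n_clicks number of clicks (>= 1).
#' @param duration_s length of the recording in seconds.
#' @param sample_rate sampling rate in Hz.
#' @param noise_sigma noise RMS amplitude; 0 gives a noise-free train with
#'   unit-peak clicks.
#' @param noise_slope_db_per_octave noise spectral slope (see [make_noise()]).
#' @param snr_db target band-limited zero-to-peak SNR; defaults to
#'   `spec$snr_db`.
#' @param seed optional integer seed; the same seed reproduces the waveform
#'   bit for bit.
#' @param start_s onset of the first click; by default placed uniformly at
#'   random in the feasible range (with a 0.25 s leading noise margin).
#' @return list with `wave` (numeric samples), `sample_rate`,
#'   `truth` (data.frame: `click`, `onset_s` = insertion start, `time_s` =
#'   envelope-peak time), `amp` (applied amplitude scale), `noise_sigma`,
#'   and `spec`.
#' @examples
#' tr <- make_click_train(click_presets()$unknown_bw, 11, 3, 194000,
#'                        snr_db = 15, seed = 1)
#' diff(tr$truth$time_s)  # ICIs near 0.12 s
#' @export
make_click_train <- function(spec, n_clicks, duration_s, sample_rate,
                             noise_sigma = 0.05,
                             noise_slope_db_per_octave = 0,
                             snr_db = NULL, seed = NULL, start_s = NULL) {
  stopifnot(inherits(spec, "click_spec"), n_clicks >= 1, duration_s > 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(snr_db)) snr_db <- spec$snr_db
  n <- as.integer(round(duration_s * sample_rate))
  w <- make_click_waveform(spec, sample_rate, amp = 1)
  t_peak <- attr(w, "t_peak_s")
  click_len_s <- length(w) / sample_rate

  if (noise_sigma > 0) {
    wave <- make_noise(n, sample_rate, noise_sigma, noise_slope_db_per_octave)
    band <- snr_cal_band(spec, sample_rate)
    sigma_b <- rms(band_filter(wave, sample_rate, band))
    pad <- numeric(512)
    peak_b <- max(abs(band_filter(c(pad, as.numeric(w), pad), sample_rate, band)))
    amp <- 10^(snr_db / 20) * sigma_b / peak_b
  } else {
    wave <- numeric(n)
    amp <- 1
  }

  icis <- if (n_clicks > 1) draw_icis(spec, n_clicks - 1) else numeric(0)
  span <- sum(icis) + click_len_s
  margin_pre <- min(0.25, duration_s * 0.1)
  margin_post <- min(0.05, duration_s * 0.02)
  avail <- duration_s - margin_pre - margin_post - span
  if (avail < 0)
    stop(sprintf("click train (span %.3f s) does not fit in %.3f s", span,
                 duration_s))
  t0 <- if (is.null(start_s)) margin_pre + runif(1) * avail else start_s
  if (t0 + span > duration_s)
    stop("click train does not fit at the requested start time")
  onsets <- t0 + cumsum(c(0, icis))
  wv <- amp * as.numeric(w)
  for (on in onsets) {
    i0 <- as.integer(round(on * sample_rate)) + 1L
    idx <- i0:(i0 + length(wv) - 1L)
    wave[idx] <- wave[idx] + wv
  }
  list(wave = wave, sample_rate = sample_rate,
       truth = data.frame(click = seq_len(n_clicks), onset_s = onsets,
                          time_s = onsets + t_peak),
       amp = amp, noise_sigma = noise_sigma, spec = spec)
}

# ICI draws: truncated-positive normal, or lognormal with the spec mean as
# median and the spec sd as log-scale sd.
draw_icis <- function(spec, n) {
  lower <- spec$duration_us * 1e-6
  if (spec$ici_dist == "lognormal") {
    ici <- rlnorm(n, meanlog = log(spec$ici_s_mean), sdlog = spec$ici_s_sd)
    pmax(ici, lower * 1.5)
  } else {
    ici <- rnorm(n, spec$ici_s_mean, spec$ici_s_sd)
    bad <- ici <= lower
    while (any(bad)) {
      ici[bad] <- rnorm(sum(bad), spec$ici_s_mean, spec$ici_s_sd)
      bad <- ici <= lower
    }
    ici
  }
}
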