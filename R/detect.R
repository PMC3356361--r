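# Band-energy-ratio click detection (ERMA-style): compare mean spectral
# power in a signal band against a guard band, frame by frame, and emit a
# click event per contiguous run of frames whose ratio exceeds a threshold.

#' Detector configuration
#'
#' Defaults target beaked-whale clicks: signal band 24–48 kHz (where the
#' upsweep carries most energy), guard band 5–20 kHz (below the beaked-whale
#' roll-off, where delphinid and vessel noise concentrate), 10 dB threshold.
#'
#' @param signal_band_hz numeric length-2, signal band (Hz).
#' @param guard_band_hz numeric length-2, guard band (Hz); must not overlap
#'   the signal band.
#' @param ratio_threshold_db detection threshold on
#'   `10*log10(signal/guard)` mean-power ratio.
#' @param min_run_frames minimum number of consecutive above-threshold
#'   frames forming an event (1: any exceedance; useful >1 only when guard
#'   smoothing is disabled).
#' @param guard_smooth_s when > 0, [detect_clicks()] stabilises the guard
#'   (noise-floor) estimate with a running mean of this length over frames
#'   before forming the ratio. A single frame's guard power has only a
#'   handful of spectral degrees of freedom, so the unsmoothed per-frame
#'   ratio fluctuates by several dB on noise alone; smoothing the
#'   slowly-varying noise floor removes that fluctuation without touching
#'   the click-scale signal band. Set to 0 for the strict per-frame ratio.
#' @param min_gap_s events closer than this are merged (also absorbs the
#'   "double click" replica into its parent event).
#' @param min_clicks_per_train trains with fewer clicks are discarded by
#'   [group_into_trains()].
#' @param max_ici_s maximum inter-click gap within one train.
#' @return list of class `detector_config`.
#' @export
detector_config <- function(signal_band_hz = c(24e3, 48e3),
                            guard_band_hz = c(5e3, 20e3),
                            ratio_threshold_db = 10,
                            min_run_frames = 1,
                            guard_smooth_s = 0.25,
                            min_gap_s = 0.015,
                            min_clicks_per_train = 3,
                            max_ici_s = 2) {
  stopifnot(length(signal_band_hz) == 2, length(guard_band_hz) == 2,
            is.finite(ratio_threshold_db), min_clicks_per_train >= 1,
            min_run_frames >= 1)
  if (max(min(signal_band_hz), min(guard_band_hz)) <
      min(max(signal_band_hz), max(guard_band_hz)))
    stop("signal and guard bands must be disjoint")
  structure(
    list(signal_band_hz = sort(signal_band_hz),
         guard_band_hz = sort(guard_band_hz),
         ratio_threshold_db = ratio_threshold_db,
         min_run_frames = as.integer(min_run_frames),
         guard_smooth_s = guard_smooth_s, min_gap_s = min_gap_s,
         min_clicks_per_train = as.integer(min_clicks_per_train),
         max_ici_s = max_ici_s),
    class = "detector_config")
}

#' Band energy ratio of one spectrum column
#'
#' `10*log10(mean power in signal band / mean power in guard band)` of a
#' magnitude-spectrum column. A zero guard band returns `+Inf`.
#'
#' @param spectrum_column numeric vector of spectral magnitudes.
#' @param freq_hz bin centre frequencies matching `spectrum_column`.
#' @param cfg a [detector_config()].
#' @return ratio in dB.
#' @export
band_energy_ratio <- function(spectrum_column, freq_hz, cfg) {
  stopifnot(length(spectrum_column) == length(freq_hz))
  nyq <- max(freq_hz)
  if (max(cfg$signal_band_hz) > nyq || max(cfg$guard_band_hz) > nyq)
    stop("detector bands exceed the Nyquist frequency")
  p <- spectrum_column^2
  sig <- mean(p[freq_hz >= cfg$signal_band_hz[1] &
                freq_hz <= cfg$signal_band_hz[2]])
  gua <- mean(p[freq_hz >= cfg$guard_band_hz[1] &
                freq_hz <= cfg$guard_band_hz[2]])
  if (gua == 0) return(Inf)
  10 * log10(sig / gua)
}

# Centred running mean with shrinking windows at the edges (cumsum-based,
# O(n); a convolution filter is far too slow for ~1500-frame windows).
running_mean <- function(x, k) {
  n <- length(x)
  h <- k %/% 2L
  cs <- c(0, cumsum(x))
  hi <- pmin(n, seq_len(n) + h)
  lo <- pmax(0L, seq_len(n) - h - 1L)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

# Frame-by-frame band-energy ratio of a whole recording, computed in chunks
# so long files never materialise a full spectrogram. Returns one ratio (dB)
# per frame for each detector config in `det_cfgs` (they share the framing).
ratio_series <- function(samples, spec_cfg, det_cfgs, chunk_frames = 20000L) {
  if (cfgs_single <- inherits(det_cfgs, "detector_config"))
    det_cfgs <- list(det_cfgs)
  if (spec_cfg$highpass_hz > 0)
    samples <- band_filter(samples, spec_cfg$sample_rate_hz,
                           c(spec_cfg$highpass_hz, Inf))
  frame <- spec_cfg$frame_size_samples
  nfft <- spec_cfg$fft_size_samples
  hop <- spec_cfg$hop_samples
  n_frames <- spectrogram_n_frames(length(samples), spec_cfg)
  if (n_frames < 1) stop("input shorter than one analysis frame")
  freq <- (0:(nfft %/% 2)) * spec_cfg$sample_rate_hz / nfft
  masks <- lapply(det_cfgs, function(dc) {
    nyq <- spec_cfg$sample_rate_hz / 2
    if (max(dc$signal_band_hz) > nyq || max(dc$guard_band_hz) > nyq)
      stop("detector bands exceed the Nyquist frequency")
    list(sig = freq >= dc$signal_band_hz[1] & freq <= dc$signal_band_hz[2],
         gua = freq >= dc$guard_band_hz[1] & freq <= dc$guard_band_hz[2])
  })
  win <- hamming_window(frame)
  sig_p <- gua_p <- matrix(NA_real_, n_frames, length(det_cfgs))
  done <- 0L
  while (done < n_frames) {
    take <- min(chunk_frames, n_frames - done)
    starts <- (done + seq_len(take) - 1L) * hop + 1L
    M <- matrix(samples[outer(0:(frame - 1L), starts, `+`)], nrow = frame) * win
    if (nfft > frame) M <- rbind(M, matrix(0, nfft - frame, ncol(M)))
    S <- mvfft(M)[seq_len(nfft %/% 2 + 1L), , drop = FALSE]
    P <- Re(S)^2 + Im(S)^2
    for (k in seq_along(masks)) {
      sig_p[done + seq_len(take), k] <- colMeans(P[masks[[k]]$sig, , drop = FALSE])
      gua_p[done + seq_len(take), k] <- colMeans(P[masks[[k]]$gua, , drop = FALSE])
    }
    done <- done + take
  }
  hop_s <- hop / spec_cfg$sample_rate_hz
  out <- matrix(NA_real_, n_frames, length(det_cfgs))
  for (k in seq_along(det_cfgs)) {
    gua <- gua_p[, k]
    gs <- det_cfgs[[k]]$guard_smooth_s
    if (!is.null(gs) && gs > 0) {
      kk <- min(n_frames, max(3L, as.integer(round(gs / hop_s)) %/% 2L * 2L + 1L))
      gua <- running_mean(gua, kk)
    }
    out[, k] <- ifelse(gua == 0, Inf, 10 * log10(sig_p[, k] / gua))
  }
  list(ratio_db = if (cfgs_single) out[, 1] else out,
       time_s = (seq_len(n_frames) - 1L) * hop_s,
       hop_s = hop_s)
}

# Collapse a logical above-threshold series into events: one event per
# contiguous run of at least min_run frames, onset at the run's peak-ratio
# frame.
runs_to_events <- function(ratio_db, time_s, threshold_db, min_run = 1L) {
  above <- is.finite(ratio_db) & ratio_db > threshold_db |
    is.infinite(ratio_db) & ratio_db > 0
  if (!any(above)) {
    return(data.frame(onset_s = numeric(0), ratio_db = numeric(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_run)
  if (length(keep) == 0)
    return(data.frame(onset_s = numeric(0), ratio_db = numeric(0)))
  onset <- ratio <- numeric(length(keep))
  for (i in seq_along(keep)) {
    idx <- starts[keep[i]]:ends[keep[i]]
    j <- idx[which.max(ratio_db[idx])]
    onset[i] <- time_s[j]
    ratio[i] <- ratio_db[j]
  }
  data.frame(onset_s = onset, ratio_db = ratio)
}

# Merge events closer than min_gap_s, keeping the higher-ratio onset.
merge_close_events <- function(ev, min_gap_s) {
  if (nrow(ev) < 2) return(ev)
  ev <- ev[order(ev$onset_s), , drop = FALSE]
  keep_onset <- ev$onset_s[1]
  keep_ratio <- ev$ratio_db[1]
  out_onset <- numeric(0)
  out_ratio <- numeric(0)
  for (i in 2:nrow(ev)) {
    if (ev$onset_s[i] - keep_onset < min_gap_s) {
      if (ev$ratio_db[i] > keep_ratio) {
        keep_ratio <- ev$ratio_db[i]
        keep_onset <- ev$onset_s[i]
      }
    } else {
      out_onset <- c(out_onset, keep_onset)
      out_ratio <- c(out_ratio, keep_ratio)
      keep_onset <- ev$onset_s[i]
      keep_ratio <- ev$ratio_db[i]
    }
  }
  data.frame(onset_s = c(out_onset, keep_onset),
             ratio_db = c(out_ratio, keep_ratio))
}

#' Detect click transients in a recording
#'
#' Frames the recording with `spec_cfg`, computes the band-energy ratio of
#' every frame, and emits one event per contiguous run of above-threshold
#' frames (onset at the run's peak-ratio frame). Events closer than
#' `det_cfg$min_gap_s` are merged.
#'
#' @param x numeric sample vector, or path to a WAV file.
#' @param sample_rate sampling rate in Hz (ignored when `x` is a file path).
#' @param spec_cfg a [spectrogram_config()]; defaults to
#'   [sg_config_detector()].
#' @param det_cfg a [detector_config()], or a list of them sharing the same
#'   framing (their events are pooled and merged).
#' @param file_id optional identifier copied into the result.
#' @return data.frame with columns `file_id`, `onset_s`, `ratio_db` and
#'   `detector` (the name of the configuration that fired; configurations
#'   are kept separate so that e.g. low-frequency sperm-whale events and
#'   high-frequency delphinid events in the same file form separate
#'   trains), sorted by detector then onset.
#' @export
detect_clicks <- function(x, sample_rate = NULL, spec_cfg = NULL,
                          det_cfg = detector_config(), file_id = NA_character_) {
  if (is.character(x)) {
    wav <- read_wav(x)
    if (is.na(file_id)) file_id <- basename(x)
    sample_rate <- wav$sample_rate
    x <- wav$samples
  }
  stopifnot(is.numeric(x), !is.null(sample_rate))
  if (is.null(spec_cfg)) spec_cfg <- sg_config_detector(sample_rate)
  single <- inherits(det_cfg, "detector_config")
  cfgs <- if (single) list(det_cfg) else det_cfg
  rs <- ratio_series(x, spec_cfg, cfgs)
  rmat <- if (single) matrix(rs$ratio_db, ncol = 1) else rs$ratio_db
  nms <- if (!is.null(names(cfgs))) names(cfgs)
    else paste0("det", seq_along(cfgs))
  ev <- do.call(rbind, lapply(seq_along(cfgs), function(k) {
    e <- runs_to_events(rmat[, k], rs$time_s, cfgs[[k]]$ratio_threshold_db,
                        cfgs[[k]]$min_run_frames)
    e <- merge_close_events(e, cfgs[[k]]$min_gap_s)
    if (nrow(e)) e$detector <- nms[k]
    else e$detector <- character(0)
    e
  }))
  data.frame(file_id = rep(file_id, nrow(ev)), onset_s = ev$onset_s,
             ratio_db = ev$ratio_db, detector = ev$detector)
}

#' Group click events into trains
#'
#' Consecutive events (of one file and one detector configuration)
#' separated by at most `det_cfg$max_ici_s` form one train; trains with
#' fewer than `det_cfg$min_clicks_per_train` events are discarded.
#'
#' @param events data.frame from [detect_clicks()] (must be time-sorted per
#'   file; it is re-sorted defensively).
#' @param det_cfg a [detector_config()].
#' @return `events` with an added integer `train_id` column, filtered to
#'   surviving trains; train ids are consecutive from 1.
#' @export
group_into_trains <- function(events, det_cfg = detector_config()) {
  if (nrow(events) == 0) {
    events$train_id <- integer(0)
    return(events)
  }
  fid <- as.character(events$file_id)
  fid[is.na(fid)] <- ""
  if (!is.null(events$detector)) fid <- paste(fid, events$detector)
  o <- order(fid, events$onset_s)
  events <- events[o, , drop = FALSE]
  fid <- fid[o]
  new_file <- c(TRUE, fid[-1] != fid[-length(fid)])
  gap <- c(Inf, diff(events$onset_s))
  events$train_id <- cumsum(new_file | gap > det_cfg$max_ici_s)
  sizes <- table(events$train_id)
  keep <- names(sizes)[sizes >= det_cfg$min_clicks_per_train]
  events <- events[events$train_id %in% as.integer(keep), , drop = FALSE]
  events$train_id <- match(events$train_id, unique(events$train_id))
  rownames(events) <- NULL
  events
}

#' Extract a waveform window around a click onset
#'
#' @param samples recording samples.
#' @param sample_rate sampling rate in Hz.
#' @param onset_s event time from [detect_clicks()].
#' @param pre_s,post_s window extent before/after the onset, in seconds.
#' @return numeric window (clipped at the recording edges).
#' @export
extract_click_window <- function(samples, sample_rate, onset_s,
                                 pre_s = 0.0015, post_s = 0.0015) {
  i0 <- max(1L, as.integer(round((onset_s - pre_s) * sample_rate)) + 1L)
  i1 <- min(length(samples), as.integer(round((onset_s + post_s) * sample_rate)))
  samples[i0:i1]
}
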