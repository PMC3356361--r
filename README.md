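# gliderpam

Passive acoustic monitoring of odontocete echolocation clicks from glider
recordings.

Deep-diving toothed whales — above all beaked whales (Ziphiidae) — are
nearly impossible to survey visually, but they echolocate almost
continuously at foraging depth. Buoyancy-driven gliders carrying a
broadband hydrophone can listen for them for weeks at a time, screening
each dive's recordings for click trains and reporting detections to shore.
`gliderpam` implements the full analysis chain behind such a survey, for
bioacousticians who need a tested, scriptable reference pipeline:

* **synthesis** — parametric click waveforms (FM sweep clicks and tone
  bursts), click trains with calibrated band-limited SNR, background noise,
  whole simulated missions with ground truth, simulated glider tracks and
  satellite-tag tracks (`click_presets()`, `make_click_train()`,
  `make_mission()`, `make_tag_track()`);
* **detection** — an ERMA-style band-energy-ratio detector on spectrogram
  frames, `R = 10\log_{10}(\bar P_{\text{signal band}} / \bar
  P_{\text{guard band}})`, thresholded per frame with an adaptive
  noise-floor guard estimate (`detect_clicks()`, `group_into_trains()`);
* **features** — per-click duration (95%-energy convention), −20 dB
  low-frequency roll-off, spectral peak, FM-upsweep test, band-limited
  zero-to-peak SNR (SNR₀₋ₚ, 15–90 kHz), and inter-click-interval series
  (`click_features()`, `train_features()`);
* **classification** — an explicit, configurable rule set separating
  Blainville's and Cuvier's beaked whales, unidentified beaked whales,
  delphinids, sperm whales and echosounders (`rule_set()`,
  `classify_train()`, `flag_files()`);
* **mission statistics** — per-class file percentages, diel profiles,
  day/night one-way ANOVA (from the sum-of-squares definitions), encounter
  counting and rates, detector-performance accounting
  (`percent_with_class()`, `diel_profile()`, `day_night_anova()`, ...);
* **tag matching** — the 6 km distance / 1.5 km ARGOS-accuracy encounter
  rule against an interpolated glider track, hypothetical whale dive-profile
  reconstruction, and whale-vocal × glider-recording interval overlap
  (`find_potential_encounters()`, `hypothetical_dive_profile()`,
  `recording_overlap()`).

The package reads and writes mono PCM-16 WAV, CSV (tracks, fixes,
detections, flags) and YAML (scenarios, rule sets). A thin command-line
wrapper is installed at `inst/scripts/glider-pam.R`.

## Worked example

```r
library(gliderpam)
fs <- 194000

# one synthetic Blainville's click train: detect with the onboard
# beaked-whale configuration, measure features, classify
tr <- make_click_train(click_presets()$blainville, n_clicks = 8,
                       duration_s = 3.5, sample_rate = fs,
                       snr_db = 15, seed = 7)
events <- detect_clicks(tr$wave, fs)
trains <- group_into_trains(events)
feats  <- classify_trains(train_features(trains, tr$wave, fs))
feats[, c("n_clicks", "ici_mean_s", "duration_us_med",
          "lf_rolloff_hz_med", "upsweep", "label")]
#>   n_clicks ici_mean_s duration_us_med lf_rolloff_hz_med upsweep      label
#> 1        8  0.3125538        234.5361          22544.92    TRUE blainville
```

All 8 clicks are recovered; the measured features — 0.31 s inter-click
interval, 235 µs duration, 22.5 kHz roll-off, rising FM contour — fall in
the Blainville's windows (250 µs, 25 kHz, 0.2–0.4 s, upsweep), so the train
is labelled `blainville`.

```r
# a small simulated mission, screened end to end
scen <- mission_scenario(n_dives = 10, files_per_dive = 10,
                         file_duration_s = 4)
m <- simulate_and_screen(scen, seed = 1)
percent_with_class(m$truth, "delphinid")   # 48.0  (generated truth)
percent_with_class(m$flags, "delphinid")   # 46.0  (pipeline estimate)
detector_performance(m$truth, m$flags, "delphinid")$file_recall_pct  # 95.8

# recording hours per acoustic encounter
encounter_rate(194, 7)
#> [1] 27.71429
```

Of 100 simulated 4-second files, 48% contained a delphinid click train;
the detector–classifier chain flags 46%, recovering 46 of the 48
truth-positive files (96% file recall). 194 h of recording over 7
encounters works out to one encounter every 27.7 h.

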