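# Rule-based species classification of click trains.
#
# The discrimination logic follows the analyst criteria: beaked-whale clicks
# carry an upsweep and a high (>= ~20 kHz) low-frequency roll-off; the two
# known species are separated by duration, roll-off and ICI windows around
# their published values; beaked-whale-like trains matching neither window
# are "unidentified beaked whale". Non-upsweep trains split into delphinid
# (short, broadband), sperm whale (long, low-frequency, slow) and
# echosounder (metronomic constant-frequency pings).

#' Species classification rule set
#'
#' Acceptance windows per species plus the beaked-whale gate. Published
#' point values carry a fractional tolerance on duration and roll-off
#' (default ±30%); ICI windows are the published range for Blainville's
#' (0.2–0.4 s) and a symmetric window around the published 0.4 s point value
#' for Cuvier's.
#'
#' @param tolerance_frac fractional tolerance applied to duration and
#'   roll-off point values.
#' @param blainville,cuvier per-species lists with `duration_us`,
#'   `lf_rolloff_hz` (point values) and `ici_s` (length-2 window).
#' @param beaked_min_rolloff_hz roll-off gate for any beaked-whale label.
#' @param delphinid_max_duration_us maximum click duration for delphinid.
#' @param sperm_min_duration_us,sperm_max_peak_hz,sperm_min_ici_s
#'   sperm-whale rule bounds.
#' @param echosounder_max_ici_cv maximum ICI coefficient of variation for a
#'   metronomic ping sequence.
#' @param echosounder_min_peak_hz minimum peak frequency for an echosounder
#'   ping (sounders operate tens of kHz; keeps slow regular sperm-whale
#'   trains out of this rule).
#' @param precedence label order in which rules are tried.
#' @return list of class `rule_set`.
#' @export
rule_set <- function(tolerance_frac = 0.30,
                     blainville = list(duration_us = 250,
                                       lf_rolloff_hz = 25000,
                                       ici_s = c(0.2, 0.4)),
                     cuvier = list(duration_us = 175,
                                   lf_rolloff_hz = 20000,
                                   ici_s = c(0.3, 0.5)),
                     beaked_min_rolloff_hz = 18000,
                     delphinid_max_duration_us = 120,
                     sperm_min_duration_us = 300,
                     sperm_max_peak_hz = 20000,
                     sperm_min_ici_s = 0.5,
                     echosounder_max_ici_cv = 0.08,
                     echosounder_min_peak_hz = 25000,
                     precedence = c("blainville", "cuvier",
                                    "unidentified_beaked_whale",
                                    "echosounder", "sperm", "delphinid")) {
  stopifnot(tolerance_frac >= 0, !anyDuplicated(precedence))
  structure(
    list(tolerance_frac = tolerance_frac, blainville = blainville,
         cuvier = cuvier, beaked_min_rolloff_hz = beaked_min_rolloff_hz,
         delphinid_max_duration_us = delphinid_max_duration_us,
         sperm_min_duration_us = sperm_min_duration_us,
         sperm_max_peak_hz = sperm_max_peak_hz,
         sperm_min_ici_s = sperm_min_ici_s,
         echosounder_max_ici_cv = echosounder_max_ici_cv,
         echosounder_min_peak_hz = echosounder_min_peak_hz,
         precedence = precedence),
    class = "rule_set")
}

in_window <- function(x, centre, tol) {
  !is.na(x) && x >= centre * (1 - tol) && x <= centre * (1 + tol)
}

species_window_match <- function(tf, sp, rules) {
  w <- rules[[sp]]
  in_window(tf$duration_us_med, w$duration_us, rules$tolerance_frac) &&
    in_window(tf$lf_rolloff_hz_med, w$lf_rolloff_hz, rules$tolerance_frac) &&
    !is.na(tf$ici_mean_s) &&
    tf$ici_mean_s >= w$ici_s[1] && tf$ici_mean_s <= w$ici_s[2]
}

# Distance to a species window centre in normalised (fractional) feature
# space; used to break ties when both species windows match.
species_distance <- function(tf, sp, rules) {
  w <- rules[[sp]]
  sqrt(((tf$duration_us_med - w$duration_us) / w$duration_us)^2 +
       ((tf$lf_rolloff_hz_med - w$lf_rolloff_hz) / w$lf_rolloff_hz)^2 +
       ((tf$ici_mean_s - mean(w$ici_s)) / mean(w$ici_s))^2)
}

#' Classify one click train
#'
#' Applies the rule set to a train-feature summary row (see
#' [train_features()]). A beaked-whale label requires an upsweep and a
#' roll-off at or above the beaked gate; among beaked-whale-like trains the
#' species windows are tried, with a nearest-window tie-break when both
#' match; beaked-whale-like trains matching no species window are labelled
#' `unidentified_beaked_whale`. Remaining trains are tried as echosounder
#' (metronomic), sperm whale (long, low-frequency, slow) and delphinid
#' (short, no upsweep); anything else is `unknown`.
#'
#' @param tf one-row data.frame of train features.
#' @param rules a [rule_set()].
#' @return list with `label` and `trace` (the matched-rule description).
#' @examples
#' tf <- data.frame(duration_us_med = 250, lf_rolloff_hz_med = 25000,
#'                  ici_mean_s = 0.3, ici_sd_s = 0.02,
#'                  peak_freq_hz_med = 38000, upsweep = TRUE, n_clicks = 8)
#' classify_train(tf, rule_set())$label
#' @export
classify_train <- function(tf, rules = rule_set()) {
  need <- c("duration_us_med", "lf_rolloff_hz_med", "ici_mean_s", "upsweep")
  if (any(!need %in% names(tf)) ||
      all(is.na(unlist(tf[intersect(need, names(tf))]))))
    return(list(label = "unknown", trace = "missing features"))

  upsweep <- isTRUE(tf$upsweep)
  beaked_like <- upsweep && !is.na(tf$lf_rolloff_hz_med) &&
    tf$lf_rolloff_hz_med >= rules$beaked_min_rolloff_hz

  matches <- character(0)
  if (beaked_like) {
    for (sp in c("blainville", "cuvier"))
      if (species_window_match(tf, sp, rules)) matches <- c(matches, sp)
  }

  for (lab in rules$precedence) {
    hit <- switch(lab,
      blainville = ,
      cuvier = {
        if (length(matches) == 2) {
          d <- vapply(matches, species_distance, numeric(1), tf = tf,
                      rules = rules)
          lab == matches[which.min(d)]
        } else lab %in% matches
      },
      unidentified_beaked_whale = beaked_like && length(matches) == 0,
      echosounder = !upsweep && !is.na(tf$ici_sd_s) &&
        !is.na(tf$ici_mean_s) &&
        tf$ici_sd_s / tf$ici_mean_s <= rules$echosounder_max_ici_cv &&
        !is.na(tf$peak_freq_hz_med) &&
        tf$peak_freq_hz_med >= rules$echosounder_min_peak_hz,
      sperm = !upsweep && !is.na(tf$duration_us_med) &&
        tf$duration_us_med >= rules$sperm_min_duration_us &&
        !is.na(tf$peak_freq_hz_med) &&
        tf$peak_freq_hz_med <= rules$sperm_max_peak_hz &&
        !is.na(tf$ici_mean_s) && tf$ici_mean_s >= rules$sperm_min_ici_s,
      delphinid = !upsweep && !is.na(tf$duration_us_med) &&
        tf$duration_us_med <= rules$delphinid_max_duration_us,
      FALSE)
    if (isTRUE(hit))
      return(list(label = lab,
                  trace = sprintf("matched %s rule (dur %.0f us, rolloff %.0f Hz, ICI %.3f s, upsweep %s)",
                                  lab, tf$duration_us_med,
                                  tf$lf_rolloff_hz_med, tf$ici_mean_s,
                                  upsweep)))
  }
  list(label = "unknown", trace = "no rule matched")
}

#' Classify a table of click trains
#'
#' @param tf data.frame from [train_features()].
#' @param rules a [rule_set()].
#' @return `tf` with added `label` column.
#' @export
classify_trains <- function(tf, rules = rule_set()) {
  tf$label <- vapply(seq_len(nrow(tf)), function(i)
    classify_train(tf[i, , drop = FALSE], rules)$label, character(1))
  tf
}

label_to_class <- function(label) {
  switch(label,
         blainville = , cuvier = ,
         unidentified_beaked_whale = "beaked_whale",
         delphinid = "delphinid",
         sperm = "sperm_whale",
         echosounder = "echosounder",
         NA_character_)
}

#' Roll train labels up to per-file presence flags
#'
#' A file's class flag is true iff at least one train of that class was
#' found in it; flags for different classes are independent. The
#' beaked-whale species detail is `blainville`/`cuvier` when a species was
#' identified (species labels take precedence over unidentified trains) and
#' `unidentified` otherwise.
#'
#' @param trains data.frame with `file_id` and `label` (from
#'   [classify_trains()]).
#' @param files data.frame with one row per analysed file (`file_id`, plus
#'   any metadata columns, which are carried through).
#' @return `files` with added columns `beaked_whale`, `delphinid`,
#'   `sperm_whale`, `echosounder` (logical) and `bw_detail` (character or
#'   `NA`).
#' @export
flag_files <- function(trains, files) {
  stopifnot("file_id" %in% names(files))
  if (nrow(trains) > 0 && !all(trains$file_id %in% files$file_id))
    stop("orphan train: file_id not present in the file index")
  for (cl in c("beaked_whale", "delphinid", "sperm_whale", "echosounder"))
    files[[cl]] <- FALSE
  files$bw_detail <- NA_character_
  for (fid in unique(trains$file_id)) {
    labs <- trains$label[trains$file_id == fid]
    cls <- unique(stats::na.omit(vapply(labs, label_to_class, character(1))))
    i <- files$file_id == fid
    for (cl in cls) files[[cl]][i] <- TRUE
    if ("beaked_whale" %in% cls) {
      files$bw_detail[i] <- if ("blainville" %in% labs) "blainville"
        else if ("cuvier" %in% labs) "cuvier" else "unidentified"
    }
  }
  files
}
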