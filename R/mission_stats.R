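# Mission-level aggregation: per-class file percentages, diel profiles,
# day/night one-way ANOVA, encounter counting and rates, and detector
# performance accounting.

#' Percentage of files containing a class
#'
#' `100 * flagged / analysed`, the headline per-class statistic of a
#' mission (e.g. "50.4% of files contained delphinid clicks").
#'
#' @param flags data.frame with one row per analysed file and a logical
#'   column named `class`.
#' @param class column name, e.g. `"delphinid"`.
#' @return percentage in `[0, 100]`.
#' @export
percent_with_class <- function(flags, class) {
  if (nrow(flags) == 0) stop("empty flag table")
  stopifnot(class %in% names(flags))
  100 * sum(flags[[class]], na.rm = TRUE) / nrow(flags)
}

#' Diel (hour-of-day) detection profile
#'
#' Buckets every analysed file by its local hour and reports per-hour
#' observation effort and the percentage of files containing the class.
#'
#' @param flags data.frame with `t_utc` (POSIXct) and a logical `class`
#'   column.
#' @param class column name.
#' @param utc_offset_h local-time offset from UTC in hours (Hawai'i: -10,
#'   no DST).
#' @param file_duration_s duration represented by one file, for the
#'   observation-minutes column.
#' @return data.frame with `hour` (0–23), `observation_minutes`,
#'   `positive_minutes` and `percent`.
#' @export
diel_profile <- function(flags, class, utc_offset_h = -10,
                         file_duration_s = 60) {
  stopifnot(class %in% names(flags), inherits(flags$t_utc, "POSIXct"))
  hr <- (as.integer(format(flags$t_utc, "%H", tz = "UTC")) +
           utc_offset_h) %% 24
  out <- data.frame(hour = 0:23)
  n <- tabulate(hr + 1L, 24)
  pos <- vapply(0:23, function(h) sum(flags[[class]][hr == h], na.rm = TRUE),
                numeric(1))
  out$observation_minutes <- n * file_duration_s / 60
  out$positive_minutes <- pos * file_duration_s / 60
  out$percent <- ifelse(n > 0, 100 * pos / n, NA_real_)
  out
}

#' One-way ANOVA between day and night detection rates
#'
#' A from-scratch one-way fixed-effects ANOVA (between/within sums of
#' squares) comparing per-observation detection percentages grouped into
#' day and night hours. Observations are typically per-dive-hour
#' percentages.
#'
#' @param hours integer vector of local hours (0–23), one per observation.
#' @param values detection percentage (or count) per observation.
#' @param day_hours,night_hours local hours defining the two groups;
#'   observations in neither set are dropped.
#' @return list with `F`, `p`, `df` (length-2), `group_means`, and the
#'   grouping used. `p` is `NA` when the within-group variance is zero
#'   or either group has fewer than 2 observations.
#' @examples
#' day_night_anova(c(10, 11, 12, 22, 23, 0), c(5, 6, 4, 60, 70, 65))
#' @export
day_night_anova <- function(hours, values, day_hours = 7:18,
                            night_hours = c(19:23, 0:6)) {
  stopifnot(length(hours) == length(values))
  grp <- ifelse(hours %in% day_hours, "day",
                ifelse(hours %in% night_hours, "night", NA))
  keep <- !is.na(grp) & !is.na(values)
  res <- oneway_anova(values[keep], grp[keep])
  c(res, list(day_hours = day_hours, night_hours = night_hours))
}

# One-way fixed-effects ANOVA from the between/within sum-of-squares
# definitions (any number of groups).
oneway_anova <- function(values, groups) {
  groups <- as.character(groups)
  keep <- !is.na(groups) & !is.na(values)
  values <- values[keep]
  groups <- groups[keep]
  k <- length(unique(groups))
  if (k < 2 || any(table(groups) < 2))
    return(list(F = NA_real_, p = NA_real_, df = c(NA, NA),
                group_means = tapply(values, groups, mean)))
  grand <- mean(values)
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum((values - means[groups])^2)
  df1 <- k - 1
  df2 <- length(values) - k
  if (ss_within == 0)
    return(list(F = Inf, p = NA_real_, df = c(df1, df2),
                group_means = means))
  Fstat <- (ss_between / df1) / (ss_within / df2)
  list(F = Fstat, p = pf(Fstat, df1, df2, lower.tail = FALSE),
       df = c(df1, df2), group_means = means)
}

#' Count acoustic encounters
#'
#' Positive files belonging to the same dive always form one encounter;
#' positives in different dives are merged only when separated by at most
#' `max_gap_s` (default: never, one encounter per dive with detections).
#'
#' @param flags data.frame with `file_id`, `dive_id`, `t_utc` and a logical
#'   `class` column, time-sorted.
#' @param class column name.
#' @param max_gap_s maximum gap (seconds) between positive files of
#'   *different* dives that still merges them into one encounter.
#' @return data.frame of encounters: `encounter`, `class`, `dive_ids`,
#'   `start_utc`, `end_utc`, `n_files`.
#' @export
count_encounters <- function(flags, class, max_gap_s = 0) {
  stopifnot(all(c("dive_id", "t_utc", class) %in% names(flags)))
  pos <- flags[which(flags[[class]]), , drop = FALSE]
  if (nrow(pos) == 0)
    return(data.frame(encounter = integer(0), class = character(0),
                      dive_ids = character(0),
                      start_utc = as.POSIXct(character(0), tz = "UTC"),
                      end_utc = as.POSIXct(character(0), tz = "UTC"),
                      n_files = integer(0)))
  pos <- pos[order(pos$t_utc), , drop = FALSE]
  n <- nrow(pos)
  new_dive <- c(TRUE, pos$dive_id[-1] != pos$dive_id[-n])
  gap <- c(Inf, as.numeric(difftime(pos$t_utc[-1], pos$t_utc[-n],
                                    units = "secs")))
  enc <- cumsum(new_dive & gap > max_gap_s)
  do.call(rbind, lapply(split(pos, enc), function(e)
    data.frame(encounter = NA_integer_, class = class,
               dive_ids = paste(unique(e$dive_id), collapse = ";"),
               start_utc = min(e$t_utc), end_utc = max(e$t_utc),
               n_files = nrow(e)))) |>
    (\(d) { d$encounter <- seq_len(nrow(d)); rownames(d) <- NULL; d })()
}

#' Encounter rate in recording hours per encounter
#'
#' @param total_recording_h total analysed recording time in hours.
#' @param n_encounters number of encounters; 0 returns `Inf`.
#' @return hours of recording per encounter.
#' @examples
#' encounter_rate(194, 7)  # one encounter every ~27.7 h
#' @export
encounter_rate <- function(total_recording_h, n_encounters) {
  stopifnot(total_recording_h >= 0, n_encounters >= 0)
  if (n_encounters == 0) return(Inf)
  total_recording_h / n_encounters
}

#' Detector performance against manually verified truth
#'
#' File-level recall (percentage of truth-positive files the detector also
#' flagged) and dive-level true/false detection counts.
#'
#' @param truth_flags,detector_flags data.frames over the *same* files with
#'   `file_id`, `dive_id` and a logical `class` column.
#' @param class column name.
#' @return list with `file_recall_pct`, `n_truth_files`, `n_detected_files`,
#'   `dive_true_detections`, `dive_false_detections`, and the flagged dive
#'   ids.
#' @examples
#' # published accounting: 79 of 109 truth files detected -> 72% recall
#' @export
detector_performance <- function(truth_flags, detector_flags, class) {
  stopifnot(class %in% names(truth_flags), class %in% names(detector_flags))
  if (!setequal(truth_flags$file_id, detector_flags$file_id))
    stop("truth and detector tables cover different file sets")
  det <- detector_flags[match(truth_flags$file_id, detector_flags$file_id), ]
  truth_pos <- which(truth_flags[[class]])
  tp_files <- sum(det[[class]][truth_pos])
  recall <- if (length(truth_pos) > 0) 100 * tp_files / length(truth_pos)
    else NA_real_
  truth_dives <- unique(truth_flags$dive_id[truth_flags[[class]]])
  det_dives <- unique(det$dive_id[det[[class]]])
  list(file_recall_pct = recall,
       n_truth_files = length(truth_pos), n_detected_files = tp_files,
       dive_true_detections = sum(det_dives %in% truth_dives),
       dive_false_detections = sum(!det_dives %in% truth_dives),
       detected_dives = det_dives)
}
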