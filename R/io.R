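# Plain-text interchange: YAML rule sets and scenarios, CSV tracks and
# fixes (ISO-8601 UTC times, decimal degrees).

#' Read and write classification rule sets as YAML
#'
#' @param rules a [rule_set()].
#' @param path YAML file path.
#' @return `read_rules()` returns a [rule_set()]; `write_rules()` returns
#'   `path` invisibly.
#' @export
write_rules <- function(rules, path) {
  stopifnot(inherits(rules, "rule_set"))
  yaml::write_yaml(unclass(rules), path)
  invisible(path)
}

#' @rdname write_rules
#' @export
read_rules <- function(path) {
  y <- yaml::read_yaml(path)
  y$blainville$ici_s <- as.numeric(y$blainville$ici_s)
  y$cuvier$ici_s <- as.numeric(y$cuvier$ici_s)
  do.call(rule_set, y)
}

#' Read and write mission scenarios as YAML
#'
#' @param scenario a [mission_scenario()].
#' @param path YAML file path.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "mission_scenario"))
  y <- unclass(scenario)
  y$start_utc <- format(y$start_utc, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  yaml::write_yaml(y, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  y$start_utc <- as.POSIXct(y$start_utc, format = "%Y-%m-%dT%H:%M:%SZ",
                            tz = "UTC")
  for (nm in c("prevalence", "class_presets", "clicks_per_train"))
    y[[nm]] <- unlist(y[[nm]])
  if (!is.null(y$diel_profile)) y$diel_profile <- as.numeric(y$diel_profile)
  do.call(mission_scenario, y)
}

parse_utc <- function(x) {
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  bad <- is.na(out)
  out[bad] <- as.POSIXct(x[bad], tz = "UTC")
  out
}

#' Read a glider track CSV
#'
#' Expected columns: `t_utc` (ISO-8601), `lat`, `lon`, `depth_m`,
#' `recording` (logical or 0/1).
#'
#' @param path CSV path.
#' @return data.frame of `GliderSample` rows.
#' @export
read_track_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("t_utc", "lat", "lon") %in% names(d)))
  d$t_utc <- parse_utc(d$t_utc)
  if ("recording" %in% names(d)) d$recording <- as.logical(d$recording)
  d
}

#' Read a tag-fix CSV
#'
#' Expected columns: `t_utc` (ISO-8601), `lat`, `lon`,
#' `accuracy_radius_km`, optionally `deployment_id`.
#'
#' @param path CSV path.
#' @return data.frame of `TagFix` rows.
#' @export
read_fixes_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("t_utc", "lat", "lon", "accuracy_radius_km") %in% names(d)))
  d$t_utc <- parse_utc(d$t_utc)
  d
}
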