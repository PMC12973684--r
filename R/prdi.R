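#' Build post-regurgitation (PRDI) windows from annotations
#'
#' Each observed regurgitation opens a half-open window
#' `[t, t + window_len_s)` during which any breath event counts as a
#' post-regurgitation deep inhalation (PRDI). Overlapping windows are kept
#' individually; membership is tested against their union.
#'
#' @param regurg_times_s sorted numeric vector of regurgitation times in
#'   seconds (or a data frame with a `regurg_time_s` column).
#' @param window_len_s window length in seconds (default 3.0).
#' @return Data frame with columns `start_s`, `end_s`, `source_regurg_s`.
#' @examples
#' build_windows(c(10, 12))
#' @export
build_windows <- function(regurg_times_s, window_len_s = 3.0) {
  if (is.data.frame(regurg_times_s))
    regurg_times_s <- regurg_times_s$regurg_time_s
  regurg_times_s <- as.numeric(regurg_times_s)
  check_scalar(window_len_s, "window_len_s", lower = 0, strict_lower = TRUE)
  if (length(regurg_times_s) == 0L)
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      source_regurg_s = numeric(0)))
  if (any(!is.finite(regurg_times_s)) || any(regurg_times_s < 0))
    fail_validation("regurgitation times must be finite and non-negative")
  if (is.unsorted(regurg_times_s, strictly = TRUE))
    fail_validation("regurgitation times must be strictly increasing")
  data.frame(start_s = regurg_times_s,
             end_s = regurg_times_s + window_len_s,
             source_regurg_s = regurg_times_s)
}

in_window_union <- function(times, windows) {
  if (nrow(windows) == 0L) return(rep(FALSE, length(times)))
  vapply(times, function(t)
    any(t >= windows$start_s & t < windows$end_s), logical(1))
}

#' Label breath events as PRDI or NRI
#'
#' An event is labeled `PRDI` iff its time falls in the union of the
#' (half-open) post-regurgitation windows, otherwise `NRI`
#' (non-rumination inhalation). Every event receives exactly one label.
#'
#' @param events data frame with an `event_time_s` (or `time_s`) column.
#' @param windows data frame from [build_windows()].
#' @return `events` with a `label` factor column (levels `NRI`, `PRDI`).
#' @export
label_events <- function(events, windows) {
  tcol <- if ("event_time_s" %in% names(events)) "event_time_s" else "time_s"
  if (!tcol %in% names(events))
    fail_validation("events must have an event_time_s column")
  inside <- in_window_union(events[[tcol]], windows)
  events$label <- factor(ifelse(inside, "PRDI", "NRI"),
                         levels = c("NRI", "PRDI"))
  events
}

#' Classify events by a depth threshold
#'
#' Predicts `PRDI` for events whose minima are at least as deep as the
#' threshold (`depth_z <= threshold_z`; deeper = more negative); ties count
#' as positive, matching the ROC convention. Truth labels are untouched.
#'
#' @param events data frame with a `depth_z` column.
#' @param threshold_z decision threshold in z-units.
#' @return `events` with a `predicted` factor column (levels `NRI`, `PRDI`).
#' @export
classify_events <- function(events, threshold_z) {
  if (!"depth_z" %in% names(events))
    fail_validation("events must have a depth_z column")
  if (!is.numeric(threshold_z) || length(threshold_z) != 1L || is.na(threshold_z))
    fail_validation("threshold_z must be a single number")
  if (any(!is.finite(events$depth_z)))
    fail_validation("event depths must be finite")
  events$predicted <- factor(ifelse(events$depth_z <= threshold_z,
                                    "PRDI", "NRI"),
                             levels = c("NRI", "PRDI"))
  events
}
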