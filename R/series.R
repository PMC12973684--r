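#' Construct a nostril temperature time series
#'
#' The basic container of the pipeline: a uniformly sampled nostril-region
#' temperature signal in degrees Celsius, with per-sample missing flags for
#' frames where no nostril pixels were available.
#'
#' @param recording_id character scalar identifying the recording.
#' @param times_s numeric vector of sample times in seconds from recording
#'   start, approximately uniform.
#' @param values_C numeric vector of temperatures in degrees Celsius; may be
#'   `NA` where `missing` is `TRUE`.
#' @param missing logical vector flagging samples with no usable measurement.
#'   Defaults to `!is.finite(values_C)`.
#' @param fs sampling rate in samples per second. Estimated from `times_s`
#'   when omitted.
#' @return An object of class `temperature_series`: a list with fields
#'   `recording_id`, `times_s`, `values_C`, `missing` and `fs`.
#' @examples
#' ts <- temperature_series("r1", (0:86) / 8.7, 30 + sin(2 * pi * 0.5 * (0:86) / 8.7))
#' ts
#' @export
temperature_series <- function(recording_id, times_s, values_C,
                               missing = NULL, fs = NULL) {
  if (!is.character(recording_id) || length(recording_id) != 1L)
    fail_validation("recording_id must be a single string")
  times_s <- as.numeric(times_s)
  values_C <- as.numeric(values_C)
  if (length(times_s) != length(values_C))
    fail_validation("times_s and values_C must have equal length")
  if (length(times_s) < 2L)
    fail_validation("a temperature series needs at least 2 samples")
  if (any(diff(times_s) <= 0))
    fail_validation("times_s must be strictly increasing")
  if (is.null(missing)) missing <- !is.finite(values_C)
  missing <- as.logical(missing)
  if (length(missing) != length(values_C))
    fail_validation("missing flags must match the number of samples")
  if (any(!missing & !is.finite(values_C)))
    fail_validation("non-missing values must be finite")
  if (is.null(fs)) {
    n <- length(times_s)
    fs <- (n - 1) / (times_s[n] - times_s[1])
  }
  check_scalar(fs, "fs", lower = 0, strict_lower = TRUE)
  structure(
    list(recording_id = recording_id, times_s = times_s,
         values_C = values_C, missing = missing, fs = fs),
    class = "temperature_series"
  )
}

#' @export
print.temperature_series <- function(x, ...) {
  cat(sprintf(
    "<temperature_series '%s': %d samples @ %.4g Hz, %.1f s, %d missing>\n",
    x$recording_id, length(x$values_C), x$fs,
    x$times_s[length(x$times_s)] - x$times_s[1], sum(x$missing)
  ))
  invisible(x)
}

#' @export
length.temperature_series <- function(x) length(x$values_C)

# ---- CSV IO ----------------------------------------------------------------

# Comment lines beginning with '#' carry metadata (recording id, config hash)
# and are skipped by the readers.

write_commented_csv <- function(df, path, meta = character()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (m in names(meta)) writeLines(sprintf("# %s=%s", m, meta[[m]]), con)
  utils::write.table(df, con, sep = ",", dec = ".", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

read_commented_csv <- function(path) {
  if (!file.exists(path)) fail_io("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (m in meta_lines) {
    kv <- sub("^#\\s*", "", m)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)],
                        stringsAsFactors = FALSE)
  attr(df, "meta") <- meta
  df
}

#' Write and read temperature series CSV files
#'
#' The on-disk dialect is comma-separated UTF-8 with a required
#' `time_s,temp_C` header; numeric fields are written with six decimals.
#' Missing samples are stored as empty fields. Metadata (recording id, and
#' optionally a configuration hash) travels in leading `#` comment lines.
#'
#' @param series a [temperature_series()].
#' @param path file path.
#' @param meta named character vector of extra metadata comment lines.
#' @return `write_series_csv` returns `path` invisibly; `read_series_csv`
#'   returns a [temperature_series()].
#' @export
write_series_csv <- function(series, path, meta = character()) {
  stopifnot(inherits(series, "temperature_series"))
  vals <- ifelse(series$missing, NA_real_, series$values_C)
  df <- data.frame(time_s = sprintf("%.6f", series$times_s),
                   temp_C = ifelse(is.na(vals), "", sprintf("%.6f", vals)))
  write_commented_csv(df, path,
                      c(recording_id = series$recording_id, meta))
}

#' @rdname write_series_csv
#' @param recording_id overrides the recording id stored in the file.
#' @export
read_series_csv <- function(path, recording_id = NULL) {
  df <- read_commented_csv(path)
  if (!all(c("time_s", "temp_C") %in% names(df)))
    fail_io("series CSV must have columns time_s,temp_C: ", path)
  meta <- attr(df, "meta")
  id <- recording_id %||% meta$recording_id %||%
    sub("\\.[^.]*$", "", basename(path))
  temperature_series(id, df$time_s, df$temp_C,
                     missing = is.na(df$temp_C))
}

#' Read and write regurgitation annotation CSV files
#'
#' Annotations give, per recording, the visually observed regurgitation times
#' in seconds from recording start (columns `recording_id,regurg_time_s`).
#'
#' @param path file path.
#' @return `read_annotations_csv` returns a data frame with columns
#'   `recording_id` and `regurg_time_s`, sorted by recording and time.
#' @export
read_annotations_csv <- function(path) {
  df <- read_commented_csv(path)
  if (!all(c("recording_id", "regurg_time_s") %in% names(df)))
    fail_io("annotation CSV must have columns recording_id,regurg_time_s: ", path)
  df$recording_id <- as.character(df$recording_id)
  df$regurg_time_s <- as.numeric(df$regurg_time_s)
  if (any(!is.finite(df$regurg_time_s)) || any(df$regurg_time_s < 0))
    fail_validation("regurgitation times must be finite and non-negative")
  df <- df[order(df$recording_id, df$regurg_time_s), , drop = FALSE]
  for (id in unique(df$recording_id)) {
    tt <- df$regurg_time_s[df$recording_id == id]
    if (any(diff(tt) <= 0))
      fail_validation("regurgitation times must be strictly increasing within recording ", id)
  }
  rownames(df) <- NULL
  df
}

#' @rdname read_annotations_csv
#' @param annotations data frame with columns `recording_id`, `regurg_time_s`.
#' @param meta named character vector of metadata comment lines.
#' @export
write_annotations_csv <- function(annotations, path, meta = character()) {
  df <- data.frame(recording_id = annotations$recording_id,
                   regurg_time_s = sprintf("%.6f", annotations$regurg_time_s))
  write_commented_csv(df, path, meta)
}

#' Read and write breath-event CSV files
#'
#' Events carry one row per detected breath minimum with columns
#' `recording_id,event_time_s,depth_z,label,predicted`; `label`/`predicted`
#' are `PRDI`/`NRI` or empty when not yet assigned.
#'
#' @param events data frame with at least `recording_id`, `event_time_s`,
#'   `depth_z`; optionally `label` and `predicted`.
#' @param path file path.
#' @param meta named character vector of metadata comment lines.
#' @export
write_events_csv <- function(events, path, meta = character()) {
  lab <- if ("label" %in% names(events)) as.character(events$label) else ""
  prd <- if ("predicted" %in% names(events)) as.character(events$predicted) else ""
  df <- data.frame(recording_id = events$recording_id,
                   event_time_s = sprintf("%.6f", events$event_time_s),
                   depth_z = sprintf("%.6f", events$depth_z),
                   label = ifelse(is.na(lab), "", lab),
                   predicted = ifelse(is.na(prd), "", prd))
  write_commented_csv(df, path, meta)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  df <- read_commented_csv(path)
  need <- c("recording_id", "event_time_s", "depth_z")
  if (!all(need %in% names(df)))
    fail_io("event CSV must have columns ", paste(need, collapse = ","), ": ", path)
  df$recording_id <- as.character(df$recording_id)
  df$event_time_s <- as.numeric(df$event_time_s)
  df$depth_z <- as.numeric(df$depth_z)
  for (col in c("label", "predicted")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
    df[[col]] <- as.character(df[[col]])
    df[[col]][!nzchar(df[[col]]) | is.na(df[[col]])] <- NA_character_
  }
  df
}
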