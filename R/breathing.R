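#' Band-pass filter specification
#'
#' The physiological breathing band for calves spans roughly 0.2-1.0 Hz
#' (12-60 breaths/min); the filter retains it while rejecting baseline drift
#' and high-frequency noise. A 3rd-order Butterworth band-pass is applied
#' forward-backward (zero phase) so event times are not biased by group
#' delay.
#'
#' @param low_hz lower band edge in Hz (default 0.2).
#' @param high_hz upper band edge in Hz (default 1.0).
#' @param order filter order (default 3).
#' @param zero_phase apply forward-backward for zero phase shift (default
#'   `TRUE`).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(low_hz = 0.2, high_hz = 1.0, order = 3L,
                        zero_phase = TRUE) {
  check_scalar(low_hz, "low_hz", lower = 0, strict_lower = TRUE)
  check_scalar(high_hz, "high_hz", lower = 0, strict_lower = TRUE)
  check_scalar(order, "order", lower = 1, upper = 8)
  if (low_hz >= high_hz)
    fail_validation("filter band edges must satisfy low_hz < high_hz (got low_hz = ",
                    low_hz, ", high_hz = ", high_hz, ")")
  structure(list(low_hz = low_hz, high_hz = high_hz,
                 order = as.integer(order),
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

# minimum series length (samples) accepted by the filter: three cycles of the
# low band edge, the settling span of the slowest retained component
bandpass_min_length <- function(fs, spec) as.integer(ceiling(3 * fs / spec$low_hz))

#' Band-pass filter a temperature signal
#'
#' Removes the mean, pads both ends by odd (point-symmetric) reflection to
#' suppress edge transients, applies the Butterworth band-pass forward and
#' (when `zero_phase`) backward, and trims the padding. Output has the same
#' length as the input and no DC component.
#'
#' @param x numeric vector (degrees Celsius) or a [temperature_series()]
#'   without missing samples.
#' @param fs sampling rate in samples/s (taken from the series when `x` is a
#'   [temperature_series()]).
#' @param spec a [filter_spec()].
#' @return Numeric vector of filtered temperature deviations.
#' @export
bandpass_filter <- function(x, fs = NULL, spec = filter_spec()) {
  if (inherits(x, "temperature_series")) {
    if (any(x$missing))
      fail_validation("series has missing samples; interpolate or split first")
    fs <- fs %||% x$fs
    x <- x$values_C
  }
  if (is.null(fs)) fail_validation("fs is required when x is a plain vector")
  check_scalar(fs, "fs", lower = 0, strict_lower = TRUE)
  if (!(spec$low_hz > 0 && spec$low_hz < spec$high_hz && spec$high_hz < fs / 2))
    fail_validation("band edges must satisfy 0 < low_hz < high_hz < fs/2 ",
                    "(low_hz = ", spec$low_hz, ", high_hz = ", spec$high_hz,
                    ", fs/2 = ", fs / 2, ")")
  n <- length(x)
  nmin <- bandpass_min_length(fs, spec)
  if (n < nmin)
    fail_validation("series too short to filter: ", n, " samples, minimum ", nmin)
  if (any(!is.finite(x))) fail_validation("input must be finite")

  xc <- x - mean(x)
  npad <- min(n - 1L, as.integer(ceiling(3 * fs / spec$low_hz)))
  front <- 2 * xc[1] - xc[(npad + 1):2]
  back <- 2 * xc[n] - xc[(n - 1):(n - npad)]
  xp <- c(front, xc, back)
  bf <- signal::butter(spec$order, c(spec$low_hz, spec$high_hz) / (fs / 2),
                       type = "pass")
  y <- signal::filter(bf, xp)
  if (spec$zero_phase) y <- rev(signal::filter(bf, rev(y)))
  y <- as.numeric(y)[(npad + 1):(npad + n)]
  y
}

#' Z-score standardization
#'
#' Centres and scales a signal to zero mean and unit sample standard
#' deviation (n - 1 denominator), removing per-recording baseline and scale
#' differences before events are pooled across recordings.
#'
#' @param x numeric vector with at least 2 samples and positive variance.
#' @return Numeric vector of z-values.
#' @export
standardize <- function(x) {
  if (length(x) < 2L) fail_validation("standardize needs at least 2 samples")
  if (any(!is.finite(x))) fail_validation("input must be finite")
  s <- stats::sd(x)
  if (s == 0) fail_validation("zero variance: degenerate (constant) recording")
  (x - mean(x)) / s
}

#' Centered moving average
#'
#' Interior sample `i` becomes the mean of samples `i - k ... i + k` with
#' `k = (window - 1) / 2`; near the edges the window is truncated (never
#' padded), so output length equals input length and no synthetic extrema are
#' created. At 8.7 samples/s the default 9-sample window spans about 1.03 s.
#'
#' @param x numeric vector.
#' @param window odd window size in samples (default 9).
#' @return Numeric vector, same length as `x`.
#' @export
smooth_ma <- function(x, window = 9L) {
  if (!is_num_scalar(window) || window < 1 || window %% 2 == 0)
    fail_validation("window must be an odd positive integer (centering is undefined for even windows)")
  n <- length(x)
  if (window > n) fail_validation("window (", window, ") exceeds signal length (", n, ")")
  if (window == 1) return(as.numeric(x))
  half <- (window - 1) / 2
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1, i - half)
  hi <- pmin(n, i + half)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Derive the breathing signal from a temperature series
#'
#' The processing chain behind event detection: gap handling, band-pass
#' filtering, z-score standardization (per segment) and centered moving
#' average smoothing. Missing-sample runs no longer than `max_gap_s` are
#' linearly interpolated; longer gaps split the recording into segments that
#' are filtered and standardized independently (interpolating long gaps would
#' fabricate breaths). Segments too short for the filter are dropped with a
#' warning and left `NA`.
#'
#' @param series a [temperature_series()].
#' @param spec a [filter_spec()].
#' @param smooth_window odd moving-average window in samples (default 9).
#' @param max_gap_s longest missing gap bridged by interpolation, seconds
#'   (default 1).
#' @return An object of class `breathing_signal`: list with `values_z`
#'   (z-units, `NA` where unprocessable), `times_s`, `fs`, `segment`
#'   (integer segment id per sample, `NA` outside segments),
#'   `smoothing_window` and `provenance` (the applied [filter_spec()] and
#'   flags).
#' @export
breathing_signal <- function(series, spec = filter_spec(), smooth_window = 9L,
                             max_gap_s = 1.0) {
  stopifnot(inherits(series, "temperature_series"))
  n <- length(series$values_C)
  fs <- series$fs
  miss <- series$missing | !is.finite(series$values_C)
  max_gap <- round(max_gap_s * fs)

  # split at missing runs longer than max_gap; shorter runs are interpolated
  seg_id <- integer(n)
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  long_gap <- r$values & r$lengths > max_gap
  cur <- 1L
  for (k in seq_along(r$lengths)) {
    if (long_gap[k]) {
      seg_id[starts[k]:ends[k]] <- NA_integer_
      cur <- cur + 1L
    } else {
      seg_id[starts[k]:ends[k]] <- cur
    }
  }
  values_z <- rep(NA_real_, n)
  nmin <- max(bandpass_min_length(fs, spec), smooth_window, 3L)
  segs <- unique(seg_id[!is.na(seg_id)])
  kept <- integer(0)
  for (s in segs) {
    idx <- which(!is.na(seg_id) & seg_id == s)
    # leading/trailing missing samples cannot be interpolated: trim them
    good <- which(!miss[idx])
    if (length(good) == 0L) { seg_id[idx] <- NA_integer_; next }
    drop <- idx[-(good[1]:good[length(good)])]
    if (length(drop)) seg_id[drop] <- NA_integer_
    idx <- idx[good[1]:good[length(good)]]
    if (length(idx) < nmin) {
      warning(sprintf("segment of %d samples is shorter than the %d-sample minimum; skipped",
                      length(idx), nmin), call. = FALSE)
      seg_id[idx] <- NA_integer_
      next
    }
    x <- series$values_C[idx]
    m <- miss[idx]
    if (any(m)) {
      x[m] <- stats::approx(idx[!m], x[!m], xout = idx[m])$y
    }
    filt <- bandpass_filter(x, fs = fs, spec = spec)
    z <- standardize(filt)
    values_z[idx] <- smooth_ma(z, smooth_window)
    kept <- c(kept, s)
  }
  structure(
    list(values_z = values_z, times_s = series$times_s, fs = fs,
         segment = seg_id, smoothing_window = as.integer(smooth_window),
         provenance = list(filter = spec, smooth_window = smooth_window,
                           max_gap_s = max_gap_s, segments = kept,
                           recording_id = series$recording_id)),
    class = "breathing_signal"
  )
}

#' @export
print.breathing_signal <- function(x, ...) {
  cat(sprintf("<breathing_signal '%s': %d samples @ %.4g Hz, %d segment(s)>\n",
              x$provenance$recording_id %||% "?", length(x$values_z), x$fs,
              length(x$provenance$segments)))
  invisible(x)
}

# prominence of a local minimum: on each side walk until a strictly lower
# sample (or the edge); the reference is the highest sample encountered, and
# the prominence is min(left, right reference) - x[i]
minimum_prominence <- function(x, i) {
  n <- length(x)
  left <- -Inf
  j <- i - 1L
  while (j >= 1L) {
    if (x[j] < x[i]) break
    if (x[j] > left) left <- x[j]
    j <- j - 1L
  }
  right <- -Inf
  j <- i + 1L
  while (j <= n) {
    if (x[j] < x[i]) break
    if (x[j] > right) right <- x[j]
    j <- j + 1L
  }
  min(left, right) - x[i]
}

detect_minima_segment <- function(x, times, fs, min_separation_s,
                                  min_prominence_z) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1)] < x[1:(n - 2)] & x[2:(n - 1)] < x[3:n]) + 1L
  if (length(cand) == 0L) return(integer(0))
  prom <- vapply(cand, function(i) minimum_prominence(x, i), numeric(1))
  cand <- cand[prom >= min_prominence_z]
  if (length(cand) == 0L) return(integer(0))
  # enforce minimum separation: deepest first, ties to the earlier index
  ord <- cand[order(x[cand], cand)]
  kept <- integer(0)
  for (i in ord) {
    if (length(kept) == 0L ||
        all(abs(times[i] - times[kept]) >= min_separation_s))
      kept <- c(kept, i)
  }
  sort(kept)
}

#' Detect breath events as local minima of the breathing signal
#'
#' Inspiratory events are strict local minima of the smoothed z-scored
#' signal: cooling of the nostril region marks air intake, so each minimum is
#' the transition from inhalation to exhalation. Candidates must clear a
#' prominence floor (rejecting noise wiggles) and a minimum separation
#' (deeper minima win), both derived from the fastest physiological breath.
#'
#' @param signal a [breathing_signal()], or a plain numeric vector (then `fs`
#'   is required).
#' @param min_separation_s minimum spacing between events in seconds
#'   (default 0.6, just below the 1-s period of a 1-Hz breath).
#' @param min_prominence_z minimum prominence in z-units (default 0.2).
#' @param fs sampling rate, only for plain-vector input.
#' @param times_s sample times, only for plain-vector input.
#' @return Data frame of breath events sorted by time: `index` (sample),
#'   `time_s`, `depth_z` (signal value at the minimum) and `segment`.
#' @export
detect_breath_minima <- function(signal, min_separation_s = 0.6,
                                 min_prominence_z = 0.2, fs = NULL,
                                 times_s = NULL) {
  check_scalar(min_separation_s, "min_separation_s", lower = 0, strict_lower = TRUE)
  check_scalar(min_prominence_z, "min_prominence_z", lower = 0, strict_lower = TRUE)
  if (inherits(signal, "breathing_signal")) {
    values <- signal$values_z
    times <- signal$times_s
    seg <- signal$segment
  } else {
    values <- as.numeric(signal)
    if (is.null(fs) && is.null(times_s))
      fail_validation("fs or times_s is required for plain-vector input")
    times <- times_s %||% ((seq_along(values) - 1) / fs)
    seg <- ifelse(is.finite(values), 1L, NA_integer_)
  }
  empty <- data.frame(index = integer(0), time_s = numeric(0),
                      depth_z = numeric(0), segment = integer(0))
  if (length(values) == 0L) return(empty)
  out <- empty
  for (s in unique(seg[!is.na(seg) & is.finite(values)])) {
    idx <- which(!is.na(seg) & seg == s & is.finite(values))
    loc <- detect_minima_segment(values[idx], times[idx], NULL,
                                 min_separation_s, min_prominence_z)
    if (length(loc) == 0L) next
    gi <- idx[loc]
    out <- rbind(out, data.frame(index = gi, time_s = times[gi],
                                 depth_z = values[gi], segment = s))
  }
  out <- out[order(out$time_s), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full signal chain on a temperature series
#'
#' Convenience wrapper: [breathing_signal()] followed by
#' [detect_breath_minima()], returning both the processed signal and the
#' event table (with the recording id attached).
#'
#' @inheritParams breathing_signal
#' @inheritParams detect_breath_minima
#' @return List with elements `signal` (a [breathing_signal()]) and `events`
#'   (data frame with `recording_id`, `index`, `event_time_s`, `depth_z`,
#'   `segment`).
#' @export
analyze_series <- function(series, spec = filter_spec(), smooth_window = 9L,
                           max_gap_s = 1.0, min_separation_s = 0.6,
                           min_prominence_z = 0.2) {
  sig <- breathing_signal(series, spec = spec, smooth_window = smooth_window,
                          max_gap_s = max_gap_s)
  ev <- detect_breath_minima(sig, min_separation_s = min_separation_s,
                             min_prominence_z = min_prominence_z)
  events <- data.frame(recording_id = rep(series$recording_id, nrow(ev)),
                       index = ev$index, event_time_s = ev$time_s,
                       depth_z = ev$depth_z, segment = ev$segment)
  list(signal = sig, events = events)
}
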