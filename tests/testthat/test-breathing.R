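fs <- 8.7

test_that("band-pass rejects DC and out-of-band drift, keeps the breathing band", {
  n <- round(120 * fs)
  t <- (seq_len(n) - 1) / fs
  interior <- t > 15 & t < 105

  # constant input: DC is outside the passband
  y0 <- bandpass_filter(rep(35, n), fs = fs)
  expect_lt(max(abs(y0)), 1e-6)

  # 0.5-Hz unit sinusoid: inside the band, amplitude preserved
  y1 <- bandpass_filter(sin(2 * pi * 0.5 * t), fs = fs)
  a1 <- max(abs(y1[interior]))
  expect_gte(a1, 0.9)
  expect_lte(a1, 1.0 + 1e-6)

  # 0.02-Hz sinusoid: drift-band, strongly attenuated
  y2 <- bandpass_filter(sin(2 * pi * 0.02 * t), fs = fs)
  expect_lt(max(abs(y2[interior])), 0.1)
})

test_that("band edge and length validation raise informative errors", {
  expect_error(filter_spec(low_hz = 1.0, high_hz = 0.2),
               class = "prdi_validation_error")
  expect_error(bandpass_filter(rnorm(500), fs = 1.5,
                               spec = filter_spec(0.2, 1.0)),
               class = "prdi_validation_error") # high_hz >= fs/2
  err <- tryCatch(bandpass_filter(rnorm(20), fs = fs),
                  error = function(e) conditionMessage(e))
  expect_match(err, "minimum 131")  # 3 cycles of the 0.2-Hz edge
})

test_that("zero-phase filtering introduces no lag on a passband sinusoid", {
  n <- round(120 * fs)
  t <- (seq_len(n) - 1) / fs
  x <- sin(2 * pi * 0.4 * t)
  y <- bandpass_filter(x, fs = fs)
  mid <- round(30 * fs):round(90 * fs)
  lags <- -5:5
  cc <- vapply(lags, function(L)
    stats::cor(x[mid], y[mid + L]), numeric(1))
  expect_equal(lags[which.max(cc)], 0)
})

test_that("z-score standardization matches its definition", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(1)
  x <- rnorm(500, 10, 3)
  z <- standardize(x)
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(stats::sd(z) - 1), 1e-9)
  # affine invariance
  expect_equal(standardize(2.5 * x + 7), z)
  expect_error(standardize(rep(1, 10)), class = "prdi_validation_error")
  expect_error(standardize(3), class = "prdi_validation_error")
})

test_that("centered moving average is exact on constants and ramps", {
  expect_equal(smooth_ma(rep(4.2, 50), 9), rep(4.2, 50))
  x <- as.numeric(1:60)
  sm <- smooth_ma(x, 9)
  expect_equal(sm[5:56], x[5:56])          # interior: symmetric window
  expect_length(sm, 60)
  expect_error(smooth_ma(x, 8), class = "prdi_validation_error")
  expect_error(smooth_ma(x, 61), class = "prdi_validation_error")
  expect_equal(smooth_ma(x, 1), x)
})

test_that("breath minima of a clean sinusoid appear at the analytic times", {
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  ev <- detect_breath_minima(sin(2 * pi * 0.5 * t), fs = fs)
  expect_equal(nrow(ev), 5)
  expect_lt(max(abs(ev$time_s - c(1.5, 3.5, 5.5, 7.5, 9.5))), 1 / fs + 1e-9)

  # monotone signal: no local minima
  expect_equal(nrow(detect_breath_minima(seq(0, 5, length.out = 100), fs = fs)), 0)
  # empty signal: empty table, not an error
  expect_equal(nrow(detect_breath_minima(numeric(0), fs = fs)), 0)
})

test_that("minima count on a clean sinusoid is within one of f*T", {
  for (f in c(0.3, 0.5, 0.8)) {
    for (Tdur in c(20, 60)) {
      t <- seq(0, Tdur - 1 / fs, by = 1 / fs)
      ev <- detect_breath_minima(sin(2 * pi * f * t), fs = fs)
      expect_true(abs(nrow(ev) - floor(f * Tdur)) <= 1,
                  label = sprintf("f=%g T=%g count=%d", f, Tdur, nrow(ev)))
    }
  }
})

test_that("of two close minima only the deeper one is kept", {
  # two dips 0.3 s apart (< 0.6 s separation), depths -1.0 and -0.6
  fs2 <- 20
  t <- seq(0, 4, by = 1 / fs2)
  dip <- function(t0, depth, width = 0.1)
    depth * exp(-((t - t0) / width)^2)
  x <- dip(1.7, -1.0) + dip(2.0, -0.6)
  ev <- detect_breath_minima(x, fs = fs2)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$time_s, 1.7, tolerance = 1 / fs2)
  # with a permissive separation both survive
  ev2 <- detect_breath_minima(x, fs = fs2, min_separation_s = 0.2)
  expect_equal(nrow(ev2), 2)
})

test_that("gap handling interpolates short gaps and splits at long ones", {
  rec <- simulate_recording(quiet_config(duration_s = 120, fs = 8.7, seed = 2))
  s <- rec$series
  # short gap: 4 samples (~0.46 s) -> interpolated, one segment
  s1 <- s; s1$missing[200:203] <- TRUE; s1$values_C[200:203] <- NA
  sig1 <- breathing_signal(s1)
  expect_equal(length(sig1$provenance$segments), 1)
  expect_true(all(is.finite(sig1$values_z)))
  # long gap: 30 samples (~3.4 s) -> two segments, gap left NA
  s2 <- s; s2$missing[500:529] <- TRUE; s2$values_C[500:529] <- NA
  sig2 <- breathing_signal(s2)
  expect_equal(length(sig2$provenance$segments), 2)
  expect_true(all(is.na(sig2$values_z[500:529])))
  expect_true(all(is.finite(sig2$values_z[-(500:529)])))
})

test_that("the full chain preserves length, timestamps and determinism", {
  rec <- simulate_recording(study_config(seed = 9))
  a <- analyze_series(rec$series)
  b <- analyze_series(rec$series)
  expect_identical(a$events, b$events)
  expect_length(a$signal$values_z, length(rec$series$values_C))
  expect_identical(a$signal$times_s, rec$series$times_s)
  dur <- max(rec$series$times_s)
  expect_true(all(a$events$event_time_s >= 0 & a$events$event_time_s <= dur))
  expect_equal(a$events$depth_z,
               a$signal$values_z[a$events$index])
})
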