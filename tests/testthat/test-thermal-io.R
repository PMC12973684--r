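test_that("nostril temperature extraction reduces masked pixels correctly", {
  uni <- matrix(30, 6, 8)
  mask <- matrix(FALSE, 6, 8); mask[3:4, 4:6] <- TRUE
  expect_equal(extract_nostril_temperature(uni, mask, "mean"), 30)

  th <- matrix(c(30, 32, 34, 36), 2, 2, byrow = TRUE)
  top <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2, byrow = TRUE)
  expect_equal(extract_nostril_temperature(th, top, "mean"), 31)
  expect_equal(extract_nostril_temperature(th, top, "min"), 30)

  expect_true(is.na(extract_nostril_temperature(th, matrix(FALSE, 2, 2))))
  expect_error(extract_nostril_temperature(th, matrix(TRUE, 3, 3)),
               class = "prdi_io_error")
})

test_that("min statistic never increases when the mask grows", {
  set.seed(42)
  for (rep in 1:20) {
    th <- matrix(rnorm(48, 30, 2), 6, 8)
    small <- matrix(FALSE, 6, 8)
    small[sample(48, 5)] <- TRUE
    big <- small
    big[sample(48, 20)] <- TRUE
    expect_lte(extract_nostril_temperature(th, big | small, "min"),
               extract_nostril_temperature(th, small, "min"))
  }
})

test_that("mask downscaling follows nearest-neighbour block mapping", {
  m <- matrix(FALSE, 4, 4); m[2, 3] <- TRUE
  expect_identical(downscale_mask(m, c(4, 4)), m)       # identity
  down <- downscale_mask(m, c(2, 2))
  # brute-force block map: source centre (1.5, 2.5) -> target (1, 2)
  expect_identical(which(down), which(matrix(c(FALSE, FALSE, TRUE, FALSE), 2, 2)))
  expect_equal(sum(down), 1)

  expect_true(all(downscale_mask(matrix(TRUE, 1080, 1440), c(120, 160))))
  expect_error(downscale_mask(matrix(TRUE, 2, 2), c(4, 4)),
               class = "prdi_validation_error")
})

test_that("downscaling is exhaustive against a brute-force oracle", {
  set.seed(7)
  for (rep in 1:10) {
    H <- sample(5:12, 1); W <- sample(5:12, 1)
    h <- sample(2:H, 1); w <- sample(2:W, 1)
    m <- matrix(runif(H * W) < 0.2, H, W)
    got <- downscale_mask(m, c(h, w))
    want <- matrix(FALSE, h, w)
    for (i in seq_len(H)) for (j in seq_len(W)) {
      if (m[i, j])
        want[floor((i - 0.5) * h / H) + 1, floor((j - 0.5) * w / W) + 1] <- TRUE
    }
    expect_identical(got, want)
  }
})

test_that("rendered frames round-trip to the simulated series", {
  rec <- simulate_recording(quiet_config(duration_s = 5, fs = 8))
  stack <- render_frames(rec, thermal_shape = c(24, 32),
                         mask_shape = c(72, 96))
  got <- series_from_frames(stack, statistic = "mean")
  expect_lt(max(abs(got$values_C - rec$series$values_C)), 1e-6)
  expect_equal(got$fs, rec$series$fs, tolerance = 1e-9)
})

test_that("a downscaled high-resolution mask always selects thermal pixels", {
  rec <- simulate_recording(quiet_config(duration_s = 2, fs = 4))
  stack <- render_frames(rec, thermal_shape = c(8, 8), mask_shape = c(64, 64))
  for (m in stack$masks)
    expect_gte(sum(downscale_mask(m, c(8, 8))), 1)
})

test_that("jittered noisy extraction still tracks the true series", {
  cors <- vapply(1:20, function(s) {
    rec <- simulate_recording(quiet_config(duration_s = 6, fs = 8, seed = s))
    stack <- render_frames(rec, thermal_shape = c(20, 24),
                           mask_shape = c(60, 72),
                           pixel_noise_sd_C = 0.1, jitter_px = 3, seed = s)
    got <- series_from_frames(stack)
    stats::cor(got$values_C, rec$series$values_C)
  }, numeric(1))
  expect_gt(min(cors), 0.95)
})

test_that("empty-mask frames become missing samples, others are unaffected", {
  rec <- simulate_recording(quiet_config(duration_s = 2, fs = 8))
  stack <- render_frames(rec, thermal_shape = c(12, 16), mask_shape = c(12, 16))
  stack$masks[[5]] <- matrix(FALSE, 12, 16)
  got <- series_from_frames(stack)
  expect_true(got$missing[5])
  expect_false(any(got$missing[-5]))
  expect_lt(max(abs(got$values_C[-5] - rec$series$values_C[-5])), 1e-6)
})

test_that("sampling rate is estimated from frame timestamps", {
  ts <- (0:49) / 8.7
  th <- replicate(50, matrix(30, 4, 4), simplify = FALSE)
  mk <- replicate(50, matrix(TRUE, 4, 4), simplify = FALSE)
  got <- series_from_frames(frame_stack(ts, th, mk))
  expect_lt(abs(got$fs - 8.7), 1e-9)
  expect_error(series_from_frames(frame_stack(ts[1], th[1], mk[1])),
               class = "prdi_validation_error")
})

test_that("series CSV write/read is an identity to six decimals", {
  rec <- simulate_recording(study_config(seed = 5, duration_s = 30))
  s <- rec$series
  s$missing[10] <- TRUE
  s$values_C[10] <- NA
  path <- tempfile(fileext = ".csv")
  write_series_csv(s, path)
  got <- read_series_csv(path)
  expect_identical(got$recording_id, s$recording_id)
  expect_equal(got$times_s, round(s$times_s, 6))
  expect_equal(got$values_C[-10], round(s$values_C[-10], 6))
  expect_identical(got$missing, s$missing)
})

test_that("annotation and event CSVs round-trip", {
  ann <- data.frame(recording_id = c("a", "a", "b"),
                    regurg_time_s = c(10.5, 42.25, 7.125))
  pa <- tempfile(fileext = ".csv")
  write_annotations_csv(ann, pa)
  got <- read_annotations_csv(pa)
  expect_identical(got$recording_id, ann$recording_id)
  expect_equal(got$regurg_time_s, ann$regurg_time_s)

  ev <- data.frame(recording_id = "a", event_time_s = c(1.5, 3.25),
                   depth_z = c(-2.1, -0.7),
                   label = c("PRDI", "NRI"), predicted = c("PRDI", "NRI"))
  pe <- tempfile(fileext = ".csv")
  write_events_csv(ev, pe, meta = c(config_hash = "deadbeef"))
  got <- read_events_csv(pe)
  expect_equal(got$depth_z, ev$depth_z)
  expect_identical(got$label, ev$label)
  expect_identical(attr(got, "meta")$config_hash, "deadbeef")
})

test_that("frame stacks survive a disk round trip via the manifest", {
  rec <- simulate_recording(quiet_config(duration_s = 1.5, fs = 6))
  stack <- render_frames(rec, thermal_shape = c(10, 12), mask_shape = c(30, 36))
  dir <- tempfile("frames")
  manifest <- write_frames(stack, dir)
  got <- read_frames(file.path(dir, "manifest.csv"))
  expect_equal(got$timestamps_s, round(stack$timestamps_s, 6))
  expect_identical(got$masks, lapply(stack$masks, function(m) m > 0))
  for (i in seq_along(got$thermal))
    expect_equal(got$thermal[[i]], stack$thermal[[i]], tolerance = 1e-6)
})
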