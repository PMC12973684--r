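#' Construct a frame stack
#'
#' A bundle of per-frame thermal matrices (degrees Celsius) and binary nostril
#' masks. Masks may be at a higher (RGB) resolution than the thermal frames;
#' they are aligned by uniform block downscaling at extraction time.
#'
#' @param timestamps_s strictly increasing frame times in seconds.
#' @param thermal list of numeric matrices, one per frame, all the same shape.
#' @param masks list of logical (or 0/1) matrices, one per frame, all the same
#'   shape, at thermal or higher resolution.
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(timestamps_s, thermal, masks) {
  timestamps_s <- as.numeric(timestamps_s)
  if (length(timestamps_s) != length(thermal) ||
      length(thermal) != length(masks))
    fail_validation("timestamps, thermal frames and masks must have equal length")
  if (length(timestamps_s) >= 2 && any(diff(timestamps_s) <= 0))
    fail_validation("timestamps must be strictly increasing")
  dims_t <- unique(lapply(thermal, dim))
  dims_m <- unique(lapply(masks, dim))
  if (length(dims_t) != 1L || length(dims_m) != 1L)
    fail_validation("all thermal frames (and all masks) must share one shape")
  if (!all(vapply(thermal, function(m) all(is.finite(m)), logical(1))))
    fail_validation("thermal values must be finite")
  structure(list(timestamps_s = timestamps_s, thermal = thermal, masks = masks),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  dt <- dim(x$thermal[[1]]); dm <- dim(x$masks[[1]])
  cat(sprintf("<frame_stack: %d frames, thermal %dx%d, masks %dx%d>\n",
              length(x$thermal), dt[1], dt[2], dm[1], dm[2]))
  invisible(x)
}

#' Downscale a binary mask to the thermal grid
#'
#' Nearest-neighbour block mapping: each source pixel centre maps into one
#' target pixel, and a target pixel is `TRUE` iff at least one mapped source
#' pixel is `TRUE`. Identity when shapes already match; upscaling is not
#' supported.
#'
#' @param mask logical or 0/1 matrix at the source (e.g. RGB) resolution.
#' @param target integer vector `c(rows, cols)` of the thermal grid.
#' @return Logical matrix of shape `target`.
#' @examples
#' m <- matrix(FALSE, 4, 4); m[2, 3] <- TRUE
#' downscale_mask(m, c(2, 2))
#' @export
downscale_mask <- function(mask, target) {
  if (!is.matrix(mask)) fail_validation("mask must be a matrix")
  H <- nrow(mask); W <- ncol(mask)
  h <- as.integer(target[1]); w <- as.integer(target[2])
  if (h < 1 || w < 1) fail_validation("target shape must be positive")
  if (H < h || W < w)
    fail_validation("upscaling masks is not supported (source ", H, "x", W,
                    ", target ", h, "x", w, ")")
  if (H == h && W == w) return(mask > 0)
  rmap <- floor(((seq_len(H) - 0.5) * h) / H) + 1L
  cmap <- floor(((seq_len(W) - 0.5) * w) / W) + 1L
  agg <- rowsum(mask * 1, rmap)                 # collapse rows
  agg <- t(rowsum(t(agg), cmap))                # collapse cols
  out <- agg > 0
  dimnames(out) <- NULL
  out
}

#' Extract a nostril temperature from one frame
#'
#' Reduces the thermal values at mask-true pixels to a single statistic.
#' Returns `NA` (the missing sentinel) when the mask selects no pixels; mask
#' and thermal frame must already share a shape (see [downscale_mask()]).
#'
#' @param thermal numeric matrix of temperatures in degrees Celsius.
#' @param mask logical or 0/1 matrix of the same shape.
#' @param statistic one of `"mean"`, `"median"`, `"min"`, `"p10"` (the 10th
#'   percentile, capturing the cooled naris rim).
#' @return A single temperature in degrees Celsius, or `NA_real_`.
#' @export
extract_nostril_temperature <- function(thermal, mask,
                                        statistic = c("mean", "median", "min", "p10")) {
  statistic <- match.arg(statistic)
  if (!is.matrix(thermal) || !is.matrix(mask))
    fail_validation("thermal and mask must be matrices")
  if (!all(dim(thermal) == dim(mask)))
    fail_io("mask shape ", paste(dim(mask), collapse = "x"),
            " does not match thermal shape ",
            paste(dim(thermal), collapse = "x"),
            " (downscale the mask first)")
  vals <- thermal[mask > 0]
  if (length(vals) == 0L) return(NA_real_)
  switch(statistic,
         mean = mean(vals),
         median = stats::median(vals),
         min = min(vals),
         p10 = unname(stats::quantile(vals, 0.10, type = 7)))
}

#' Assemble a temperature series from a frame stack
#'
#' One sample per frame via [extract_nostril_temperature()]; frames whose mask
#' is empty are flagged missing. The sampling rate is estimated as
#' `(n - 1) / (t_last - t_first)`; if frame-interval jitter exceeds 1% the
#' median interval is used instead and a warning is raised.
#'
#' @param stack a [frame_stack()].
#' @param statistic reduction statistic, see [extract_nostril_temperature()].
#' @param recording_id identifier for the resulting series.
#' @return A [temperature_series()].
#' @export
series_from_frames <- function(stack, statistic = "mean",
                               recording_id = "frames") {
  stopifnot(inherits(stack, "frame_stack"))
  nf <- length(stack$thermal)
  if (nf < 2L) fail_validation("need at least 2 frames to form a series")
  dt <- diff(stack$timestamps_s)
  fs <- (nf - 1) / (stack$timestamps_s[nf] - stack$timestamps_s[1])
  if (max(abs(dt - stats::median(dt))) / stats::median(dt) > 0.01) {
    warning("frame interval jitter exceeds 1%; using median interval for fs",
            call. = FALSE)
    fs <- 1 / stats::median(dt)
  }
  tdim <- dim(stack$thermal[[1]])
  vals <- vapply(seq_len(nf), function(i) {
    m <- stack$masks[[i]]
    if (!all(dim(m) == tdim)) m <- downscale_mask(m, tdim)
    extract_nostril_temperature(stack$thermal[[i]], m, statistic)
  }, numeric(1))
  temperature_series(recording_id, stack$timestamps_s, vals,
                     missing = is.na(vals), fs = fs)
}

# elliptical nostril footprint, centred, semi-axes ~ 1/6 of each dimension
ellipse_mask <- function(shape, dr = 0L, dc = 0L) {
  H <- shape[1]; W <- shape[2]
  cy <- (H + 1) / 2 + dr
  cx <- (W + 1) / 2 + dc
  ry <- max(1, H / 6)
  rx <- max(1, W / 6)
  row_d <- (seq_len(H) - cy) / ry
  col_d <- (seq_len(W) - cx) / rx
  outer(row_d^2, col_d^2, `+`) <= 1
}

#' Render synthetic thermal frames and nostril masks for a recording
#'
#' For each sample of the recording, produces a thermal matrix whose
#' nostril-ellipse pixels carry the series temperature (plus optional pixel
#' noise) over a cooler background, and a binary mask marking the same
#' ellipse at (possibly higher) mask resolution. The thermal footprint is the
#' block-downscaled mask, so with zero pixel noise
#' [series_from_frames()] with `statistic = "mean"` recovers the input series
#' exactly.
#'
#' @param recording a [simulate_recording()] result.
#' @param thermal_shape `c(rows, cols)` of the thermal frames (default
#'   `c(120, 160)`).
#' @param mask_shape `c(rows, cols)` of the masks (default `c(1080, 1440)`).
#' @param pixel_noise_sd_C per-pixel thermal noise SD in degrees Celsius.
#' @param jitter_px maximum per-frame integer jitter (at mask resolution) of
#'   the ellipse centre, emulating segmentation wobble.
#' @param background_offset_C background temperature relative to the nostril
#'   value (default -5).
#' @param seed seed for pixel noise and jitter (defaults to the recording's
#'   seed plus 1000).
#' @return A [frame_stack()].
#' @export
render_frames <- function(recording,
                          thermal_shape = c(120L, 160L),
                          mask_shape = c(1080L, 1440L),
                          pixel_noise_sd_C = 0,
                          jitter_px = 0L,
                          background_offset_C = -5,
                          seed = NULL) {
  stopifnot(inherits(recording, "synthetic_recording"))
  thermal_shape <- as.integer(thermal_shape)
  mask_shape <- as.integer(mask_shape)
  if (any(thermal_shape < 4L) || any(mask_shape < 4L))
    fail_validation("frame shapes must be at least 4 pixels in each dimension")
  if (any(mask_shape < thermal_shape))
    fail_validation("mask resolution must be >= thermal resolution")
  check_scalar(pixel_noise_sd_C, "pixel_noise_sd_C", lower = 0)
  check_scalar(jitter_px, "jitter_px", lower = 0)
  set.seed(seed %||% (recording$config$seed + 1000L))

  values <- recording$series$values_C
  n <- length(values)
  base_mask <- ellipse_mask(mask_shape)
  base_down <- downscale_mask(base_mask, thermal_shape)
  thermal <- vector("list", n)
  masks <- vector("list", n)
  for (i in seq_len(n)) {
    if (jitter_px > 0) {
      dr <- sample.int(2L * jitter_px + 1L, 1L) - jitter_px - 1L
      dc <- sample.int(2L * jitter_px + 1L, 1L) - jitter_px - 1L
      m <- ellipse_mask(mask_shape, dr, dc)
      dm <- downscale_mask(m, thermal_shape)
    } else {
      m <- base_mask
      dm <- base_down
    }
    th <- matrix(values[i] + background_offset_C,
                 thermal_shape[1], thermal_shape[2])
    th[dm] <- values[i]
    if (pixel_noise_sd_C > 0)
      th <- th + matrix(stats::rnorm(length(th), 0, pixel_noise_sd_C),
                        nrow(th), ncol(th))
    thermal[[i]] <- th
    masks[[i]] <- m
  }
  frame_stack(recording$series$times_s, thermal, masks)
}

# ---- frame stack on disk ----------------------------------------------------

#' Write and read a frame stack on disk
#'
#' Masks are written as single-channel 0/255 PNG files, thermal frames as
#' headerless CSV matrices, and a `manifest.csv` lists per-frame timestamps
#' and file paths.
#'
#' @param stack a [frame_stack()].
#' @param dir output directory (created if needed).
#' @return `write_frames` returns the manifest path invisibly; `read_frames`
#'   returns a [frame_stack()].
#' @export
write_frames <- function(stack, dir) {
  stopifnot(inherits(stack, "frame_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(stack$thermal)
  tp <- sprintf("thermal_%05d.csv", seq_len(n))
  mp <- sprintf("mask_%05d.png", seq_len(n))
  for (i in seq_len(n)) {
    utils::write.table(stack$thermal[[i]], file.path(dir, tp[i]), sep = ",",
                       row.names = FALSE, col.names = FALSE)
    png::writePNG((stack$masks[[i]] > 0) * 1, file.path(dir, mp[i]))
  }
  manifest <- data.frame(frame = seq_len(n),
                         time_s = sprintf("%.6f", stack$timestamps_s),
                         thermal_path = tp, mask_path = mp)
  path <- file.path(dir, "manifest.csv")
  write_commented_csv(manifest, path)
  invisible(path)
}

#' @rdname write_frames
#' @param manifest path to a `manifest.csv` written by `write_frames`.
#' @export
read_frames <- function(manifest) {
  df <- read_commented_csv(manifest)
  need <- c("time_s", "thermal_path", "mask_path")
  if (!all(need %in% names(df)))
    fail_io("manifest must have columns ", paste(need, collapse = ","))
  dir <- dirname(manifest)
  thermal <- lapply(file.path(dir, df$thermal_path), function(p) {
    if (!file.exists(p)) fail_io("thermal frame not found: ", p)
    as.matrix(utils::read.table(p, sep = ",", header = FALSE))
  })
  thermal <- lapply(thermal, function(m) { dimnames(m) <- NULL; m })
  masks <- lapply(file.path(dir, df$mask_path), function(p) {
    if (!file.exists(p)) fail_io("mask frame not found: ", p)
    img <- png::readPNG(p)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    img > 0.5
  })
  frame_stack(as.numeric(df$time_s), thermal, masks)
}
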