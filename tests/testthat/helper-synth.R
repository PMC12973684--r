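# shared fixtures, built in code

# small clean configuration: no randomness in the waveform
quiet_config <- function(duration_s = 8, fs = 8, seed = 1, ...) {
  sim_config(duration_s = duration_s, fs = fs, noise_sd_C = 0,
             drift_amp_C = 0, amp_jitter_sd = 0, seed = seed, ...)
}

# default study conditions at a given seed
study_config <- function(seed, duration_s = 120, ...) {
  sim_config(duration_s = duration_s, seed = seed, ...)
}

# pooled labeled events from n simulated recordings
pooled_events <- function(n_rec, seed0 = 100, duration_s = 120, ...) {
  out <- NULL
  for (r in seq_len(n_rec)) {
    rec <- simulate_recording(study_config(seed = seed0 + r,
                                           duration_s = duration_s, ...))
    res <- analyze_series(rec$series)
    ev <- label_events(res$events, build_windows(rec$regurg_times_s))
    out <- if (is.null(out)) ev else rbind(out, ev)
  }
  out
}

# random labeled-event instance for ROC/sweep property tests
random_instance <- function(n_max = 30) {
  npos <- sample(1:(n_max %/% 2), 1)
  nneg <- sample(1:(n_max %/% 2), 1)
  # draw from a small value grid so ties occur regularly
  depths <- round(c(stats::rnorm(npos, -2, 0.8), stats::rnorm(nneg, -1, 0.8)), 1)
  data.frame(depth_z = depths,
             label = c(rep("PRDI", npos), rep("NRI", nneg)))
}

# tie-aware concordant-pair fraction: independent AUC oracle
auc_pair_count <- function(events) {
  pd <- events$depth_z[events$label == "PRDI"]
  nd <- events$depth_z[events$label == "NRI"]
  s <- 0
  for (p in pd) s <- s + sum(p < nd) + 0.5 * sum(p == nd)
  s / (length(pd) * length(nd))
}
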