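# shared fixture builders; everything is generated in code

FS <- 32

time_axis <- function(duration_s, fs = FS) seq(0, duration_s - 1 / fs,
                                               by = 1 / fs)

sine <- function(freq_hz, duration_s, fs = FS, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq_hz * time_axis(duration_s, fs) + phase)
}

# small recording wrapper with sensible defaults
make_recording <- function(acc, gyr = acc, fs = FS, ...) {
  imu_recording(acc, gyr, sampling_rate_hz = fs, ...)
}

# brute-force moving percentile (type-7 quantile per centred window)
brute_moving_percentile <- function(x, window_s, rate_hz, p = 95) {
  w <- round(window_s * rate_hz)
  left <- floor((w - 1) / 2)
  right <- w - 1 - left
  n <- length(x)
  vapply(seq_len(n), function(i) {
    unname(quantile(x[max(1, i - left):min(n, i + right)], p / 100,
                    type = 7))
  }, numeric(1))
}

# brute-force extraction of TRUE runs with duration in [min_s, max_s]
brute_mask_events <- function(mask, rate_hz, min_s = 10, max_s = 90) {
  out <- data.frame(onset_s = numeric(0), duration_s = numeric(0))
  i <- 1L
  n <- length(mask)
  while (i <= n) {
    if (mask[i]) {
      j <- i
      while (j < n && mask[j + 1L]) j <- j + 1L
      len_s <- (j - i + 1L) / rate_hz
      if (len_s >= min_s && len_s <= max_s)
        out <- rbind(out, data.frame(onset_s = (i - 1L) / rate_hz,
                                     duration_s = len_s))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# brute-force gap-tolerant matcher over label vectors
brute_gap_confusion <- function(det, ref, g) {
  n <- length(det)
  tp <- fp <- fn <- 0L
  for (i in seq_len(n)) {
    win <- max(1, i - g):min(n, i + g)
    if (det[i]) {
      if (any(ref[win])) tp <- tp + 1L else fp <- fp + 1L
    }
    if (ref[i] && !any(det[win])) fn <- fn + 1L
  }
  list(tp = tp, fp = fp, fn = fn, tn = n - tp - fp - fn)
}

# labelled breath track straight from logical vectors (4-s breaths)
track_from_labels <- function(det, ref) {
  n <- length(det)
  tr <- segment_breaths(seq(0, by = 4, length.out = n + 1))
  tr$re_positive <- det
  tr$ref_positive <- ref
  tr
}

run_pipeline_f1 <- function(preset, duration_s = 3600, seed = 7, gap = 1) {
  sim <- simulate_recording(scenario_presets(preset, duration_s = duration_s,
                                             seed = seed))
  det <- detect_events(sim$recording)
  track <- segment_breaths(sim$ground_truth$breath_nadir_times_s)
  track <- label_breaths(track, det, sim$ground_truth$events)
  list(det = det, counts = gap_tolerant_confusion(track, gap),
       metrics = binary_metrics(gap_tolerant_confusion(track, gap)))
}
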