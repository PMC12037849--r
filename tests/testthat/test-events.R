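# constructed RA profile: steady level with a fractional dip
ra_with_dip <- function(level = 20, dip_frac = 0.6, dip_on = 120,
                        dip_len = 20, duration = 300, fs = FS) {
  tt <- time_axis(duration, fs)
  ra <- rep(level, length(tt))
  ra[tt >= dip_on & tt < dip_on + dip_len] <- level * (1 - dip_frac)
  ra
}

test_that("moving percentile matches a brute-force oracle", {
  x <- c(rep(0, 100), 100, rep(0, 100))
  expect_equal(moving_percentile(x, 3, 32),
               brute_moving_percentile(x, 3, 32))
  set.seed(8)
  for (i in 1:5) {
    y <- rnorm(200 + i * 37)
    ws <- sample(c(0.25, 1, 3), 1)
    expect_equal(moving_percentile(y, ws, 32, 95),
                 brute_moving_percentile(y, ws, 32, 95))
  }
  expect_equal(moving_percentile(rep(4, 100), 3, 32), rep(4, 100))
  ramp <- seq_len(500) / 10
  expect_true(all(diff(moving_percentile(ramp, 3, 32)) >= 0))
  expect_error(moving_percentile(1:10, -1, 32), "positive")
  expect_error(moving_percentile(1:10, 0.01, 32), ">= 2")
})

test_that("amplitude events follow the dual-envelope criterion", {
  # constant-amplitude breathing: envelopes overlap, no events
  set.seed(9)
  steady <- abs(20 * sin(2 * pi * 0.47 * time_axis(300))) + rnorm(9600, 0, 0.3)
  expect_equal(nrow(amplitude_events(steady, 32)$events), 0L)

  # 60% dip for 20 s -> exactly one event near the true onset
  res <- amplitude_events(ra_with_dip(dip_frac = 0.6, dip_len = 20), 32)
  expect_equal(nrow(res$events), 1L)
  expect_lt(abs(res$events$onset_s - 120), 3)
  expect_true(res$events$duration_s >= 10 && res$events$duration_s <= 90)

  # below minimum duration
  expect_equal(nrow(amplitude_events(ra_with_dip(dip_len = 5), 32)$events),
               0L)
  # prolonged total dropout: the slow envelope adapts within half its
  # window, so signal loss yields at most short edge transients and never
  # an event spanning the loss
  drop <- amplitude_events(
    ra_with_dip(dip_frac = 1, dip_on = 120, dip_len = 120, duration = 500),
    32)$events
  expect_true(all(drop$duration_s <= 20))
  expect_false(any(drop$onset_s < 140 & drop$onset_s + drop$duration_s > 220))
  # the 90-s cap itself: an overlong condition run is discarded entirely,
  # not truncated
  long_mask <- rep(c(FALSE, TRUE, FALSE), times = 32 * c(30, 100, 30))
  expect_equal(nrow(imuapnea:::mask_runs_to_events(long_mask, 32, 10, 90)),
               0L)
  ok_mask <- rep(c(FALSE, TRUE, FALSE), times = 32 * c(30, 89, 30))
  expect_equal(imuapnea:::mask_runs_to_events(ok_mask, 32, 10, 90)$duration_s,
               89)
})

test_that("amplitude criterion is scale invariant and depth monotone", {
  base <- ra_with_dip(dip_frac = 0.5, dip_len = 25)
  ev0 <- amplitude_events(base, 32)$events
  for (a in c(0.01, 3, 1000)) {
    expect_equal(amplitude_events(a * base, 32)$events, ev0)
  }
  # deepening the dip never removes the event
  for (frac in c(0.5, 0.7, 0.9, 0.99)) {
    ev <- amplitude_events(ra_with_dip(dip_frac = frac, dip_len = 25),
                           32)$events
    expect_equal(nrow(ev), 1L)
  }
})

test_that("event extraction equals the brute-force mask-run oracle", {
  cfg <- detection_config()
  set.seed(10)
  for (i in 1:8) {
    ra <- abs(rnorm(3000, 10, 4)) + 1
    # random dips of random length
    for (k in 1:3) {
      on <- sample(2500, 1)
      len <- sample(200:1500, 1)
      ra[on:min(3000, on + len)] <- ra[on:min(3000, on + len)] * 0.1
    }
    res <- amplitude_events(ra, 32, cfg)
    mask <- res$fast < cfg$reduction_factor * res$slow
    expect_identical(res$suppression, mask)
    expect_equal(res$events[, c("onset_s", "duration_s")],
                 brute_mask_events(mask, 32), ignore_attr = TRUE)
  }
})

test_that("frequency events honour the upper envelope and suppression", {
  # steady breathing frequency: no events
  set.seed(11)
  rf_steady <- rep(0.25, 9600) + rnorm(9600, 0, 0.002)
  none <- frequency_events(rf_steady, rep(FALSE, 9600), rate_hz = 32)
  expect_equal(nrow(none$events), 0L)

  # RF drops 0.25 -> 0.12 for 20 s, no amplitude suppression; the drop is
  # shorter than the 30-s envelope window, so the upper envelope holds and
  # one event is emitted near the true onset
  tt <- time_axis(300)
  rf <- ifelse(tt >= 120 & tt < 140, 0.12, 0.25)
  one <- frequency_events(rf, rep(FALSE, length(rf)), rate_hz = 32)
  expect_equal(nrow(one$events), 1L)
  expect_lt(abs(one$events$onset_s - 120), 5)

  # identical drop fully suppressed by the amplitude mask
  sup <- tt >= 110 & tt < 160
  expect_equal(nrow(frequency_events(rf, sup, rate_hz = 32)$events), 0L)

  # suppression guarantee: no frequency event overlaps an active
  # amplitude-condition sample
  part <- tt >= 128 & tt < 131
  evp <- frequency_events(rf, part, rate_hz = 32)$events
  for (i in seq_len(nrow(evp))) {
    idx <- which(tt >= evp$onset_s[i] & tt < evp$onset_s[i] + evp$duration_s[i])
    expect_false(any(part[idx]))
  }
  expect_error(frequency_events(rf, rep(FALSE, 10), rate_hz = 32),
               "time base")
})

test_that("detect_events runs both channels and reports hourly indices", {
  # 30-min recording with 6 deep apneas -> index = count / 0.5 h
  ev <- data.frame(onset_s = seq(120, by = 280, length.out = 6),
                   duration_s = 20, depth_fraction = 0.95, type = "apnea",
                   freq_drop_fraction = 0)
  sim <- simulate_recording(scenario_spec(duration_s = 1800,
                                          event_schedule = ev, seed = 2))
  det <- detect_events(sim$recording)
  expect_equal(det$indices$monitoring_hours, 0.5)
  expect_equal(det$indices$raei_acc * 0.5,
               round(det$indices$raei_acc * 0.5))
  expect_true(abs(det$indices$raei_acc - 12) <= 4)     # 6 events / 0.5 h
  expect_true(abs(det$indices$raei_gyro - 12) <= 4)
  expect_true(all(det$events$duration_s >= 10 & det$events$duration_s <= 90))

  short <- make_recording(matrix(rnorm(32 * 60 * 3), ncol = 3))
  expect_error(detect_events(short), "5 minutes")
})

test_that("events fully inside bridged gaps are discarded", {
  # event-free breathing with a 30-s gap: bridging flat-lines the carrier,
  # which would look like an apnea, but the span is known to be bridged
  tt <- time_axis(900)
  carrier <- 20 * sin(2 * pi * 0.25 * tt)
  sig <- cbind(carrier, 0.5 * carrier, 0.25 * carrier)
  gap <- tt >= 400 & tt < 430
  in_span <- function(ev) ev$onset_s >= 399 & ev$onset_s + ev$duration_s <= 431

  # positive control: an actual 30-s flatline (no gap mask) is detected
  flat <- sig
  flat[gap, ] <- 0
  det_flat <- detect_events(imu_recording(flat, flat, 32))
  amp_flat <- det_flat$events[det_flat$events$source == "amplitude", ]
  expect_gt(sum(in_span(amp_flat)), 0)

  # same span flagged as a gap: bridged, and nothing detected inside it
  rec <- imu_recording(sig, sig, 32, gap_mask = gap)
  det <- detect_events(rec)
  expect_equal(sum(in_span(det$events)), 0)
})

test_that("detected events export as a readable annotation set", {
  ev <- data.frame(onset_s = 100, duration_s = 20, depth_fraction = 0.95,
                   type = "apnea", freq_drop_fraction = 0)
  sim <- simulate_recording(scenario_spec(duration_s = 400,
                                          event_schedule = ev, seed = 3))
  det <- detect_events(sim$recording)
  ann <- events_as_annotations(det)
  expect_true(all(ann$type == "respiratory_event"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_annotations(ann, f)
  back <- read_annotations(f)
  expect_equal(nrow(back), nrow(ann))
  expect_true(all(c("source", "channel") %in% names(back)))
})
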