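#' Scenario specification for the synthetic IMU generator
#'
#' Describes an overnight abdomen-worn IMU recording: a quasi-sinusoidal
#' respiratory carrier (~14 cycles/min with per-cycle lognormal period
#' jitter and slow amplitude drift), projected onto a posture-dependent
#' axis direction, with scheduled apnea/hypopnea episodes and out-of-band
#' contaminants (pulse 0.7--2.5 Hz, movement bursts 2--4 Hz, cardiac
#' vibration >= 8 Hz, white noise).
#'
#' @param duration_s recording length, seconds.
#' @param sampling_rate_hz sampling rate (default 32).
#' @param breath_rate_cpm mean respiratory rate, cycles/min (default 14,
#'   the typical adult value in suspected-apnea cohorts).
#' @param breath_amplitude_mg,breath_amplitude_dps respiratory amplitude of
#'   the acceleration / gyroscope carrier (defaults 20 mG, 20 dps — the
#'   middle of the 10--30 range an abdomen-worn sensor sees).
#' @param cycle_jitter_cv per-cycle lognormal coefficient of variation of
#'   the breathing period (default 0.05).
#' @param amplitude_drift_frac slow amplitude drift fraction (default 0.2,
#'   i.e. +/-20% over minutes).
#' @param respiratory_axis_schedule data.frame `start_s, ux, uy, uz`
#'   (unit vectors) giving the respiratory movement direction over time;
#'   default is a fixed oblique direction.
#' @param event_schedule data.frame `onset_s, duration_s, depth_fraction,
#'   type, freq_drop_fraction`; `type` in `apnea` (depth >= 0.9),
#'   `hypopnea` (depth in (0.3, 0.9)), or `freq_only` (depth 0, frequency
#'   reduction only — the obstructive flavour where respiratory effort
#'   preserves amplitude). Events must not overlap and must last >= 10 s.
#' @param pulse_band_amp,movement_band_amp,hf_band_amp,white_sd noise
#'   amplitudes (mG / dps).
#' @param seed integer seed; all randomness derives from it.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(duration_s = 3600, sampling_rate_hz = 32,
                          breath_rate_cpm = 14, breath_amplitude_mg = 20,
                          breath_amplitude_dps = 20, cycle_jitter_cv = 0.05,
                          amplitude_drift_frac = 0.2,
                          respiratory_axis_schedule = NULL,
                          event_schedule = NULL,
                          pulse_band_amp = 2, movement_band_amp = 3,
                          hf_band_amp = 1, white_sd = 0.5, seed = 1L) {
  if (is.null(respiratory_axis_schedule))
    respiratory_axis_schedule <- data.frame(
      start_s = 0, ux = 0.2, uy = 0.4, uz = sqrt(1 - 0.2^2 - 0.4^2))
  nrm <- sqrt(respiratory_axis_schedule$ux^2 +
              respiratory_axis_schedule$uy^2 +
              respiratory_axis_schedule$uz^2)
  if (any(abs(nrm - 1) > 1e-6))
    stop("respiratory axis vectors must be unit-norm")
  if (is.null(event_schedule))
    event_schedule <- data.frame(onset_s = numeric(0),
                                 duration_s = numeric(0),
                                 depth_fraction = numeric(0),
                                 type = character(0),
                                 freq_drop_fraction = numeric(0))
  ev <- event_schedule
  if (nrow(ev)) {
    if (any(ev$duration_s < 10))
      stop("scheduled events must last >= 10 s")
    bad_type <- setdiff(unique(ev$type), c("apnea", "hypopnea", "freq_only"))
    if (length(bad_type))
      stop("unknown event type(s): ", paste(bad_type, collapse = ", "))
    if (any(ev$type == "apnea" & ev$depth_fraction < 0.9))
      stop("apnea events need depth_fraction >= 0.9")
    if (any(ev$type == "hypopnea" & (ev$depth_fraction <= 0.3 |
                                     ev$depth_fraction >= 0.9)))
      stop("hypopnea events need depth_fraction in (0.3, 0.9)")
    o <- order(ev$onset_s)
    ev <- ev[o, , drop = FALSE]
    if (nrow(ev) > 1L &&
        any(ev$onset_s[-1L] < (ev$onset_s + ev$duration_s)[-nrow(ev)]))
      stop("scheduled events must not overlap")
    if (any(ev$onset_s + ev$duration_s > duration_s))
      stop("scheduled events must fit within the recording")
  }
  structure(list(duration_s = duration_s,
                 sampling_rate_hz = sampling_rate_hz,
                 breath_rate_cpm = breath_rate_cpm,
                 breath_amplitude_mg = breath_amplitude_mg,
                 breath_amplitude_dps = breath_amplitude_dps,
                 cycle_jitter_cv = cycle_jitter_cv,
                 amplitude_drift_frac = amplitude_drift_frac,
                 respiratory_axis_schedule = respiratory_axis_schedule,
                 event_schedule = ev,
                 pulse_band_amp = pulse_band_amp,
                 movement_band_amp = movement_band_amp,
                 hf_band_amp = hf_band_amp,
                 white_sd = white_sd,
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

# Breathing phase with per-cycle period jitter and optional per-sample
# frequency scaling; returns phase plus the nadir times (phase = 3*pi/2
# mod 2*pi, where sin(phase) is minimal).
breathing_phase <- function(n, fs, base_f, jitter_cv, freq_scale) {
  sdlog <- sqrt(log(1 + jitter_cv^2))
  dt <- 1 / fs
  phase <- numeric(n)
  jit <- rlnorm(1, -sdlog^2 / 2, sdlog)
  next_cycle <- 2 * pi
  # generous pre-draw of per-cycle jitter factors
  pool <- rlnorm(ceiling(n * dt * base_f * 1.5) + 8, -sdlog^2 / 2, sdlog)
  k <- 1L
  for (i in 2:n) {
    phase[i] <- phase[i - 1] + 2 * pi * base_f * jit * freq_scale[i] * dt
    if (phase[i] >= next_cycle) {
      k <- k + 1L
      jit <- pool[min(k, length(pool))]
      next_cycle <- next_cycle + 2 * pi
    }
  }
  # nadir times: linear-interpolated crossings of 3*pi/2 + 2*pi*m
  if (max(phase) < 1.5 * pi) return(list(phase = phase,
                                         nadir_times_s = numeric(0)))
  targets <- seq(1.5 * pi, max(phase), by = 2 * pi)
  nad <- approx(phase, (seq_len(n) - 1) * dt, xout = targets,
                ties = "ordered")$y
  list(phase = phase, nadir_times_s = nad[!is.na(nad)])
}

# smooth 0..1 activation of scheduled events with raised-cosine edges
event_activation <- function(tt, onset, duration, ramp_s = 1.5) {
  a <- numeric(length(tt))
  for (i in seq_along(onset)) {
    t0 <- onset[i]; t1 <- onset[i] + duration[i]
    up <- tt >= t0 & tt < t0 + ramp_s
    on <- tt >= t0 + ramp_s & tt < t1 - ramp_s
    dn <- tt >= t1 - ramp_s & tt < t1
    a[up] <- pmax(a[up], (1 - cos(pi * (tt[up] - t0) / ramp_s)) / 2)
    a[on] <- 1
    a[dn] <- pmax(a[dn], (1 + cos(pi * (tt[dn] - (t1 - ramp_s)) / ramp_s)) / 2)
  }
  a
}

# one tri-axial channel: carrier * amplitude envelope projected on the
# axis schedule, plus out-of-band contaminants
synth_channel <- function(spec, amp0, sub_seed) {
  set.seed(sub_seed)
  fs <- spec$sampling_rate_hz
  n <- round(spec$duration_s * fs)
  tt <- (seq_len(n) - 1) / fs
  ev <- spec$event_schedule
  freq_scale <- rep(1, n)
  depth_mod <- rep(1, n)
  if (nrow(ev)) {
    for (i in seq_len(nrow(ev))) {
      act <- event_activation(tt, ev$onset_s[i], ev$duration_s[i])
      depth_mod <- depth_mod * (1 - ev$depth_fraction[i] * act)
      freq_scale <- freq_scale * (1 - ev$freq_drop_fraction[i] * act)
    }
  }
  bp <- breathing_phase(n, fs, spec$breath_rate_cpm / 60,
                        spec$cycle_jitter_cv, freq_scale)
  drift_period <- runif(1, 240, 420)
  drift <- 1 + spec$amplitude_drift_frac *
    sin(2 * pi * tt / drift_period + runif(1, 0, 2 * pi))
  carrier <- amp0 * drift * depth_mod * sin(bp$phase)
  # posture: piecewise-constant unit direction
  sched <- spec$respiratory_axis_schedule
  seg <- findInterval(tt, sched$start_s)
  seg[seg < 1L] <- 1L
  dir <- cbind(sched$ux[seg], sched$uy[seg], sched$uz[seg])
  sig <- dir * carrier
  # contaminants (all outside the 0.13-0.7 Hz respiratory band)
  pulse_f <- runif(1, 0.9, 1.4)
  pulse <- spec$pulse_band_amp * sin(2 * pi * pulse_f * tt + runif(1, 0, 6))
  hf <- spec$hf_band_amp * sin(2 * pi * 9.2 * tt + runif(1, 0, 6))
  # sparse 2-4 Hz movement bursts (~1 per 2 min, 2-4 s long)
  burst <- numeric(n)
  n_bursts <- max(0L, round(spec$duration_s / 120))
  if (n_bursts > 0L && spec$movement_band_amp > 0) {
    b_on <- runif(n_bursts, 0, spec$duration_s - 5)
    b_len <- runif(n_bursts, 2, 4)
    b_f <- runif(n_bursts, 2, 4)
    for (i in seq_len(n_bursts)) {
      w <- tt >= b_on[i] & tt < b_on[i] + b_len[i]
      burst[w] <- burst[w] +
        spec$movement_band_amp * sin(2 * pi * b_f[i] * tt[w])
    }
  }
  for (j in 1:3) {
    sig[, j] <- sig[, j] + (pulse + hf + burst) * runif(1, 0.5, 1) +
      rnorm(n, 0, spec$white_sd)
  }
  list(signal = sig, nadir_times_s = bp$nadir_times_s)
}

#' Simulate an overnight IMU recording with ground truth
#'
#' Generates acceleration and gyroscope channels from the same event and
#' posture schedule but with independent noise realizations and breathing
#' jitter (the gyroscope sees the same breaths through its own coupling).
#' Deterministic given `spec$seed`; sub-seeds for the two channels are
#' derived from it.
#'
#' @param spec a [scenario_spec()].
#' @return List with `recording` (an [imu_recording()]) and `ground_truth`:
#'   `events` (an [annotation_set()]; scheduled apneas map to
#'   `central_apnea`, hypopneas to `hypopnea`, frequency-only events to
#'   `obstructive_apnea`), `breath_nadir_times_s` (acceleration-channel
#'   carrier nadirs), and `posture_change_times_s`.
#' @export
simulate_recording <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  acc <- synth_channel(spec, spec$breath_amplitude_mg,
                       sub_seed = spec$seed * 1000L + 1L)
  gyr <- synth_channel(spec, spec$breath_amplitude_dps,
                       sub_seed = spec$seed * 1000L + 2L)
  rec <- imu_recording(acc$signal, gyr$signal,
                       sampling_rate_hz = spec$sampling_rate_hz,
                       device_label = "generic")
  ev <- spec$event_schedule
  truth_events <- annotation_set(
    if (nrow(ev)) data.frame(
      onset_s = ev$onset_s, duration_s = ev$duration_s,
      type = c(apnea = "central_apnea", hypopnea = "hypopnea",
               freq_only = "obstructive_apnea")[ev$type])
    else NULL,
    total_time_s = spec$duration_s)
  list(recording = rec,
       ground_truth = list(
         events = truth_events,
         breath_nadir_times_s = acc$nadir_times_s,
         posture_change_times_s =
           spec$respiratory_axis_schedule$start_s[-1L]),
       spec = spec)
}

# evenly spaced onsets with uniform jitter, non-overlapping by construction
spaced_onsets <- function(k, duration_s, event_len_s, seed, margin_s = 25) {
  set.seed(seed)
  slot <- duration_s / k
  jitter_max <- pmax(0, slot - event_len_s - margin_s)
  (seq_len(k) - 1) * slot + margin_s / 2 + runif(k, 0, jitter_max)
}

#' Named scenario presets
#'
#' `"normal_night"`: event-free breathing at default noise.
#' `"moderate_sa"`: ~20 events/h (mix of apneas, hypopneas and
#' frequency-only obstructive events). `"severe_sa"`: ~45 events/h.
#' `"posture_switcher"`: the moderate event load plus 4 posture rotations
#' per hour. `"noisy"`: event-free with all noise bands at high amplitude.
#'
#' @param name preset name.
#' @param duration_s recording length, seconds (default 3600).
#' @param seed integer seed.
#' @return A [scenario_spec()].
#' @export
scenario_presets <- function(name, duration_s = 3600, seed = 1L) {
  hours <- duration_s / 3600
  mixed_schedule <- function(per_hour, sched_seed) {
    k <- round(per_hour * hours)
    types <- rep(c("apnea", "hypopnea", "apnea", "hypopnea", "freq_only"),
                 length.out = k)
    set.seed(sched_seed)
    dur <- runif(k, 15, 30)
    onsets <- spaced_onsets(k, duration_s, max(dur), sched_seed * 7L + 3L)
    data.frame(
      onset_s = onsets, duration_s = dur,
      depth_fraction = ifelse(types == "apnea", 0.95,
                              ifelse(types == "hypopnea", 0.6, 0)),
      type = types,
      freq_drop_fraction = ifelse(types == "freq_only", 0.45, 0))
  }
  rotations <- function(per_hour) {
    k <- round(per_hour * hours)
    # successive 90-degree-ish rotations of the respiratory direction
    dirs <- rbind(c(0.2, 0.4, sqrt(1 - 0.2)),
                  c(sqrt(1 - 0.2), 0.2, 0.4),
                  c(0.4, sqrt(1 - 0.2), 0.2),
                  c(0.0, sqrt(0.5), sqrt(0.5)),
                  c(sqrt(0.5), 0.0, sqrt(0.5)))
    i <- rep_len(seq_len(nrow(dirs)), k + 1L)
    data.frame(start_s = c(0, seq_len(k) * duration_s / (k + 1)),
               ux = dirs[i, 1], uy = dirs[i, 2], uz = dirs[i, 3])
  }
  switch(name,
    normal_night = scenario_spec(duration_s = duration_s, seed = seed),
    moderate_sa = scenario_spec(duration_s = duration_s, seed = seed,
                                event_schedule = mixed_schedule(20,
                                                                seed + 100L)),
    severe_sa = scenario_spec(duration_s = duration_s, seed = seed,
                              event_schedule = mixed_schedule(45,
                                                              seed + 200L)),
    posture_switcher = scenario_spec(
      duration_s = duration_s, seed = seed,
      event_schedule = mixed_schedule(20, seed + 100L),
      respiratory_axis_schedule = rotations(4)),
    noisy = scenario_spec(duration_s = duration_s, seed = seed,
                          pulse_band_amp = 8, movement_band_amp = 12,
                          hf_band_amp = 5, white_sd = 2),
    stop("unknown preset: ", name,
         " (use normal_night, moderate_sa, severe_sa, posture_switcher, ",
         "noisy)"))
}
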