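#' Detection configuration
#'
#' Named constants of the event detector, kept in one object so every
#' threshold is overridable in one place.
#'
#' @param reduction_factor envelope ratio threshold: a sample is
#'   event-candidate when `fast < reduction_factor * slow` (amplitude) or
#'   `RF_t < reduction_factor * upper_envelope` (frequency). 0.7 encodes
#'   the ">30% reduction" criterion.
#' @param min_duration_s,max_duration_s accepted event duration bounds,
#'   seconds. Runs shorter than `min_duration_s` are ignored; runs longer
#'   than `max_duration_s` are discarded entirely (prolonged signal loss,
#'   not an event).
#' @param fast_window_s,slow_window_s moving-percentile window widths for
#'   the fast and slow amplitude envelopes, seconds.
#' @param percentile envelope percentile (95 rather than the maximum, to
#'   resist transient noise spikes).
#' @param epoch_s dominant-axis selection epoch, seconds.
#' @return A `detection_config` list.
#' @export
detection_config <- function(reduction_factor = 0.7, min_duration_s = 10,
                             max_duration_s = 90, fast_window_s = 3,
                             slow_window_s = 30, percentile = 95,
                             epoch_s = 30) {
  structure(list(reduction_factor = reduction_factor,
                 min_duration_s = min_duration_s,
                 max_duration_s = max_duration_s,
                 fast_window_s = fast_window_s,
                 slow_window_s = slow_window_s,
                 percentile = percentile,
                 epoch_s = epoch_s),
            class = "detection_config")
}

#' Moving percentile over a centred time window
#'
#' Per-sample percentile of the values inside a centred window of
#' `window_s` seconds, truncated at the series boundaries (output length
#' equals input length). Percentiles use R's default quantile definition
#' (type 7).
#'
#' @param series numeric vector.
#' @param window_s window width in seconds (`window_s * rate_hz >= 2`).
#' @param rate_hz sampling rate.
#' @param percentile percentile in (0, 100], default 95.
#' @return Numeric vector, same length as `series`.
#' @export
moving_percentile <- function(series, window_s, rate_hz, percentile = 95) {
  if (!is.numeric(window_s) || window_s <= 0)
    stop("window_s must be positive")
  w <- round(window_s * rate_hz)
  if (w < 2) stop("window_s * rate_hz must be >= 2")
  .moving_percentile_cpp(as.numeric(series), as.integer(w),
                         percentile / 100)
}

# maximal TRUE runs of mask with duration in [min_s, max_s]; runs longer
# than max_s are dropped, not truncated
mask_runs_to_events <- function(mask, rate_hz, min_s, max_s) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths / rate_hz >= min_s) &
    (r$lengths / rate_hz <= max_s)
  data.frame(onset_s = (starts[keep] - 1L) / rate_hz,
             duration_s = r$lengths[keep] / rate_hz)
}

#' Detect respiratory events from the amplitude series
#'
#' Computes the fast (3 s) and slow (30 s) 95th-percentile envelopes of
#' `RA_t` and flags samples where the fast envelope falls more than 30%
#' below the slow envelope. Maximal runs of flagged samples lasting 10 to
#' 90 s become respiratory events; the per-sample condition mask is also
#' returned because it suppresses the frequency pathway (Step 5). The
#' criterion is a self-ratio, so it is invariant to overall signal scale.
#'
#' @param ra numeric `RA_t` vector (from [respiratory_amplitude()]).
#' @param rate_hz sampling rate.
#' @param config a [detection_config()].
#' @return List with `events` (data.frame `onset_s`, `duration_s`),
#'   `suppression` (logical per-sample condition mask), and the `fast` and
#'   `slow` envelopes.
#' @export
amplitude_events <- function(ra, rate_hz, config = detection_config()) {
  fast <- moving_percentile(ra, config$fast_window_s, rate_hz,
                            config$percentile)
  slow <- moving_percentile(ra, config$slow_window_s, rate_hz,
                            config$percentile)
  mask <- fast < config$reduction_factor * slow
  ev <- mask_runs_to_events(mask, rate_hz, config$min_duration_s,
                            config$max_duration_s)
  if (nrow(ev)) ev$source <- "amplitude"
  else ev$source <- character(0)
  list(events = ev, suppression = mask, fast = fast, slow = slow)
}

#' Detect respiratory events from the frequency series
#'
#' Flags samples where `RF_t` drops more than 30% below its own upper
#' envelope (95th percentile, 30-s window), excluding samples where the
#' amplitude condition mask is active — an amplitude-detected event must
#' not be double counted by the frequency pathway. Runs of 10--90 s become
#' events.
#'
#' @param rf a `respiratory_frequency` object (or numeric RF_t vector).
#' @param suppression logical per-sample mask from [amplitude_events()]
#'   of the same channel.
#' @param rate_hz sampling rate (required when `rf` is a plain vector).
#' @param config a [detection_config()].
#' @return List with `events` (data.frame) and the `upper` envelope.
#' @export
frequency_events <- function(rf, suppression, rate_hz = NULL,
                             config = detection_config()) {
  if (inherits(rf, "respiratory_frequency")) {
    values <- rf$values
    rate_hz <- rf$sampling_rate_hz
  } else {
    values <- as.numeric(rf)
    if (is.null(rate_hz)) stop("rate_hz required for plain vectors")
  }
  if (length(suppression) != length(values))
    stop("suppression mask and RF series must share a time base")
  upper <- moving_percentile(values, config$slow_window_s, rate_hz,
                             config$percentile)
  mask <- (values < config$reduction_factor * upper) & !suppression
  ev <- mask_runs_to_events(mask, rate_hz, config$min_duration_s,
                            config$max_duration_s)
  if (nrow(ev)) ev$source <- "frequency"
  else ev$source <- character(0)
  list(events = ev, upper = upper)
}

# Drop events lying entirely inside a bridged gap span. Spans are padded
# by pad_s (the fast-envelope window) because the condition mask smears a
# little past the bridged samples.
drop_bridged_events <- function(ev, spans, pad_s = 0) {
  if (!nrow(ev) || is.null(spans) || !nrow(spans)) return(ev)
  inside <- vapply(seq_len(nrow(ev)), function(i) {
    any(ev$onset_s[i] >= spans$onset_s - pad_s &
        ev$onset_s[i] + ev$duration_s[i] <=
          spans$onset_s + spans$duration_s + pad_s)
  }, logical(1))
  ev[!inside, , drop = FALSE]
}

#' Run the full detector on a recording
#'
#' Applies the five processing steps independently to the acceleration and
#' gyroscope channels: per-axis band-pass, respiratory amplitude,
#' dominant-axis waveform and respiratory frequency, amplitude-based event
#' detection, and suppressed frequency-based event detection. Gap samples
#' are linearly bridged before filtering and events falling entirely
#' within bridged spans are discarded. Hourly indices use the recording
#' duration as monitoring time.
#'
#' @param recording an [imu_recording()], at least 5 minutes long.
#' @param config a [detection_config()].
#' @param spec optional [filter_spec()]; defaults to the standard
#'   0.13--0.7 Hz design at the recording's sampling rate.
#' @return A `detection_result`: list with `events` (data.frame `onset_s`,
#'   `duration_s`, `source`, `channel`), `indices` (list `raei_acc`,
#'   `rfei_acc`, `raei_gyro`, `rfei_gyro`, `monitoring_hours`), and
#'   per-channel intermediates (`ra`, `fast`, `slow`, `rf`, `suppression`).
#' @examples
#' \donttest{
#' sim <- simulate_recording(scenario_presets("moderate_sa",
#'                                            duration_s = 1800, seed = 1))
#' det <- detect_events(sim$recording)
#' det$indices$raei_acc
#' }
#' @export
detect_events <- function(recording, config = detection_config(),
                          spec = NULL) {
  stopifnot(inherits(recording, "imu_recording"))
  if (recording$duration_s < 300)
    stop("recording shorter than 5 minutes; envelopes would be unstable")
  fs <- recording$sampling_rate_hz
  if (is.null(spec)) spec <- filter_spec(fs)
  br <- bridge_gaps(recording)
  rec <- br$recording
  channels <- list(acceleration = rec$acceleration,
                   gyroscope = rec$gyroscope)
  all_events <- list()
  intermediates <- list()
  counts <- list()
  for (ch in names(channels)) {
    filt <- apply(channels[[ch]], 2, bandpass_axis, spec = spec)
    ra <- respiratory_amplitude(filt)
    amp <- amplitude_events(ra, fs, config)
    axes <- select_dominant_axes(filt, fs, config$epoch_s)
    wave <- build_respiratory_waveform(filt, axes, spec)
    rf <- respiratory_frequency(wave)
    fre <- frequency_events(rf, amp$suppression, config = config)
    ev_a <- drop_bridged_events(amp$events, br$bridged_spans,
                                pad_s = config$fast_window_s)
    ev_f <- drop_bridged_events(fre$events, br$bridged_spans,
                                pad_s = config$fast_window_s)
    ev_a$channel <- rep(ch, nrow(ev_a))
    ev_f$channel <- rep(ch, nrow(ev_f))
    all_events[[paste0(ch, "_amplitude")]] <- ev_a
    all_events[[paste0(ch, "_frequency")]] <- ev_f
    counts[[ch]] <- c(amplitude = nrow(ev_a), frequency = nrow(ev_f))
    intermediates[[ch]] <- list(ra = ra, fast = amp$fast, slow = amp$slow,
                                suppression = amp$suppression,
                                waveform = wave, rf = rf,
                                rf_upper = fre$upper)
  }
  events <- do.call(rbind, all_events)
  rownames(events) <- NULL
  hours <- recording$duration_s / 3600
  indices <- list(
    raei_acc = counts$acceleration[["amplitude"]] / hours,
    rfei_acc = counts$acceleration[["frequency"]] / hours,
    raei_gyro = counts$gyroscope[["amplitude"]] / hours,
    rfei_gyro = counts$gyroscope[["frequency"]] / hours,
    monitoring_hours = hours)
  structure(list(events = events, indices = indices,
                 channels = intermediates,
                 sampling_rate_hz = fs),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  i <- x$indices
  cat("<detection_result> ", nrow(x$events), " events over ",
      round(i$monitoring_hours, 2), " h\n",
      "  RAEI acc ", round(i$raei_acc, 2), "/h, RFEI acc ",
      round(i$rfei_acc, 2), "/h, RAEI gyro ", round(i$raei_gyro, 2),
      "/h, RFEI gyro ", round(i$rfei_gyro, 2), "/h\n", sep = "")
  invisible(x)
}

#' Export detected events as an annotation set
#'
#' Events get `type = "respiratory_event"` and keep their `source` and
#' `channel` columns, so the CSV written by [write_annotations()] can be
#' read back by [read_annotations()].
#'
#' @param result a `detection_result` from [detect_events()].
#' @return An [annotation_set()].
#' @export
events_as_annotations <- function(result) {
  ev <- result$events
  ev$type <- rep("respiratory_event", nrow(ev))
  annotation_set(ev[, c("onset_s", "duration_s", "type", "source",
                        "channel")],
                 total_time_s = result$indices$monitoring_hours * 3600)
}
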