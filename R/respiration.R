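#' Respiratory amplitude from three filtered axes
#'
#' Combines the band-pass-filtered X, Y, Z signals into a single
#' non-negative scalar per sample, `RA_t = sqrt(X_t^2 + Y_t^2 + Z_t^2)`.
#' Being a norm, `RA_t` is invariant under any fixed rotation of the sensor
#' axes, which is what makes the amplitude pathway robust to posture.
#'
#' @param filtered_x,filtered_y,filtered_z numeric vectors of equal length
#'   (outputs of [bandpass_axis()]), or a single N x 3 matrix as
#'   `filtered_x`.
#' @return Numeric vector `RA_t` (same units as the inputs, mG or dps).
#' @export
respiratory_amplitude <- function(filtered_x, filtered_y = NULL,
                                  filtered_z = NULL) {
  if (is.matrix(filtered_x) && is.null(filtered_y)) {
    stopifnot(ncol(filtered_x) == 3L)
    filtered_y <- filtered_x[, 2]
    filtered_z <- filtered_x[, 3]
    filtered_x <- filtered_x[, 1]
  }
  n <- length(filtered_x)
  if (length(filtered_y) != n || length(filtered_z) != n)
    stop("axis signals must have equal length")
  sqrt(filtered_x^2 + filtered_y^2 + filtered_z^2)
}

# sample index ranges of consecutive epochs of epoch_s seconds; the final
# partial epoch is its own epoch
epoch_bounds <- function(n, rate_hz, epoch_s = 30) {
  len <- max(1L, round(epoch_s * rate_hz))
  starts <- seq.int(1L, n, by = len)
  ends <- pmin(starts + len - 1L, n)
  data.frame(start = starts, end = ends)
}

#' Select the dominant respiratory axis per 30-s epoch
#'
#' For each epoch, picks the filtered axis with the largest excursion range
#' (max minus min) — the axis most strongly reflecting respiratory
#' movement. Exact ties go to the lowest axis index.
#'
#' @param filtered_xyz N x 3 matrix of band-pass-filtered axis signals.
#' @param rate_hz sampling rate.
#' @param epoch_s epoch length, seconds (default 30); the final partial
#'   epoch is treated as its own epoch.
#' @return Integer vector of axis indices (1 = X, 2 = Y, 3 = Z), one per
#'   epoch, with the epoch bounds attached as attribute `"epochs"`.
#' @export
select_dominant_axes <- function(filtered_xyz, rate_hz, epoch_s = 30) {
  stopifnot(is.matrix(filtered_xyz), ncol(filtered_xyz) == 3L)
  ep <- epoch_bounds(nrow(filtered_xyz), rate_hz, epoch_s)
  choice <- integer(nrow(ep))
  for (e in seq_len(nrow(ep))) {
    seg <- filtered_xyz[ep$start[e]:ep$end[e], , drop = FALSE]
    rng <- apply(seg, 2, function(v) max(v) - min(v))
    choice[e] <- which.max(rng)   # which.max takes the first on ties
  }
  attr(choice, "epochs") <- ep
  choice
}

#' Build the concatenated dominant-axis respiratory waveform
#'
#' Concatenates the per-epoch dominant-axis segments into one waveform,
#' flipping each epoch's polarity when that gives better phase continuity
#' at the junction. The continuity cost of a candidate sign combines the
#' value jump and the slope jump at the junction (the slope weighted by
#' the reciprocal angular frequency of the passband centre, where value
#' and slope contribute equal amplitude), so a junction that happens to
#' fall on a zero crossing of the waveform still resolves the correct
#' sign; ties keep +1. The concatenation is then re-filtered with the same
#' band-pass to remove
#' junction artifacts. This tracks the respiratory waveform across posture
#' changes that rotate the respiratory movement vector between axes.
#'
#' @param filtered_xyz N x 3 matrix of band-pass-filtered axis signals.
#' @param axis_choices per-epoch axis indices from [select_dominant_axes()].
#' @param spec the [filter_spec()] used for the original filtering.
#' @return A `respiratory_waveform`: list with `values` (length N),
#'   `epoch_axis_choices`, `epoch_polarity`, `sampling_rate_hz`.
#' @export
build_respiratory_waveform <- function(filtered_xyz, axis_choices, spec) {
  ep <- attr(axis_choices, "epochs")
  if (is.null(ep))
    stop("axis_choices must come from select_dominant_axes()")
  n <- nrow(filtered_xyz)
  out <- numeric(n)
  pol <- integer(length(axis_choices))
  prev_last <- NA_real_
  prev_slope <- NA_real_
  fs <- spec$sampling_rate_hz
  # weight making a slope jump commensurate with a value jump for a
  # sinusoid at the passband's geometric centre
  w_slope <- 1 / (2 * pi * sqrt(spec$low_cut_hz * spec$high_cut_hz))
  for (e in seq_along(axis_choices)) {
    seg <- filtered_xyz[ep$start[e]:ep$end[e], axis_choices[e]]
    if (e == 1L || is.na(prev_last) || length(seg) < 2L) {
      s <- 1L
    } else {
      head_slope <- (seg[2L] - seg[1L]) * fs
      cost <- function(sgn) abs(prev_last - sgn * seg[1L]) +
        w_slope * abs(prev_slope - sgn * head_slope)
      s <- if (cost(-1) < cost(1)) -1L else 1L
    }
    pol[e] <- s
    seg <- s * seg
    out[ep$start[e]:ep$end[e]] <- seg
    prev_last <- seg[length(seg)]
    prev_slope <- if (length(seg) >= 2L)
      (seg[length(seg)] - seg[length(seg) - 1L]) * fs else NA_real_
  }
  structure(list(values = bandpass_axis(out, spec),
                 epoch_axis_choices = as.integer(axis_choices),
                 epoch_polarity = pol,
                 sampling_rate_hz = spec$sampling_rate_hz),
            class = "respiratory_waveform")
}

# negative-to-positive zero-crossing times (seconds, 0-based), linearly
# interpolated between the bracketing samples
zero_crossings_up <- function(values, rate_hz) {
  n <- length(values)
  a <- values[-n]
  b <- values[-1L]
  idx <- which(a < 0 & b >= 0)
  if (!length(idx)) return(numeric(0))
  frac <- -a[idx] / (b[idx] - a[idx])
  (idx - 1 + frac) / rate_hz
}

#' Respiratory frequency series from the respiratory waveform
#'
#' Estimates breathing cycle lengths as the intervals between consecutive
#' negative-to-positive zero crossings of the waveform, interpolates them
#' as a step function (each time point takes the cycle length of the cycle
#' containing it) and returns the reciprocal as the per-sample respiratory
#' frequency `RF_t` in Hz. Samples before the first and after the last
#' crossing take the nearest defined cycle's value. Crossings closer than
#' the minimum physiological cycle length (1 / `high_cut_hz` of the band,
#' ~1.43 s) are treated as residual ripple and merged into the following
#' cycle.
#'
#' @param waveform a `respiratory_waveform` from
#'   [build_respiratory_waveform()], or a plain numeric vector (then
#'   `rate_hz` is required).
#' @param rate_hz sampling rate, when `waveform` is a plain vector.
#' @param min_cycle_s minimum accepted cycle length, seconds.
#' @return A `respiratory_frequency` object: list with `values` (RF_t, Hz,
#'   one per sample), `cycle_boundaries` (crossing times, s) and
#'   `sampling_rate_hz`.
#' @export
respiratory_frequency <- function(waveform, rate_hz = NULL,
                                  min_cycle_s = 1 / 0.7) {
  if (inherits(waveform, "respiratory_waveform")) {
    values <- waveform$values
    rate_hz <- waveform$sampling_rate_hz
  } else {
    values <- as.numeric(waveform)
    if (is.null(rate_hz)) stop("rate_hz required for plain vectors")
  }
  cr <- zero_crossings_up(values, rate_hz)
  # merge cycles shorter than min_cycle_s into the next cycle by dropping
  # the crossing that would close them
  if (length(cr) >= 2L) {
    keep <- cr[1L]
    for (t in cr[-1L]) {
      if (t - keep[length(keep)] >= min_cycle_s) keep <- c(keep, t)
    }
    cr <- keep
  }
  if (length(cr) < 2L)
    stop("no respiratory cycles detected (fewer than 2 zero crossings)")
  n <- length(values)
  tt <- (seq_len(n) - 1) / rate_hz
  cyc_len <- diff(cr)
  # cycle index of each sample: findInterval over crossing times; clamp
  # to the first/last cycle outside the crossed span
  ci <- findInterval(tt, cr)
  ci[ci < 1L] <- 1L
  ci[ci > length(cyc_len)] <- length(cyc_len)
  structure(list(values = 1 / cyc_len[ci],
                 cycle_boundaries = cr,
                 sampling_rate_hz = rate_hz),
            class = "respiratory_frequency")
}
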