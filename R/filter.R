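#' Band-pass filter specification for respiratory extraction
#'
#' Linear-phase FIR band-pass isolating the respiratory band. The default
#' 0.13--0.7 Hz passband keeps breathing (>= 0.13 Hz, i.e. cycle length
#' < 7.7 s) while rejecting DC/baseline drift, pulse waves (0.7--2.5 Hz),
#' coarse body movements (2--4 Hz) and cardiac vibration (>= 8 Hz). A
#' breathing pause longer than ~7.7 s has no in-band energy, so the
#' filtered amplitude collapses during apneas lasting >= 10 s — this is
#' what makes the downstream envelope criterion work.
#'
#' The default tap count is about 8 cycles of the low cutoff
#' (`8 * fs / 0.13`, rounded to odd) so that the transition band is narrow
#' enough to attenuate 0.13 Hz-adjacent drift; taps are windowed-sinc
#' (Hamming), DC-corrected to exactly zero gain at 0 Hz, and normalized to
#' unit gain at the passband's geometric centre.
#'
#' @param sampling_rate_hz sampling rate of the signal to filter.
#' @param low_cut_hz,high_cut_hz passband edges (Hz);
#'   `0 < low < high < sampling_rate_hz / 2`.
#' @param n_taps odd filter length; default `round_odd(8 * fs / low_cut)`.
#' @param design_window taper; only `"hamming"` is implemented.
#' @return A `filter_spec` with the designed taps attached (`$taps`).
#' @export
filter_spec <- function(sampling_rate_hz, low_cut_hz = 0.13,
                        high_cut_hz = 0.7, n_taps = NULL,
                        design_window = c("hamming")) {
  design_window <- match.arg(design_window)
  if (!(low_cut_hz > 0 && low_cut_hz < high_cut_hz))
    stop("need 0 < low_cut_hz < high_cut_hz")
  if (high_cut_hz >= sampling_rate_hz / 2)
    stop("high_cut_hz must be below the Nyquist frequency (",
         sampling_rate_hz / 2, " Hz)")
  if (is.null(n_taps)) {
    n_taps <- round(8 * sampling_rate_hz / low_cut_hz)
    if (n_taps %% 2L == 0L) n_taps <- n_taps + 1L
  }
  n_taps <- as.integer(n_taps)
  if (n_taps %% 2L == 0L || n_taps < 3L)
    stop("n_taps must be odd and >= 3")
  spec <- structure(list(sampling_rate_hz = sampling_rate_hz,
                         low_cut_hz = low_cut_hz, high_cut_hz = high_cut_hz,
                         n_taps = n_taps, design_window = design_window),
                    class = "filter_spec")
  spec$taps <- fir_bandpass_taps(spec)
  spec
}

# Windowed-sinc band-pass taps: ideal response times Hamming window,
# then (1) subtract the tap mean so H(0) is exactly 0 and (2) scale to
# unit gain at the geometric centre of the passband.
fir_bandpass_taps <- function(spec) {
  m <- (spec$n_taps - 1L) / 2L
  k <- -m:m
  fl <- spec$low_cut_hz / spec$sampling_rate_hz   # normalized (cycles/sample)
  fh <- spec$high_cut_hz / spec$sampling_rate_hz
  h <- ifelse(k == 0L, 2 * (fh - fl),
              (sin(2 * pi * fh * k) - sin(2 * pi * fl * k)) / (pi * k))
  w <- 0.54 + 0.46 * cos(pi * k / m)   # Hamming, centred
  h <- h * w
  h <- h - mean(h)                     # exact DC rejection
  fc <- sqrt(spec$low_cut_hz * spec$high_cut_hz)
  gain <- abs(filter_response(h, fc, spec$sampling_rate_hz))
  h / gain
}

# Complex frequency response of a tap vector at frequency f_hz.
filter_response <- function(taps, f_hz, sampling_rate_hz) {
  n <- seq_along(taps) - 1
  sum(taps * exp(-2i * pi * f_hz / sampling_rate_hz * n))
}

#' Zero-phase band-pass filtering of one axis signal
#'
#' Applies the symmetric FIR kernel in a single centred pass (a symmetric
#' kernel has exactly linear phase, so a centred pass is zero-phase and
#' event timing is not delayed). Edges are handled by reflection padding;
#' the convolution runs via FFT.
#'
#' @param axis_signal numeric vector, one IMU axis.
#' @param spec a [filter_spec()] whose sampling rate matches the signal.
#' @return Filtered signal of identical length.
#' @export
bandpass_axis <- function(axis_signal, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  n <- length(axis_signal)
  if (n <= spec$n_taps)
    stop("signal shorter than the filter (", n, " <= ", spec$n_taps,
         " taps); use a shorter filter or a longer signal")
  m <- (spec$n_taps - 1L) / 2L
  # reflect about the end samples so the padding is continuous
  pre <- axis_signal[(m + 1L):2L]
  post <- axis_signal[(n - 1L):(n - m)]
  x <- c(2 * axis_signal[1L] - pre, axis_signal, 2 * axis_signal[n] - post)
  y <- convolve(x, rev(spec$taps), type = "open")
  y[(2L * m + 1L):(2L * m + n)]
}
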