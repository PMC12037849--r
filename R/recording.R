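#' Construct an IMU recording
#'
#' Container for a synchronized tri-axial acceleration + gyroscope recording.
#' Internal units are fixed: milli-G (mG) for acceleration and degrees per
#' second (dps) for the gyroscope; unit conversion happens at the I/O
#' boundary only. Missing or unreadable samples are flagged in `gap_mask`
#' rather than dropped, so downstream window arithmetic stays on a uniform
#' time base.
#'
#' @param acceleration numeric N x 3 matrix (columns X, Y, Z), in mG.
#' @param gyroscope numeric N x 3 matrix (columns X, Y, Z), in dps.
#' @param sampling_rate_hz positive sampling rate (30 or 32 Hz typical).
#' @param device_label one of `"amue_link"`, `"xperia"`, `"iphone"`,
#'   `"generic"`.
#' @param start_offset_s offset of the first sample, seconds.
#' @param gap_mask logical vector of length N; `TRUE` marks missing/invalid
#'   samples.
#' @return An object of class `imu_recording` with fields as above plus
#'   `n_samples` and `duration_s = N / sampling_rate_hz`.
#' @seealso [read_recording()], [write_recording()], [detect_events()]
#' @export
imu_recording <- function(acceleration, gyroscope, sampling_rate_hz,
                          device_label = "generic", start_offset_s = 0,
                          gap_mask = NULL) {
  acceleration <- as.matrix(acceleration)
  gyroscope <- as.matrix(gyroscope)
  if (ncol(acceleration) != 3L || ncol(gyroscope) != 3L)
    stop("acceleration and gyroscope must each have 3 columns (X, Y, Z)")
  n <- nrow(acceleration)
  if (nrow(gyroscope) != n)
    stop("validation error: acceleration and gyroscope differ in length (",
         n, " vs ", nrow(gyroscope), ")")
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1L ||
      sampling_rate_hz <= 0)
    stop("sampling_rate_hz must be a single positive number")
  device_label <- match.arg(device_label,
                            c("amue_link", "xperia", "iphone", "generic"))
  if (is.null(gap_mask)) {
    gap_mask <- !stats::complete.cases(acceleration) |
      !stats::complete.cases(gyroscope)
  }
  gap_mask <- as.logical(gap_mask)
  if (length(gap_mask) != n)
    stop("gap_mask must have one entry per sample")
  ok <- !gap_mask
  if (any(!is.finite(acceleration[ok, ])) || any(!is.finite(gyroscope[ok, ])))
    stop("validation error: non-finite values outside gap_mask")
  colnames(acceleration) <- c("x", "y", "z")
  colnames(gyroscope) <- c("x", "y", "z")
  structure(list(
    device_label = device_label,
    sampling_rate_hz = sampling_rate_hz,
    acceleration = acceleration,
    gyroscope = gyroscope,
    start_offset_s = start_offset_s,
    gap_mask = gap_mask,
    n_samples = n,
    duration_s = n / sampling_rate_hz
  ), class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat("<imu_recording> ", x$device_label, ", ", x$sampling_rate_hz, " Hz, ",
      x$n_samples, " samples (", round(x$duration_s, 1), " s), ",
      sum(x$gap_mask), " gap sample(s)\n", sep = "")
  invisible(x)
}

# time of each sample, seconds from recording start (0-based)
sample_times <- function(rec) {
  rec$start_offset_s + (seq_len(rec$n_samples) - 1) / rec$sampling_rate_hz
}

#' Read an IMU recording from a headered CSV file
#'
#' The on-disk format is a CSV with columns `t, ax, ay, az, gx, gy, gz`
#' preceded by a YAML header block in `#`-prefixed lines declaring at least
#' `device`, `sampling_rate_hz`, `acceleration_units` (`mG` or `G`) and
#' `gyroscope_units` (`dps` or `rps`); `start_offset_s` is optional.
#' Values are converted to the internal mG / dps units per the declared
#' header units. Rows with unreadable samples become gap-mask entries,
#' never silent drops.
#'
#' @param path file path.
#' @return An [imu_recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("recording file not found: ", path)
  lines <- readLines(path)
  hdr_idx <- grep("^#", lines)
  if (length(hdr_idx) == 0L)
    stop("format error: missing header block in ", path)
  hdr <- yaml::yaml.load(paste(sub("^#\\s?", "", lines[hdr_idx]),
                               collapse = "\n"))
  required <- c("device", "sampling_rate_hz", "acceleration_units",
                "gyroscope_units")
  missing <- setdiff(required, names(hdr))
  if (length(missing))
    stop("format error: header missing field(s): ",
         paste(missing, collapse = ", "))
  body <- lines[-hdr_idx]
  df <- read.csv(text = paste(body, collapse = "\n"))
  need <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  if (!all(need %in% names(df)))
    stop("format error: expected columns ", paste(need, collapse = ", "))
  acc <- as.matrix(df[, c("ax", "ay", "az")])
  gyr <- as.matrix(df[, c("gx", "gy", "gz")])
  acc_scale <- switch(hdr$acceleration_units,
                      mG = 1, G = 1000,
                      stop("format error: unknown acceleration_units '",
                           hdr$acceleration_units, "' (use mG or G)"))
  gyr_scale <- switch(hdr$gyroscope_units,
                      dps = 1, rps = 180 / pi,
                      stop("format error: unknown gyroscope_units '",
                           hdr$gyroscope_units, "' (use dps or rps)"))
  imu_recording(acc * acc_scale, gyr * gyr_scale,
                sampling_rate_hz = hdr$sampling_rate_hz,
                device_label = hdr$device,
                start_offset_s = if (is.null(hdr$start_offset_s)) 0
                                 else hdr$start_offset_s)
}

#' Write an IMU recording to a headered CSV file
#'
#' Inverse of [read_recording()]; always writes internal units (mG, dps).
#' Gap samples are written as `NA` and round-trip back into the gap mask.
#'
#' @param rec an [imu_recording()].
#' @param path destination file path.
#' @param digits significant digits for sample values (metadata is exact).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, digits = 7) {
  stopifnot(inherits(rec, "imu_recording"))
  hdr <- c(
    paste0("# device: ", rec$device_label),
    paste0("# sampling_rate_hz: ", format(rec$sampling_rate_hz, digits = 15)),
    "# acceleration_units: mG",
    "# gyroscope_units: dps",
    paste0("# start_offset_s: ", format(rec$start_offset_s, digits = 15))
  )
  acc <- rec$acceleration
  gyr <- rec$gyroscope
  acc[rec$gap_mask, ] <- NA_real_
  gyr[rec$gap_mask, ] <- NA_real_
  df <- data.frame(t = signif(sample_times(rec), 10),
                   ax = signif(acc[, 1], digits),
                   ay = signif(acc[, 2], digits),
                   az = signif(acc[, 3], digits),
                   gx = signif(gyr[, 1], digits),
                   gy = signif(gyr[, 2], digits),
                   gz = signif(gyr[, 3], digits))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Linearly bridge gap samples in both channels so filtering sees a
# continuous signal; returns the recording plus the bridged spans
# (data.frame onset_s/duration_s) so events falling entirely inside a
# bridged span can be discarded downstream.
bridge_gaps <- function(rec) {
  spans <- data.frame(onset_s = numeric(0), duration_s = numeric(0))
  if (any(rec$gap_mask)) {
    idx <- seq_len(rec$n_samples)
    fill <- function(mat) {
      for (j in 1:3) {
        v <- mat[, j]
        v[rec$gap_mask] <- NA
        mat[, j] <- approx(idx[!rec$gap_mask], v[!rec$gap_mask], xout = idx,
                           rule = 2)$y
      }
      mat
    }
    rec$acceleration <- fill(rec$acceleration)
    rec$gyroscope <- fill(rec$gyroscope)
    r <- rle(rec$gap_mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    spans <- data.frame(
      onset_s = (starts[keep] - 1L) / rec$sampling_rate_hz,
      duration_s = r$lengths[keep] / rec$sampling_rate_hz)
    rec$gap_mask <- rep(FALSE, rec$n_samples)
  }
  list(recording = rec, bridged_spans = spans)
}
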