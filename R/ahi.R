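SEVERITY_LEVELS <- c("no_sa", "mild", "moderate", "severe")

#' Estimate the respiratory event index (REI)
#'
#' Applies the device's multiple-regression model to the four hourly event
#' indices: `raw = intercept + c1*RAEI_acc + c2*RFEI_acc + c3*RAEI_gyro +
#' c4*RFEI_gyro`, clipped at zero (an AHI estimate cannot be negative).
#'
#' @param indices list or `detection_result$indices` with `raei_acc`,
#'   `rfei_acc`, `raei_gyro`, `rfei_gyro` (events/h).
#' @param model a [device_model()].
#' @return A `rei_estimate`: list with `rei` (= `max(0, raw)`),
#'   `raw_linear_value` and `device_label`.
#' @examples
#' m <- load_device_model("xperia")
#' estimate_rei(list(raei_acc = 0, rfei_acc = 0, raei_gyro = 0,
#'                   rfei_gyro = 0), m)$rei  # 1.43, the model intercept
#' @export
estimate_rei <- function(indices, model) {
  stopifnot(inherits(model, "device_model"))
  if (inherits(indices, "detection_result")) indices <- indices$indices
  raw <- model$intercept +
    model$coef_raei_acc * indices$raei_acc +
    model$coef_rfei_acc * indices$rfei_acc +
    model$coef_raei_gyro * indices$raei_gyro +
    model$coef_rfei_gyro * indices$rfei_gyro
  structure(list(rei = max(0, raw), raw_linear_value = raw,
                 device_label = model$device_label),
            class = "rei_estimate")
}

# shared lower-closed interval grading on cutoffs c(mild, moderate, severe)
grade_on_cutoffs <- function(x, cutoffs) {
  cls <- SEVERITY_LEVELS[findInterval(x, c(cutoffs[["mild"]],
                                           cutoffs[["moderate"]],
                                           cutoffs[["severe"]])) + 1L]
  factor(cls, levels = SEVERITY_LEVELS, ordered = TRUE)
}

#' Classify sleep-apnea severity from a PSG AHI
#'
#' Standard grid: AHI < 5 no SA, 5--15 mild, 15--30 moderate, >= 30
#' severe; intervals are closed on the left.
#'
#' @param ahi non-negative AHI value(s).
#' @return Ordered factor over `no_sa < mild < moderate < severe`.
#' @export
classify_severity_from_ahi <- function(ahi) {
  if (any(ahi < 0)) stop("AHI must be non-negative")
  grade_on_cutoffs(ahi, c(mild = 5, moderate = 15, severe = 30))
}

#' Classify sleep-apnea severity from an estimated REI
#'
#' Uses the device-specific REI cutoffs (e.g. 5/17/30 for the GPS tracker,
#' 5/15/30 for the Android phone, 5/13/36 for the iPhone), lower-closed.
#'
#' @param rei non-negative REI value(s).
#' @param model a [device_model()] carrying the cutoffs.
#' @return Ordered factor over `no_sa < mild < moderate < severe`.
#' @export
classify_severity_from_rei <- function(rei, model) {
  stopifnot(inherits(model, "device_model"))
  grade_on_cutoffs(rei, model$cutoffs)
}

#' Binary screen at an REI threshold
#'
#' Positive when `rei >= threshold` (cutoffs are inclusive).
#'
#' @param rei REI value(s).
#' @param threshold positive screening cutoff (e.g. the device's
#'   moderate-or-worse cutoff).
#' @return Logical.
#' @export
binary_screen <- function(rei, threshold) {
  if (any(threshold <= 0)) stop("threshold must be positive")
  rei >= threshold
}
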