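# Device-specific AHI regression coefficients and REI severity cutoffs.
# These defaults are published operating points for three abdomen-worn
# devices; they are data, not logic, and can be overridden from YAML or
# re-fitted from labelled data with fit_device_model().
BUILTIN_DEVICE_MODELS <- list(
  amue_link = list(intercept = 1.71, coef_raei_acc = 0.20,
                   coef_rfei_acc = 0.82, coef_raei_gyro = -0.44,
                   coef_rfei_gyro = -2.60,
                   cutoffs = c(mild = 5, moderate = 17, severe = 30)),
  xperia = list(intercept = 1.43, coef_raei_acc = 0.17,
                coef_rfei_acc = 0.84, coef_raei_gyro = 0.21,
                coef_rfei_gyro = -5.64,
                cutoffs = c(mild = 5, moderate = 15, severe = 30)),
  iphone = list(intercept = 0.34, coef_raei_acc = 0.95,
                coef_rfei_acc = 0.71, coef_raei_gyro = -0.62,
                coef_rfei_gyro = 1.36,
                cutoffs = c(mild = 5, moderate = 13, severe = 36))
)

#' Construct a device model
#'
#' Holds the multiple-regression coefficients mapping the four hourly event
#' indices (RAEI and RFEI from the acceleration and gyroscope channels) to
#' an estimated AHI (the respiratory event index, REI), together with the
#' REI cutoffs used for severity grading.
#'
#' @param device_label device name.
#' @param intercept,coef_raei_acc,coef_rfei_acc,coef_raei_gyro,coef_rfei_gyro
#'   regression coefficients (AHI units per event/h).
#' @param cutoffs named numeric `c(mild=, moderate=, severe=)` REI cutoffs;
#'   must be strictly increasing.
#' @return A `device_model` object.
#' @export
device_model <- function(device_label, intercept, coef_raei_acc,
                         coef_rfei_acc, coef_raei_gyro, coef_rfei_gyro,
                         cutoffs = c(mild = 5, moderate = 15, severe = 30)) {
  cutoffs <- c(mild = unname(cutoffs["mild"]),
               moderate = unname(cutoffs["moderate"]),
               severe = unname(cutoffs["severe"]))
  if (any(is.na(cutoffs)) || !(cutoffs[1] < cutoffs[2] &&
                               cutoffs[2] < cutoffs[3]))
    stop("cutoffs must be named (mild, moderate, severe) and increasing")
  structure(list(device_label = device_label,
                 intercept = intercept,
                 coef_raei_acc = coef_raei_acc,
                 coef_rfei_acc = coef_rfei_acc,
                 coef_raei_gyro = coef_raei_gyro,
                 coef_rfei_gyro = coef_rfei_gyro,
                 cutoffs = cutoffs),
            class = "device_model")
}

#' @export
print.device_model <- function(x, ...) {
  cat("<device_model> ", x$device_label, "\n",
      "  REI = ", x$intercept, " + ", x$coef_raei_acc, "*RAEI_acc + ",
      x$coef_rfei_acc, "*RFEI_acc + ", x$coef_raei_gyro, "*RAEI_gyro + ",
      x$coef_rfei_gyro, "*RFEI_gyro\n",
      "  cutoffs: mild >= ", x$cutoffs["mild"], ", moderate >= ",
      x$cutoffs["moderate"], ", severe >= ", x$cutoffs["severe"], "\n",
      sep = "")
  invisible(x)
}

#' Load a device model by name or from a YAML config
#'
#' `name_or_path` may be a built-in device name (`"amue_link"`, `"xperia"`,
#' `"iphone"`) or the path of a YAML file with keys `device`, `intercept`,
#' `coefficients: {raei_acc, rfei_acc, raei_gyro, rfei_gyro}` and
#' `cutoffs: {mild, moderate, severe}`. When a YAML file names a built-in
#' device, any field it omits falls back to that device's defaults, so a
#' config can override a single coefficient.
#'
#' @param name_or_path device name or YAML path.
#' @return A [device_model()].
#' @examples
#' load_device_model("xperia")   # intercept 1.43, cutoffs 5/15/30
#' @export
load_device_model <- function(name_or_path) {
  if (name_or_path %in% names(BUILTIN_DEVICE_MODELS)) {
    d <- BUILTIN_DEVICE_MODELS[[name_or_path]]
    return(device_model(name_or_path, d$intercept, d$coef_raei_acc,
                        d$coef_rfei_acc, d$coef_raei_gyro, d$coef_rfei_gyro,
                        d$cutoffs))
  }
  if (!file.exists(name_or_path))
    stop("unknown device name and no such config file: ", name_or_path)
  cfg <- yaml::read_yaml(name_or_path)
  dev <- if (is.null(cfg$device)) "generic" else cfg$device
  base <- if (dev %in% names(BUILTIN_DEVICE_MODELS))
    BUILTIN_DEVICE_MODELS[[dev]]
  else list(intercept = 0, coef_raei_acc = 0, coef_rfei_acc = 0,
            coef_raei_gyro = 0, coef_rfei_gyro = 0,
            cutoffs = c(mild = 5, moderate = 15, severe = 30))
  pick <- function(a, b) if (is.null(a)) b else a
  co <- cfg$coefficients
  cu <- cfg$cutoffs
  device_model(
    dev,
    intercept = pick(cfg$intercept, base$intercept),
    coef_raei_acc = pick(co$raei_acc, base$coef_raei_acc),
    coef_rfei_acc = pick(co$rfei_acc, base$coef_rfei_acc),
    coef_raei_gyro = pick(co$raei_gyro, base$coef_raei_gyro),
    coef_rfei_gyro = pick(co$rfei_gyro, base$coef_rfei_gyro),
    cutoffs = c(mild = pick(cu$mild, base$cutoffs[["mild"]]),
                moderate = pick(cu$moderate, base$cutoffs[["moderate"]]),
                severe = pick(cu$severe, base$cutoffs[["severe"]])))
}

#' Write a device model to YAML
#'
#' @param model a [device_model()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_device_model <- function(model, path) {
  stopifnot(inherits(model, "device_model"))
  yaml::write_yaml(list(
    device = model$device_label,
    intercept = model$intercept,
    coefficients = list(raei_acc = model$coef_raei_acc,
                        rfei_acc = model$coef_rfei_acc,
                        raei_gyro = model$coef_raei_gyro,
                        rfei_gyro = model$coef_rfei_gyro),
    cutoffs = as.list(model$cutoffs)), path)
  invisible(path)
}

#' Fit a device model by ordinary least squares
#'
#' Regresses a reference AHI on the four hourly event indices, for users
#' with labelled recordings who want their own coefficients (plain OLS, no
#' regularization).
#'
#' @param data data.frame with columns `ahi`, `raei_acc`, `rfei_acc`,
#'   `raei_gyro`, `rfei_gyro`.
#' @param device_label label for the fitted model.
#' @param cutoffs REI severity cutoffs to attach (default AHI grid 5/15/30).
#' @return A [device_model()].
#' @export
fit_device_model <- function(data, device_label = "generic",
                             cutoffs = c(mild = 5, moderate = 15,
                                         severe = 30)) {
  fit <- lm(ahi ~ raei_acc + rfei_acc + raei_gyro + rfei_gyro, data = data)
  b <- coef(fit)
  device_model(device_label, b[["(Intercept)"]], b[["raei_acc"]],
               b[["rfei_acc"]], b[["raei_gyro"]], b[["rfei_gyro"]], cutoffs)
}
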