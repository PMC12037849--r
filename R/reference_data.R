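#' Published reference validation tables
#'
#' Ships the published clinical validation operating points for the three
#' supported abdomen-worn devices as plain data:
#' \describe{
#'   \item{`breath_concordance`}{per-device, per-split breath-by-breath
#'     confusion counts (TP/FP/FN/TN) with the printed percentage metrics
#'     and F1.}
#'   \item{`severity_confusion`}{list of 4x4 severity confusion matrices
#'     (rows = predicted REI class, columns = reference AHI class), keyed
#'     `device.group`.}
#'   \item{`severity_macro_f1`}{printed macro-F1 per matrix; rows with
#'     `verified = FALSE` are matrices whose printed macro-F1 is not
#'     reproducible from the printed counts under any consistent
#'     convention (a typesetting ambiguity in the source table) and are
#'     excluded from tests.}
#' }
#'
#' @return A list with elements `breath_concordance`, `severity_confusion`
#'   and `severity_macro_f1`.
#' @export
reference_tables <- function() {
  p <- function(f) system.file("extdata", f, package = "imuapnea",
                               mustWork = TRUE)
  conc <- read.csv(p("breath_concordance_counts.csv"))
  conf_long <- read.csv(p("severity_confusion.csv"))
  mf1 <- read.csv(p("severity_macro_f1.csv"))
  mats <- list()
  for (dev in unique(conf_long$device)) {
    for (grp in unique(conf_long$group)) {
      sub <- conf_long[conf_long$device == dev & conf_long$group == grp, ]
      sub <- sub[match(SEVERITY_LEVELS, sub$rei_class), ]
      m <- as.matrix(sub[, c("no_sa", "mild", "moderate", "severe")])
      dimnames(m) <- list(predicted = SEVERITY_LEVELS,
                          reference = SEVERITY_LEVELS)
      mats[[paste(dev, grp, sep = ".")]] <- m
    }
  }
  list(breath_concordance = conc, severity_confusion = mats,
       severity_macro_f1 = mf1)
}
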