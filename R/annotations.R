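ANNOTATION_TYPES <- c("obstructive_apnea", "central_apnea", "mixed_apnea",
                      "hypopnea", "respiratory_event")

#' Construct an annotation set
#'
#' A time-sorted list of scored respiratory events (PSG-style apnea/hypopnea
#' annotations, or exported detector events). Timestamps are seconds from
#' recording start; every event occupies the half-open interval
#' `[onset_s, onset_s + duration_s)`.
#'
#' @param events data.frame with columns `onset_s` (>= 0), `duration_s`
#'   (> 0) and `type` (one of `r paste(ANNOTATION_TYPES, collapse = ", ")`).
#'   Extra columns are preserved.
#' @param total_time_s total observation time, seconds; defaults to the end
#'   of the last event.
#' @return An `annotation_set`: the events sorted by onset, with
#'   `total_time_s` attached as an attribute.
#' @export
annotation_set <- function(events, total_time_s = NULL) {
  if (is.null(events) || nrow(events) == 0L) {
    events <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                         type = character(0))
  }
  stopifnot(all(c("onset_s", "duration_s", "type") %in% names(events)))
  if (any(events$onset_s < 0))
    stop("validation error: negative event onset")
  if (any(events$duration_s <= 0))
    stop("validation error: non-positive event duration")
  bad <- setdiff(unique(as.character(events$type)), ANNOTATION_TYPES)
  if (length(bad))
    stop("unknown event type(s): ", paste(bad, collapse = ", "),
         "; accepted types are: ", paste(ANNOTATION_TYPES, collapse = ", "))
  events <- events[order(events$onset_s), , drop = FALSE]
  rownames(events) <- NULL
  if (is.null(total_time_s))
    total_time_s <- if (nrow(events)) max(events$onset_s + events$duration_s)
                    else 0
  if (nrow(events) && any(events$onset_s + events$duration_s > total_time_s +
                          1e-9))
    stop("validation error: event extends beyond total_time_s")
  structure(events, total_time_s = total_time_s,
            class = c("annotation_set", "data.frame"))
}

#' Read event annotations from CSV
#'
#' Expects columns `onset_s`, `duration_s`, `type`; rows are normalized and
#' sorted by onset. An empty body with a valid header yields an empty set.
#'
#' @param path file path.
#' @param total_time_s optional total observation time (seconds).
#' @return An [annotation_set()].
#' @export
read_annotations <- function(path, total_time_s = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- read.csv(path)
  annotation_set(df, total_time_s = total_time_s)
}

#' Write event annotations to CSV
#'
#' @param ann an [annotation_set()] (or compatible data.frame).
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  write.csv(as.data.frame(ann), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# half-open interval overlap: [a0, a1) vs [b0, b1)
intervals_overlap <- function(a0, a1, b0, b1) a0 < b1 & b0 < a1
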