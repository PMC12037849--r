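#' Segment a reference respiratory trace into breaths
#'
#' Breath intervals are delimited by consecutive respiratory nadir points
#' (as scored on an abdominal inductance plethysmogram, or any band-limited
#' respiratory trace). When a series is supplied, nadirs are local minima
#' separated by at least the minimum physiological cycle length (~1.43 s);
#' closer minima keep only the deeper one. An explicit nadir-time vector
#' can be supplied instead.
#'
#' @param x numeric respiratory series (with `rate_hz`) or, when
#'   `rate_hz` is `NULL`, a strictly increasing vector of nadir times in
#'   seconds.
#' @param rate_hz sampling rate of the series, or `NULL` for a nadir list.
#' @param min_separation_s minimum nadir separation, seconds.
#' @return A `breath_track`: data.frame with one row per breath
#'   (`start_s`, `end_s`, half-open `[start_s, end_s)`), label columns
#'   `re_positive`/`ref_positive` initialized to `NA`, and the nadir times
#'   as attribute `"nadir_times_s"`.
#' @export
segment_breaths <- function(x, rate_hz = NULL, min_separation_s = 1 / 0.7) {
  if (is.null(rate_hz)) {
    nadirs <- as.numeric(x)
    if (is.unsorted(nadirs, strictly = TRUE))
      stop("nadir times must be strictly increasing")
  } else {
    v <- as.numeric(x)
    n <- length(v)
    is_min <- which(v[2:(n - 1)] < v[1:(n - 2)] &
                    v[2:(n - 1)] <= v[3:n]) + 1L
    if (length(is_min)) {
      kept <- is_min[1L]
      for (i in is_min[-1L]) {
        last <- kept[length(kept)]
        if ((i - last) / rate_hz >= min_separation_s) {
          kept <- c(kept, i)
        } else if (v[i] < v[last]) {
          kept[length(kept)] <- i   # keep the deeper of the pair
        }
      }
    } else kept <- integer(0)
    nadirs <- (kept - 1L) / rate_hz
  }
  if (length(nadirs) < 2L)
    stop("fewer than 2 nadirs; cannot segment breaths")
  breaths <- data.frame(start_s = nadirs[-length(nadirs)],
                        end_s = nadirs[-1L],
                        re_positive = NA, ref_positive = NA)
  structure(breaths, nadir_times_s = nadirs,
            class = c("breath_track", "data.frame"))
}

#' Label breaths by overlap with detected and reference events
#'
#' A breath is RE-positive when its half-open interval overlaps at least
#' one detected respiratory event (union over all channel-by-source event
#' lists), and reference-positive when it overlaps at least one reference
#' apnea/hypopnea annotation.
#'
#' @param track a `breath_track` from [segment_breaths()].
#' @param detected data.frame of detected events (`onset_s`, `duration_s`;
#'   e.g. `detect_events(rec)$events`), or a `detection_result`.
#' @param reference an [annotation_set()] (or compatible data.frame).
#' @return The track with `re_positive` and `ref_positive` filled in.
#' @export
label_breaths <- function(track, detected, reference) {
  stopifnot(inherits(track, "breath_track"))
  if (inherits(detected, "detection_result")) detected <- detected$events
  overlap_any <- function(ev) {
    if (is.null(ev) || nrow(ev) == 0L) return(rep(FALSE, nrow(track)))
    vapply(seq_len(nrow(track)), function(i) {
      any(intervals_overlap(track$start_s[i], track$end_s[i],
                            ev$onset_s, ev$onset_s + ev$duration_s))
    }, logical(1))
  }
  track$re_positive <- overlap_any(detected)
  track$ref_positive <- overlap_any(as.data.frame(reference))
  track
}

#' Breath-by-breath confusion counts with a breath-gap tolerance
#'
#' Matches detected-positive and reference-positive breaths allowing a
#' misalignment of up to `gap_breaths` breaths, because annotation flags
#' may be placed anywhere between event onset and termination. A
#' detected-positive breath counts as TP if any reference-positive breath
#' lies within `gap_breaths` of it (else FP); a reference-positive breath
#' with no detected-positive breath within `gap_breaths` counts as FN;
#' everything else is TN. Matching is non-consuming: one reference breath
#' may legitimize several adjacent detections.
#'
#' @param track a labelled `breath_track`.
#' @param gap_breaths non-negative integer tolerance (default 1).
#' @return A `confusion_counts` list: `tp`, `fp`, `fn`, `tn`
#'   (`tp+fp+fn+tn` equals the number of breaths).
#' @export
gap_tolerant_confusion <- function(track, gap_breaths = 1) {
  det <- track$re_positive
  ref <- track$ref_positive
  if (anyNA(det) || anyNA(ref))
    stop("breath labels not populated; run label_breaths() first")
  n <- length(det)
  g <- as.integer(gap_breaths)
  near <- function(v, i) any(v[max(1L, i - g):min(n, i + g)])
  tp <- fp <- fn <- 0L
  for (i in which(det)) {
    if (near(ref, i)) tp <- tp + 1L else fp <- fp + 1L
  }
  for (j in which(ref)) {
    if (!near(det, j)) fn <- fn + 1L
  }
  structure(list(tp = tp, fp = fp, fn = fn, tn = n - tp - fp - fn),
            class = "confusion_counts")
}

#' Binary classification metrics from confusion counts
#'
#' @param counts a `confusion_counts` (or list/vector with `tp`, `fp`,
#'   `fn`, `tn`).
#' @return List with `sensitivity`, `specificity`, `accuracy`, `ppv`,
#'   `npv`, `f1`; metrics with a zero denominator are `NA` rather than
#'   errors.
#' @examples
#' # printed operating point of an abdomen-worn tracker, training split
#' binary_metrics(list(tp = 2915, fp = 564, fn = 1242, tn = 183343))
#' @export
binary_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  div <- function(a, b) if (b > 0) a / b else NA_real_
  sens <- div(tp, tp + fn)
  ppv <- div(tp, tp + fp)
  f1 <- if (!is.na(sens) && !is.na(ppv) && (sens + ppv) > 0)
    2 * ppv * sens / (ppv + sens) else NA_real_
  list(sensitivity = sens,
       specificity = div(tn, tn + fp),
       accuracy = div(tp + tn, tp + fp + fn + tn),
       ppv = ppv,
       npv = div(tn, tn + fn),
       f1 = f1)
}

#' Macro F1 over a 4x4 severity confusion matrix
#'
#' One-vs-rest F1 per severity class (rows = predicted class, columns =
#' reference class, order no SA / mild / moderate / severe), averaged
#' without weights. A class with undefined precision or recall and no true
#' positives contributes 0 — the convention under which the published
#' per-device macro-F1 values are reproducible.
#'
#' @param m 4x4 non-negative integer matrix.
#' @return Macro-averaged F1 in `[0, 1]`.
#' @export
macro_f1 <- function(m) {
  m <- as.matrix(m)
  stopifnot(nrow(m) == ncol(m), all(m >= 0))
  f1 <- vapply(seq_len(nrow(m)), function(k) {
    tp <- m[k, k]
    fp <- sum(m[k, ]) - tp
    fn <- sum(m[, k]) - tp
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1)
}

#' Severity confusion matrix from paired classifications
#'
#' @param predicted,reference ordered factors from
#'   [classify_severity_from_rei()] / [classify_severity_from_ahi()].
#' @return 4x4 integer matrix, rows = predicted, columns = reference.
#' @export
severity_confusion <- function(predicted, reference) {
  predicted <- factor(predicted, levels = SEVERITY_LEVELS)
  reference <- factor(reference, levels = SEVERITY_LEVELS)
  unclass(table(predicted = predicted, reference = reference))
}

#' Bland-Altman agreement summary
#'
#' Differences are `estimate - reference`; limits of agreement are the
#' mean difference +/- 1.96 sample standard deviations. Pearson r and RMSE
#' are included for convenience.
#'
#' @param reference,estimate paired numeric vectors (>= 3 pairs).
#' @return List with `mean_difference`, `loa_low`, `loa_high`, `sd`, `r`,
#'   `rmse`, `n`.
#' @export
bland_altman <- function(reference, estimate) {
  if (length(reference) != length(estimate))
    stop("reference and estimate must be paired")
  if (length(reference) < 3) stop("need at least 3 pairs")
  d <- estimate - reference
  s <- sd(d)
  list(mean_difference = mean(d),
       loa_low = mean(d) - 1.96 * s,
       loa_high = mean(d) + 1.96 * s,
       sd = s,
       r = if (sd(reference) > 0 && sd(estimate) > 0)
         cor(reference, estimate) else NA_real_,
       rmse = sqrt(mean(d^2)),
       n = length(d))
}

#' ROC curve, AUC and optimal cutoff
#'
#' Empirical ROC over all score thresholds (predicted positive when
#' `score >= cutoff`); AUC by the trapezoidal rule, which equals the
#' tie-corrected Mann-Whitney statistic. The optimal cutoff maximizes
#' Youden's J = sensitivity + specificity - 1; ties take the lowest
#' cutoff.
#'
#' @param scores numeric scores (higher = more likely positive).
#' @param labels logical (or 0/1) reference labels; both classes required.
#' @return List with `auc`, `optimal_cutoff`, and the ROC path
#'   (`data.frame` `cutoff`, `tpr`, `fpr`).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  if (!any(labels) || all(labels))
    stop("both classes must be present in labels")
  cuts <- sort(unique(scores))
  npos <- sum(labels)
  nneg <- sum(!labels)
  tpr <- vapply(cuts, function(c) sum(scores >= c & labels) / npos,
                numeric(1))
  fpr <- vapply(cuts, function(c) sum(scores >= c & !labels) / nneg,
                numeric(1))
  # path from (1,1) (lowest cutoff) to (0,0), plus the closing corners
  path <- data.frame(cutoff = c(-Inf, cuts, Inf),
                     tpr = c(1, tpr, 0), fpr = c(1, fpr, 0))
  o <- order(path$fpr, path$tpr)
  auc <- sum(diff(path$fpr[o]) *
             (path$tpr[o][-1] + path$tpr[o][-nrow(path)]) / 2)
  j <- tpr - fpr
  best <- cuts[which(j == max(j))]
  list(auc = auc, optimal_cutoff = min(best),
       roc = path[nrow(path):1, ])
}
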