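test_that("breath segmentation finds nadirs or accepts explicit lists", {
  tr <- segment_breaths(sine(0.25, 60), rate_hz = 32)
  expect_true(abs(nrow(tr) - 15) <= 1)

  nad <- c(0, 4.1, 8.0, 12.3, 16.1)
  tr2 <- segment_breaths(nad)
  expect_equal(nrow(tr2), 4L)
  expect_equal(attr(tr2, "nadir_times_s"), nad)

  expect_error(segment_breaths(rep(1, 200), rate_hz = 32), "fewer than 2")
  expect_error(segment_breaths(c(3, 2, 1)), "strictly increasing")
  # nadirs closer than the physiological minimum are merged
  noisy <- sine(0.25, 60) + 0.02 * sine(5, 60)
  tr3 <- segment_breaths(noisy, rate_hz = 32)
  expect_true(all(diff(attr(tr3, "nadir_times_s")) >= 1 / 0.7))
})

test_that("breath labelling uses half-open interval overlap", {
  tr <- segment_breaths(seq(0, 40, by = 4))       # 10 breaths of 4 s
  # event spanning two breaths -> both positive
  det <- data.frame(onset_s = 6, duration_s = 4)
  lab <- label_breaths(tr, det,
                       annotation_set(NULL, total_time_s = 40))
  expect_equal(which(lab$re_positive), c(2L, 3L))
  expect_false(any(lab$ref_positive))

  # 15-s reference apnea covering breaths 4-7 exactly
  ref <- annotation_set(data.frame(onset_s = 13, duration_s = 15,
                                   type = "central_apnea"))
  lab2 <- label_breaths(tr, data.frame(onset_s = numeric(0),
                                       duration_s = numeric(0)), ref)
  expect_equal(which(lab2$ref_positive), 4:7)
  expect_equal(sum(lab2$ref_positive), 4L)
  # boundary: event ending exactly at a nadir does not leak into the next
  # breath (half-open intervals)
  ref_b <- annotation_set(data.frame(onset_s = 4, duration_s = 4,
                                     type = "hypopnea"))
  lab3 <- label_breaths(tr, det[0, ], ref_b)
  expect_equal(which(lab3$ref_positive), 2L)
})

test_that("gap-tolerant matching follows the one-breath-gap convention", {
  det <- rep(FALSE, 10); ref <- det
  det[5] <- TRUE; ref[6] <- TRUE
  cc1 <- gap_tolerant_confusion(track_from_labels(det, ref), 1)
  expect_equal(cc1[c("tp", "fp", "fn", "tn")],
               list(tp = 1L, fp = 0L, fn = 0L, tn = 9L))
  cc0 <- gap_tolerant_confusion(track_from_labels(det, ref), 0)
  expect_equal(cc0[c("tp", "fp", "fn", "tn")],
               list(tp = 0L, fp = 1L, fn = 1L, tn = 8L))

  same <- as.logical(rbinom(30, 1, 0.3))
  ccs <- gap_tolerant_confusion(track_from_labels(same, same), 0)
  expect_equal(ccs$tp, sum(same))
  expect_equal(ccs$fp + ccs$fn, 0L)
  expect_equal(ccs$tn, sum(!same))
})

test_that("gap matching equals the brute-force matcher for g in {0,1}", {
  set.seed(20)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    det <- as.logical(rbinom(n, 1, 0.3))
    ref <- as.logical(rbinom(n, 1, 0.3))
    tr <- track_from_labels(det, ref)
    for (g in 0:1) {
      got <- gap_tolerant_confusion(tr, g)
      exp <- brute_gap_confusion(det, ref, g)
      expect_equal(got[c("tp", "fp", "fn", "tn")], exp)
    }
    # g = 0 equals exact element-wise comparison
    cc <- gap_tolerant_confusion(tr, 0)
    expect_equal(cc$tp, sum(det & ref))
    expect_equal(cc$fp, sum(det & !ref))
    expect_equal(cc$fn, sum(!det & ref))
    # sensitivity never decreases with a wider gap
    m0 <- binary_metrics(gap_tolerant_confusion(tr, 0))
    m1 <- binary_metrics(gap_tolerant_confusion(tr, 1))
    if (!is.na(m0$sensitivity) && !is.na(m1$sensitivity))
      expect_gte(m1$sensitivity, m0$sensitivity)
  }
})

test_that("binary metrics reproduce the published operating points", {
  m <- binary_metrics(list(tp = 2915, fp = 564, fn = 1242, tn = 183343))
  expect_equal(round(m$sensitivity, 3), 0.701)
  expect_equal(round(m$specificity, 3), 0.997)
  expect_equal(round(m$ppv, 3), 0.838)
  expect_equal(round(m$f1, 3), 0.763)

  expect_equal(round(binary_metrics(list(tp = 2359, fp = 398, fn = 634,
                                         tn = 109034))$f1, 3), 0.821)

  perfect <- binary_metrics(list(tp = 10, fp = 0, fn = 0, tn = 10))
  expect_true(all(unlist(perfect) == 1))

  degenerate <- binary_metrics(list(tp = 0, fp = 0, fn = 0, tn = 0))
  expect_true(is.na(degenerate$sensitivity))
  expect_true(is.na(degenerate$f1))
})

test_that("macro F1 reproduces the published severity scores", {
  ref <- reference_tables()
  expect_equal(round(macro_f1(ref$severity_confusion$xperia.training), 3),
               0.699)
  expect_equal(round(macro_f1(ref$severity_confusion$amue_link.training), 3),
               0.586)
  expect_equal(macro_f1(diag(c(3, 3, 3, 3))), 1)
  # empty class contributes zero, not NaN
  m <- diag(c(5, 5, 5, 0))
  expect_equal(macro_f1(m), 0.75)
})

test_that("macro F1 is invariant under joint row/column permutation", {
  set.seed(21)
  m <- matrix(rpois(16, 3), 4)
  for (i in 1:5) {
    p <- sample(4)
    expect_equal(macro_f1(m[p, p]), macro_f1(m))
  }
})

test_that("Bland-Altman summarises paired differences", {
  x <- c(5, 10, 20, 30)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$mean_difference, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))
  expect_equal(ba0$rmse, 0)

  ba2 <- bland_altman(x, x + 2)
  expect_equal(ba2$mean_difference, 2)
  expect_equal(ba2$sd, 0)

  # hand-computed: diffs {2, -2, 3}, mean 1, sd sqrt(7)
  ba <- bland_altman(c(10, 20, 30), c(12, 18, 33))
  expect_equal(ba$mean_difference, 1)
  expect_equal(ba$sd, sqrt(7))
  expect_equal(ba$loa_low, 1 - 1.96 * sqrt(7))
  expect_equal(ba$loa_high, 1 + 1.96 * sqrt(7))
  expect_equal(ba$rmse, sqrt(mean(c(4, 4, 9))))

  expect_error(bland_altman(1:2, 2:3), "3 pairs")
})

test_that("ROC AUC equals the Mann-Whitney statistic; cutoff maximizes J", {
  r <- roc_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(r$auc, 1)
  expect_equal(r$optimal_cutoff, 3)

  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12),
                       c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))$auc, 0)

  set.seed(22)
  for (i in 1:10) {
    n <- sample(10:60, 1)
    scores <- round(rnorm(n), 1)           # ties likely
    labels <- rbinom(n, 1, 0.4) == 1
    if (!any(labels) || all(labels)) next
    auc <- roc_auc(scores, labels)$auc
    # oracle: normalized Mann-Whitney U with ties counted half
    pos <- scores[labels]; neg <- scores[!labels]
    u <- 0
    for (p in pos) u <- u + sum(p > neg) + 0.5 * sum(p == neg)
    expect_equal(auc, u / (length(pos) * length(neg)), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:4, c(TRUE, TRUE, TRUE, TRUE)), "both classes")
})

test_that("severity_confusion builds the predicted-by-reference matrix", {
  pred <- classify_severity_from_ahi(c(2, 7, 20, 40, 3))
  ref <- classify_severity_from_ahi(c(3, 20, 20, 35, 40))
  m <- severity_confusion(pred, ref)
  expect_equal(sum(m), 5)
  expect_equal(m["no_sa", "no_sa"], 1L)
  expect_equal(m["mild", "moderate"], 1L)
  expect_equal(m["no_sa", "severe"], 1L)
})
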