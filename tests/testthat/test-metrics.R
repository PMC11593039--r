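test_that("classification metrics agree with a naive recount on random tables", {
  set.seed(101)
  for (i in 1:25) {
    cts <- as.list(sample(0:200, 4, replace = TRUE))
    names(cts) <- c("tp", "tn", "fp", "fn")
    if (cts$tp + cts$fn == 0 || cts$tn + cts$fp == 0) next
    cc <- confusion_counts(tp = cts$tp, tn = cts$tn, fp = cts$fp, fn = cts$fn)
    rep <- classification_metrics(cc)
    est <- setNames(rep$estimate, rep$metric)
    expect_equal(est[["sensitivity"]], cts$tp / (cts$tp + cts$fn))
    expect_equal(est[["specificity"]], cts$tn / (cts$tn + cts$fp))
    expect_equal(est[["accuracy"]],
                 (cts$tp + cts$tn) / Reduce(`+`, cts))
    if (cts$tp + cts$fp > 0) {
      expect_equal(est[["precision"]], cts$tp / (cts$tp + cts$fp))
    }
  }
})

test_that("confusion counts from calls match manual tabulation", {
  set.seed(7)
  pred <- runif(50) > 0.5
  truth <- runif(50) > 0.6
  cc <- tabulate_confusion(pred, truth)
  expect_s3_class(cc, "confusion_counts")
  expect_identical(cc$tp + cc$tn + cc$fp + cc$fn, 50L)
  expect_identical(cc$tp, sum(pred & truth))
  expect_error(confusion_counts(-1, 0, 0, 0), "non-negative")
})

test_that("Clopper-Pearson interval matches binom.test and a zero-denominator metric degrades gracefully", {
  for (xn in list(c(90, 99), c(0, 10), c(10, 10), c(37, 120))) {
    rep <- classification_metrics(
      confusion_counts(tp = xn[1], fn = xn[2] - xn[1], fp = 0, tn = 1))
    ref <- binom.test(xn[1], xn[2])$conf.int
    i <- which(rep$metric == "sensitivity")
    expect_equal(rep$lower[i], ref[1], tolerance = 1e-10)
    expect_equal(rep$upper[i], ref[2], tolerance = 1e-10)
  }
  # no predicted positives: precision undefined, rest intact
  rep <- classification_metrics(confusion_counts(tp = 0, fn = 5, fp = 0, tn = 20))
  expect_true(is.na(rep$estimate[rep$metric == "precision"]))
  expect_equal(rep$estimate[rep$metric == "specificity"], 1)
})

test_that("Clopper-Pearson CI attains near-nominal coverage in simulation", {
  set.seed(2024)
  n <- 99
  p <- 0.9
  x <- rbinom(2000, n, p)
  lo <- ifelse(x == 0, 0, qbeta(0.025, x, n - x + 1))
  hi <- ifelse(x == n, 1, qbeta(0.975, x + 1, n - x))
  covered <- mean(lo <= p & p <= hi)
  expect_gte(covered, 0.93)
})

test_that("perfect classification yields unit metrics with CI upper bounds at 1", {
  rep <- classification_metrics(confusion_counts(tp = 12, fn = 0, fp = 0, tn = 30))
  expect_true(all(rep$estimate == 1))
  expect_true(all(rep$upper == 1))
})

test_that("segmentation overlap identities hold exactly on random mask pairs", {
  set.seed(11)
  for (i in 1:30) {
    a <- random_mask(15, 15, runif(1, 0.1, 0.7))
    b <- random_mask(15, 15, runif(1, 0.1, 0.7))
    if (sum(a) + sum(b) == 0) next
    r <- seg_overlap(a, b)
    expect_equal(r$dsc, r$f1)
    expect_equal(r$dsc, 1 - (r$fnd + r$fpd) / 2, tolerance = 1e-12)
    expect_equal(r$iou, r$dsc / (2 - r$dsc), tolerance = 1e-12)
  }
})

test_that("segmentation overlap handles identity, disjoint and empty cases", {
  m <- matrix(0L, 8, 8); m[2:5, 2:5] <- 1L
  r <- seg_overlap(m, m)
  expect_equal(r$dsc, 1); expect_equal(r$iou, 1)
  expect_equal(r$fnd, 0); expect_equal(r$fpd, 0)

  d <- matrix(0L, 8, 8); d[6:8, 6:8] <- 1L
  m2 <- matrix(0L, 8, 8); m2[1:3, 1:3] <- 1L
  r2 <- seg_overlap(d, m2)
  expect_equal(r2$dsc, 0)
  expect_equal(r2$fnd + r2$fpd, 2)

  z <- matrix(0L, 8, 8)
  expect_error(seg_overlap(z, z), "empty")
  expect_error(seg_overlap(m, matrix(0L, 4, 4)), "shape")
})

test_that("AUROC equals the exhaustive pair-counting oracle, including ties", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(6:40, 1)
    labels <- c(TRUE, FALSE, runif(n - 2) > 0.5)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE) # force ties
    expect_equal(auroc(scores, labels), brute_auroc(scores, labels))
  }
})

test_that("AUROC limits and invariances", {
  labels <- c(rep(TRUE, 4), rep(FALSE, 5))
  sep <- c(rep(0.9, 4), rep(0.1, 5))
  expect_equal(auroc(sep, labels), 1.0)
  expect_equal(auroc(rep(0.3, 9), labels), 0.5)
  set.seed(9)
  s <- runif(9)
  expect_equal(auroc(s, labels), auroc(qlogis(s) * 3 + 2, labels)) # monotone map
  expect_error(auroc(s, rep(TRUE, 9)), "positive and one negative")
})

test_that("ROC curve is monotone, spans the unit box and integrates to the AUROC", {
  set.seed(17)
  labels <- runif(60) > 0.5
  labels[1:2] <- c(TRUE, FALSE)
  scores <- round(runif(60), 2)
  rc <- roc_curve(scores, labels)
  expect_true(all(diff(rc$tpr) >= 0))
  expect_true(all(diff(rc$fpr) >= 0))
  expect_equal(rc$tpr[1], 0); expect_equal(rc$fpr[1], 0)
  expect_equal(rc$tpr[nrow(rc)], 1); expect_equal(rc$fpr[nrow(rc)], 1)
  trap <- sum(diff(rc$fpr) * (head(rc$tpr, -1) + tail(rc$tpr, -1)) / 2)
  expect_equal(trap, auroc(scores, labels), tolerance = 1e-12)
})

test_that("AUROC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  labels <- runif(80) > 0.4
  labels[1:2] <- c(TRUE, FALSE)
  scores <- runif(80)
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores,
    levels = c(FALSE, TRUE), direction = "<"))))
  expect_equal(auroc(scores, labels), ref, tolerance = 1e-10)
})

test_that("percentage formatting uses two decimals with round-half-even", {
  expect_identical(format_pct(0.909090909), "90.91")
  expect_identical(format_pct(0.5), "50.00")
})
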