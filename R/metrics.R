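#' Confusion counts for vertebra-wise classification
#'
#' Build a `confusion_counts` object either from the four counts directly or
#' from paired logical vectors of predictions and truth labels.
#'
#' @param tp,tn,fp,fn Non-negative integer counts.
#' @return An object of class `confusion_counts`.
#' @examples
#' confusion_counts(tp = 90, fn = 9, fp = 82, tn = 800)
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers")
  }
  structure(as.list(stats::setNames(as.integer(counts), names(counts))),
            class = "confusion_counts")
}

#' Tabulate confusion counts from binary calls and truth labels
#'
#' @param pred Logical vector of positive calls.
#' @param truth Logical vector of true labels, same length.
#' @return A `confusion_counts` object.
#' @export
tabulate_confusion <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  pred <- as.logical(pred)
  truth <- as.logical(truth)
  if (anyNA(pred) || anyNA(truth)) stop("pred and truth must not contain NA")
  confusion_counts(
    tp = sum(pred & truth),
    tn = sum(!pred & !truth),
    fp = sum(pred & !truth),
    fn = sum(!pred & truth)
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
    dimnames = list(truth = c("positive", "negative"),
                    call = c("positive", "negative")))
  print(m)
  invisible(x)
}

# Exact (Clopper-Pearson) binomial interval via the beta quantile identity.
clopper_pearson <- function(x, n, level = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n)
  alpha <- 1 - level
  lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(lower = lower, upper = upper)
}

# Wilson score interval (no continuity correction).
wilson_interval <- function(x, n, level = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  denom <- 1 + z^2 / n
  c(lower = (centre - half) / denom, upper = (centre + half) / denom)
}

#' Vertebra-wise classification metrics with exact binomial CIs
#'
#' Computes sensitivity, specificity, accuracy and precision from a confusion
#' matrix, each with a Clopper-Pearson exact binomial confidence interval at
#' `ci_level`. The accuracy interval treats correct calls as binomial over the
#' full cohort size. A metric whose denominator is zero is reported as `NA`
#' (with `NA` bounds) rather than aborting the report.
#'
#' @param counts A `confusion_counts` object.
#' @param ci_level Confidence level in (0, 1); default 0.95.
#' @param auroc Optional AUROC value to carry in the report.
#' @param ci_method `"clopper-pearson"` (exact, default) or `"wilson"`
#'   (score interval). Published reports sometimes mix the two across
#'   metrics, so both are available.
#' @return A `metric_report`: data frame with columns `metric`, `estimate`,
#'   `lower`, `upper`, `x` (successes) and `n` (denominator).
#' @examples
#' classification_metrics(confusion_counts(tp = 90, fn = 9, fp = 82, tn = 800))
#' @export
classification_metrics <- function(counts, ci_level = 0.95, auroc = NULL,
                                   ci_method = c("clopper-pearson", "wilson")) {
  ci_method <- match.arg(ci_method)
  ci_fun <- if (ci_method == "wilson") wilson_interval else clopper_pearson
  stopifnot(inherits(counts, "confusion_counts"))
  stopifnot(ci_level > 0, ci_level < 1)
  total <- counts$tp + counts$tn + counts$fp + counts$fn
  if (total <= 0) stop("confusion counts sum to zero")
  spec <- list(
    sensitivity = c(counts$tp, counts$tp + counts$fn),
    specificity = c(counts$tn, counts$tn + counts$fp),
    accuracy    = c(counts$tp + counts$tn, total),
    precision   = c(counts$tp, counts$tp + counts$fp)
  )
  rows <- lapply(names(spec), function(m) {
    x <- spec[[m]][1]
    n <- spec[[m]][2]
    if (n == 0) {
      data.frame(metric = m, estimate = NA_real_, lower = NA_real_,
                 upper = NA_real_, x = x, n = n)
    } else {
      ci <- ci_fun(x, n, ci_level)
      data.frame(metric = m, estimate = x / n, lower = ci[["lower"]],
                 upper = ci[["upper"]], x = x, n = n)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "ci_level") <- ci_level
  attr(out, "auroc") <- auroc
  class(out) <- c("metric_report", "data.frame")
  out
}

#' Format a proportion as a percentage string
#'
#' Two decimals, round-half-even (the convention of base [round()]).
#'
#' @param p Proportion in \[0, 1\].
#' @param digits Decimal places, default 2.
#' @return Character vector like `"90.91"`.
#' @export
format_pct <- function(p, digits = 2) {
  formatC(round(100 * p, digits), format = "f", digits = digits)
}

#' @export
print.metric_report <- function(x, ...) {
  lv <- attr(x, "ci_level")
  au <- attr(x, "auroc")
  if (!is.null(au)) cat(sprintf("AUROC: %.3f\n", au))
  for (i in seq_len(nrow(x))) {
    if (is.na(x$estimate[i])) {
      cat(sprintf("%-12s undefined (denominator 0)\n", x$metric[i]))
    } else {
      cat(sprintf("%-12s %s%% (%s-%s%%, %d%% CI) [%d/%d]\n",
        x$metric[i], format_pct(x$estimate[i]), format_pct(x$lower[i]),
        format_pct(x$upper[i]), round(100 * lv), x$x[i], x$n[i]))
    }
  }
  invisible(x)
}

#' Pixel-overlap metrics for a segmentation mask pair
#'
#' Pixel-wise comparison of a predicted binary mask against a reference mask:
#' Dice similarity coefficient (DSC), false-negative Dice (FND), false-positive
#' Dice (FPD), intersection over union (IoU), and the pixel-wise sensitivity,
#' specificity, F1 and accuracy from the same counts. These satisfy the exact
#' identities DSC = F1, DSC = 1 - (FND + FPD) / 2 and IoU = DSC / (2 - DSC).
#'
#' @param pred,truth Binary arrays of identical shape (logical or 0/1).
#' @return A list of class `seg_overlap_report`.
#' @export
seg_overlap <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth)) {
    stop("pred and truth must have identical shape")
  }
  pred <- as_binary(pred, "pred")
  truth <- as_binary(truth, "truth")
  tp <- sum(pred & truth)
  fp <- sum(pred & !truth)
  fn <- sum(!pred & truth)
  tn <- sum(!pred & !truth)
  if (tp + fp + fn == 0) {
    stop("both masks are empty: overlap metrics are undefined")
  }
  dsc <- 2 * tp / (2 * tp + fp + fn)
  structure(list(
    dsc = dsc,
    fnd = 2 * fn / (2 * tp + fp + fn),
    fpd = 2 * fp / (2 * tp + fp + fn),
    iou = tp / (tp + fp + fn),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    f1 = dsc,
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    counts = confusion_counts(tp = tp, tn = tn, fp = fp, fn = fn)
  ), class = "seg_overlap_report")
}

#' @export
print.seg_overlap_report <- function(x, ...) {
  cat(sprintf("DSC %.3f  FND %.3f  FPD %.3f  IoU %.3f\n",
              x$dsc, x$fnd, x$fpd, x$iou))
  cat(sprintf("sens %.3f  spec %.3f  F1 %.3f  acc %.3f\n",
              x$sensitivity, x$specificity, x$f1, x$accuracy))
  invisible(x)
}

as_binary <- function(x, what) {
  v <- as.vector(x)
  if (is.logical(v)) return(v)
  if (!all(v %in% c(0, 1))) stop(sprintf("%s is not a binary mask", what))
  v == 1
}

#' ROC curve over all score thresholds
#'
#' Sweeps the decision threshold across every unique score (plus an `Inf`
#' sentinel giving the (0, 0) corner) and reports the false and true positive
#' rates at each. Calls are made with the `>=` convention.
#'
#' @param scores Numeric scores, higher meaning more positive.
#' @param labels Logical (or 0/1) truth labels.
#' @return Data frame with columns `threshold`, `fpr`, `tpr`, ordered from
#'   (0, 0) to (1, 1).
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  if (anyNA(scores) || anyNA(labels)) stop("scores and labels must not contain NA")
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC requires at least one positive and one negative label")
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & labels) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !labels) / n_neg, numeric(1))
  data.frame(threshold = thr, fpr = fpr, tpr = tpr)
}

#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney U statistic: the probability that a
#' random positive outscores a random negative, with ties counted one half.
#' This equals trapezoidal integration of [roc_curve()].
#'
#' @inheritParams roc_curve
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUROC requires at least one positive and one negative label")
  }
  r <- rank(scores) # midranks handle ties at half credit
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Serialize a set of per-method metric reports as JSON
#'
#' @param reports Named list of `metric_report` objects (e.g. one per fusion
#'   method).
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @param digits Significant digits kept in the JSON (default keeps full
#'   precision).
#' @return The JSON string, invisibly when written to `path`.
#' @export
metrics_to_json <- function(reports, path = NULL, digits = NA) {
  payload <- lapply(reports, function(r) {
    stopifnot(inherits(r, "metric_report"))
    entry <- lapply(seq_len(nrow(r)), function(i) {
      list(estimate = r$estimate[i], lower = r$lower[i], upper = r$upper[i],
           x = r$x[i], n = r$n[i])
    })
    names(entry) <- r$metric
    entry$ci_level <- attr(r, "ci_level")
    if (!is.null(attr(r, "auroc"))) entry$auroc <- attr(r, "auroc")
    entry
  })
  txt <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = digits,
                          pretty = TRUE, na = "null")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
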