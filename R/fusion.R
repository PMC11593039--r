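#' Configuration for the HLR/detector fusion strategies
#'
#' Four decision rules per vertebra, combining the quantitative height loss
#' ratio (HLR) with the detector confidence:
#' \describe{
#'   \item{Method 1 (HLR only)}{positive iff `HLR >= hlr_threshold`.}
#'   \item{Method 2 (detector only)}{positive iff
#'     `confidence >= dl_positive_threshold`.}
#'   \item{Method 3 (positive override)}{an HLR-negative vertebra is
#'     reclassified positive when the detector confidence clears the
#'     operating threshold: positive iff HLR-positive OR
#'     `confidence >= dl_positive_threshold`.}
#'   \item{Method 4 (negative override)}{an HLR-positive vertebra is
#'     reclassified negative when the detector produced no supporting
#'     detection: positive iff HLR-positive AND
#'     `confidence >= dl_negation_threshold`.}
#' }
#' The negation criterion is deliberately weaker than the Method-2 operating
#' point: its default (`1e-6`) means "any detection box at all" (a vertebra
#' with no matched box carries confidence 0). Setting it to 0 disables the
#' negative override entirely (Method 4 reduces to Method 1), and setting
#' `dl_positive_threshold` to 1 disables the positive override (Method 3
#' reduces to Method 1) as long as confidences stay below 1.
#'
#' @param hlr_threshold HLR positivity cutoff tau, default 0.25 (the
#'   diagnostic threshold; 0.20 counts mild deformities too).
#' @param dl_positive_threshold Detector operating threshold for Methods 2
#'   and 3.
#' @param dl_negation_threshold Weaker threshold for Method 4's negative
#'   override; must not exceed `dl_positive_threshold`.
#' @return An object of class `fusion_config`.
#' @export
fusion_config <- function(hlr_threshold = 0.25,
                          dl_positive_threshold = 0.5,
                          dl_negation_threshold = 1e-6) {
  stopifnot(hlr_threshold >= 0, hlr_threshold <= 1,
            dl_positive_threshold >= 0, dl_positive_threshold <= 1,
            dl_negation_threshold >= 0,
            dl_negation_threshold <= dl_positive_threshold)
  structure(list(hlr_threshold = hlr_threshold,
                 dl_positive_threshold = dl_positive_threshold,
                 dl_negation_threshold = dl_negation_threshold),
            class = "fusion_config")
}

#' Classify vertebrae by one of the four fusion strategies
#'
#' Vectorized over vertebrae. Besides the binary call, each decision carries
#' a continuous fused score suitable for ROC analysis (Method 1: the HLR;
#' Method 2: the confidence; Method 3: 1 for HLR-positives, else the
#' confidence; Method 4: the confidence for HLR-positives, else 0) and the
#' provenance of the call (which rule fired). All threshold comparisons use
#' `>=`.
#'
#' @param hlr Height loss ratios in \[0, 1).
#' @param confidence Detector confidences in \[0, 1\] (0 = no detection).
#'   May be `NULL` only for method 1.
#' @param method Integer 1-4.
#' @param cfg A [fusion_config()].
#' @param vertebra Optional vertebra ids carried through.
#' @return Data frame of class `fusion_decisions`: `vertebra`, `method`,
#'   `call` (logical), `provenance`, `fused_score`.
#' @export
classify <- function(hlr, confidence = NULL, method,
                     cfg = fusion_config(), vertebra = seq_along(hlr)) {
  stopifnot(inherits(cfg, "fusion_config"), method %in% 1:4)
  if (any(hlr < 0) || any(hlr >= 1)) stop("HLR must lie in [0, 1)")
  if (is.null(confidence)) {
    if (method != 1) stop("detector confidence required for methods 2-4")
    confidence <- rep(NA_real_, length(hlr))
  }
  stopifnot(length(confidence) == length(hlr),
            length(vertebra) == length(hlr))
  if (method != 1 && (any(confidence < 0) || any(confidence > 1))) {
    stop("confidence must lie in [0, 1]")
  }
  tau <- cfg$hlr_threshold
  th_pos <- cfg$dl_positive_threshold
  th_neg <- cfg$dl_negation_threshold
  hlr_pos <- hlr >= tau
  res <- switch(method,
    `1` = list(call = hlr_pos,
               prov = ifelse(hlr_pos, "hlr", "hlr"),
               score = hlr),
    `2` = list(call = confidence >= th_pos,
               prov = rep("dl", length(hlr)),
               score = confidence),
    `3` = list(call = hlr_pos | confidence >= th_pos,
               prov = ifelse(hlr_pos, "hlr",
                      ifelse(confidence >= th_pos, "override", "dl")),
               score = ifelse(hlr_pos, 1, confidence)),
    `4` = list(call = hlr_pos & confidence >= th_neg,
               prov = ifelse(!hlr_pos, "hlr",
                      ifelse(confidence >= th_neg, "hlr", "override")),
               score = ifelse(hlr_pos, confidence, 0))
  )
  structure(data.frame(vertebra = vertebra, method = method,
                       call = res$call, provenance = res$prov,
                       fused_score = res$score),
            class = c("fusion_decisions", "data.frame"))
}

#' Classify a cohort and score it against truth labels
#'
#' Aligns morphometry records, detector scores and truth labels by vertebra
#' id, applies [classify()] and tabulates the confusion counts.
#'
#' @param records Data frame with `vertebra` and `hlr` (e.g. from
#'   [morphometry_table()]).
#' @param scores Data frame with `vertebra` and `confidence`, or `NULL` for
#'   method 1.
#' @param truth Data frame with `vertebra` and logical `fractured`.
#' @param method Integer 1-4.
#' @param cfg A [fusion_config()].
#' @return List of class `cohort_result`: `decisions`, `counts`
#'   (`confusion_counts`), `method`.
#' @export
classify_cohort <- function(records, scores = NULL, truth, method,
                            cfg = fusion_config()) {
  stopifnot(all(c("vertebra", "hlr") %in% names(records)),
            all(c("vertebra", "fractured") %in% names(truth)))
  ord <- order(records$vertebra)
  records <- records[ord, ]
  if (!setequal(records$vertebra, truth$vertebra) ||
      anyDuplicated(records$vertebra) || anyDuplicated(truth$vertebra)) {
    offenders <- union(setdiff(records$vertebra, truth$vertebra),
                       setdiff(truth$vertebra, records$vertebra))
    stop(sprintf("vertebra ids misaligned between records and truth: %s",
                 paste(offenders, collapse = ", ")))
  }
  truth <- truth[match(records$vertebra, truth$vertebra), ]
  conf <- NULL
  if (!is.null(scores)) {
    stopifnot(all(c("vertebra", "confidence") %in% names(scores)))
    if (!all(records$vertebra %in% scores$vertebra)) {
      stop(sprintf("missing detector scores for vertebrae: %s",
        paste(setdiff(records$vertebra, scores$vertebra), collapse = ", ")))
    }
    conf <- scores$confidence[match(records$vertebra, scores$vertebra)]
  }
  dec <- classify(records$hlr, conf, method, cfg, vertebra = records$vertebra)
  structure(list(decisions = dec,
                 counts = tabulate_confusion(dec$call, truth$fractured),
                 method = method),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("fusion method %d on %d vertebrae\n", x$method,
              nrow(x$decisions)))
  print(x$counts)
  invisible(x)
}

#' Evaluate all four fusion strategies on one cohort
#'
#' @inheritParams classify_cohort
#' @param ci_level Confidence level for the metric CIs.
#' @return Named list `method1` .. `method4` of lists with `counts`,
#'   `metrics` (a `metric_report` including the fused-score AUROC) and
#'   `decisions`.
#' @export
evaluate_methods <- function(records, scores, truth, cfg = fusion_config(),
                             ci_level = 0.95) {
  lapply(stats::setNames(1:4, paste0("method", 1:4)), function(m) {
    res <- classify_cohort(records, scores, truth, m, cfg)
    tr <- truth$fractured[match(res$decisions$vertebra, truth$vertebra)]
    au <- tryCatch(auroc(res$decisions$fused_score, tr),
                   error = function(e) NULL)
    list(counts = res$counts,
         metrics = classification_metrics(res$counts, ci_level, auroc = au),
         decisions = res$decisions)
  })
}
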