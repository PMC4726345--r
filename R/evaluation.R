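#' Confusion counts with RIF as the positive class
#'
#' @param calls character vector of predicted labels (`"RIF"`/`"control"`).
#' @param truth matched vector of true labels.
#' @return A list of class `confusion_counts`: `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(calls, truth) {
  if (length(calls) != length(truth)) stop("calls and truth differ in length")
  ok <- c("RIF", "control")
  bad <- setdiff(unique(c(calls, truth)), ok)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  structure(list(tp = sum(calls == "RIF" & truth == "RIF"),
                 fp = sum(calls == "RIF" & truth == "control"),
                 fn = sum(calls == "control" & truth == "RIF"),
                 tn = sum(calls == "control" & truth == "control")),
            class = "confusion_counts")
}

#' Wilson score confidence interval for a binomial proportion
#'
#' Interval center `(p + z^2/2n) / (1 + z^2/n)` with half-width
#' `z * sqrt(p(1-p)/n + z^2/4n^2) / (1 + z^2/n)`, `z` the exact two-sided
#' normal quantile. Has better small-sample coverage than the Wald interval
#' and sensible behavior at 0/n and n/n.
#'
#' @param successes number of successes (0..n).
#' @param n number of trials (>= 1).
#' @param level confidence level (default 0.95).
#' @return Numeric `c(low, high)` on the proportion (0..1) scale.
#' @export
wilson_ci <- function(successes, n, level = 0.95) {
  if (n < 1) stop("n must be >= 1")
  if (successes < 0 || successes > n) stop("successes must be in 0..n")
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  low <- if (successes == 0) 0 else max(0, center - half)
  high <- if (successes == n) 1 else min(1, center + half)
  c(low = low, high = high)
}

#' Diagnostic metrics with Wilson confidence intervals
#'
#' PPV, NPV, sensitivity, specificity and overall accuracy from a confusion
#' table, each reported as a percentage with its 95% Wilson interval and the
#' underlying numerator/denominator. A metric with a zero denominator is
#' reported as `NA` (undefined), never as 0.
#'
#' @param counts a `confusion_counts`.
#' @param level confidence level.
#' @return A data.frame: `metric`, `estimate`, `ci_low`, `ci_high` (percent),
#'   `numerator`, `denominator`.
#' @export
metrics_report <- function(counts, level = 0.95) {
  defs <- list(
    NPV = c(counts$tn, counts$tn + counts$fn),
    PPV = c(counts$tp, counts$tp + counts$fp),
    sensitivity = c(counts$tp, counts$tp + counts$fn),
    specificity = c(counts$tn, counts$tn + counts$fp),
    accuracy = c(counts$tp + counts$tn,
                 counts$tp + counts$fp + counts$fn + counts$tn))
  rows <- lapply(names(defs), function(nm) {
    num <- defs[[nm]][1]; den <- defs[[nm]][2]
    if (den == 0) {
      data.frame(metric = nm, estimate = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, numerator = num, denominator = den,
                 stringsAsFactors = FALSE)
    } else {
      ci <- wilson_ci(num, den, level)
      data.frame(metric = nm, estimate = 100 * num / den,
                 ci_low = 100 * ci[["low"]], ci_high = 100 * ci[["high"]],
                 numerator = num, denominator = den, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' The standard minimum-likelihood convention: the two-sided P is the sum of
#' hypergeometric probabilities of all tables (with the observed margins) no
#' more probable than the observed one. Degenerate tables with a zero margin
#' return P = 1 with a warning.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return Two-sided P value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2) || any(table < 0) ||
      any(table != round(table))) {
    stop("need a 2x2 table of nonnegative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warning("degenerate table with a zero margin; P = 1")
    return(1)
  }
  stats::fisher.test(table, alternative = "two.sided")$p.value
}

#' ROC curve and AUC with DeLong confidence interval
#'
#' AUC is the probability that a randomly chosen RIF score exceeds a randomly
#' chosen control score, ties counted half (the Mann-Whitney convention);
#' the CI uses the asymptotic DeLong variance. The curve is reported at every
#' score threshold, and the operating point at the classification threshold
#' is marked.
#'
#' @param scores numeric signature scores.
#' @param truth matched labels (`"RIF"`/`"control"`); both classes required.
#' @param threshold operating threshold to mark (default 0.5).
#' @param level confidence level for the AUC CI.
#' @return A list of class `roc_result`: `auc`, `ci` (low/high), `curve`
#'   (data.frame threshold, fpr, tpr), `operating_point`.
#' @export
roc_auc <- function(scores, truth, threshold = 0.5, level = 0.95) {
  if (length(unique(truth)) < 2) stop("both classes must be present")
  r <- pROC::roc(response = truth, predictor = scores,
                 levels = c("control", "RIF"), direction = "<",
                 quiet = TRUE)
  ci <- as.numeric(pROC::ci.auc(r, conf.level = level, method = "delong"))
  curve <- data.frame(threshold = r$thresholds,
                      fpr = 1 - r$specificities, tpr = r$sensitivities)
  op <- c(fpr = mean(scores[truth == "control"] >= threshold),
          tpr = mean(scores[truth == "RIF"] >= threshold))
  structure(list(auc = as.numeric(pROC::auc(r)), ci = c(low = ci[1],
                                                        high = ci[3]),
                 curve = curve, operating_point = op),
            class = "roc_result")
}

#' Full classification report
#'
#' Convenience wrapper producing the confusion counts, metric table, exact
#' test P, and ROC/AUC for a scored sample set.
#'
#' @param scored data.frame with `score`, `call`, `truth` columns (as
#'   returned by [loocv()] or [validate_signature()]).
#' @param threshold operating threshold.
#' @return A list of class `classification_report`.
#' @export
classification_report <- function(scored, threshold = 0.5) {
  counts <- confusion_counts(scored$call, scored$truth)
  tab <- matrix(c(counts$tp, counts$fn, counts$fp, counts$tn), 2, 2,
                dimnames = list(call = c("RIF", "control"),
                                truth = c("RIF", "control")))
  structure(list(counts = counts,
                 metrics = metrics_report(counts),
                 fisher_p = fisher_exact_2x2(tab),
                 roc = roc_auc(scored$score, scored$truth, threshold)),
            class = "classification_report")
}
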