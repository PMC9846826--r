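#' Binary classification metrics panel
#'
#' Computes the screening-battery metrics from predicted and true labels,
#' with the active class as positive. Predictions may contain the
#' conformal outcomes `both` and `empty`; by default all metrics are
#' computed on single-label predictions only and `coverage` reports the
#' single-label fraction. With `countUnclassified = TRUE`, `both`/`empty`
#' predictions are kept and counted as errors for every class (coverage 1
#' convention).
#'
#' Balanced PPV and NPV are the predictive values of the
#' prevalence-normalized confusion matrix: each true class row is rescaled
#' to equal mass before PPV = TP/(TP+FP) and NPV = TN/(TN+FN) are taken,
#' so the values describe a hypothetical 50/50 prevalence. Degenerate
#' denominators yield `NA` rather than propagating NaN.
#'
#' @param predictions character vector over `active`, `inactive`, `both`,
#'   `empty`.
#' @param labels true labels over `active`/`inactive`, aligned.
#' @param probActive optional score for ranking (active-class probability,
#'   or the conformal p1); enables AUC.
#' @param epsilon optional significance level recorded in the report.
#' @param countUnclassified count `both`/`empty` as errors instead of
#'   excluding them?
#' @return one-row data.frame: `accuracy`, `balanced_accuracy`,
#'   `sensitivity`, `specificity`, `balanced_ppv`, `balanced_npv`, `mcc`,
#'   `auc`, `coverage`, `epsilon`.
#' @examples
#' evaluateMetrics(c("active", "inactive", "active", "inactive"),
#'                 c("active", "inactive", "inactive", "inactive"))
#' @export
evaluateMetrics <- function(predictions, labels, probActive = NULL,
                            epsilon = NA_real_,
                            countUnclassified = FALSE) {
  predictions <- as.character(predictions)
  labels <- as.character(labels)
  stopifnot(length(predictions) == length(labels),
            all(labels %in% c("active", "inactive")),
            all(predictions %in% c("active", "inactive", "both", "empty")))
  single <- predictions %in% c("active", "inactive")
  coverage <- mean(single)
  if (countUnclassified) {
    keep <- rep(TRUE, length(labels))
    coverage <- 1
  } else {
    keep <- single
  }
  pr <- predictions[keep]
  tr <- labels[keep]
  tp <- sum(pr == "active" & tr == "active")
  fn <- sum(pr != "active" & tr == "active")
  fp <- sum(pr == "active" & tr == "inactive")
  # in the coverage-1 convention a both/empty prediction is an error for
  # either true class: it counts in fn for true actives and against tn
  # for true inactives
  tn <- sum(pr == "inactive" & tr == "inactive")
  div <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- div(tp, tp + fn)
  spec <- div(tn, tn + fp)
  acc <- div(tp + tn, tp + fn + fp + tn)
  bacc <- if (is.na(sens) || is.na(spec)) NA_real_ else (sens + spec) / 2
  # prevalence-normalized predictive values: rescale each true-class row
  # to unit mass (sens, 1-sens) vs (1-spec, spec)
  bppv <- if (is.na(sens) || is.na(spec)) NA_real_ else
    div(sens, sens + (1 - spec))
  bnpv <- if (is.na(sens) || is.na(spec)) NA_real_ else
    div(spec, spec + (1 - sens))
  mccDen <- sqrt(as.numeric(tp + fp)) * sqrt(as.numeric(tp + fn)) *
    sqrt(as.numeric(tn + fp)) * sqrt(as.numeric(tn + fn))
  mcc <- if (mccDen > 0)
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / mccDen else NA_real_
  auc <- NA_real_
  if (!is.null(probActive)) {
    sc <- probActive[keep]
    if (length(unique(tr)) == 2) {
      auc <- as.numeric(suppressMessages(pROC::auc(pROC::roc(
        tr, sc, levels = c("inactive", "active"), direction = "<"))))
    }
  }
  data.frame(accuracy = acc, balanced_accuracy = bacc,
             sensitivity = sens, specificity = spec,
             balanced_ppv = bppv, balanced_npv = bnpv,
             mcc = mcc, auc = auc, coverage = coverage,
             epsilon = epsilon)
}
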