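#' Build per-class Mondrian calibration tables
#'
#' From a calibration split with known labels, collects the model's
#' conformity scores separately per class (the Mondrian condition): the
#' active table holds the predicted active-class probability of the true
#' actives, the inactive table holds the inactive-class probability
#' (`1 - p(active)`) of the true inactives. Both are stored sorted.
#'
#' @param probActive numeric vector of predicted active-class probabilities
#'   for the calibration compounds.
#' @param labels true labels, factor or character over `active`/`inactive`.
#' @return list with components `active` and `inactive`, each a
#'   [CalibrationTable-class].
#' @examples
#' cal <- buildCalibration(c(0.9, 0.8, 0.6, 0.4, 0.1, 0.3),
#'                         c(rep("active", 4), rep("inactive", 2)))
#' cal$active    # scores 0.4 0.6 0.8 0.9
#' cal$inactive  # scores 0.7 0.9
#' @export
buildCalibration <- function(probActive, labels) {
  stopifnot(length(probActive) == length(labels),
            all(probActive >= 0 & probActive <= 1))
  labels <- as.character(labels)
  stopifnot(all(labels %in% c("active", "inactive")))
  nAct <- sum(labels == "active")
  nIna <- sum(labels == "inactive")
  if (nAct == 0 || nIna == 0)
    stop("calibration set lacks members of class: ",
         if (nAct == 0) "active" else "inactive")
  list(
    active = new("CalibrationTable", classLabel = "active",
                 scores = sort(probActive[labels == "active"])),
    inactive = new("CalibrationTable", classLabel = "inactive",
                   scores = sort(1 - probActive[labels == "inactive"]))
  )
}

#' Conformal p-value of a conformity score against a calibration table
#'
#' The rank of a test compound's conformity score within the class
#' calibration table, with the +1 correction:
#' \deqn{p = \frac{\#\{s \in \mathrm{table} : s \le c\} + 1}{n + 1}}
#' Ties count toward the numerator (unsmoothed, deterministic). With
#' `smoothed = TRUE`, ties contribute a uniformly drawn fraction instead
#' (classical smoothed conformal p-value; requires a seeded RNG for
#' reproducibility).
#'
#' @param conformity numeric vector of conformity scores (the model
#'   probability for the table's class).
#' @param table a [CalibrationTable-class].
#' @param smoothed use the randomized tie-break variant?
#' @return numeric vector of p-values in (0, 1].
#' @examples
#' tab <- new("CalibrationTable", classLabel = "active",
#'            scores = c(0.4, 0.6, 0.8, 0.9))
#' pValue(0.7, tab)   # 3/5
#' @export
pValue <- function(conformity, table, smoothed = FALSE) {
  stopifnot(is(table, "CalibrationTable"))
  s <- table@scores
  n <- length(s)
  if (n < 1) stop("empty calibration table")
  if (!smoothed) {
    # findInterval on a sorted table = #{s <= conformity}, vectorized
    (findInterval(conformity, s) + 1) / (n + 1)
  } else {
    vapply(conformity, function(cf) {
      lt <- sum(s < cf)
      eq <- sum(s == cf)
      (lt + stats::runif(1) * (eq + 1)) / (n + 1)
    }, numeric(1))
  }
}

#' Four-way conformal class assignment
#'
#' A class enters the prediction set when its conformal p-value is at or
#' above the significance level (acceptable error) `epsilon`. The four
#' outcomes are `active` / `inactive` (single-label), `both` (the model
#' cannot separate the classes at this error level) and `empty` (the
#' compound conforms to neither class).
#'
#' @param p1 active-class p-values.
#' @param p0 inactive-class p-values.
#' @param epsilon significance level in \[0, 1\].
#' @return character vector over `active`, `inactive`, `both`, `empty`.
#' @examples
#' assignClass(0.95, 0.01, 0.2)   # "active"
#' assignClass(0.5, 0.5, 0.2)     # "both"
#' @export
assignClass <- function(p1, p0, epsilon) {
  stopifnot(length(epsilon) == 1, epsilon >= 0, epsilon <= 1,
            length(p1) == length(p0),
            all(p1 >= 0 & p1 <= 1), all(p0 >= 0 & p0 <= 1))
  inA <- p1 >= epsilon
  inI <- p0 >= epsilon
  ifelse(inA & inI, "both",
         ifelse(inA, "active", ifelse(inI, "inactive", "empty")))
}

#' Aggregate conformal p-values across calibration iterations
#'
#' Calibration-set resampling is repeated (10 iterations by default in the
#' training protocol) and the per-iteration p-value pairs are combined by
#' the componentwise median, which is permutation-invariant, robust, and
#' keeps the result in (0, 1].
#'
#' @param p1,p0 numeric matrices (iterations x compounds) or vectors of
#'   per-iteration p-values for a single compound.
#' @return list with `p1` and `p0`, the per-compound medians.
#' @export
aggregateIterations <- function(p1, p0) {
  if (is.null(dim(p1))) p1 <- matrix(p1, ncol = 1)
  if (is.null(dim(p0))) p0 <- matrix(p0, ncol = 1)
  stopifnot(nrow(p1) >= 1, identical(dim(p1), dim(p0)))
  list(p1 = apply(p1, 2, stats::median),
       p0 = apply(p0, 2, stats::median))
}

#' Per-class validity of conformal predictions
#'
#' Validity for class c is the fraction of true-c compounds whose
#' prediction set at `epsilon` contains c: a `both` assignment is correct
#' for either class, an `empty` assignment is wrong for both. Under
#' exchangeability, Mondrian calibration guarantees per-class validity of
#' at least `1 - epsilon` in expectation.
#'
#' @param p1,p0 conformal p-values, aligned with `labels`.
#' @param labels true labels over `active`/`inactive`.
#' @param epsilon significance level.
#' @return named numeric, validity for `active` and `inactive` (`NA` when a
#'   class has no members).
#' @export
conformalValidity <- function(p1, p0, labels, epsilon) {
  labels <- as.character(labels)
  stopifnot(length(p1) == length(labels), length(p0) == length(labels))
  inSet <- cbind(active = p1 >= epsilon, inactive = p0 >= epsilon)
  vapply(c(active = "active", inactive = "inactive"), function(cl) {
    sel <- labels == cl
    if (!any(sel)) return(NA_real_)
    mean(inSet[sel, cl])
  }, numeric(1))
}

#' Per-class efficiency of conformal predictions
#'
#' Efficiency is the fraction of compounds receiving a single-label
#' (informative) assignment at `epsilon` — neither `both` nor `empty`.
#' With labels it is reported per true class; without labels a single
#' overall fraction is returned.
#'
#' @param p1,p0 conformal p-values.
#' @param epsilon significance level.
#' @param labels optional true labels over `active`/`inactive`.
#' @return named numeric per class, or a single overall fraction.
#' @export
conformalEfficiency <- function(p1, p0, epsilon, labels = NULL) {
  single <- assignClass(p1, p0, epsilon) %in% c("active", "inactive")
  if (is.null(labels)) return(c(overall = mean(single)))
  labels <- as.character(labels)
  vapply(c(active = "active", inactive = "inactive"), function(cl) {
    sel <- labels == cl
    if (!any(sel)) return(NA_real_)
    mean(single[sel])
  }, numeric(1))
}

#' Conformal p-values for new compounds from one trained model
#'
#' Applies every sub-model (fold x calibration iteration) of a
#' [ConformalModel-class] to a descriptor matrix and aggregates the
#' per-sub-model p-value pairs with [aggregateIterations()] (componentwise
#' median). Deterministic given the stored model artifact.
#'
#' @param model a [ConformalModel-class].
#' @param newdata numeric matrix of descriptors whose column names must
#'   match the model's descriptor list exactly (same set and order).
#' @return list with numeric vectors `p1` and `p0`, one entry per row of
#'   `newdata`.
#' @export
conformalPredict <- function(model, newdata) {
  stopifnot(is(model, "ConformalModel"))
  newdata <- as.matrix(newdata)
  if (!identical(colnames(newdata), model@descriptorNames))
    stop("descriptor mismatch: screening input must carry the model's ",
         "descriptor set in training order")
  k <- length(model@forests)
  p1 <- matrix(NA_real_, k, nrow(newdata))
  p0 <- matrix(NA_real_, k, nrow(newdata))
  for (i in seq_len(k)) {
    pr <- predict(model@forests[[i]], newdata, type = "prob")[, "active"]
    p1[i, ] <- pValue(pr, model@calibrations[[i]]$active)
    p0[i, ] <- pValue(1 - pr, model@calibrations[[i]]$inactive)
  }
  aggregateIterations(p1, p0)
}
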