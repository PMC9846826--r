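#' Stratified train/calibration/test splits
#'
#' Builds a k-fold cross-validation plan in which, per fold, 20% of the
#' data is reserved for testing, 60% for training and 20% for calibration
#' (with the default 5 folds). Test sets across folds partition the data;
#' every part preserves the class ratio to within one compound per class.
#'
#' @param labels factor or character over `active`/`inactive`.
#' @param folds number of folds (default 5).
#' @param calFraction fraction of the non-test pool reserved for
#'   calibration (default 0.25, i.e. 20% of the full data when
#'   `folds = 5`).
#' @param seed integer seed; identical seeds give identical splits.
#' @return list of length `folds`; each element has integer index vectors
#'   `train`, `calibration`, `test`.
#' @export
splitStratified <- function(labels, folds = 5, calFraction = 0.25, seed = 1) {
  labels <- as.character(labels)
  classes <- c("active", "inactive")
  stopifnot(all(labels %in% classes))
  counts <- table(factor(labels, levels = classes))
  if (any(counts < folds))
    stop("class too small to stratify into ", folds, " folds: ",
         paste(names(counts)[counts < folds], collapse = ", "))
  set.seed(seed)
  foldId <- integer(length(labels))
  for (cl in classes) {
    idx <- sample(which(labels == cl))
    foldId[idx] <- rep_len(seq_len(folds), length(idx))
  }
  lapply(seq_len(folds), function(f) {
    test <- which(foldId == f)
    pool <- which(foldId != f)
    cal <- integer()
    for (cl in classes) {
      poolC <- pool[labels[pool] == cl]
      nCal <- max(1L, round(calFraction * length(poolC)))
      cal <- c(cal, sample(poolC, nCal))
    }
    list(train = sort(setdiff(pool, cal)),
         calibration = sort(cal),
         test = sort(test))
  })
}

#' Train a random-forest bioactivity classifier
#'
#' Thin, seeded wrapper around [randomForest::randomForest()] with the
#' screening-battery defaults: 200 trees and the Gini impurity split
#' criterion (the default for classification forests). Returns an object
#' whose `predict(..., type = "prob")` yields class probabilities.
#'
#' @param x numeric descriptor matrix (compounds x descriptors).
#' @param y labels, factor or character over `active`/`inactive`.
#' @param ntree number of trees (default 200).
#' @param seed integer seed; identical seed and data give identical
#'   forests.
#' @return a `randomForest` classification object.
#' @export
trainForest <- function(x, y, ntree = 200, seed = 1) {
  y <- factor(as.character(y), levels = c("active", "inactive"))
  if (nlevels(droplevels(y)) < 2)
    stop("training set contains a single class")
  set.seed(seed)
  randomForest::randomForest(as.matrix(x), y, ntree = ntree)
}

#' Cross-validated Mondrian conformal training for one endpoint
#'
#' The full conformal protocol: stratified k-fold split (test 20%, train
#' 60%, calibration 20% per fold); within each fold the 80% non-test pool
#' is re-partitioned into train/calibration `iterations` times with a
#' fresh seed, a forest is trained and Mondrian calibration tables are
#' built per iteration; test-set p-value pairs are aggregated over the
#' iterations by the componentwise median. Validity and efficiency are
#' reported per class on the pooled test predictions for every
#' significance level in `epsilons`.
#'
#' @param dataset an [AssayDataset-class].
#' @param folds cross-validation folds (default 5).
#' @param iterations calibration resamplings per fold (default 10).
#' @param ntree trees per forest (default 200).
#' @param epsilons significance grid (default `c(0.1, 0.15, 0.2, 0.25,
#'   0.3)`).
#' @param seed master seed; all sub-seeds are derived from it.
#' @return list with components:
#'   \describe{
#'     \item{model}{a [ConformalModel-class] holding every fold x
#'       iteration sub-model, usable for screening new compounds.}
#'     \item{test}{data.frame of pooled held-out predictions:
#'       `compound_id`, `label`, `fold`, aggregated `p1`, `p0`.}
#'     \item{metrics}{data.frame per epsilon: per-class validity and
#'       efficiency.}
#'   }
#' @export
trainConformal <- function(dataset, folds = 5, iterations = 10, ntree = 200,
                           epsilons = c(0.1, 0.15, 0.2, 0.25, 0.3),
                           seed = 1) {
  stopifnot(is(dataset, "AssayDataset"))
  x <- descriptors(dataset)
  y <- activityLabels(dataset)
  plan <- splitStratified(y, folds = folds, seed = seed)
  set.seed(seed)
  subSeed <- matrix(sample.int(.Machine$integer.max,
                               folds * iterations),
                    nrow = folds)
  forests <- list()
  calibs <- list()
  testRows <- vector("list", folds)
  for (f in seq_len(folds)) {
    test <- plan[[f]]$test
    pool <- sort(c(plan[[f]]$train, plan[[f]]$calibration))
    p1 <- matrix(NA_real_, iterations, length(test))
    p0 <- matrix(NA_real_, iterations, length(test))
    for (j in seq_len(iterations)) {
      s <- subSeed[f, j]
      # re-partition the pool 75/25 (= 60/20 of the full data), stratified
      part <- .splitPool(y[pool], calFraction = 0.25, seed = s)
      tr <- pool[part$train]
      ca <- pool[part$calibration]
      rf <- trainForest(x[tr, , drop = FALSE], y[tr], ntree = ntree,
                        seed = s)
      probCal <- predict(rf, x[ca, , drop = FALSE], type = "prob")[, "active"]
      cal <- buildCalibration(probCal, y[ca])
      probTest <- predict(rf, x[test, , drop = FALSE],
                          type = "prob")[, "active"]
      p1[j, ] <- pValue(probTest, cal$active)
      p0[j, ] <- pValue(1 - probTest, cal$inactive)
      forests[[length(forests) + 1L]] <- rf
      calibs[[length(calibs) + 1L]] <- cal
    }
    agg <- aggregateIterations(p1, p0)
    testRows[[f]] <- data.frame(
      compound_id = compoundIds(dataset)[test],
      label = as.character(y[test]),
      fold = f, p1 = agg$p1, p0 = agg$p0,
      stringsAsFactors = FALSE)
  }
  test <- do.call(rbind, testRows)
  metrics <- do.call(rbind, lapply(epsilons, function(eps) {
    v <- conformalValidity(test$p1, test$p0, test$label, eps)
    e <- conformalEfficiency(test$p1, test$p0, eps, test$label)
    data.frame(epsilon = eps,
               validity_active = v[["active"]],
               validity_inactive = v[["inactive"]],
               efficiency_active = e[["active"]],
               efficiency_inactive = e[["inactive"]])
  }))
  model <- new("ConformalModel",
               endpointName = endpointName(dataset),
               descriptorNames = colnames(x),
               forests = forests, calibrations = calibs,
               epsilons = epsilons, seed = as.integer(seed))
  list(model = model, test = test, metrics = metrics)
}

# stratified train/calibration cut of a non-test pool (no test part)
.splitPool <- function(labels, calFraction = 0.25, seed = 1) {
  labels <- as.character(labels)
  set.seed(seed)
  cal <- integer()
  for (cl in c("active", "inactive")) {
    idxC <- which(labels == cl)
    nCal <- max(1L, round(calFraction * length(idxC)))
    if (nCal >= length(idxC))
      stop("class too small to reserve a calibration part: ", cl)
    cal <- c(cal, sample(idxC, nCal))
  }
  list(train = sort(setdiff(seq_along(labels), cal)),
       calibration = sort(cal))
}

#' Compare imbalance-handling training protocols
#'
#' Runs the same stratified cross-validation with each requested protocol
#' and reports one averaged metrics row per protocol. Non-conformal
#' protocols train on the full 80% non-test pool after resampling
#' ([resampleProtocol()]) and predict by majority vote; the conformal
#' protocol (`"cp"`) follows [trainConformal()] and is reported twice,
#' mirroring the two conventions for conformal scoring: once over
#' single-label predictions only (`cp`, coverage < 1) and once with
#' `both`/`empty` assignments counted as errors (`cp_all`, coverage 1).
#'
#' @param dataset an [AssayDataset-class] that passes [filterAssay()].
#' @param protocols subset of `c("naive", "undersample", "oversample_dup",
#'   "smote", "rose", "cp")`.
#' @param folds,iterations,ntree,seed as in [trainConformal()];
#'   `iterations` applies to `"cp"` only.
#' @param epsilon significance level for conformal class assignment
#'   (default 0.2).
#' @return data.frame, one row per protocol (two for `"cp"`), with the
#'   metrics of [evaluateMetrics()] computed on the pooled test
#'   predictions of all folds.
#' @export
runProtocolComparison <- function(dataset,
                                  protocols = c("naive", "undersample",
                                                "oversample_dup", "smote",
                                                "rose", "cp"),
                                  folds = 5, iterations = 10, ntree = 200,
                                  epsilon = 0.2, seed = 1) {
  stopifnot(is(dataset, "AssayDataset"))
  protocols <- match.arg(protocols, several.ok = TRUE)
  x <- descriptors(dataset)
  y <- activityLabels(dataset)
  plan <- splitStratified(y, folds = folds, seed = seed)
  rows <- list()
  for (proto in setdiff(protocols, "cp")) {
    pred <- character(length(y))
    prob <- numeric(length(y))
    for (f in seq_len(folds)) {
      test <- plan[[f]]$test
      pool <- sort(c(plan[[f]]$train, plan[[f]]$calibration))
      rs <- resampleProtocol(x[pool, , drop = FALSE], y[pool],
                             protocol = proto, seed = seed + f)
      rf <- trainForest(rs$x, rs$y, ntree = ntree, seed = seed + f)
      pr <- predict(rf, x[test, , drop = FALSE], type = "prob")[, "active"]
      prob[test] <- pr
      pred[test] <- ifelse(pr >= 0.5, "active", "inactive")
    }
    m <- evaluateMetrics(pred, y, probActive = prob)
    rows[[proto]] <- cbind(protocol = proto, m)
  }
  if ("cp" %in% protocols) {
    cv <- trainConformal(dataset, folds = folds, iterations = iterations,
                         ntree = ntree, epsilons = epsilon, seed = seed)
    assign4 <- assignClass(cv$test$p1, cv$test$p0, epsilon)
    mSingle <- evaluateMetrics(assign4, cv$test$label,
                               probActive = cv$test$p1, epsilon = epsilon)
    mSingle$validity_active <- cv$metrics$validity_active
    mSingle$validity_inactive <- cv$metrics$validity_inactive
    mSingle$efficiency_active <- cv$metrics$efficiency_active
    mSingle$efficiency_inactive <- cv$metrics$efficiency_inactive
    rows[["cp"]] <- cbind(protocol = "cp", mSingle)
    mAll <- evaluateMetrics(assign4, cv$test$label,
                            probActive = cv$test$p1, epsilon = epsilon,
                            countUnclassified = TRUE)
    rows[["cp_all"]] <- cbind(protocol = "cp_all", mAll)
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    miss <- setdiff(c("validity_active", "validity_inactive",
                      "efficiency_active", "efficiency_inactive"),
                    names(r))
    for (nm in miss) r[[nm]] <- NA_real_
    r
  }))
  rownames(out) <- NULL
  out
}
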