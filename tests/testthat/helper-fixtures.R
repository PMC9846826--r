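# Small shared fixtures, built in code at test time.

# A modest trained battery + screened planted library; cheap enough to
# rebuild per test file, deterministic by construction.
makeSmallScreen <- function(nEndpoints = 3, seed = 42) {
  prev <- stats::setNames(c(0.12, 0.2, 0.15)[seq_len(nEndpoints)],
                          paste0("ep", seq_len(nEndpoints)))
  fx <- makeBatteryFixture(nEndpoints = nEndpoints, prevalences = prev,
                           nPerEndpoint = 150, librarySize = 40,
                           nFeatures = 8, separation = 3,
                           nNearDuplicates = 3, seed = seed)
  models <- lapply(fx$datasets, function(d)
    trainConformal(d, folds = 3, iterations = 2, ntree = 50,
                   seed = seed)$model)
  pvm <- screenLibrary(models, fx$library$descriptors)
  list(fixture = fx, models = models, pvm = pvm)
}

# Hand-crafted p-value matrix with exactly known cells.
craftedPVM <- function(p1, p0, endpoints = NULL) {
  p1 <- as.matrix(p1); p0 <- as.matrix(p0)
  if (!is.null(endpoints)) colnames(p1) <- colnames(p0) <- endpoints
  pValueMatrix(p1, p0)
}

# Independent brute-force conformal p-value: explicit loop and count.
bruteForcePValue <- function(conformity, scores) {
  count <- 0L
  for (s in scores) if (s <= conformity) count <- count + 1L
  (count + 1) / (length(scores) + 1)
}

# Independent metrics from an explicit confusion matrix.
bruteForceMetrics <- function(tp, fn, fp, tn) {
  list(
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    accuracy = (tp + tn) / (tp + fn + fp + tn),
    mcc = {
      den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
      if (den > 0) (tp * tn - fp * fn) / den else NA_real_
    })
}
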