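test_that("stratified splits preserve class ratios and partition the data", {
  labels <- rep(c("active", "inactive"), c(10, 90))
  plan <- splitStratified(labels, folds = 5, seed = 4)
  expect_length(plan, 5)
  for (f in plan) {
    expect_length(f$test, 20)
    expect_equal(sum(labels[f$test] == "active"), 2)
    expect_length(intersect(f$train, f$calibration), 0)
    expect_length(intersect(f$train, f$test), 0)
  }
  # test sets partition the data
  allTest <- sort(unlist(lapply(plan, `[[`, "test")))
  expect_identical(allTest, seq_along(labels))
  # same seed, same split
  expect_identical(splitStratified(labels, folds = 5, seed = 4), plan)
  expect_error(splitStratified(rep(c("active", "inactive"), c(3, 97)),
                               folds = 5), "active")
})

test_that("stratification bound holds on random compositions", {
  set.seed(19)
  for (i in 1:20) {
    n <- sample(80:300, 1)
    nA <- sample(10:(n %/% 2), 1)
    labels <- sample(rep(c("active", "inactive"), c(nA, n - nA)))
    plan <- splitStratified(labels, folds = 5, seed = i)
    full <- mean(labels == "active")
    for (f in plan) {
      for (part in f) {
        expect_lte(abs(mean(labels[part] == "active") - full),
                   1 / length(part) + 1e-9)
      }
    }
  }
})

test_that("forest training is seeded and probabilistic", {
  ds <- makeEndpointDataset(300, 0.2, separation = 3, nFeatures = 8,
                            seed = 6)
  x <- descriptors(ds); y <- activityLabels(ds)
  rf1 <- trainForest(x, y, ntree = 60, seed = 8)
  rf2 <- trainForest(x, y, ntree = 60, seed = 8)
  p1 <- predict(rf1, x, type = "prob")
  p2 <- predict(rf2, x, type = "prob")
  expect_identical(p1, p2)
  expect_equal(unname(rowSums(p1)), rep(1, nrow(x)))
  expect_error(trainForest(x, rep("inactive", nrow(x))), "single class")
})

test_that("undersampling yields exact class balance", {
  ds <- makeEndpointDataset(100, 0.1, seed = 2, nFeatures = 4)
  rs <- resampleProtocol(descriptors(ds), activityLabels(ds),
                         "undersample", seed = 3)
  expect_equal(as.vector(table(rs$y)), c(10, 10))
  # undersampled rows are a subset of the originals
  expect_true(all(apply(rs$x, 1, function(r)
    any(colSums(abs(t(descriptors(ds)) - r)) < 1e-12))))
})

test_that("duplication oversampling only copies minority compounds", {
  ds <- makeEndpointDataset(100, 0.1, seed = 2, nFeatures = 4)
  x <- descriptors(ds); y <- activityLabels(ds)
  rs <- resampleProtocol(x, y, "oversample_dup", seed = 3)
  expect_equal(as.vector(table(rs$y)), c(90, 90))
  # first nrow(x) rows are the untouched originals
  expect_equal(rs$x[seq_len(nrow(x)), ], x, ignore_attr = TRUE)
  extras <- rs$x[-seq_len(nrow(x)), , drop = FALSE]
  minRows <- x[y == "active", , drop = FALSE]
  expect_true(all(apply(extras, 1, function(r)
    any(colSums(abs(t(minRows) - r)) < 1e-12))))
})

test_that("SMOTE interpolates on segments between minority neighbors", {
  # minority placed on a line: synthetic points must stay on it
  set.seed(14)
  nMin <- 12; nMaj <- 60
  tRaw <- sort(runif(nMin))
  dir <- c(2, -1, 0.5)
  xMin <- outer(tRaw, dir) + 5
  xMaj <- matrix(rnorm(nMaj * 3, sd = 0.1), nMaj, 3)
  x <- rbind(xMin, xMaj)
  colnames(x) <- c("a", "b", "c")
  y <- rep(c("active", "inactive"), c(nMin, nMaj))
  rs <- resampleProtocol(x, y, "smote", seed = 9)
  expect_equal(as.vector(table(rs$y)), c(60, 60))
  synth <- rs$x[-seq_len(nrow(x)), , drop = FALSE]
  # on the line: recover affine coefficient from first coordinate and
  # check all coordinates agree, with coefficient inside the hull
  for (i in seq_len(nrow(synth))) {
    tHat <- (synth[i, 1] - 5) / dir[1]
    expect_equal(unname(synth[i, ]), unname(outer(tHat, dir)[1, ] + 5),
                 tolerance = 1e-8)
    expect_gte(tHat, min(tRaw) - 1e-9)
    expect_lte(tHat, max(tRaw) + 1e-9)
  }
  expect_error(
    resampleProtocol(x[c(1:4, 13:60), ], y[c(1:4, 13:60)], "smote"),
    "minority")
})

test_that("ROSE doubles the data with balanced smoothed classes", {
  ds <- makeEndpointDataset(100, 0.1, seed = 2, nFeatures = 4)
  rs <- resampleProtocol(descriptors(ds), activityLabels(ds), "rose",
                         seed = 5)
  expect_equal(nrow(rs$x), 200)
  expect_equal(as.vector(table(rs$y)), c(100, 100))
  expect_false(any(!is.finite(rs$x)))
  # smoothed: samples are near, but not identical to, original rows
  expect_false(any(duplicated(rbind(descriptors(ds), rs$x))[-(1:100)]))
})

test_that("naive protocol leaves the training part untouched", {
  ds <- makeEndpointDataset(60, 0.2, seed = 2, nFeatures = 4)
  rs <- resampleProtocol(descriptors(ds), activityLabels(ds), "naive")
  expect_identical(rs$x, descriptors(ds))
  expect_identical(as.character(rs$y), as.character(activityLabels(ds)))
})

test_that("metrics panel matches hand-computed confusion values", {
  m <- evaluateMetrics(c("active", "inactive", "active", "inactive"),
                       c("active", "inactive", "active", "inactive"))
  expect_equal(m$mcc, 1)
  expect_equal(m$balanced_accuracy, 1)
  # confusion TP=3 FN=1 FP=2 TN=4
  pred <- rep(c("active", "inactive", "active", "inactive"), c(3, 1, 2, 4))
  truth <- rep(c("active", "inactive"), c(4, 6))
  m2 <- evaluateMetrics(pred, truth)
  expect_equal(m2$sensitivity, 0.75)
  expect_equal(m2$specificity, 2 / 3, tolerance = 1e-9)
  expect_equal(m2$mcc, 10 / sqrt(600), tolerance = 1e-9)
  expect_equal(m2$coverage, 1)
  # coverage counts only single-label assignments
  pred3 <- c(rep("active", 4), rep("inactive", 4), "both", "empty")
  m3 <- evaluateMetrics(pred3, rep(c("active", "inactive"), 5))
  expect_equal(m3$coverage, 0.8)
})

test_that("metrics agree with a brute-force oracle on random confusions", {
  set.seed(23)
  for (i in 1:200) {
    cnt <- sample(0:30, 4, replace = TRUE)  # tp, fn, fp, tn
    if (cnt[1] + cnt[2] == 0 || cnt[3] + cnt[4] == 0) next
    pred <- rep(c("active", "inactive", "active", "inactive"), cnt)
    truth <- rep(c("active", "active", "inactive", "inactive"), cnt)
    m <- evaluateMetrics(pred, truth)
    o <- bruteForceMetrics(cnt[1], cnt[2], cnt[3], cnt[4])
    expect_equal(m$sensitivity, o$sensitivity)
    expect_equal(m$specificity, o$specificity)
    expect_equal(m$accuracy, o$accuracy)
    expect_equal(m$mcc, o$mcc)
  }
})

test_that("degenerate confusion matrices report NA, not NaN", {
  m <- evaluateMetrics(rep("active", 4), rep("active", 4))
  expect_true(is.na(m$specificity))
  expect_false(is.nan(m$balanced_accuracy))
})

test_that("protocol comparison emits the expected schema", {
  ds <- makeEndpointDataset(250, 0.12, separation = 3, nFeatures = 6,
                            seed = 33)
  tab <- runProtocolComparison(ds, protocols = c("naive", "cp"),
                               folds = 3, iterations = 2, ntree = 40,
                               seed = 33)
  expect_setequal(tab$protocol, c("naive", "cp", "cp_all"))
  cpRow <- tab[tab$protocol == "cp", ]
  expect_false(is.na(cpRow$validity_active))
  expect_false(is.na(cpRow$efficiency_inactive))
  expect_lte(cpRow$coverage, 1)
  expect_true(is.na(tab[tab$protocol == "naive", "validity_active"]))
  expect_equal(tab[tab$protocol == "cp_all", "coverage"], 1)
  # bit-reproducible under a fixed master seed
  tab2 <- runProtocolComparison(ds, protocols = c("naive", "cp"),
                                folds = 3, iterations = 2, ntree = 40,
                                seed = 33)
  expect_identical(tab, tab2)
})

test_that("cross-validated conformal training is reproducible", {
  ds <- makeEndpointDataset(300, 0.15, separation = 3, nFeatures = 6,
                            seed = 44)
  cv1 <- trainConformal(ds, folds = 3, iterations = 2, ntree = 40,
                        seed = 44)
  cv2 <- trainConformal(ds, folds = 3, iterations = 2, ntree = 40,
                        seed = 44)
  expect_identical(cv1$test, cv2$test)
  expect_identical(cv1$metrics, cv2$metrics)
  # pooled test predictions cover every compound once
  expect_setequal(cv1$test$compound_id, compoundIds(ds))
  expect_equal(nrow(cv1$test), length(ds))
})
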