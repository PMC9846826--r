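test_that("calibration tables are class-conditional and sorted", {
  cal <- buildCalibration(c(0.9, 0.8, 0.6, 0.4, 0.1, 0.3),
                          c(rep("active", 4), rep("inactive", 2)))
  expect_equal(cal$active@scores, c(0.4, 0.6, 0.8, 0.9))
  expect_equal(cal$inactive@scores, c(0.7, 0.9))
  expect_identical(cal$active@classLabel, "active")
  expect_error(buildCalibration(c(0.2, 0.6), c("active", "active")),
               "inactive")
})

test_that("conformal p-values match their definition and bounds", {
  tab <- new("CalibrationTable", classLabel = "active",
             scores = c(0.4, 0.6, 0.8, 0.9))
  expect_equal(pValue(0.7, tab), 3 / 5)
  expect_equal(pValue(1.0, tab), 1.0)           # maximal rank
  expect_equal(pValue(0.0, tab), 1 / 5)         # +1 correction floor
  expect_equal(pValue(0.6, tab), 3 / 5)         # tie counts in numerator
  expect_error(pValue(0.5, new("CalibrationTable", classLabel = "active",
                               scores = numeric(0))))
})

test_that("p-values agree exactly with a brute-force oracle", {
  set.seed(101)
  for (i in 1:1000) {
    n <- sample(1:60, 1)
    scores <- sort(round(runif(n), 2))
    conf <- round(runif(1), 2)
    tab <- new("CalibrationTable", classLabel = "active", scores = scores)
    expect_identical(pValue(conf, tab), bruteForcePValue(conf, scores))
  }
})

test_that("smoothed p-values stay in (0, 1] and preserve rank order", {
  tab <- new("CalibrationTable", classLabel = "active",
             scores = sort(runif(50)))
  set.seed(5)
  ps <- pValue(runif(200), tab, smoothed = TRUE)
  expect_true(all(ps > 0 & ps <= 1))
  set.seed(9)
  a <- pValue(c(0.1, 0.9), tab, smoothed = TRUE)
  expect_lt(a[1], a[2])
})

test_that("four-way class assignment follows the epsilon rule", {
  expect_identical(assignClass(0.95, 0.01, 0.2), "active")
  expect_identical(assignClass(0.01, 0.95, 0.2), "inactive")
  expect_identical(assignClass(0.5, 0.5, 0.2), "both")
  expect_identical(assignClass(0.1, 0.1, 0.2), "empty")
  # boundary: p-value equal to epsilon means the class is included
  expect_identical(assignClass(0.2, 0.1, 0.2), "active")
  expect_identical(assignClass(0.2, 0.2, 0.2), "both")
  # vectorized
  expect_identical(assignClass(c(0.9, 0.1), c(0.1, 0.9), 0.2),
                   c("active", "inactive"))
})

test_that("prediction sets are nested across significance levels", {
  setAt <- function(p1, p0, eps) {
    c("active", "inactive")[c(p1 >= eps, p0 >= eps)]
  }
  set.seed(21)
  for (i in 1:200) {
    p1 <- runif(1); p0 <- runif(1)
    eps <- sort(runif(2))
    s1 <- setAt(p1, p0, eps[1])   # lower epsilon, larger set
    s2 <- setAt(p1, p0, eps[2])
    expect_true(all(s2 %in% s1))
  }
})

test_that("iteration aggregation is the componentwise median", {
  single <- aggregateIterations(0.4, 0.6)
  expect_equal(single$p1, 0.4)
  expect_equal(single$p0, 0.6)
  agg <- aggregateIterations(matrix(c(0.1, 0.2, 0.9), 3, 1),
                             matrix(c(0.3, 0.5, 0.7), 3, 1))
  expect_equal(agg$p1, 0.2)
  expect_equal(agg$p0, 0.5)
  # permutation invariance
  p1 <- matrix(runif(30), 10, 3); p0 <- matrix(runif(30), 10, 3)
  perm <- sample(10)
  expect_equal(aggregateIterations(p1, p0),
               aggregateIterations(p1[perm, ], p0[perm, ]))
})

test_that("validity and efficiency count prediction-set membership", {
  # all 'both': correct for every class
  v <- conformalValidity(rep(0.9, 6), rep(0.9, 6),
                         rep(c("active", "inactive"), 3), 0.2)
  expect_equal(unname(v), c(1, 1))
  # 5 true actives: 3 'active', 1 'inactive', 1 'empty' -> 0.6
  p1 <- c(0.9, 0.8, 0.7, 0.05, 0.01)
  p0 <- c(0.1, 0.1, 0.1, 0.90, 0.01)
  v2 <- conformalValidity(p1, p0, rep("active", 5), 0.2)
  expect_equal(unname(v2[["active"]]), 0.6)
  expect_true(is.na(v2[["inactive"]]))
  # efficiency: 3 single + 1 empty of 4 -> 0.75 overall
  e <- conformalEfficiency(c(0.9, 0.9, 0.05, 0.05),
                           c(0.1, 0.05, 0.9, 0.1), 0.2)
  expect_equal(unname(e), 0.75)
  eAll <- conformalEfficiency(rep(0.9, 4), rep(0.9, 4), 0.2)
  expect_equal(unname(eAll), 0)
})

test_that("true-class p-values are approximately uniform", {
  # exchangeable scores: calibration and test drawn from one distribution
  set.seed(31)
  tab <- new("CalibrationTable", classLabel = "active",
             scores = sort(runif(999)))
  ps <- pValue(runif(1000), tab)
  ks <- unname(suppressWarnings(stats::ks.test(ps, "punif"))$statistic)
  expect_lt(ks, 0.1)
})

test_that("Mondrian per-class error is bounded by epsilon on exchangeable data", {
  # single split with >= 500 test compounds per class
  ds <- makeEndpointDataset(2500, 0.5, separation = 2, nFeatures = 10,
                            seed = 17)
  x <- descriptors(ds); y <- activityLabels(ds)
  set.seed(17)
  idx <- sample(2500)
  trainIdx <- idx[1:1000]; calIdx <- idx[1001:1500]; testIdx <- idx[1501:2500]
  rf <- trainForest(x[trainIdx, ], y[trainIdx], ntree = 100, seed = 17)
  cal <- buildCalibration(
    predict(rf, x[calIdx, ], type = "prob")[, "active"], y[calIdx])
  pr <- predict(rf, x[testIdx, ], type = "prob")[, "active"]
  p1 <- pValue(pr, cal$active)
  p0 <- pValue(1 - pr, cal$inactive)
  yTest <- y[testIdx]
  for (eps in c(0.1, 0.15, 0.2, 0.25, 0.3)) {
    v <- conformalValidity(p1, p0, yTest, eps)
    for (cl in c("active", "inactive")) {
      nC <- sum(yTest == cl)
      bound <- eps + 3 * sqrt(eps * (1 - eps) / nC)
      expect_lte(1 - v[[cl]], bound)
    }
  }
})

test_that("conformal prediction on new data is deterministic and guarded", {
  sc <- makeSmallScreen(nEndpoints = 2, seed = 13)
  m <- sc$models[[1]]
  lib <- sc$fixture$library$descriptors
  a <- conformalPredict(m, lib)
  b <- conformalPredict(m, lib)
  expect_identical(a, b)
  expect_true(all(a$p1 > 0 & a$p1 <= 1))
  badLib <- lib[, rev(seq_len(ncol(lib)))]
  expect_error(conformalPredict(m, badLib), "descriptor mismatch")
})
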