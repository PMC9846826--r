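test_that("fingerprints encode which class has the larger p-value", {
  set.seed(3)
  pvm <- craftedPVM(p1 = matrix(runif(23 * 5), 5, 23),
                    p0 = matrix(runif(23 * 5), 5, 23))
  fp <- bioactivityFingerprint(pvm)
  expect_equal(dim(fp), c(5, 23))
  expect_true(all(fp %in% c(0L, 1L)))
  expect_identical(fp, (pActive(pvm) > pInactive(pvm)) + 0L,
                   ignore_attr = TRUE)
  # ties give bit 0
  pvmTie <- craftedPVM(matrix(0.5, 2, 4), matrix(0.5, 2, 4))
  expect_true(all(bioactivityFingerprint(pvmTie) == 0L))
  # single known cell
  pvmOne <- craftedPVM(cbind(0.9), cbind(0.1))
  expect_equal(unname(bioactivityFingerprint(pvmOne)[1, 1]), 1L)
})

test_that("Tanimoto similarity follows c / (a + b - c)", {
  expect_equal(tanimoto(c(1, 1, 0), c(0, 1, 1)), 1 / 3)
  expect_equal(tanimoto(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_equal(tanimoto(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)
  expect_warning(z <- tanimoto(c(0, 0), c(0, 0)), "all-zero")
  expect_equal(z, 0)
  expect_error(tanimoto(c(1, 0), c(1, 0, 1)))
})

test_that("Tanimoto is symmetric and bounded on random fingerprints", {
  set.seed(29)
  for (i in 1:1000) {
    len <- sample(5:30, 1)
    a <- rbinom(len, 1, 0.4); b <- rbinom(len, 1, 0.4)
    if (sum(a) + sum(b) == 0) next
    tab <- tanimoto(a, b)
    expect_identical(tab, tanimoto(b, a))
    expect_gte(tab, 0); expect_lte(tab, 1)
    if (sum(a) > 0) expect_equal(tanimoto(a, a), 1)
  }
})

test_that("Tanimoto ranking matches an exhaustive brute-force scan", {
  set.seed(37)
  n <- 300
  fps <- matrix(rbinom(n * 23, 1, 0.5), n, 23,
                dimnames = list(sprintf("c%03d", seq_len(n)), NULL))
  ref <- rbinom(23, 1, 0.5)
  ranked <- rankByTanimoto(fps, ref, cutoff = 0.5)
  # oracle: loop over every compound, compute T, filter, sort
  sims <- numeric(n)
  for (i in seq_len(n)) {
    a <- sum(fps[i, ]); b <- sum(ref); cc <- sum(fps[i, ] & ref)
    sims[i] <- if (a + b == 0) 0 else cc / (a + b - cc)
  }
  keep <- which(sims >= 0.5)
  ord <- keep[order(-sims[keep], rownames(fps)[keep])]
  expect_identical(ranked$compound_id, rownames(fps)[ord])
  expect_equal(ranked$tanimoto, sims[ord])
})

test_that("a library containing the reference ranks it first with T = 1", {
  set.seed(41)
  fps <- matrix(rbinom(20 * 23, 1, 0.3), 20, 23,
                dimnames = list(sprintf("c%02d", 1:20), NULL))
  ref <- fps[7, ]
  if (sum(ref) == 0) ref[1] <- 1L
  fps[7, ] <- ref
  ranked <- rankByTanimoto(fps, ref, cutoff = 0.8)
  expect_equal(ranked$tanimoto[1], 1)
  expect_true("c07" %in% ranked$compound_id[ranked$exact_match])
  exact <- rankByTanimoto(fps, ref, cutoff = 1)
  expect_true(all(exact$tanimoto == 1))
})

test_that("planted near-duplicates of a dense reference exceed the cutoff", {
  fx <- makeBatteryFixture(nEndpoints = 23, nPerEndpoint = 100,
                           librarySize = 50, nNearDuplicates = 4, seed = 51)
  profiles <- fx$library$profiles
  refFp <- fx$referenceProfiles["REF_A", ]
  ranked <- rankByTanimoto(profiles, refFp, cutoff = 0.8)
  dupIds <- sprintf("DUP_A_%02d", 1:4)
  expect_true(all(dupIds %in% ranked$compound_id))
  # brute-force Hamming-to-Tanimoto check for each planted duplicate
  for (id in dupIds) {
    ham <- sum(profiles[id, ] != refFp)
    expect_lte(ham, 2)
    expect_gte(tanimoto(profiles[id, ], refFp),
               (sum(refFp) - ham) / (sum(refFp) + ham))
  }
})

test_that("t-SNE embedding is shaped, seeded and locally faithful", {
  # two planted profile groups far apart in p-value space
  set.seed(61)
  n <- 60
  grp <- rep(c(1, 2), each = n / 2)
  p1 <- matrix(0, n, 10); p0 <- matrix(0, n, 10)
  p1[grp == 1, ] <- matrix(runif(10 * n / 2, 0.75, 1), n / 2)
  p1[grp == 2, ] <- matrix(runif(10 * n / 2, 0.01, 0.2), n / 2)
  p0[grp == 1, ] <- matrix(runif(10 * n / 2, 0.01, 0.2), n / 2)
  p0[grp == 2, ] <- matrix(runif(10 * n / 2, 0.75, 1), n / 2)
  pvm <- craftedPVM(p1, p0)
  emb <- embedPValues(pvm, perplexity = 10, seed = 5, maxIter = 300)
  expect_equal(nrow(emb), n)
  emb2 <- embedPValues(pvm, perplexity = 10, seed = 5, maxIter = 300)
  expect_identical(emb, emb2)
  co <- as.matrix(emb[, c("x", "y")])
  d <- as.matrix(dist(co))
  within <- mean(d[grp == 1, grp == 1][upper.tri(diag(n / 2))])
  between <- mean(d[grp == 1, grp == 2])
  expect_lt(within, between)
  expect_error(embedPValues(pvm, perplexity = 30), "perplexity")
})

test_that("density clustering recovers planted blobs around a reference", {
  set.seed(71)
  blobA <- cbind(rnorm(40, 0, 0.5), rnorm(40, 0, 0.5))
  blobB <- cbind(rnorm(40, 20, 0.5), rnorm(40, 20, 0.5))
  emb <- data.frame(compound_id = sprintf("c%02d", 1:80),
                    x = c(blobA[, 1], blobB[, 1]),
                    y = c(blobA[, 2], blobB[, 2]))
  members <- clusterAround(emb, "c01")
  expect_setequal(members, sprintf("c%02d", 1:40))
  # permutation invariance of membership
  perm <- sample(80)
  membersPerm <- clusterAround(emb[perm, ], "c01")
  expect_setequal(membersPerm, members)
  # isolated reference -> singleton
  emb2 <- rbind(emb, data.frame(compound_id = "lone", x = 500, y = 500))
  expect_identical(clusterAround(emb2, "lone"), "lone")
  expect_error(clusterAround(emb, "missing"), "reference")
})

test_that("consensus is the intersection without the reference", {
  expect_identical(consensusSet(c("a", "b", "c"), c("b", "c", "d")),
                   c("b", "c"))
  expect_length(consensusSet(c("a", "b"), c("c", "d")), 0)
  expect_setequal(consensusSet(c("ref", "a", "b"), c("ref", "a", "b"),
                               referenceId = "ref"), c("a", "b"))
  hits <- data.frame(compound_id = c("a", "x"), tanimoto = c(1, 0.9))
  expect_identical(consensusSet(c("a", "b"), hits), "a")
})
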