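#' Bioactivity fingerprints from conformal p-value profiles
#'
#' Converts each compound's p-value profile into a binary fingerprint of
#' length equal to the battery size: bit j is 1 when `p1 > p0` for
#' endpoint j and 0 otherwise (ties give 0). The bits express which class
#' carries the larger p-value, not the class assignment at any
#' significance level, so fingerprints are threshold-free.
#'
#' @param matrix a [PValueMatrix-class].
#' @return integer 0/1 matrix (compounds x endpoints) with dimnames.
#' @export
bioactivityFingerprint <- function(matrix) {
  stopifnot(is(matrix, "PValueMatrix"))
  fp <- (matrix@p1 > matrix@p0) + 0L
  storage.mode(fp) <- "integer"
  fp
}

#' Tanimoto similarity of two binary fingerprints
#'
#' `T = c / (a + b - c)` with `a`, `b` the on-bit counts of the two
#' fingerprints and `c` the shared on-bits. Two all-zero fingerprints have
#' no on-bits to compare; they return 0 with a warning rather than NaN.
#'
#' @param fpA,fpB binary vectors of equal length.
#' @return similarity in \[0, 1\].
#' @examples
#' tanimoto(c(1, 1, 0), c(0, 1, 1))   # 1/3
#' @export
tanimoto <- function(fpA, fpB) {
  stopifnot(length(fpA) == length(fpB),
            all(fpA %in% c(0, 1)), all(fpB %in% c(0, 1)))
  a <- sum(fpA); b <- sum(fpB); cc <- sum(fpA & fpB)
  if (a + b == 0) {
    warning("both fingerprints are all-zero; returning 0")
    return(0)
  }
  cc / (a + b - cc)
}

#' Rank library compounds by Tanimoto similarity to a reference
#'
#' Compares every library fingerprint with the reference profile, keeps
#' compounds at or above the similarity cutoff, and orders them by
#' descending similarity with ties broken deterministically by compound
#' id. Exact profile matches (`T = 1`) are flagged.
#'
#' @param fingerprints 0/1 matrix (compounds x endpoints) with compound
#'   ids as rownames, e.g. from [bioactivityFingerprint()].
#' @param reference binary vector of the same battery length.
#' @param cutoff similarity cutoff in \[0, 1\], default 0.8.
#' @return data.frame `compound_id`, `tanimoto`, `exact_match`, sorted.
#' @export
rankByTanimoto <- function(fingerprints, reference, cutoff = 0.8) {
  fingerprints <- as.matrix(fingerprints)
  stopifnot(ncol(fingerprints) == length(reference))
  ids <- rownames(fingerprints)
  if (is.null(ids)) ids <- paste0("cmpd_", seq_len(nrow(fingerprints)))
  sims <- apply(fingerprints, 1, function(r)
    suppressWarnings(tanimoto(r, reference)))
  keep <- which(sims >= cutoff)
  ord <- keep[order(-sims[keep], ids[keep])]
  data.frame(compound_id = ids[ord], tanimoto = unname(sims[ord]),
             exact_match = unname(sims[ord] == 1),
             stringsAsFactors = FALSE)
}

#' t-SNE embedding of conformal p-value profiles
#'
#' Embeds each compound's p-value profile into two dimensions with exact
#' (non-approximated) t-distributed stochastic neighbor embedding:
#' per-point bandwidths are calibrated to the target perplexity by binary
#' search, affinities use the symmetrized Gaussian kernel, the low-
#' dimensional kernel is the Student t with one degree of freedom, and the
#' map is optimized by momentum gradient descent with early exaggeration.
#' Deterministic given the seed.
#'
#' The default feature set concatenates the p1 and p0 profiles (2 x
#' battery size features); `features = "p1_only"` uses the active-class
#' profile alone.
#'
#' @param matrix a [PValueMatrix-class].
#' @param perplexity t-SNE perplexity (default 30); requires
#'   `3 * perplexity < n - 1` compounds.
#' @param seed integer seed for the map initialization.
#' @param features `"p1_and_p0"` (default) or `"p1_only"`.
#' @param maxIter gradient-descent iterations (default 500).
#' @return data.frame `compound_id`, `x`, `y`, with attributes
#'   `perplexity` and `seed`.
#' @export
embedPValues <- function(matrix, perplexity = 30, seed = 1,
                         features = c("p1_and_p0", "p1_only"),
                         maxIter = 500) {
  stopifnot(is(matrix, "PValueMatrix"))
  features <- match.arg(features)
  X <- switch(features,
              p1_and_p0 = cbind(matrix@p1, matrix@p0),
              p1_only = matrix@p1)
  Y <- .tsne(X, perplexity = perplexity, seed = seed, maxIter = maxIter)
  out <- data.frame(compound_id = matrix@compoundIds,
                    x = Y[, 1], y = Y[, 2], stringsAsFactors = FALSE)
  attr(out, "perplexity") <- perplexity
  attr(out, "seed") <- seed
  attr(out, "features") <- features
  out
}

#' Density-connected cluster around a reference compound
#'
#' Delimits the embedded neighborhood of a reference compound by
#' density-based clustering (DBSCAN) on the 2-D map and returns the
#' members of the density-connected component containing the reference.
#' If the reference is noise at the chosen density, the reference alone is
#' returned. Defaults: `minPts = 4`; `eps` defaults to the 0.9 quantile
#' of the per-point distance to the `minPts`-th nearest neighbor — an
#' inclusive reading of the usual k-NN distance knee heuristic, chosen so
#' that the border points of a dense region stay attached to it.
#'
#' @param embedding data.frame from [embedPValues()] (columns
#'   `compound_id`, `x`, `y`).
#' @param referenceId compound id present in the embedding.
#' @param eps DBSCAN radius; `NULL` (default) applies the quantile
#'   heuristic.
#' @param minPts DBSCAN core-point threshold (default 4).
#' @return character vector of member compound ids (reference included).
#' @export
clusterAround <- function(embedding, referenceId, eps = NULL, minPts = 4) {
  stopifnot(all(c("compound_id", "x", "y") %in% names(embedding)))
  ids <- embedding$compound_id
  if (!referenceId %in% ids)
    stop("reference id not present in embedding: ", referenceId)
  coords <- as.matrix(embedding[, c("x", "y")])
  if (is.null(eps)) {
    d <- as.matrix(stats::dist(coords))
    diag(d) <- Inf
    kdist <- apply(d, 1, function(r) sort(r)[minPts])
    eps <- stats::quantile(kdist, 0.9, names = FALSE)
  }
  cl <- .dbscan(coords, eps = eps, minPts = minPts)
  ref <- cl[ids == referenceId]
  if (ref == 0L) return(referenceId)   # noise -> singleton
  ids[cl == ref]
}

#' Consensus of t-SNE cluster and Tanimoto hit list
#'
#' Intersects the embedded-cluster membership with the Tanimoto hit list
#' for the same reference compound; the reference itself is excluded from
#' the report.
#'
#' @param tsneMembers character vector of compound ids (e.g. from
#'   [clusterAround()]).
#' @param tanimotoHits character vector of compound ids, or the data.frame
#'   returned by [rankByTanimoto()].
#' @param referenceId optional reference id to drop from the result.
#' @return character vector of consensus compound ids.
#' @export
consensusSet <- function(tsneMembers, tanimotoHits, referenceId = NULL) {
  if (is.data.frame(tanimotoHits)) tanimotoHits <- tanimotoHits$compound_id
  out <- intersect(tsneMembers, tanimotoHits)
  if (!is.null(referenceId)) out <- setdiff(out, referenceId)
  out
}

# ---- internal: exact t-SNE -------------------------------------------------

# Per-point Gaussian bandwidth calibration: binary search on precision
# beta so the conditional distribution's perplexity matches the target.
.tsneAffinities <- function(X, perplexity, tol = 1e-5) {
  n <- nrow(X)
  D2 <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; betaMin <- -Inf; betaMax <- Inf
    Di <- D2[i, -i]
    for (iter in 1:50) {
      Pi <- exp(-Di * beta)
      sumPi <- sum(Pi)
      if (sumPi == 0) sumPi <- .Machine$double.eps
      H <- log(sumPi) + beta * sum(Di * Pi) / sumPi
      if (abs(H - logU) < tol) break
      if (H > logU) {
        betaMin <- beta
        beta <- if (is.finite(betaMax)) (beta + betaMax) / 2 else beta * 2
      } else {
        betaMax <- beta
        beta <- if (is.finite(betaMin)) (beta + betaMin) / 2 else beta / 2
      }
    }
    P[i, -i] <- Pi / sumPi
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, .Machine$double.eps)
}

.tsne <- function(X, perplexity = 30, seed = 1, maxIter = 500,
                  eta = 200, exaggeration = 12, exaggerateUntil = 100) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n - 1 < 3 * perplexity)
    stop("perplexity ", perplexity, " too large for ", n,
         " compounds (need n > 3 * perplexity + 1)")
  P <- .tsneAffinities(X, perplexity)
  set.seed(seed)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  dY <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  momentum <- 0.5
  Pe <- P * exaggeration
  for (it in seq_len(maxIter)) {
    if (it == exaggerateUntil + 1) Pe <- P
    if (it == 251) momentum <- 0.8
    # Student-t kernel in the map
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, `+`) - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), .Machine$double.eps)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- momentum * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

# ---- internal: DBSCAN ------------------------------------------------------

# Plain DBSCAN on a small coordinate matrix; returns cluster ids with 0 =
# noise. O(n^2), fine at prioritization scale.
.dbscan <- function(coords, eps, minPts) {
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  neighbors <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(neighbors, length, integer(1)) >= minPts
  cl <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (cl[i] != 0L || !core[i]) next
    cur <- cur + 1L
    queue <- i
    cl[i] <- cur
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      for (nb in neighbors[[q]]) {
        if (cl[nb] == 0L) {
          cl[nb] <- cur
          if (core[nb]) queue <- c(queue, nb)
        }
      }
    }
  }
  cl
}
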