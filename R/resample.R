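#' Resample a training set to counter class imbalance
#'
#' Implements the five non-conformal imbalance-handling protocols:
#' \describe{
#'   \item{naive}{no resampling; the training part is returned unchanged.}
#'   \item{undersample}{random rows of the majority class are removed until
#'     its size exactly matches the minority class.}
#'   \item{oversample_dup}{the minority class is enlarged by duplicating
#'     real rows until it matches the majority size.}
#'   \item{smote}{synthetic minority rows are created by interpolating
#'     between a minority compound and one of its `k` (default 5) nearest
#'     same-class neighbors, at a uniformly drawn point on the connecting
#'     segment. Neighbors are found by Euclidean distance on standardized
#'     descriptors (zero mean, unit variance computed from the training
#'     part), while interpolation happens in raw descriptor space.}
#'   \item{rose}{both classes are enlarged with kernel-density-smoothed
#'     bootstrap samples: rows are drawn with replacement per class and
#'     jittered with per-feature Gaussian noise at the Silverman bandwidth
#'     for that class. Output has twice the original number of rows with
#'     exactly balanced classes. This is a from-description implementation
#'     of the smoothed-bootstrap idea; it is not a port of any particular
#'     ROSE release.}
#' }
#' Oversampling protocols never delete majority rows; original rows are
#' always retained.
#'
#' @param x numeric descriptor matrix of the training part.
#' @param y labels over `active`/`inactive`, aligned with `x`.
#' @param protocol one of `naive`, `undersample`, `oversample_dup`,
#'   `smote`, `rose`.
#' @param seed integer seed for all randomness.
#' @param k SMOTE neighbor count (default 5; SMOTE requires a minority
#'   class of at least `k + 1` compounds).
#' @return list with resampled `x` (matrix) and `y` (factor).
#' @export
resampleProtocol <- function(x, y,
                             protocol = c("naive", "undersample",
                                          "oversample_dup", "smote",
                                          "rose"),
                             seed = 1, k = 5) {
  protocol <- match.arg(protocol)
  x <- as.matrix(x)
  y <- factor(as.character(y), levels = c("active", "inactive"))
  stopifnot(nrow(x) == length(y), all(table(y) > 0))
  counts <- table(y)
  minorityClass <- names(counts)[which.min(counts)]
  majorityClass <- names(counts)[which.max(counts)]
  iMin <- which(y == minorityClass)
  iMaj <- which(y == majorityClass)
  set.seed(seed)
  switch(protocol,
    naive = list(x = x, y = y),
    undersample = {
      keep <- sort(c(iMin, sample(iMaj, length(iMin))))
      list(x = x[keep, , drop = FALSE], y = y[keep])
    },
    oversample_dup = {
      need <- length(iMaj) - length(iMin)
      extra <- sample(iMin, need, replace = TRUE)
      idx <- c(seq_len(nrow(x)), extra)
      list(x = x[idx, , drop = FALSE], y = y[idx])
    },
    smote = {
      if (length(iMin) < k + 1)
        stop("SMOTE needs at least ", k + 1, " minority compounds")
      need <- length(iMaj) - length(iMin)
      z <- scale(x)
      z[, attr(z, "scaled:scale") == 0] <- 0
      dMin <- as.matrix(stats::dist(z[iMin, , drop = FALSE]))
      diag(dMin) <- Inf
      nn <- apply(dMin, 1, function(d) order(d)[seq_len(k)])
      synth <- matrix(NA_real_, need, ncol(x))
      base <- sample(seq_along(iMin), need, replace = TRUE)
      for (s in seq_len(need)) {
        i <- base[s]
        j <- nn[sample.int(k, 1), i]
        t <- stats::runif(1)
        synth[s, ] <- x[iMin[i], ] + t * (x[iMin[j], ] - x[iMin[i], ])
      }
      colnames(synth) <- colnames(x)
      list(x = rbind(x, synth),
           y = factor(c(as.character(y), rep(minorityClass, need)),
                      levels = levels(y)))
    },
    rose = {
      nOut <- nrow(x)   # per class; total output = 2 x original
      parts <- lapply(c(minorityClass, majorityClass), function(cl) {
        idx <- which(y == cl)
        xc <- x[idx, , drop = FALSE]
        nC <- nrow(xc); d <- ncol(xc)
        # per-feature Silverman bandwidth for a d-variate Gaussian kernel
        h <- apply(xc, 2, stats::sd) * (4 / ((d + 2) * nC))^(1 / (d + 4))
        boot <- xc[sample.int(nC, nOut, replace = TRUE), , drop = FALSE]
        noise <- matrix(stats::rnorm(nOut * d), nOut, d)
        sm <- boot + sweep(noise, 2, h, `*`)
        colnames(sm) <- colnames(x)
        list(x = sm, y = rep(cl, nOut))
      })
      list(x = do.call(rbind, lapply(parts, `[[`, "x")),
           y = factor(unlist(lapply(parts, `[[`, "y")),
                      levels = levels(y)))
    })
}
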