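#' Active-class prevalences of the reference screening battery
#'
#' The 23 nuclear-receptor qHTS endpoints (agonism/antagonism molecular
#' initiating events of the Tox21 screening program) span active fractions
#' from 0.77% to 24.25%; these values parameterize the default battery
#' fixture so synthetic endpoints carry realistic skew.
#'
#' @return named numeric vector of 23 active fractions in (0, 1).
#' @export
batteryPrevalences <- function() {
  c("AhR activation"        = 0.1094,
    "AR agonism"            = 0.0300,
    "AR antagonism"         = 0.0628,
    "CAR agonism"           = 0.1180,
    "CAR antagonism"        = 0.0249,
    "ER-alpha agonism"      = 0.0442,
    "ER-alpha antagonism"   = 0.0423,
    "FXR agonism"           = 0.0116,
    "FXR antagonism"        = 0.0260,
    "GR agonism"            = 0.0204,
    "GR antagonism"         = 0.0470,
    "PPAR-delta agonism"    = 0.0102,
    "PPAR-delta antagonism" = 0.0077,
    "PPAR-gamma agonism"    = 0.0256,
    "PPAR-gamma antagonism" = 0.0490,
    "PR agonism"            = 0.0146,
    "PR antagonism"         = 0.1201,
    "PXR agonism"           = 0.2425,
    "RAR agonism"           = 0.0504,
    "RAR antagonism"        = 0.0953,
    "RXR agonism"           = 0.0261,
    "TR-beta antagonism"    = 0.0465,
    "VDR3 antagonism"       = 0.0078)
}

#' Generate one imbalanced synthetic endpoint dataset
#'
#' Two multivariate Gaussian classes in descriptor space: inactives are
#' centred at the origin, actives at a mean shifted by `separation` pooled
#' standard deviations (the shift is spread evenly over all features, so
#' the Euclidean distance between class means equals `separation`). The
#' realized active count is exactly `round(n * activeFraction)`. With the
#' defaults (20 features, separation 2.5) a 200-tree random forest reaches
#' a test AUC near 0.9 on 4%-active data, emulating a well-performing but
#' imperfect bioactivity model.
#'
#' @param n number of compounds.
#' @param activeFraction active-class fraction in (0, 1).
#' @param separation distance between class means in pooled-sigma units
#'   (default 2.5).
#' @param nFeatures descriptor count (default 20).
#' @param covariance `"spherical"` (default) or `"correlated"`
#'   (equicorrelated features, rho = 0.3).
#' @param seed integer seed.
#' @param endpointName name for the resulting dataset.
#' @return an [AssayDataset-class] with exact labels.
#' @export
makeEndpointDataset <- function(n, activeFraction, separation = 2.5,
                                nFeatures = 20,
                                covariance = c("spherical", "correlated"),
                                seed = 1,
                                endpointName = "synthetic endpoint") {
  covariance <- match.arg(covariance)
  stopifnot(n > 0, activeFraction > 0, activeFraction < 1, separation >= 0)
  nActive <- round(n * activeFraction)
  if (nActive < 1)
    stop("active count rounds to zero; increase n or activeFraction")
  set.seed(seed)
  x <- matrix(stats::rnorm(n * nFeatures), n, nFeatures)
  if (covariance == "correlated") {
    rho <- 0.3
    sigma <- matrix(rho, nFeatures, nFeatures)
    diag(sigma) <- 1
    x <- x %*% chol(sigma)
  }
  labels <- rep(c("active", "inactive"), c(nActive, n - nActive))
  shift <- separation / sqrt(nFeatures)
  x[labels == "active", ] <- x[labels == "active", ] + shift
  colnames(x) <- sprintf("desc_%02d", seq_len(nFeatures))
  assayDataset(endpointName, x, labels,
               compoundIds = sprintf("syn_%05d", seq_len(n)))
}

#' Generate a full battery fixture with a planted screening library
#'
#' Builds one training dataset per endpoint over a shared descriptor
#' space, plus a disjoint screening library whose compounds have known
#' per-endpoint class membership. Each endpoint owns a random unit
#' direction in descriptor space; its actives are shifted along that
#' direction. Library compounds are generated from their true activity
#' profile (sum of the directions of their active endpoints) plus unit
#' noise.
#'
#' Two designated reference compounds carry prescribed, on-bit-rich
#' activity profiles, and `nNearDuplicates` planted near-duplicates of
#' each reference differ from it by a profile Hamming distance of at most
#' 2 — guaranteeing Tanimoto similarity >= 0.8 to the reference profile
#' fingerprint whenever the reference has at least 18 on-bits.
#'
#' @param nEndpoints battery size (default 23).
#' @param prevalences active fraction per endpoint (default
#'   [batteryPrevalences()]); length must equal `nEndpoints`.
#' @param nPerEndpoint training compounds per endpoint (default 400).
#' @param librarySize screening-library compounds excluding references and
#'   near-duplicates (default 200).
#' @param nFeatures shared descriptor dimension (default 16).
#' @param separation class-mean shift per endpoint (default 3).
#' @param nNearDuplicates planted near-duplicates per reference
#'   (default 5).
#' @param seed integer seed.
#' @return list with components:
#'   \describe{
#'     \item{datasets}{named list of [AssayDataset-class], one per
#'       endpoint.}
#'     \item{library}{list with `descriptors` (matrix), `profiles`
#'       (0/1 matrix of true per-endpoint activity), `compoundIds`.}
#'     \item{referenceIds}{ids of the two reference compounds
#'       (`REF_A`, `REF_B`).}
#'     \item{referenceProfiles}{their true 0/1 profiles.}
#'   }
#' @export
makeBatteryFixture <- function(nEndpoints = 23,
                               prevalences = batteryPrevalences(),
                               nPerEndpoint = 400, librarySize = 200,
                               nFeatures = 16, separation = 3,
                               nNearDuplicates = 5, seed = 1) {
  stopifnot(length(prevalences) == nEndpoints)
  epNames <- names(prevalences)
  if (is.null(epNames)) epNames <- sprintf("endpoint_%02d", seq_len(nEndpoints))
  set.seed(seed)
  # one unit direction per endpoint
  U <- matrix(stats::rnorm(nEndpoints * nFeatures), nEndpoints, nFeatures)
  U <- U / sqrt(rowSums(U^2))
  datasets <- lapply(seq_len(nEndpoints), function(e) {
    nAct <- max(1L, round(nPerEndpoint * prevalences[[e]]))
    x <- matrix(stats::rnorm(nPerEndpoint * nFeatures),
                nPerEndpoint, nFeatures)
    lab <- rep(c("active", "inactive"), c(nAct, nPerEndpoint - nAct))
    x[lab == "active", ] <- x[lab == "active", ] +
      matrix(separation * U[e, ], nAct, nFeatures, byrow = TRUE)
    colnames(x) <- sprintf("desc_%02d", seq_len(nFeatures))
    assayDataset(epNames[e], x, lab,
                 compoundIds = sprintf("trn_%s_%04d", e,
                                       seq_len(nPerEndpoint)))
  })
  names(datasets) <- epNames
  # reference profiles: dense on-bit patterns (>= 18 of 23 on)
  offA <- intersect(c(2, 5, 9), seq_len(nEndpoints))
  offB <- intersect(c(1, 7, 12, 15), seq_len(nEndpoints))
  refA <- rep(1L, nEndpoints); refA[offA] <- 0L
  refB <- rep(1L, nEndpoints); refB[offB] <- 0L
  flipProfile <- function(p, nFlips) {
    pos <- sample(length(p), nFlips)
    p[pos] <- 1L - p[pos]
    p
  }
  dupProfiles <- rbind(
    t(vapply(seq_len(nNearDuplicates),
             function(i) flipProfile(refA, sample(0:2, 1)),
             integer(nEndpoints))),
    t(vapply(seq_len(nNearDuplicates),
             function(i) flipProfile(refB, sample(0:2, 1)),
             integer(nEndpoints))))
  randProfiles <- t(vapply(seq_len(librarySize), function(i)
    as.integer(stats::runif(nEndpoints) < unname(prevalences)),
    integer(nEndpoints)))
  profiles <- rbind(refA, refB, dupProfiles, randProfiles)
  ids <- c("REF_A", "REF_B",
           sprintf("DUP_A_%02d", seq_len(nNearDuplicates)),
           sprintf("DUP_B_%02d", seq_len(nNearDuplicates)),
           sprintf("LIB_%04d", seq_len(librarySize)))
  rownames(profiles) <- ids
  colnames(profiles) <- epNames
  descriptors <- profiles %*% (separation * U) +
    matrix(stats::rnorm(nrow(profiles) * nFeatures),
           nrow(profiles), nFeatures)
  colnames(descriptors) <- sprintf("desc_%02d", seq_len(nFeatures))
  rownames(descriptors) <- ids
  list(datasets = datasets,
       library = list(descriptors = descriptors, profiles = profiles,
                      compoundIds = ids),
       referenceIds = c("REF_A", "REF_B"),
       referenceProfiles = rbind(REF_A = refA, REF_B = refB))
}

#' Generate raw replicate records with controlled corruption
#'
#' Expands per-compound truth labels into replicate bioassay records,
#' flipping each replicate with probability `flipRate` and replacing it
#' with `Inconclusive` with probability `inconclusiveRate`, to exercise
#' the replicate-aggregation and curation rules against known ground
#' truth.
#'
#' @param truthLabels character vector over `active`/`inactive`.
#' @param nReplicates replicates per compound (default 3).
#' @param flipRate probability a replicate reports the wrong class.
#' @param inconclusiveRate probability a replicate is Inconclusive
#'   (applied first).
#' @param seed integer seed.
#' @return list with `table` (data.frame: `compound_id`, `replicate`,
#'   `label`), `truth`, and `recovery` — the fractions of compounds whose
#'   [aggregateReplicates()] result matches truth, is wrong, or is
#'   excluded.
#' @export
makeReplicateTable <- function(truthLabels, nReplicates = 3, flipRate = 0,
                               inconclusiveRate = 0, seed = 1) {
  stopifnot(all(truthLabels %in% c("active", "inactive")),
            flipRate >= 0, flipRate < 1,
            inconclusiveRate >= 0, inconclusiveRate < 1)
  n <- length(truthLabels)
  set.seed(seed)
  ids <- sprintf("cmpd_%05d", seq_len(n))
  rows <- lapply(seq_len(n), function(i) {
    lab <- character(nReplicates)
    for (r in seq_len(nReplicates)) {
      if (stats::runif(1) < inconclusiveRate) {
        lab[r] <- "Inconclusive"
      } else {
        wrong <- stats::runif(1) < flipRate
        truth <- truthLabels[i]
        obs <- if (wrong) setdiff(c("active", "inactive"), truth) else truth
        lab[r] <- c(active = "Active", inactive = "Inactive")[obs]
      }
    }
    data.frame(compound_id = ids[i], replicate = seq_len(nReplicates),
               label = lab, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  resolved <- vapply(split(tab$label, tab$compound_id)[ids],
                     aggregateReplicates, character(1))
  recovery <- c(correct = mean(resolved == truthLabels),
                wrong = mean(resolved != truthLabels &
                               resolved != "excluded"),
                excluded = mean(resolved == "excluded"))
  list(table = tab, truth = stats::setNames(truthLabels, ids),
       recovery = recovery)
}

#' Write a battery fixture to disk in the chemistry-module CSV formats
#'
#' Materializes [makeBatteryFixture()] output as one dataset archive per
#' endpoint (see [writeAssayDataset()]) plus the screening library as
#' `library_descriptors.csv` and `library_profiles.csv`.
#'
#' @param fixture output of [makeBatteryFixture()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeBatteryFixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(fixture$datasets)) {
    safe <- gsub("[^A-Za-z0-9]+", "_", nm)
    writeAssayDataset(fixture$datasets[[nm]],
                      file.path(dir, paste0("endpoint_", safe)))
  }
  utils::write.csv(
    data.frame(compound_id = fixture$library$compoundIds,
               fixture$library$descriptors, check.names = FALSE),
    file.path(dir, "library_descriptors.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(compound_id = fixture$library$compoundIds,
               fixture$library$profiles, check.names = FALSE),
    file.path(dir, "library_profiles.csv"), row.names = FALSE)
  invisible(dir)
}
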