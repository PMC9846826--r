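#' Screen a compound library with a battery of conformal models
#'
#' Applies every trained [ConformalModel-class] in the battery to the
#' library and collects the aggregated conformal p-value pairs into a
#' [PValueMatrix-class]. The library featurization must carry exactly the
#' descriptor set and order stored in each model artifact; any mismatch is
#' a hard error rather than a silent reorder.
#'
#' @param battery named list of [ConformalModel-class] objects; names (or
#'   the models' endpoint names) become the endpoint columns.
#' @param library descriptor matrix (compounds x descriptors, rownames =
#'   compound ids) or an [AssayDataset-class].
#' @return a [PValueMatrix-class], compounds x endpoints.
#' @export
screenLibrary <- function(battery, library) {
  if (is(battery, "ConformalModel")) battery <- list(battery)
  stopifnot(length(battery) > 0,
            all(vapply(battery, is, logical(1), "ConformalModel")))
  if (is(library, "AssayDataset")) library <- descriptors(library)
  library <- as.matrix(library)
  nms <- names(battery)
  if (is.null(nms))
    nms <- vapply(battery, endpointName, character(1))
  ids <- rownames(library)
  if (is.null(ids)) ids <- paste0("cmpd_", seq_len(nrow(library)))
  p1 <- matrix(NA_real_, nrow(library), length(battery),
               dimnames = list(ids, nms))
  p0 <- p1
  for (m in seq_along(battery)) {
    pred <- conformalPredict(battery[[m]], library)
    p1[, m] <- pred$p1
    p0[, m] <- pred$p0
  }
  pValueMatrix(p1, p0, compoundIds = ids, endpointNames = nms)
}

#' Elementwise conformal class assignment for a screening matrix
#'
#' @param matrix a [PValueMatrix-class].
#' @param epsilon significance level in \[0, 1\].
#' @return character matrix (compounds x endpoints) over `active`,
#'   `inactive`, `both`, `empty`.
#' @seealso [assignClass()]
#' @export
classifyMatrix <- function(matrix, epsilon) {
  stopifnot(is(matrix, "PValueMatrix"))
  out <- assignClass(as.vector(matrix@p1), as.vector(matrix@p0), epsilon)
  matrix(out, nrow(matrix@p1), ncol(matrix@p1),
         dimnames = dimnames(matrix@p1))
}

#' High-confidence actives and inactives per endpoint
#'
#' The strict selection strategy for prioritizing costly experimental
#' follow-up: a compound is a high-confidence active for an endpoint when
#' its active p-value strictly exceeds `epsStrict` while the inactive
#' p-value does not; symmetrically for inactives. The default 0.8 keeps
#' only compounds with very strong conformity to a single class.
#'
#' @param matrix a [PValueMatrix-class].
#' @param epsStrict strict selection threshold in (0.5, 1\].
#' @return named list per endpoint, each with character vectors `active`
#'   and `inactive` of compound ids.
#' @export
highConfidenceSelection <- function(matrix, epsStrict = 0.8) {
  stopifnot(is(matrix, "PValueMatrix"),
            epsStrict > 0.5, epsStrict <= 1)
  ids <- matrix@compoundIds
  out <- lapply(seq_along(matrix@endpointNames), function(m) {
    p1 <- matrix@p1[, m]; p0 <- matrix@p0[, m]
    list(active = ids[p1 > epsStrict & p0 <= epsStrict],
         inactive = ids[p0 > epsStrict & p1 <= epsStrict])
  })
  names(out) <- matrix@endpointNames
  out
}

#' Out-of-domain compounds per endpoint
#'
#' A compound is out of the applicability domain of an endpoint model when
#' both its conformal p-values fall strictly below the threshold: it is
#' not sufficiently similar to the active or the inactive class.
#'
#' @param matrix a [PValueMatrix-class].
#' @param threshold similarity threshold in (0, 1), default 0.2.
#' @return named list per endpoint of compound-id character vectors.
#' @export
outOfDomain <- function(matrix, threshold = 0.2) {
  stopifnot(is(matrix, "PValueMatrix"), threshold > 0, threshold < 1)
  ids <- matrix@compoundIds
  out <- lapply(seq_along(matrix@endpointNames), function(m) {
    ids[matrix@p1[, m] < threshold & matrix@p0[, m] < threshold]
  })
  names(out) <- matrix@endpointNames
  out
}

#' Summarize a screening run per endpoint
#'
#' For each endpoint: the percentage of library compounds assigned active,
#' inactive and unclassified (`both`/`empty`) at `epsilon`; high-confidence
#' counts at `epsStrict`; out-of-domain counts; and the fold difference of
#' predicted versus expected actives. The expected-actives anchor is the
#' endpoint's training prevalence, so
#' `fold_difference = %predicted_active / %training_active`. When balanced
#' PPV values are supplied, a PPV-adjusted variant
#' `fold_difference_ppv = (%predicted_active x balanced_ppv) /
#' %training_active` is emitted alongside — the two candidate readings of
#' an expected-false-positive correction.
#'
#' @param matrix a [PValueMatrix-class].
#' @param epsilon class-assignment significance level (default 0.2).
#' @param trainingPrevalence named numeric, training active fraction in
#'   (0, 1\] per endpoint.
#' @param balancedPPV optional named numeric per endpoint.
#' @param epsStrict strict selection threshold (default 0.8).
#' @param oodThreshold out-of-domain threshold (default 0.2).
#' @return data.frame, one row per endpoint: `endpoint`, `pct_active`,
#'   `pct_inactive`, `pct_unclassified`, `n_high_conf_active`,
#'   `n_high_conf_inactive`, `n_out_of_domain`, `fold_difference`,
#'   `fold_difference_ppv`.
#' @export
summarizeScreen <- function(matrix, epsilon = 0.2, trainingPrevalence,
                            balancedPPV = NULL, epsStrict = 0.8,
                            oodThreshold = 0.2) {
  stopifnot(is(matrix, "PValueMatrix"))
  eps <- matrix@endpointNames
  stopifnot(all(eps %in% names(trainingPrevalence)))
  assign4 <- classifyMatrix(matrix, epsilon)
  hc <- highConfidenceSelection(matrix, epsStrict)
  ood <- outOfDomain(matrix, oodThreshold)
  n <- length(matrix@compoundIds)
  rows <- lapply(seq_along(eps), function(m) {
    a <- assign4[, m]
    pctA <- 100 * sum(a == "active") / n
    pctI <- 100 * sum(a == "inactive") / n
    pctU <- 100 * sum(a %in% c("both", "empty")) / n
    prev <- trainingPrevalence[[eps[m]]]
    fold <- if (prev > 0) (pctA / 100) / prev else NA_real_
    foldPPV <- if (!is.null(balancedPPV) && prev > 0)
      fold * balancedPPV[[eps[m]]] else NA_real_
    data.frame(endpoint = eps[m], pct_active = pctA, pct_inactive = pctI,
               pct_unclassified = pctU,
               n_high_conf_active = length(hc[[m]]$active),
               n_high_conf_inactive = length(hc[[m]]$inactive),
               n_out_of_domain = length(ood[[m]]),
               fold_difference = fold,
               fold_difference_ppv = foldPPV,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write screening outputs as plain-text artifacts
#'
#' Emits the long-format p-value matrix (`pvalues.csv`: compound,
#' endpoint, p1, p0), the class-assignment grid (`assignments.csv`), the
#' per-endpoint summary (`summary.csv`) and the out-of-domain table
#' (`out_of_domain.csv`).
#'
#' @param matrix a [PValueMatrix-class].
#' @param dir output directory (created if needed).
#' @param epsilon,trainingPrevalence,balancedPPV,epsStrict,oodThreshold
#'   passed to [summarizeScreen()]; `trainingPrevalence` may be omitted to
#'   skip the summary.
#' @return `dir`, invisibly.
#' @export
writeScreenResults <- function(matrix, dir, epsilon = 0.2,
                               trainingPrevalence = NULL,
                               balancedPPV = NULL, epsStrict = 0.8,
                               oodThreshold = 0.2) {
  stopifnot(is(matrix, "PValueMatrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  long <- data.frame(
    compound = rep(matrix@compoundIds, times = length(matrix@endpointNames)),
    endpoint = rep(matrix@endpointNames, each = length(matrix@compoundIds)),
    p1 = as.vector(matrix@p1), p0 = as.vector(matrix@p0))
  utils::write.csv(long, file.path(dir, "pvalues.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(classifyMatrix(matrix, epsilon)),
                   file.path(dir, "assignments.csv"))
  ood <- outOfDomain(matrix, oodThreshold)
  oodTab <- data.frame(
    endpoint = rep(names(ood), lengths(ood)),
    compound = unlist(ood, use.names = FALSE))
  utils::write.csv(oodTab, file.path(dir, "out_of_domain.csv"),
                   row.names = FALSE)
  if (!is.null(trainingPrevalence)) {
    utils::write.csv(
      summarizeScreen(matrix, epsilon, trainingPrevalence, balancedPPV,
                      epsStrict, oodThreshold),
      file.path(dir, "summary.csv"), row.names = FALSE)
  }
  invisible(dir)
}
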