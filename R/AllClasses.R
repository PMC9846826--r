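#' @import methods
NULL

#' AssayDataset: labelled compounds for one bioassay endpoint
#'
#' Container for a curated, featurized dataset for a single molecular
#' initiating event (receptor agonism or antagonism). Every compound carries
#' a fixed-length numeric descriptor vector and a resolved binary activity
#' label.
#'
#' @slot endpointName single string naming the endpoint, conventionally
#'   `"<receptor> <agonism|antagonism>"`.
#' @slot compoundIds character vector of opaque compound identifiers,
#'   unique within the dataset.
#' @slot descriptors numeric matrix, compounds in rows and descriptors in
#'   columns; column names are the descriptor names shared by every record.
#'   No non-finite entries are allowed (sentinel replacement happens at
#'   featurization time, see [computeDescriptors()]).
#' @slot labels factor with levels `active`, `inactive`, one resolved label
#'   per compound.
#'
#' @seealso [assayDataset()] for construction, [activeRatio()],
#'   [filterAssay()], [makeEndpointDataset()].
#' @export
setClass("AssayDataset",
  slots = c(
    endpointName = "character",
    compoundIds  = "character",
    descriptors  = "matrix",
    labels       = "factor"
  )
)

setValidity("AssayDataset", function(object) {
  msg <- character()
  n <- nrow(object@descriptors)
  if (length(object@endpointName) != 1L)
    msg <- c(msg, "endpointName must be a single string")
  if (length(object@compoundIds) != n)
    msg <- c(msg, "compoundIds length must match descriptor rows")
  if (anyDuplicated(object@compoundIds))
    msg <- c(msg, "compoundIds must be unique")
  if (length(object@labels) != n)
    msg <- c(msg, "labels length must match descriptor rows")
  if (!identical(levels(object@labels), c("active", "inactive")))
    msg <- c(msg, "labels must be a factor with levels active, inactive")
  if (anyNA(object@labels))
    msg <- c(msg, "every record needs exactly one resolved label")
  if (!is.numeric(object@descriptors))
    msg <- c(msg, "descriptors must be numeric")
  else if (n > 0 && !all(is.finite(object@descriptors)))
    msg <- c(msg, "descriptors must be finite (apply sentinel replacement first)")
  if (is.null(colnames(object@descriptors)))
    msg <- c(msg, "descriptor columns must be named")
  if (length(msg)) msg else TRUE
})

#' Construct an AssayDataset
#'
#' @param endpointName endpoint name (receptor + agonism/antagonism).
#' @param descriptors numeric matrix (compounds x descriptors) with column
#'   names.
#' @param labels character or factor over `active`/`inactive`.
#' @param compoundIds compound identifiers; defaults to descriptor rownames
#'   or `cmpd_1 ... cmpd_n`.
#' @return an [AssayDataset-class] object.
#' @examples
#' x <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("d1", "d2")))
#' ds <- assayDataset("ER-alpha agonism", x,
#'                    rep(c("active", "inactive"), c(2, 8)))
#' activeRatio(ds)
#' @export
assayDataset <- function(endpointName, descriptors, labels,
                         compoundIds = NULL) {
  descriptors <- as.matrix(descriptors)
  if (is.null(compoundIds)) {
    compoundIds <- rownames(descriptors)
    if (is.null(compoundIds))
      compoundIds <- paste0("cmpd_", seq_len(nrow(descriptors)))
  }
  rownames(descriptors) <- compoundIds
  labels <- factor(as.character(labels), levels = c("active", "inactive"))
  new("AssayDataset",
      endpointName = endpointName,
      compoundIds  = as.character(compoundIds),
      descriptors  = descriptors,
      labels       = labels)
}

#' CalibrationTable: sorted conformity scores for one class
#'
#' Mondrian conformal prediction keeps one calibration table per class,
#' built only from calibration compounds truly of that class. The
#' conformity score used throughout this package is the classifier's
#' predicted probability for the table's own class, so scores live in
#' \[0, 1\] and are stored sorted ascending.
#'
#' @slot classLabel `"active"` or `"inactive"`.
#' @slot scores sorted numeric vector of conformity scores in \[0, 1\].
#' @seealso [buildCalibration()], [pValue()].
#' @export
setClass("CalibrationTable",
  slots = c(classLabel = "character", scores = "numeric")
)

setValidity("CalibrationTable", function(object) {
  msg <- character()
  if (!(length(object@classLabel) == 1L &&
        object@classLabel %in% c("active", "inactive")))
    msg <- c(msg, "classLabel must be 'active' or 'inactive'")
  s <- object@scores
  if (length(s) < 1L)
    msg <- c(msg, "calibration table needs at least one score")
  if (anyNA(s) || any(s < 0 | s > 1))
    msg <- c(msg, "scores must lie in [0, 1]")
  if (is.unsorted(s))
    msg <- c(msg, "scores must be sorted ascending")
  if (length(msg)) msg else TRUE
})

#' ConformalModel: a trained Mondrian conformal predictor for one endpoint
#'
#' Bundles the underlying random forests and the per-class calibration
#' tables from every fold x calibration-iteration sub-model, plus the
#' descriptor list the forests were trained on. Prediction aggregates the
#' sub-models' conformal p-values by the componentwise median.
#'
#' @slot endpointName endpoint the model was trained for.
#' @slot descriptorNames descriptor names, in training order; screening
#'   input must match exactly.
#' @slot forests list of `randomForest` objects (one per fold x iteration).
#' @slot calibrations list parallel to `forests`; each element is a list
#'   with components `active` and `inactive`, both [CalibrationTable-class].
#' @slot epsilons significance grid the model was evaluated on.
#' @slot seed integer master seed used for training.
#' @seealso [trainConformal()], [conformalPredict()], [screenLibrary()].
#' @export
setClass("ConformalModel",
  slots = c(
    endpointName    = "character",
    descriptorNames = "character",
    forests         = "list",
    calibrations    = "list",
    epsilons        = "numeric",
    seed            = "integer"
  )
)

setValidity("ConformalModel", function(object) {
  msg <- character()
  if (length(object@forests) < 1L)
    msg <- c(msg, "model needs at least one trained forest")
  if (length(object@forests) != length(object@calibrations))
    msg <- c(msg, "forests and calibrations must be parallel lists")
  ok <- vapply(object@calibrations, function(cc) {
    is.list(cc) && all(c("active", "inactive") %in% names(cc)) &&
      is(cc$active, "CalibrationTable") && is(cc$inactive, "CalibrationTable")
  }, logical(1))
  if (!all(ok))
    msg <- c(msg, "each calibration entry needs active and inactive tables")
  if (any(object@epsilons < 0 | object@epsilons > 1))
    msg <- c(msg, "epsilons must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' PValueMatrix: compounds x endpoints grid of conformal p-values
#'
#' The substrate for screening summaries, bioactivity fingerprints and
#' embeddings: for every library compound and every endpoint model, the
#' aggregated conformal p-value for the active class (`p1`) and the
#' inactive class (`p0`). Both lie in (0, 1] by the +1 correction in
#' [pValue()].
#'
#' @slot compoundIds library compound identifiers (rows).
#' @slot endpointNames battery endpoint names (columns).
#' @slot p1 numeric matrix of active-class p-values.
#' @slot p0 numeric matrix of inactive-class p-values.
#' @seealso [screenLibrary()], [classifyMatrix()], [bioactivityFingerprint()].
#' @export
setClass("PValueMatrix",
  slots = c(
    compoundIds   = "character",
    endpointNames = "character",
    p1            = "matrix",
    p0            = "matrix"
  )
)

setValidity("PValueMatrix", function(object) {
  msg <- character()
  d <- c(length(object@compoundIds), length(object@endpointNames))
  if (!identical(dim(object@p1), d) || !identical(dim(object@p0), d))
    msg <- c(msg, "p1/p0 dimensions must match id and endpoint lists")
  for (nm in c("p1", "p0")) {
    p <- slot(object, nm)
    if (length(p) > 0 && (anyNA(p) || any(p <= 0 | p > 1)))
      msg <- c(msg, sprintf("%s values must lie in (0, 1]", nm))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PValueMatrix
#'
#' @param p1,p0 numeric matrices (compounds x endpoints) of conformal
#'   p-values in (0, 1].
#' @param compoundIds,endpointNames row/column identity; default to the
#'   dimnames of `p1`.
#' @return a [PValueMatrix-class] object.
#' @export
pValueMatrix <- function(p1, p0, compoundIds = rownames(p1),
                         endpointNames = colnames(p1)) {
  p1 <- as.matrix(p1); p0 <- as.matrix(p0)
  if (is.null(compoundIds))
    compoundIds <- paste0("cmpd_", seq_len(nrow(p1)))
  if (is.null(endpointNames))
    endpointNames <- paste0("endpoint_", seq_len(ncol(p1)))
  dimnames(p1) <- dimnames(p0) <- list(compoundIds, endpointNames)
  new("PValueMatrix", compoundIds = as.character(compoundIds),
      endpointNames = as.character(endpointNames), p1 = p1, p0 = p0)
}
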