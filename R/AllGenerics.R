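#' Endpoint name of an object
#' @param x an object carrying an endpoint name.
#' @return single character string.
#' @export
setGeneric("endpointName", function(x) standardGeneric("endpointName"))

#' Compound identifiers of an object
#' @param x an object carrying compound identifiers.
#' @return character vector.
#' @export
setGeneric("compoundIds", function(x) standardGeneric("compoundIds"))

#' Descriptor matrix of a dataset
#' @param x an [AssayDataset-class].
#' @return numeric matrix, compounds x descriptors.
#' @export
setGeneric("descriptors", function(x) standardGeneric("descriptors"))

#' Activity labels of a dataset
#' @param x an [AssayDataset-class].
#' @return factor over `active`/`inactive`.
#' @export
setGeneric("activityLabels", function(x) standardGeneric("activityLabels"))

#' Active-class prevalence of a dataset
#'
#' Exact fraction of compounds labelled `active`.
#' @param x an [AssayDataset-class].
#' @return numeric in \[0, 1\].
#' @export
setGeneric("activeRatio", function(x) standardGeneric("activeRatio"))

#' Endpoint names covered by an object
#' @param x an object spanning several endpoints.
#' @return character vector.
#' @export
setGeneric("endpointNames", function(x) standardGeneric("endpointNames"))

#' Active-class conformal p-values
#' @param x a [PValueMatrix-class].
#' @return numeric matrix, compounds x endpoints.
#' @export
setGeneric("pActive", function(x) standardGeneric("pActive"))

#' Inactive-class conformal p-values
#' @param x a [PValueMatrix-class].
#' @return numeric matrix, compounds x endpoints.
#' @export
setGeneric("pInactive", function(x) standardGeneric("pInactive"))

# ---- AssayDataset methods ----

#' @describeIn AssayDataset-class endpoint name.
#' @param x,object an `AssayDataset`.
#' @export
setMethod("endpointName", "AssayDataset", function(x) x@endpointName)

#' @describeIn AssayDataset-class compound identifiers.
#' @export
setMethod("compoundIds", "AssayDataset", function(x) x@compoundIds)

#' @describeIn AssayDataset-class descriptor matrix.
#' @export
setMethod("descriptors", "AssayDataset", function(x) x@descriptors)

#' @describeIn AssayDataset-class activity labels.
#' @export
setMethod("activityLabels", "AssayDataset", function(x) x@labels)

#' @describeIn AssayDataset-class exact active fraction,
#'   `count(active) / count(all)`.
#' @export
setMethod("activeRatio", "AssayDataset", function(x) {
  mean(x@labels == "active")
})

#' @describeIn AssayDataset-class number of compounds.
#' @export
setMethod("length", "AssayDataset", function(x) length(x@compoundIds))

#' @describeIn AssayDataset-class compact display.
#' @export
setMethod("show", "AssayDataset", function(object) {
  cat(sprintf(
    "AssayDataset '%s': %d compounds, %d descriptors, %.2f%% active\n",
    object@endpointName, length(object@compoundIds),
    ncol(object@descriptors), 100 * activeRatio(object)))
  invisible(object)
})

#' @describeIn AssayDataset-class subset compounds by index.
#' @param i index vector over compounds.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "AssayDataset", function(x, i, j, ..., drop = FALSE) {
  new("AssayDataset",
      endpointName = x@endpointName,
      compoundIds  = x@compoundIds[i],
      descriptors  = x@descriptors[i, , drop = FALSE],
      labels       = x@labels[i])
})

# ---- CalibrationTable methods ----

#' @describeIn CalibrationTable-class number of calibration scores.
#' @param x,object a `CalibrationTable`.
#' @export
setMethod("length", "CalibrationTable", function(x) length(x@scores))

#' @describeIn CalibrationTable-class compact display.
#' @export
setMethod("show", "CalibrationTable", function(object) {
  cat(sprintf("CalibrationTable (%s): %d scores in [%.3f, %.3f]\n",
              object@classLabel, length(object@scores),
              min(object@scores), max(object@scores)))
  invisible(object)
})

# ---- ConformalModel methods ----

#' @describeIn ConformalModel-class endpoint name.
#' @param x,object a `ConformalModel`.
#' @export
setMethod("endpointName", "ConformalModel", function(x) x@endpointName)

#' @describeIn ConformalModel-class compact display.
#' @export
setMethod("show", "ConformalModel", function(object) {
  ncal <- vapply(object@calibrations,
                 function(cc) length(cc$active@scores) +
                   length(cc$inactive@scores), numeric(1))
  cat(sprintf(
    "ConformalModel '%s': %d sub-models, %d descriptors, ~%d calibration scores each\n",
    object@endpointName, length(object@forests),
    length(object@descriptorNames), round(mean(ncal))))
  invisible(object)
})

# ---- PValueMatrix methods ----

#' @describeIn PValueMatrix-class compound identifiers.
#' @param x,object a `PValueMatrix`.
#' @export
setMethod("compoundIds", "PValueMatrix", function(x) x@compoundIds)

#' @describeIn PValueMatrix-class endpoint names.
#' @export
setMethod("endpointNames", "PValueMatrix", function(x) x@endpointNames)

#' @describeIn PValueMatrix-class active-class p-values.
#' @export
setMethod("pActive", "PValueMatrix", function(x) x@p1)

#' @describeIn PValueMatrix-class inactive-class p-values.
#' @export
setMethod("pInactive", "PValueMatrix", function(x) x@p0)

#' @describeIn PValueMatrix-class dimensions (compounds, endpoints).
#' @export
setMethod("dim", "PValueMatrix", function(x) dim(x@p1))

#' @describeIn PValueMatrix-class compact display.
#' @export
setMethod("show", "PValueMatrix", function(object) {
  cat(sprintf("PValueMatrix: %d compounds x %d endpoints\n",
              length(object@compoundIds), length(object@endpointNames)))
  invisible(object)
})
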