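#' Standardize a SMILES string
#'
#' Minimal structure standardization for QSAR input: keep the largest
#' fragment (salt/counter-ion stripping), neutralize charges where a simple
#' proton add/remove suffices, and emit the canonical SMILES of the result.
#' The operation is idempotent: standardizing an already-standard string
#' returns it unchanged. This is a deliberately small canonicalization
#' pipeline, not a full QSAR-ready curation workflow (no tautomer
#' enumeration, no stereo repair).
#'
#' @param smiles character vector of raw SMILES.
#' @param onError `"stop"` (default) raises an error naming the offending
#'   input; `"na"` returns `NA` for unparsable entries so callers can
#'   collect rejects.
#' @return character vector of canonical SMILES, same length as input.
#' @examples
#' standardizeStructure(c("OCC", "CCO"))           # identical canonical form
#' standardizeStructure("CCO.[Na+].[Cl-]")         # salt stripped -> "CCO"
#' @export
standardizeStructure <- function(smiles, onError = c("stop", "na")) {
  onError <- match.arg(onError)
  stopifnot(is.character(smiles))
  if (any(!nzchar(smiles) | is.na(smiles))) {
    if (onError == "stop")
      stop("empty or missing SMILES input")
  }
  # -r keeps the largest contiguous fragment; --neutralize adds/removes
  # protons on simple charged centres. One call per molecule keeps row
  # alignment when some inputs fail to parse.
  ops <- data.frame(names = c("r", "neutralize"), args = c("", ""))
  out <- vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    res <- tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", s, options = ops),
      error = function(e) "")
    res <- sub("[\t\n ].*$", "", res)
    if (!nzchar(res)) NA_character_ else res
  }, character(1), USE.NAMES = FALSE)
  bad <- which(is.na(out))
  if (length(bad) && onError == "stop")
    stop("unparsable SMILES: ", paste(smiles[bad], collapse = ", "))
  out
}

#' Compute physicochemical descriptors for standardized structures
#'
#' Featurizes each structure with the full 2-D physicochemical descriptor
#' set of the Open Babel toolkit as exposed by [ChemmineR::propOB()]:
#' hydrogen-bond acceptors (two definitions), hydrogen-bond donors, logP,
#' molar refractivity, molecular weight, fluorine count and topological
#' polar surface area. The descriptor list and order are fixed for a given
#' toolkit release and are stored in every model artifact so screening
#' featurization is guaranteed identical.
#'
#' Non-finite descriptor values are replaced by the sentinel `0` and the
#' affected rows are reported in the `"flagged"` attribute; structures for
#' which the descriptor engine fails entirely are returned as flagged rows
#' of sentinels so the caller can exclude them from modeling.
#'
#' @param smiles character vector of standardized SMILES
#'   (see [standardizeStructure()]).
#' @return numeric matrix (structures x descriptors) with SMILES rownames,
#'   attribute `"flagged"` holding indices of rows with replaced or failed
#'   values, and attribute `"toolkit"` recording the descriptor engine.
#' @examples
#' d <- computeDescriptors("CCO")
#' d[, "MW"]   # molecular weight of ethanol, ~46.07
#' @export
computeDescriptors <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) > 0)
  descNames <- c("HBA1", "HBA2", "HBD", "logP", "MR", "MW", "nF", "TPSA")
  out <- matrix(NA_real_, length(smiles), length(descNames),
                dimnames = list(smiles, descNames))
  ok <- !is.na(smiles) & nzchar(smiles)
  if (any(ok)) {
    batch <- smiles[ok]
    names(batch) <- sprintf("m%06d", seq_along(batch))  # unique SDF ids
    props <- tryCatch({
      p <- suppressWarnings(ChemmineR::propOB(ChemmineR::smiles2sdf(batch)))
      if (nrow(p) == length(batch)) p else NULL
    }, error = function(e) NULL)
    if (!is.null(props)) {
      out[ok, ] <- as.matrix(props[, descNames])
    } else {
      # engine failure on the batch: recover structure by structure
      for (i in which(ok)) {
        p <- tryCatch(
          suppressWarnings(ChemmineR::propOB(
            ChemmineR::smiles2sdf(stats::setNames(smiles[i], "m1")))),
          error = function(e) NULL)
        if (!is.null(p)) out[i, ] <- as.matrix(p[1, descNames])
      }
    }
  }
  flagged <- which(apply(out, 1, function(r) any(!is.finite(r))))
  out[!is.finite(out)] <- 0
  structure(out, flagged = unname(flagged),
            toolkit = paste0("OpenBabel/", utils::packageVersion("ChemmineOB")))
}

#' Read a compound table from CSV or SMILES file
#'
#' Reads a tabular chemistry file, standardizes every structure, and
#' separates parsable records from rejects. Unparsable structures are never
#' silently dropped: they are returned in a rejects table with their row
#' number and reason.
#'
#' @param path CSV file, or a `.smi` file (whitespace-separated
#'   `SMILES id` per line, no header).
#' @param columnMap named list mapping roles to column names for CSV input:
#'   `id`, `smiles` (both mandatory) and optionally `label` (a per-replicate
#'   activity column over Active/Inactive/Inconclusive).
#' @return list with components `records` (data.frame: `compound_id`,
#'   `smiles_raw`, `smiles_standard`, and `label` when mapped) and `rejects`
#'   (data.frame: `row`, `compound_id`, `smiles_raw`, `reason`).
#' @export
readCompoundTable <- function(path,
                              columnMap = list(id = "compound_id",
                                               smiles = "smiles")) {
  stopifnot(file.exists(path))
  if (grepl("\\.smi$", path, ignore.case = TRUE)) {
    raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                             col.names = c("smiles", "id")[1:2],
                             fill = TRUE, comment.char = "")
    if (nrow(raw) == 0) {
      warning("empty compound file: ", path)
      return(list(records = emptyRecords(FALSE), rejects = emptyRejects()))
    }
    if (!"id" %in% names(raw) || all(!nzchar(raw$id)))
      raw$id <- paste0("cmpd_", seq_len(nrow(raw)))
    tab <- data.frame(compound_id = as.character(raw$id),
                      smiles_raw = raw$smiles, stringsAsFactors = FALSE)
    hasLabel <- FALSE
  } else {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (nrow(raw) == 0) {
      warning("empty compound file: ", path)
      return(list(records = emptyRecords(!is.null(columnMap$label)),
                  rejects = emptyRejects()))
    }
    need <- c(columnMap$id, columnMap$smiles)
    missingCols <- setdiff(need, names(raw))
    if (length(missingCols))
      stop("missing mandatory column(s): ", paste(missingCols, collapse = ", "))
    tab <- data.frame(compound_id = as.character(raw[[columnMap$id]]),
                      smiles_raw = as.character(raw[[columnMap$smiles]]),
                      stringsAsFactors = FALSE)
    hasLabel <- !is.null(columnMap$label)
    if (hasLabel) {
      if (!columnMap$label %in% names(raw))
        stop("missing mandatory column(s): ", columnMap$label)
      tab$label <- as.character(raw[[columnMap$label]])
    }
  }
  tab$smiles_standard <- standardizeStructure(tab$smiles_raw, onError = "na")
  bad <- which(is.na(tab$smiles_standard))
  rejects <- if (length(bad)) {
    data.frame(row = bad, compound_id = tab$compound_id[bad],
               smiles_raw = tab$smiles_raw[bad],
               reason = "unparsable SMILES", stringsAsFactors = FALSE)
  } else emptyRejects()
  records <- tab[setdiff(seq_len(nrow(tab)), bad), , drop = FALSE]
  rownames(records) <- NULL
  cols <- c("compound_id", "smiles_raw", "smiles_standard",
            if (hasLabel) "label")
  list(records = records[, cols, drop = FALSE], rejects = rejects)
}

emptyRecords <- function(hasLabel) {
  d <- data.frame(compound_id = character(), smiles_raw = character(),
                  smiles_standard = character(), stringsAsFactors = FALSE)
  if (hasLabel) d$label <- character()
  d
}

emptyRejects <- function() {
  data.frame(row = integer(), compound_id = character(),
             smiles_raw = character(), reason = character(),
             stringsAsFactors = FALSE)
}

#' Aggregate replicate activity calls into one resolved label
#'
#' Replicate bioassay records for one compound are resolved by a two-thirds
#' majority: the compound is `active` (resp. `inactive`) when at least 2/3
#' of its replicates agree on that call, and `excluded` otherwise.
#' Inconclusive replicates never win the vote; by default they stay in the
#' denominator, which makes the 2/3 threshold harder to reach
#' (conservative). Set `dropInconclusive = TRUE` to remove them before the
#' vote instead.
#'
#' @param replicateLabels character vector over
#'   `Active`/`Inactive`/`Inconclusive` (case-insensitive).
#' @param dropInconclusive drop Inconclusive replicates before voting?
#' @return one of `"active"`, `"inactive"`, `"excluded"`.
#' @examples
#' aggregateReplicates(c("Active", "Active", "Inactive"))   # "active"
#' aggregateReplicates(c("Active", "Inactive"))             # "excluded"
#' @export
aggregateReplicates <- function(replicateLabels, dropInconclusive = FALSE) {
  stopifnot(length(replicateLabels) > 0)
  lab <- tolower(as.character(replicateLabels))
  if (!all(lab %in% c("active", "inactive", "inconclusive")))
    stop("replicate labels must be Active, Inactive or Inconclusive")
  if (dropInconclusive) {
    lab <- lab[lab != "inconclusive"]
    if (length(lab) == 0) return("excluded")
  }
  n <- length(lab)
  if (sum(lab == "active") / n >= 2 / 3) return("active")
  if (sum(lab == "inactive") / n >= 2 / 3) return("inactive")
  "excluded"
}

#' Apply the minimum active-ratio curation filter
#'
#' Endpoints whose active class is vanishingly small cannot support a
#' usable classifier; datasets are kept only when their active fraction
#' meets a minimum ratio (default 0.3%, boundary inclusive).
#'
#' @param dataset an [AssayDataset-class].
#' @param minActiveRatio keep threshold on [activeRatio()]; default 0.003.
#' @return list with `keep` (logical), `activeRatio`, and a human-readable
#'   `reason`.
#' @export
filterAssay <- function(dataset, minActiveRatio = 0.003) {
  stopifnot(is(dataset, "AssayDataset"), length(dataset) > 0)
  r <- activeRatio(dataset)
  keep <- r >= minActiveRatio
  list(keep = keep, activeRatio = r,
       reason = sprintf("active ratio %.4f %s cutoff %.4f", r,
                        if (keep) ">=" else "<", minActiveRatio))
}

#' Write / read an AssayDataset archive
#'
#' The archive is a directory of plain-text files: `compounds.csv`
#' (id + label), `descriptors.csv` (the descriptor matrix) and
#' `metadata.json` (endpoint name, active ratio, descriptor names and
#' toolkit note), so a screening run can reuse the identical descriptor
#' set and order.
#'
#' @param dataset an [AssayDataset-class].
#' @param dir archive directory (created if needed).
#' @return `writeAssayDataset` returns `dir` invisibly; `readAssayDataset`
#'   returns the reconstructed [AssayDataset-class].
#' @export
writeAssayDataset <- function(dataset, dir) {
  stopifnot(is(dataset, "AssayDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(
    data.frame(compound_id = compoundIds(dataset),
               label = as.character(activityLabels(dataset))),
    file.path(dir, "compounds.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(descriptors(dataset)),
                   file.path(dir, "descriptors.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(endpoint_name = endpointName(dataset),
         active_ratio = activeRatio(dataset),
         n_compounds = length(dataset),
         descriptor_names = colnames(descriptors(dataset))),
    file.path(dir, "metadata.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeAssayDataset
#' @export
readAssayDataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  cmp <- utils::read.csv(file.path(dir, "compounds.csv"),
                         stringsAsFactors = FALSE)
  desc <- as.matrix(utils::read.csv(file.path(dir, "descriptors.csv")))
  colnames(desc) <- meta$descriptor_names
  assayDataset(meta$endpoint_name, desc, cmp$label,
               compoundIds = as.character(cmp$compound_id))
}
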