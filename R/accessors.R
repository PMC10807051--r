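#' @include AllGenerics.R
NULL

#' Accessors for AssociationNetwork
#'
#' \code{edges} returns the edge table; \code{nodes} the sorted unique gene
#' set (union of edge endpoints).
#'
#' @param object an \linkS4class{AssociationNetwork}.
#' @param ... ignored.
#' @return \code{edges}: data.frame; \code{nodes}: character vector.
#' @aliases edges nodes
#' @export
setMethod("edges", "AssociationNetwork", function(object, ...) object@edges)

#' @rdname edges-AssociationNetwork-method
#' @export
setMethod("nodes", "AssociationNetwork", function(object, ...) {
  sort(unique(c(object@edges$gene1, object@edges$gene2)))
})

setMethod("show", "AssociationNetwork", function(object) {
  cat(sprintf("AssociationNetwork: %d nodes, %d edges (%d negative)\n",
              length(nodes(object)), nrow(object@edges),
              sum(object@edges$coefficient < 0)))
})

#' Accessors for MechModel tables
#'
#' Return the model's component tables and summary counts. \code{modelCounts}
#' reports the number of genes, species, ratelaws, TARs and parameters (all
#' numeric constants carried by gene records, ratelaws and TARs).
#'
#' @param object a \linkS4class{MechModel}.
#' @param ... ignored.
#' @aliases compartments speciesTable geneTable rateLaws tarTable omicsTable
#'   modelCounts provenanceLog
#' @export
setMethod("compartments", "MechModel", function(object, ...) object@compartments)

#' @rdname compartments-MechModel-method
#' @export
setMethod("speciesTable", "MechModel", function(object, ...) object@species)

#' @rdname compartments-MechModel-method
#' @export
setMethod("geneTable", "MechModel", function(object, ...) object@genes)

#' @rdname compartments-MechModel-method
#' @export
setMethod("rateLaws", "MechModel", function(object, ...) object@ratelaws)

#' @rdname compartments-MechModel-method
#' @export
setMethod("tarTable", "MechModel", function(object, ...) object@tars)

#' @rdname compartments-MechModel-method
#' @export
setMethod("omicsTable", "MechModel", function(object, ...) object@omics)

#' @rdname compartments-MechModel-method
#' @export
setMethod("modelCounts", "MechModel", function(object, ...) {
  nRlPars <- sum(vapply(object@ratelaws$parameters,
                        function(p) length(.parseParams(p)), integer(1)))
  ## per gene: copy_number, kG_ac, kG_in, kTC_basal, kTCd; per TAR: K_A, n_A
  c(genes = nrow(object@genes),
    species = nrow(object@species),
    ratelaws = nrow(object@ratelaws),
    tars = nrow(object@tars),
    parameters = 5L * nrow(object@genes) + nRlPars + 2L * nrow(object@tars))
})

#' @rdname compartments-MechModel-method
#' @export
setMethod("provenanceLog", "MechModel", function(object, ...) object@provenance)

setMethod("show", "MechModel", function(object) {
  ct <- modelCounts(object)
  cat("MechModel\n")
  cat(sprintf("  %d compartment(s), %d genes, %d species, %d ratelaws, %d TARs, %d parameters\n",
              nrow(object@compartments), ct["genes"], ct["species"],
              ct["ratelaws"], ct["tars"], ct["parameters"]))
  if (nrow(object@genes)) {
    exp <- sum(object@genes$origin == "expansion")
    if (exp > 0) cat(sprintf("  %d gene(s) added by expansion\n", exp))
  }
})

setMethod("show", "ExpansionReport", function(object) {
  cat(sprintf("ExpansionReport: +%d genes, +%d species, +%d ratelaws, +%d TARs\n",
              object@genesAdded, object@speciesAdded, object@ratelawsAdded,
              object@tarsAdded))
  if (nrow(object@dropped))
    cat(sprintf("  %d TAR candidate(s) dropped (%s)\n", nrow(object@dropped),
                paste(unique(object@dropped$reason), collapse = ", ")))
  if (nrow(object@defaultsUsed))
    cat(sprintf("  %d parameter default(s) used\n", nrow(object@defaultsUsed)))
})

#' Accessors for TimeCourse
#'
#' @param object a \linkS4class{TimeCourse}.
#' @param ... ignored.
#' @aliases tcTimes tcValues
#' @export
setMethod("tcTimes", "TimeCourse", function(object, ...) object@times)

#' @rdname tcTimes-TimeCourse-method
#' @export
setMethod("tcValues", "TimeCourse", function(object, ...) object@values)

setMethod("show", "TimeCourse", function(object) {
  cat(sprintf("TimeCourse: %d time points over %.3g h, %d state variables\n",
              length(object@times), diff(range(object@times)) / 3600,
              ncol(object@values)))
})

#' Accessors for FitResults
#'
#' @param object a \linkS4class{FitResults}.
#' @param ... ignored.
#' @aliases fitTable fitProfiles
#' @export
setMethod("fitTable", "FitResults", function(object, ...) object@table)

#' @rdname fitTable-FitResults-method
#' @export
setMethod("fitProfiles", "FitResults", function(object, ...) object@profiles)

setMethod("show", "FitResults", function(object) {
  tb <- object@table
  cat(sprintf("FitResults: %d parameter(s), %d fitted, %d already steady/flat\n",
              nrow(tb), sum(!tb$skipped), sum(tb$skipped)))
})

#' Accessor for KnockoutScreen
#'
#' @param object a \linkS4class{KnockoutScreen}.
#' @param ... ignored.
#' @aliases screenTable
#' @export
setMethod("screenTable", "KnockoutScreen", function(object, ...) object@table)

setMethod("show", "KnockoutScreen", function(object) {
  tb <- object@table
  obs <- unique(tb$gene[tb$classification == "observable"])
  cat(sprintf("KnockoutScreen: %d gene(s) x %d readout(s), threshold %.3g\n",
              length(unique(tb$gene)), length(object@readouts),
              object@threshold))
  cat(sprintf("  observable: %s\n",
              if (length(obs)) paste(obs, collapse = ", ") else "(none)"))
})
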