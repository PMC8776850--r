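#' Accessors for ProteoImpute classes
#'
#' Standard slot accessors: `abundances()` returns the values matrix (with
#' `NA` at missing positions), `missingMask()` the logical mask,
#' `sampleIds()`/`proteinIds()` the identifiers, `spaceTag()` the value space,
#' `nSamples()`/`nProteins()` the dimensions and `missingRate()` the overall
#' missing fraction. `completedMatrix()` extracts the filled matrix of an
#' [ImputationResult-class]; `mixingMatrix()`/`profileMatrix()` the factors of
#' a [FactorModel-class] or [CamModel-class]; `objectiveTrace()` the
#' optimization trace; `markerSets()` and `mdlScores()` the archetype markers
#' and model-order scores of a [CamModel-class].
#'
#' @param x an object of the documented class.
#' @return the slot contents, see above.
#' @name accessors
#' @aliases abundances missingMask sampleIds proteinIds spaceTag nSamples
#'   nProteins missingRate completedMatrix mixingMatrix profileMatrix
#'   objectiveTrace markerSets mdlScores
NULL

#' @rdname accessors
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))
#' @rdname accessors
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("proteinIds", function(x) standardGeneric("proteinIds"))
#' @rdname accessors
#' @export
setGeneric("spaceTag", function(x) standardGeneric("spaceTag"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("nProteins", function(x) standardGeneric("nProteins"))
#' @rdname accessors
#' @export
setGeneric("missingRate", function(x) standardGeneric("missingRate"))
#' @rdname accessors
#' @export
setGeneric("completedMatrix", function(x) standardGeneric("completedMatrix"))
#' @rdname accessors
#' @export
setGeneric("mixingMatrix", function(x) standardGeneric("mixingMatrix"))
#' @rdname accessors
#' @export
setGeneric("profileMatrix", function(x) standardGeneric("profileMatrix"))
#' @rdname accessors
#' @export
setGeneric("objectiveTrace", function(x) standardGeneric("objectiveTrace"))
#' @rdname accessors
#' @export
setGeneric("markerSets", function(x) standardGeneric("markerSets"))
#' @rdname accessors
#' @export
setGeneric("mdlScores", function(x) standardGeneric("mdlScores"))

#' @rdname accessors
setMethod("abundances", "AbundanceMatrix", function(x) x@values)
#' @rdname accessors
setMethod("missingMask", "AbundanceMatrix", function(x) is.na(x@values))
#' @rdname accessors
setMethod("sampleIds", "AbundanceMatrix", function(x) rownames(x@values))
#' @rdname accessors
setMethod("proteinIds", "AbundanceMatrix", function(x) colnames(x@values))
#' @rdname accessors
setMethod("spaceTag", "AbundanceMatrix", function(x) x@space)
#' @rdname accessors
setMethod("nSamples", "AbundanceMatrix", function(x) nrow(x@values))
#' @rdname accessors
setMethod("nProteins", "AbundanceMatrix", function(x) ncol(x@values))
#' @rdname accessors
setMethod("missingRate", "AbundanceMatrix", function(x) mean(is.na(x@values)))

#' @rdname accessors
setMethod("sampleIds", "ExternalScores", function(x) rownames(x@scores))
#' @rdname accessors
setMethod("sampleIds", "GroundTruth", function(x) x@sampleIds)
#' @rdname accessors
setMethod("proteinIds", "GroundTruth", function(x) x@proteinIds)
#' @rdname accessors
setMethod("spaceTag", "GroundTruth", function(x) x@space)

#' @rdname accessors
setMethod("completedMatrix", "ImputationResult", function(x) x@completed)
#' @rdname accessors
setMethod("spaceTag", "ImputationResult", function(x) x@space)

#' @rdname accessors
setMethod("mixingMatrix", "FactorModel", function(x) x@A)
#' @rdname accessors
setMethod("profileMatrix", "FactorModel", function(x) x@S)
#' @rdname accessors
setMethod("objectiveTrace", "FactorModel", function(x) x@objective)

#' @rdname accessors
setMethod("mixingMatrix", "CamModel", function(x) x@A)
#' @rdname accessors
setMethod("profileMatrix", "CamModel", function(x) x@S)
#' @rdname accessors
setMethod("markerSets", "CamModel", function(x) x@markerSets)
#' @rdname accessors
setMethod("mdlScores", "CamModel", function(x) x@mdlByK)

#' Subset an AbundanceMatrix
#'
#' Standard `[` subsetting by sample and protein (index, id or logical);
#' always returns an `AbundanceMatrix`.
#'
#' @param x an [AbundanceMatrix-class].
#' @param i,j sample and protein selectors.
#' @param ... ignored.
#' @param drop ignored (never drops).
#' @export
setMethod("[", "AbundanceMatrix", function(x, i, j, ..., drop = FALSE) {
  v <- x@values[i, j, drop = FALSE]
  new("AbundanceMatrix", values = v, space = x@space)
})

setMethod("show", "AbundanceMatrix", function(object) {
  cat(sprintf("AbundanceMatrix: %d samples x %d proteins [%s space]\n",
              nrow(object@values), ncol(object@values), object@space))
  cat(sprintf("  missing: %d/%d entries (%.1f%%)\n",
              sum(is.na(object@values)), length(object@values),
              100 * mean(is.na(object@values))))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: |Omega| = %d held-out entries [%s space] over %d proteins\n",
              length(object@values), object@space,
              length(unique(object@proteinIds))))
})

setMethod("show", "ImputationResult", function(object) {
  cat(sprintf("ImputationResult: method '%s', %d entries filled [%s space]\n",
              object@method, nrow(object@filled), object@space))
})

setMethod("show", "FactorModel", function(object) {
  cat(sprintf(
    "FactorModel: rank %d, lambdaA=%g lambdaS=%g alpha=%g; %d iterations, %s\n",
    ncol(object@A), object@lambdaA, object@lambdaS, object@alphaFused,
    length(object@objective),
    if (isTRUE(object@converged)) "converged" else "not converged"))
})

setMethod("show", "CamModel", function(object) {
  cat(sprintf("CamModel: k = %d archetypes, %d marker proteins\n",
              object@k, object@nMG))
  cat("  description length by k:\n")
  print(round(object@mdlByK, 3))
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth: %d samples x %d proteins, %d archetypes, noise sd %g\n",
              nrow(object@ATrue), ncol(object@STrue), ncol(object@ATrue),
              object@noiseSigma))
})
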