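#' Accessors for anaerGS data classes
#'
#' Small accessor generics: \code{dosages} returns the dosage matrix of a
#' [MarkerMatrix-class]; \code{genotypeIds} and \code{markerIds} its
#' dimnames (genotype ids also apply to relationship matrices, fits, GEBV
#' tables and donor lists); \code{grmValues} the relationship values;
#' \code{blups}, \code{pev} and \code{fixedEffects} the parts of a
#' [FitResult-class]; \code{varianceComponents} its
#' [VarianceComponents-class]; \code{gebvs} the genotype-by-trait matrix of
#' a [GEBVTable-class]; \code{donorTable} the ranked data.frame of a
#' [DonorList-class].
#'
#' @param x an anaerGS object.
#' @return The extracted component (matrix, named numeric vector or
#'   data.frame, as documented above).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname accessors
#' @export
setGeneric("genotypeIds", function(x) standardGeneric("genotypeIds"))
#' @rdname accessors
#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))
#' @rdname accessors
#' @export
setGeneric("grmValues", function(x) standardGeneric("grmValues"))
#' @rdname accessors
#' @export
setGeneric("blups", function(x) standardGeneric("blups"))
#' @rdname accessors
#' @export
setGeneric("pev", function(x) standardGeneric("pev"))
#' @rdname accessors
#' @export
setGeneric("fixedEffects", function(x) standardGeneric("fixedEffects"))
#' @rdname accessors
#' @export
setGeneric("varianceComponents", function(x) standardGeneric("varianceComponents"))
#' @rdname accessors
#' @export
setGeneric("gebvs", function(x) standardGeneric("gebvs"))
#' @rdname accessors
#' @export
setGeneric("donorTable", function(x) standardGeneric("donorTable"))

#' @rdname accessors
#' @export
setMethod("dosages", "MarkerMatrix", function(x) x@dosages)
#' @rdname accessors
#' @export
setMethod("genotypeIds", "MarkerMatrix", function(x) rownames(x@dosages))
#' @rdname accessors
#' @export
setMethod("markerIds", "MarkerMatrix", function(x) colnames(x@dosages))
#' @rdname accessors
#' @export
setMethod("genotypeIds", "GenomicRelationshipMatrix", function(x) rownames(x@values))
#' @rdname accessors
#' @export
setMethod("grmValues", "GenomicRelationshipMatrix", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("blups", "FitResult", function(x) x@blups)
#' @rdname accessors
#' @export
setMethod("pev", "FitResult", function(x) x@pev)
#' @rdname accessors
#' @export
setMethod("fixedEffects", "FitResult", function(x) x@fixedEstimates)
#' @rdname accessors
#' @export
setMethod("varianceComponents", "FitResult", function(x) x@varcomp)
#' @rdname accessors
#' @export
setMethod("genotypeIds", "FitResult", function(x) names(x@blups))
#' @rdname accessors
#' @export
setMethod("gebvs", "GEBVTable", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("genotypeIds", "GEBVTable", function(x) rownames(x@values))
#' @rdname accessors
#' @export
setMethod("donorTable", "DonorList", function(x) x@table)

setMethod("show", "MarkerMatrix", function(object) {
  d <- object@dosages
  cat(sprintf("MarkerMatrix: %d genotypes x %d markers, %.2f%% missing\n",
              nrow(d), ncol(d), 100 * mean(is.na(d))))
})

setMethod("show", "GenomicRelationshipMatrix", function(object) {
  cat(sprintf(
    "GenomicRelationshipMatrix: %d genotypes, denominator %.4f, ridge %.1e\n",
    nrow(object@values), object@denominator, object@ridge))
  cat(sprintf("  mean diagonal %.4f, mean off-diagonal %.4f\n",
              mean(diag(object@values)),
              mean(object@values[upper.tri(object@values)])))
})

setMethod("show", "MarkerQCReport", function(object) {
  cat(sprintf("MarkerQCReport: %d samples dropped, %d markers dropped\n",
              nrow(object@droppedSamples), nrow(object@droppedMarkers)))
  cat(sprintf("  mean sample call rate %.3f, mean heterozygosity %.3f\n",
              mean(object@sampleCallRate), mean(object@sampleHeterozygosity)))
})

setMethod("show", "VarianceComponents", function(object) {
  cat(sprintf(
    "VarianceComponents (%s): sigma2_g = %.6g, sigma2_e = %.6g, H2 = %.3f\n",
    object@method, object@sigma2g, object@sigma2e,
    object@sigma2g / (object@sigma2g + object@sigma2e)))
  cat(sprintf("  %s after %d iterations\n", object@convergence,
              object@nIterations))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: %d observations (%d dropped), %d genotype BLUPs\n",
              object@nObs, object@nDropped, length(object@blups)))
  show(object@varcomp)
})

setMethod("show", "GEBVTable", function(object) {
  cat(sprintf("GEBVTable [%s]%s: %d genotypes x %d traits\n",
              object@environment,
              if (object@standardized) " (standardized)" else "",
              nrow(object@values), ncol(object@values)))
})

setMethod("show", "DonorList", function(object) {
  tb <- object@table
  cat(sprintf(
    "DonorList [%s]: %d entries + %d checks (index >= %g, germination >= %g%%)\n",
    object@rule, sum(!tb$is_check), sum(tb$is_check),
    object@indexMin, object@germMin))
  if (nrow(tb)) print(utils::head(tb, 10), row.names = FALSE)
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d entries + %d checks x %d, %d x %d lattice, %d replications\n",
    object@nEntries, object@nChecks, object@checkReps,
    object@plotsPerBlock, object@blocksPerReplication, object@nReplications))
  cat(sprintf("  %d markers, experiments %s x conditions %s, seed %d\n",
              object@nMarkers, paste(object@experiments, collapse = "/"),
              paste(object@conditions, collapse = "/"), object@rngSeed))
})
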