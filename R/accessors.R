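#' Accessors for twinGxE containers
#'
#' @param x A \linkS4class{GenotypeMatrix}, \linkS4class{TwinCohort},
#'   \linkS4class{TruthTable} or \linkS4class{LatentFactorModel}.
#' @name accessors
NULL

#' @describeIn accessors sample-by-SNP dosage matrix.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @describeIn accessors per-SNP annotation DataFrame.
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' @describeIn accessors the cohort's GenotypeMatrix.
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @describeIn accessors expression SummarizedExperiment of a cohort.
#' @export
setGeneric("expressionData", function(x) standardGeneric("expressionData"))

#' @describeIn accessors per-sample metadata DataFrame.
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' @describeIn accessors the planted-effect TruthTable.
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))

#' @describeIn accessors planted-effect table (DataFrame).
#' @export
setGeneric("plantedEffects", function(x) standardGeneric("plantedEffects"))

#' @describeIn accessors realized latent-factor score matrix.
#' @export
setGeneric("latentScores", function(x) standardGeneric("latentScores"))

#' @describeIn accessors factor score matrix of a LatentFactorModel.
#' @export
setGeneric("factorScores", function(x) standardGeneric("factorScores"))

#' @describeIn accessors factor loading matrix of a LatentFactorModel.
#' @export
setGeneric("factorLoadings", function(x) standardGeneric("factorLoadings"))

#' @describeIn accessors per-factor phenotype correlation table.
#' @export
setGeneric("phenotypeCorr", function(x) standardGeneric("phenotypeCorr"))

setMethod("dosages", "GenotypeMatrix", function(x) x@dosages)
setMethod("snpInfo", "GenotypeMatrix", function(x) x@snps)
setMethod("dosages", "TwinCohort", function(x) x@genotypes@dosages)
setMethod("snpInfo", "TwinCohort", function(x) x@genotypes@snps)
setMethod("genotypes", "TwinCohort", function(x) x@genotypes)
setMethod("expressionData", "TwinCohort", function(x) x@expression)
setMethod("sampleData", "TwinCohort", function(x) x@samples)
setMethod("truthTable", "TwinCohort", function(x) x@truth)
setMethod("plantedEffects", "TruthTable", function(x) x@effects)
setMethod("plantedEffects", "TwinCohort", function(x) x@truth@effects)
setMethod("latentScores", "TruthTable", function(x) x@latentScores)
setMethod("latentScores", "TwinCohort", function(x) x@truth@latentScores)
setMethod("factorScores", "LatentFactorModel", function(x) x@scores)
setMethod("factorLoadings", "LatentFactorModel", function(x) x@loadings)
setMethod("phenotypeCorr", "LatentFactorModel", function(x) x@phenotypeCorr)

#' Processing state of an expression matrix
#'
#' Expression matrices move through the states \code{raw ->
#' depth_normalized -> filtered -> int_transformed -> residualized};
#' each processing step checks that its input is in an admissible state
#' and advances the flag.
#'
#' @param x A \code{SummarizedExperiment} produced by twinGxE.
#' @return A character scalar state flag.
#' @export
expressionState <- function(x) {
    st <- S4Vectors::metadata(x)$state
    if (is.null(st)) "raw" else st
}

.STATES <- c("raw", "depth_normalized", "filtered", "int_transformed",
             "residualized")

# advance the state flag, enforcing forward-only transitions
.setState <- function(x, new, allowed_from) {
    cur <- expressionState(x)
    if (!cur %in% allowed_from)
        stop(sprintf("cannot move expression state '%s' -> '%s' (allowed from: %s)",
                     cur, new, paste(allowed_from, collapse = ", ")))
    S4Vectors::metadata(x)$state <- new
    x
}

# assay extraction helper: the single expression assay
.exprAssay <- function(x) SummarizedExperiment::assay(x, "expr")
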