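#' SimulationConfig: parameters of the synthetic twin-cohort generator
#'
#' Describes a twin-structured cohort (monozygotic and dizygotic pairs plus
#' unrelated singletons), a biallelic genotype panel, a continuous
#' adiposity-like phenotype, and exon-level expression with optional
#' planted genetic, phenotypic, interaction, latent-confounder and
#' mediated-trans effects. The seed fully determines all generated data.
#'
#' Expression is generated directly on the scale of the inverse-normal
#' transformed data that the downstream models operate on (Gaussian
#' signal plus Gaussian noise); an optional negative-binomial count layer
#' maps this signal onto raw read counts for exercising the
#' quantification steps.
#'
#' @slot nMzPairs,nDzPairs,nUnrelated integer counts of sample units.
#' @slot nSnps,nGenes integer panel sizes.
#' @slot mafRange numeric(2), minor allele frequency bounds in [0.05, 0.5].
#' @slot exonsPerGeneRange integer(2), inclusive range of meta-exon counts.
#' @slot phenotypeMean,phenotypeSd numeric, BMI-like scale (default 25 / 4).
#' @slot phenotypeHeritability numeric in [0, 1]; additive genetic fraction
#'   of phenotype variance (shared fully within MZ, half within DZ pairs).
#' @slot ageRange numeric(2), years; co-twins share their age.
#' @slot nLatentFactors integer, number of hidden confounders.
#' @slot latentPhenotypeCorr numeric, per-factor correlation with the
#'   phenotype (recycled/truncated to \code{nLatentFactors}).
#' @slot latentFactorSd numeric, per-factor loading standard deviation.
#' @slot latentLoadingDensity numeric in (0, 1], fraction of features a
#'   factor loads on.
#' @slot varFamily,varZygosity numeric, variances of the family and
#'   zygosity (excess MZ sharing) random intercepts on expression.
#' @slot noiseSd numeric, residual expression noise SD.
#' @slot techSd numeric, SD of technical-covariate effects on expression.
#' @slot ldRho numeric in [0, 1); AR(1) correlation between adjacent loci
#'   on a haplotype (0 = independent loci).
#' @slot countLayer logical; also derive negative-binomial read counts.
#' @slot effectGrid data.frame of planted effects (see
#'   \code{\link{plantedEffect}}); may have zero rows.
#' @slot seed integer.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
    representation(
        nMzPairs = "integer", nDzPairs = "integer", nUnrelated = "integer",
        nSnps = "integer", nGenes = "integer",
        mafRange = "numeric", exonsPerGeneRange = "integer",
        phenotypeMean = "numeric", phenotypeSd = "numeric",
        phenotypeHeritability = "numeric", ageRange = "numeric",
        nLatentFactors = "integer", latentPhenotypeCorr = "numeric",
        latentFactorSd = "numeric", latentLoadingDensity = "numeric",
        varFamily = "numeric", varZygosity = "numeric",
        noiseSd = "numeric", techSd = "numeric",
        ldRho = "numeric", countLayer = "logical",
        effectGrid = "data.frame", seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    cnt <- c(object@nMzPairs, object@nDzPairs, object@nUnrelated,
             object@nSnps, object@nGenes)
    if (any(cnt < 0)) msg <- c(msg, "all counts must be >= 0")
    if (object@nMzPairs + object@nDzPairs + object@nUnrelated == 0)
        msg <- c(msg, "cohort must contain at least one sample")
    if (object@nSnps == 0) msg <- c(msg, "nSnps must be positive")
    mr <- object@mafRange
    if (length(mr) != 2 || mr[1] > mr[2] || mr[1] < 0.05 || mr[2] > 0.5)
        msg <- c(msg, "mafRange must be within [0.05, 0.5]")
    er <- object@exonsPerGeneRange
    if (length(er) != 2 || er[1] < 1 || er[1] > er[2])
        msg <- c(msg, "exonsPerGeneRange must be a valid positive range")
    if (object@phenotypeHeritability < 0 || object@phenotypeHeritability > 1)
        msg <- c(msg, "phenotypeHeritability must lie in [0, 1]")
    if (object@ldRho < 0 || object@ldRho >= 1)
        msg <- c(msg, "ldRho must lie in [0, 1)")
    if (any(abs(object@latentPhenotypeCorr) > 1))
        msg <- c(msg, "latentPhenotypeCorr entries must lie in [-1, 1]")
    if (object@latentLoadingDensity <= 0 || object@latentLoadingDensity > 1)
        msg <- c(msg, "latentLoadingDensity must lie in (0, 1]")
    if (any(c(object@varFamily, object@varZygosity) < 0) ||
        object@noiseSd <= 0)
        msg <- c(msg, "variance components must be >= 0 and noiseSd > 0")
    eg <- object@effectGrid
    if (nrow(eg)) {
        if (!all(c("kind", "gene_id", "snp_id") %in% colnames(eg)))
            msg <- c(msg, "effectGrid must come from plantedEffect()")
        else if (!all(eg$kind %in% c("main_eqtl", "gxe_interaction",
                                     "trans_mediated")))
            msg <- c(msg, "unknown planted-effect kind")
        if (!is.null(eg$mediation_fraction) &&
            any(eg$mediation_fraction < 0 | eg$mediation_fraction > 1,
                na.rm = TRUE))
            msg <- c(msg, "mediation_fraction must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
})

#' Build a validated SimulationConfig
#'
#' Defaults describe the study conditions the package targets: roughly 700
#' usable samples from an adult female twin registry (ages 38-84, BMI mean
#' 25, SD 4), imputed common variants (MAF 5-50 percent), five latent
#' confounders of which the leading three correlate with the phenotype
#' (max r = 0.5), and modest familial variance on expression.
#'
#' @param nMzPairs,nDzPairs,nUnrelated cohort structure
#'   (default 120/120/220, i.e. 700 samples).
#' @param nSnps,nGenes panel sizes.
#' @param mafRange,exonsPerGeneRange,phenotypeMean,phenotypeSd,ageRange
#'   see the class documentation.
#' @param phenotypeHeritability additive genetic fraction of the phenotype.
#' @param nLatentFactors,latentPhenotypeCorr,latentFactorSd,latentLoadingDensity
#'   latent-confounder structure.
#' @param varFamily,varZygosity,noiseSd,techSd expression variance components.
#' @param ldRho AR(1) haplotype LD (0 = independent loci).
#' @param countLayer derive a negative-binomial count layer.
#' @param effectGrid planted effects, rows from \code{\link{plantedEffect}}.
#' @param seed integer seed; fully determines the cohort.
#' @return A \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(nMzPairs = 5, nDzPairs = 5, nUnrelated = 10,
#'                         nSnps = 50, nGenes = 10, seed = 1)
#' @export
simulationConfig <- function(nMzPairs = 120L, nDzPairs = 120L,
        nUnrelated = 220L, nSnps = 2000L, nGenes = 200L,
        mafRange = c(0.05, 0.5), exonsPerGeneRange = c(1L, 8L),
        phenotypeMean = 25, phenotypeSd = 4, phenotypeHeritability = 0.4,
        ageRange = c(38, 84), nLatentFactors = 5L,
        latentPhenotypeCorr = c(0.5, 0.3, 0.2, 0, 0), latentFactorSd = 0.3,
        latentLoadingDensity = 1, varFamily = 0.05, varZygosity = 0.05,
        noiseSd = 0.3, techSd = 0.05, ldRho = 0, countLayer = FALSE,
        effectGrid = emptyEffectGrid(), seed = 1L) {
    k <- as.integer(nLatentFactors)
    lpc <- if (k > 0) rep_len(latentPhenotypeCorr, k) else numeric()
    lsd <- if (k > 0) rep_len(latentFactorSd, k) else numeric()
    new("SimulationConfig",
        nMzPairs = as.integer(nMzPairs), nDzPairs = as.integer(nDzPairs),
        nUnrelated = as.integer(nUnrelated), nSnps = as.integer(nSnps),
        nGenes = as.integer(nGenes), mafRange = as.numeric(mafRange),
        exonsPerGeneRange = as.integer(exonsPerGeneRange),
        phenotypeMean = phenotypeMean, phenotypeSd = phenotypeSd,
        phenotypeHeritability = phenotypeHeritability,
        ageRange = as.numeric(ageRange), nLatentFactors = k,
        latentPhenotypeCorr = lpc, latentFactorSd = lsd,
        latentLoadingDensity = latentLoadingDensity,
        varFamily = varFamily, varZygosity = varZygosity,
        noiseSd = noiseSd, techSd = techSd, ldRho = ldRho,
        countLayer = isTRUE(countLayer),
        effectGrid = as.data.frame(effectGrid), seed = as.integer(seed))
}

#' Describe one planted effect
#'
#' @param kind one of \code{"main_eqtl"}, \code{"gxe_interaction"},
#'   \code{"trans_mediated"}.
#' @param gene_id target gene (e.g. \code{"G0003"}); for
#'   \code{trans_mediated} rows leave \code{NA} (targets are drawn).
#' @param snp_id SNP identifier, or \code{NA} to use the cis SNP nearest
#'   the gene's TSS.
#' @param beta_snp main genotype effect, expression SD per allele.
#' @param beta_pheno phenotype effect, expression SD per phenotype unit.
#' @param beta_interaction interaction effect, expression SD per
#'   (allele x phenotype unit).
#' @param mediator_gene_id for \code{trans_mediated}: the cis gene whose
#'   expression transmits the signal; must itself carry a
#'   \code{gxe_interaction}.
#' @param n_trans_targets for \code{trans_mediated}: number of trans
#'   target genes.
#' @param mediation_fraction fraction of the target interaction signal
#'   routed through the mediator's realized expression, in [0, 1].
#' @return One-row data.frame suitable for rbind-ing into an effect grid.
#' @examples
#' rbind(plantedEffect("gxe_interaction", "G0001", beta_interaction = 0.04),
#'       plantedEffect("trans_mediated", mediator_gene_id = "G0001",
#'                     n_trans_targets = 10, beta_interaction = 0.08))
#' @export
plantedEffect <- function(kind, gene_id = NA_character_,
        snp_id = NA_character_, beta_snp = 0, beta_pheno = 0,
        beta_interaction = 0, mediator_gene_id = NA_character_,
        n_trans_targets = 0L, mediation_fraction = 1) {
    kind <- match.arg(kind, c("main_eqtl", "gxe_interaction",
                              "trans_mediated"))
    data.frame(kind = kind, gene_id = gene_id, snp_id = snp_id,
               beta_snp = beta_snp, beta_pheno = beta_pheno,
               beta_interaction = beta_interaction,
               mediator_gene_id = mediator_gene_id,
               n_trans_targets = as.integer(n_trans_targets),
               mediation_fraction = mediation_fraction,
               stringsAsFactors = FALSE)
}

#' @rdname plantedEffect
#' @export
emptyEffectGrid <- function()
    plantedEffect("main_eqtl")[0, , drop = FALSE]
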