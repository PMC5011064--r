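#' @import methods
#' @importFrom S4Vectors DataFrame metadata `metadata<-`
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment RangedSummarizedExperiment
#' @importFrom stats setNames vcov
NULL

#' GenotypeMatrix: sample-by-SNP allele dosages
#'
#' Container for imputed or hard-called biallelic dosages on the [0, 2]
#' scale together with per-SNP annotation (position, alleles, minor allele
#' frequency). Rows are samples, columns are SNPs.
#'
#' @slot dosages numeric matrix, samples x SNPs; entries in [0, 2];
#'   dimnames give sample and SNP identifiers.
#' @slot snps \code{DataFrame} with one row per SNP: \code{chrom},
#'   \code{pos} (1-based bp), \code{ea} (effect allele), \code{oa}
#'   (other allele), \code{maf}.
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
    representation(dosages = "matrix", snps = "DataFrame"))

setValidity("GenotypeMatrix", function(object) {
    msg <- character()
    d <- object@dosages
    if (ncol(d) != nrow(object@snps))
        msg <- c(msg, "number of dosage columns must equal number of SNP rows")
    if (!all(c("chrom", "pos", "ea", "oa", "maf") %in% colnames(object@snps)))
        msg <- c(msg, "snps must have columns chrom, pos, ea, oa, maf")
    if (length(d) && (min(d, na.rm = TRUE) < 0 || max(d, na.rm = TRUE) > 2))
        msg <- c(msg, "dosages must lie in [0, 2]")
    if (is.null(rownames(d)) || is.null(colnames(d)))
        msg <- c(msg, "dosages must carry sample and SNP dimnames")
    if (nrow(object@snps) && any(object@snps$maf < 0 | object@snps$maf > 0.5))
        msg <- c(msg, "maf must lie in [0, 0.5]")
    if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param dosages numeric matrix (samples x SNPs) with dimnames.
#' @param snps data.frame or DataFrame of SNP annotation (chrom, pos, ea,
#'   oa, maf); if \code{maf} is absent it is computed from the dosages.
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
GenotypeMatrix <- function(dosages, snps) {
    snps <- as(snps, "DataFrame")
    if (is.null(snps$maf)) {
        af <- colMeans(dosages, na.rm = TRUE) / 2
        snps$maf <- pmin(af, 1 - af)
    }
    rownames(snps) <- colnames(dosages)
    new("GenotypeMatrix", dosages = dosages, snps = snps)
}

#' TruthTable: realized planted effects of a simulated cohort
#'
#' Records every effect planted by the cohort generator (main eQTLs,
#' genotype-by-phenotype interactions, mediated trans targets) with its
#' realized coefficients, plus the realized latent-factor scores, so that
#' downstream recovery can be verified by identifier.
#'
#' @slot effects \code{DataFrame}: one row per planted effect with columns
#'   \code{kind}, \code{gene_id}, \code{snp_id}, \code{beta_snp},
#'   \code{beta_pheno}, \code{beta_interaction}, \code{mediator_gene_id},
#'   \code{mediation_fraction}.
#' @slot latentScores numeric matrix, samples x factors (0 columns when
#'   latent factors are disabled).
#' @exportClass TruthTable
setClass("TruthTable",
    representation(effects = "DataFrame", latentScores = "matrix"))

setValidity("TruthTable", function(object) {
    eff <- object@effects
    req <- c("kind", "gene_id", "snp_id", "beta_snp", "beta_pheno",
             "beta_interaction", "mediator_gene_id", "mediation_fraction")
    if (!all(req %in% colnames(eff)))
        return(paste("effects must have columns:", paste(req, collapse = ", ")))
    trans <- eff[eff$kind == "trans_mediated", , drop = FALSE]
    if (nrow(trans)) {
        gxe <- eff$gene_id[eff$kind == "gxe_interaction"]
        if (!all(trans$mediator_gene_id %in% gxe))
            return("every trans_mediated effect needs a mediator gene carrying a gxe_interaction")
    }
    cis <- eff[eff$kind %in% c("main_eqtl", "gxe_interaction"), , drop = FALSE]
    if (anyDuplicated(cis$gene_id))
        return("a gene may carry at most one planted cis effect")
    TRUE
})

#' TwinCohort: a simulated or loaded twin-structured expression cohort
#'
#' Bundles aligned genotypes, exon-level expression (a
#' \code{SummarizedExperiment} whose rowRanges are meta-exons), per-sample
#' metadata and, for simulated cohorts, the table of planted effects.
#'
#' @slot genotypes A \linkS4class{GenotypeMatrix}.
#' @slot expression A \code{SummarizedExperiment} (assay \code{"expr"});
#'   \code{metadata(x)$state} tracks the processing state.
#' @slot samples \code{DataFrame}: \code{sample_id}, \code{phenotype},
#'   \code{age}, \code{family}, \code{zygosity} and technical covariates.
#' @slot truth A \linkS4class{TruthTable}.
#' @exportClass TwinCohort
setClass("TwinCohort",
    representation(genotypes = "GenotypeMatrix",
                   expression = "RangedSummarizedExperiment",
                   samples = "DataFrame",
                   truth = "TruthTable"))

setValidity("TwinCohort", function(object) {
    ids <- object@samples$sample_id
    msg <- character()
    if (!identical(rownames(object@genotypes@dosages), ids))
        msg <- c(msg, "genotype rows must match samples$sample_id")
    if (!identical(colnames(object@expression), ids))
        msg <- c(msg, "expression columns must match samples$sample_id")
    if (length(msg)) msg else TRUE
})

#' LatentFactorModel: broad-variance latent factors of an expression matrix
#'
#' Holds factor scores and loadings from the latent-factor decomposition
#' of family/technical-corrected expression residuals, together with each
#' factor's correlation with the study phenotype.
#'
#' @slot k integer, number of factors.
#' @slot scores numeric matrix, samples x k; columns mutually orthogonal
#'   and ordered by variance explained (non-increasing).
#' @slot loadings numeric matrix, features x k.
#' @slot varExplained numeric vector, proportion of total variance per factor.
#' @slot phenotypeCorr \code{DataFrame} with per-factor \code{r} and
#'   \code{p} against the phenotype (0 rows when no phenotype supplied).
#' @exportClass LatentFactorModel
setClass("LatentFactorModel",
    representation(k = "integer", scores = "matrix", loadings = "matrix",
                   varExplained = "numeric", phenotypeCorr = "DataFrame"))

setValidity("LatentFactorModel", function(object) {
    if (ncol(object@scores) != object@k || ncol(object@loadings) != object@k)
        return("scores and loadings must have k columns")
    if (is.unsorted(rev(object@varExplained)))
        return("factors must be ordered by non-increasing variance explained")
    TRUE
})

setMethod("show", "GenotypeMatrix", function(object) {
    cat(sprintf("GenotypeMatrix: %d samples x %d SNPs\n",
                nrow(object@dosages), ncol(object@dosages)))
    if (nrow(object@snps))
        cat(sprintf("  MAF range: %.3f-%.3f; chromosomes: %s\n",
                    min(object@snps$maf), max(object@snps$maf),
                    paste(unique(object@snps$chrom), collapse = ", ")))
})

setMethod("show", "TwinCohort", function(object) {
    sm <- object@samples
    nmz <- sum(table(sm$zygosity) == 2L)
    nfam <- sum(table(sm$family) == 2L)
    cat(sprintf("TwinCohort: %d samples (%d MZ pairs, %d DZ pairs, %d unrelated)\n",
                nrow(sm), nmz, nfam - nmz, nrow(sm) - 2L * nfam))
    cat(sprintf("  expression: %d meta-exons [state: %s]\n",
                nrow(object@expression),
                expressionState(object@expression)))
    cat(sprintf("  genotypes: %d SNPs; planted effects: %d\n",
                ncol(object@genotypes@dosages), nrow(object@truth@effects)))
})

setMethod("show", "TruthTable", function(object) {
    cat(sprintf("TruthTable: %d planted effects (%s); %d latent factors\n",
                nrow(object@effects),
                paste(names(table(object@effects$kind)), collapse = ", "),
                ncol(object@latentScores)))
})

setMethod("show", "LatentFactorModel", function(object) {
    cat(sprintf("LatentFactorModel: k = %d (%d samples x %d features)\n",
                object@k, nrow(object@scores), nrow(object@loadings)))
    cat(sprintf("  variance explained (top 5): %s\n",
                paste(sprintf("%.3f", utils::head(object@varExplained, 5)),
                      collapse = ", ")))
    if (nrow(object@phenotypeCorr)) {
        r <- object@phenotypeCorr$r
        cat(sprintf("  max |factor-phenotype r| = %.2f (factor %d)\n",
                    max(abs(r)), which.max(abs(r))))
    }
})
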