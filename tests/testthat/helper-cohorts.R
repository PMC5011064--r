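# Shared fixtures, all generated in code. The medium cohort is cached per
# test run since several files exercise it.

tinyConfig <- function(...) {
    simulationConfig(nMzPairs = 5L, nDzPairs = 5L, nUnrelated = 10L,
                     nSnps = 40L, nGenes = 8L, seed = 101L, ...)
}

.cohortCache <- new.env(parent = emptyenv())

cachedCohort <- function(key, config) {
    if (is.null(.cohortCache[[key]]))
        .cohortCache[[key]] <- simulateCohort(config)
    .cohortCache[[key]]
}

# 300 samples, one planted interaction, used across scan tests
mediumCohort <- function() {
    cachedCohort("medium", simulationConfig(
        nMzPairs = 50L, nDzPairs = 50L, nUnrelated = 100L,
        nSnps = 300L, nGenes = 30L, seed = 42L,
        effectGrid = rbind(
            plantedEffect("gxe_interaction", "G0005", beta_snp = 0.1,
                          beta_interaction = 0.06),
            plantedEffect("main_eqtl", "G0010", beta_snp = 0.3))))
}

# build an expression SummarizedExperiment directly from a matrix and a
# minimal per-exon annotation (for micro-fixtures independent of the
# generator)
makeToySE <- function(x, geneId = rownames(x), chrom = "chr1",
                      tss = seq_len(nrow(x)) * 1e5, state = "residualized") {
    gr <- GenomicRanges::GRanges(chrom,
        IRanges::IRanges(tss, width = 100), strand = "+",
        gene_id = geneId, tss = tss)
    names(gr) <- rownames(x)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(expr = x), rowRanges = gr,
        colData = S4Vectors::DataFrame(row.names = colnames(x)))
    S4Vectors::metadata(se)$state <- state
    se
}

# independent normal-equations OLS oracle (coefficients, SEs, p-values);
# deliberately a different algorithm from the package's QR/FWL path
oracleOls <- function(X, y) {
    XtX <- crossprod(X)
    beta <- solve(XtX, crossprod(X, y))
    r <- y - X %*% beta
    df <- length(y) - ncol(X)
    sigma2 <- sum(r^2) / df
    se <- unname(sqrt(sigma2 * diag(solve(XtX))))
    tstat <- as.numeric(beta) / se
    list(beta = as.numeric(beta), se = se,
         p = unname(2 * pt(abs(tstat), df, lower.tail = FALSE)), df = df)
}

# 700-sample cohort carrying a mediated trans network
simulateCohortArgsTrans <- function() {
    simulationConfig(nMzPairs = 120L, nDzPairs = 120L,
        nUnrelated = 220L, nSnps = 60L, nGenes = 40L,
        exonsPerGeneRange = c(1L, 2L), seed = 88L,
        effectGrid = rbind(
            plantedEffect("gxe_interaction", "G0002", beta_snp = 0.1,
                          beta_interaction = 0.05),
            plantedEffect("trans_mediated", mediator_gene_id = "G0002",
                          n_trans_targets = 20L, beta_interaction = 0.08,
                          mediation_fraction = 0.9)))
}

# metadata data.frame for n unrelated samples (no twin structure)
unrelatedMetadata <- function(n, seed = 1) {
    set.seed(seed)
    data.frame(sample_id = sprintf("S%04d", seq_len(n)),
               phenotype = rnorm(n, 25, 4), age = runif(n, 38, 84),
               family = sprintf("F%04d", seq_len(n)),
               zygosity = sprintf("Z%04d", seq_len(n)))
}
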