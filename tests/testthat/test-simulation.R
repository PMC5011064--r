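test_that("monozygotic co-twins carry identical genotype vectors", {
    g <- simulateGenotypes(simulationConfig(nMzPairs = 1L, nDzPairs = 0L,
        nUnrelated = 0L, nSnps = 50L, nGenes = 5L, seed = 3L))
    d <- dosages(g)
    expect_identical(d[1, ], d[2, ])
})

test_that("dizygotic within-pair dosage correlation matches the expected 1/2", {
    # closed-form oracle: one shared parental allele per locus in
    # expectation gives corr(g1, g2) = 1/2 for any allele frequency
    g <- simulateGenotypes(simulationConfig(nMzPairs = 0L,
        nDzPairs = 500L, nUnrelated = 0L, nSnps = 25L, nGenes = 5L,
        mafRange = c(0.29, 0.31), seed = 11L))
    d <- dosages(g)
    t1 <- d[seq(1, 999, 2), ]; t2 <- d[seq(2, 1000, 2), ]
    r <- vapply(seq_len(ncol(d)), function(j) cor(t1[, j], t2[, j]), 0)
    expect_equal(mean(r), 0.5, tolerance = 0.05)
})

test_that("generation is bit-identical under a fixed seed", {
    cfg <- tinyConfig()
    c1 <- simulateCohort(cfg); c2 <- simulateCohort(cfg)
    expect_identical(dosages(c1), dosages(c2))
    expect_identical(SummarizedExperiment::assay(expressionData(c1)),
                     SummarizedExperiment::assay(expressionData(c2)))
    expect_identical(as.data.frame(sampleData(c1)),
                     as.data.frame(sampleData(c2)))
})

test_that("dosages and realized MAF respect the configured bounds", {
    g <- simulateGenotypes(simulationConfig(nMzPairs = 20L,
        nDzPairs = 20L, nUnrelated = 60L, nSnps = 200L, nGenes = 20L,
        mafRange = c(0.2, 0.4), seed = 5L))
    d <- dosages(g)
    expect_true(all(d >= 0 & d <= 2))
    # realized MAF within bounds plus binomial sampling error
    expect_true(all(snpInfo(g)$maf > 0.2 - 0.1 &
                    snpInfo(g)$maf < 0.4 + 0.1))
})

test_that("degenerate configurations are rejected", {
    expect_error(simulationConfig(nMzPairs = 0L, nDzPairs = 0L,
                                  nUnrelated = 0L), "at least one sample")
    expect_error(simulationConfig(nSnps = 0L), "nSnps")
    expect_error(simulationConfig(mafRange = c(0.01, 0.5)), "mafRange")
    expect_error(simulationConfig(effectGrid = plantedEffect(
        "trans_mediated", mediator_gene_id = "G0001",
        mediation_fraction = 1.5)), "mediation_fraction")
    expect_error(simulateCohort(tinyConfig(effectGrid = plantedEffect(
        "gxe_interaction", "G9999"))), "unknown gene")
    expect_error(simulateCohort(tinyConfig(effectGrid = plantedEffect(
        "gxe_interaction", "G0001", snp_id = "rs999999"))), "unknown SNP")
})

test_that("under the global null the phenotype slope is centred at zero", {
    ch <- cachedCohort("null-small", simulationConfig(nMzPairs = 0L,
        nDzPairs = 0L, nUnrelated = 150L, nSnps = 100L, nGenes = 100L,
        exonsPerGeneRange = c(1L, 1L), nLatentFactors = 0L,
        varFamily = 0, varZygosity = 0, seed = 13L))
    x <- SummarizedExperiment::assay(expressionData(ch))
    P <- as.data.frame(sampleData(ch))$phenotype
    pv <- apply(x, 1, function(y) summary(lm(y ~ P))$coefficients[2, 4])
    # type-I error at alpha = 0.05 within the binomial 99% CI
    expect_lt(abs(mean(pv < 0.05) - 0.05),
              2.58 * sqrt(0.05 * 0.95 / length(pv)) + 1e-9)
})

test_that("planted interaction coefficients are recovered by OLS on the generating model", {
    # oracle = OLS on the exact generating design; at beta 0.03 and
    # n = 700 the estimate must fall within 2 SE most of the time
    hits <- 0L; nrep <- 40L
    for (s in seq_len(nrep)) {
        ch <- simulateCohort(simulationConfig(nMzPairs = 0L,
            nDzPairs = 0L, nUnrelated = 700L, nSnps = 4L, nGenes = 2L,
            exonsPerGeneRange = c(1L, 1L), nLatentFactors = 0L,
            varFamily = 0, varZygosity = 0, seed = 600L + s,
            effectGrid = plantedEffect("gxe_interaction", "G0001",
                                       beta_interaction = 0.03)))
        eff <- as.data.frame(plantedEffects(ch))
        sm <- as.data.frame(sampleData(ch))
        y <- SummarizedExperiment::assay(expressionData(ch))[1, ]
        g <- dosages(ch)[, eff$snp_id[1]]
        Pc <- sm$phenotype - mean(sm$phenotype)
        aC <- sm$age - mean(sm$age)
        f <- oracleOls(cbind(1, aC, aC^2, Pc, g, g * Pc), y)
        hits <- hits + (abs(f$beta[6] - 0.03) <= 2 * f$se[6])
    }
    expect_gte(hits / nrep, 0.9)
})

test_that("latent factor scores correlate with the phenotype as configured", {
    ch <- cachedCohort("latent", simulationConfig(nMzPairs = 50L,
        nDzPairs = 50L, nUnrelated = 150L, nSnps = 50L, nGenes = 40L,
        nLatentFactors = 3L, latentPhenotypeCorr = c(0.5, 0.2, 0),
        seed = 7L))
    r <- cor(latentScores(ch), as.data.frame(sampleData(ch))$phenotype)
    expect_equal(r[1], 0.5, tolerance = 0.1)
    expect_lt(abs(r[3]), 0.15)
})

test_that("MZ pairs resemble each other more than DZ pairs in expression", {
    ch <- cachedCohort("herit", simulationConfig(nMzPairs = 200L,
        nDzPairs = 200L, nUnrelated = 0L, nSnps = 40L, nGenes = 20L,
        exonsPerGeneRange = c(1L, 1L), nLatentFactors = 0L,
        varFamily = 0.3, varZygosity = 0.3, noiseSd = 0.3, techSd = 0,
        seed = 17L))
    x <- SummarizedExperiment::assay(expressionData(ch))
    sm <- as.data.frame(sampleData(ch))
    mz <- which(sm$type == "MZ" | sm$sample_id %in%
                sm$sample_id[seq_len(400)])
    rMZ <- mean(vapply(seq_len(nrow(x)), function(i)
        cor(x[i, seq(1, 399, 2)], x[i, seq(2, 400, 2)]), 0))
    rDZ <- mean(vapply(seq_len(nrow(x)), function(i)
        cor(x[i, seq(401, 799, 2)], x[i, seq(402, 800, 2)]), 0))
    expect_gt(rMZ, rDZ)
    expect_gt(rMZ, 0.6)   # (0.3 + 0.3) / 0.69 shared for MZ
})

test_that("trans planting routes the interaction through the mediator as configured", {
    base <- function(frac, s) simulateCohort(simulationConfig(
        nMzPairs = 0L, nDzPairs = 0L, nUnrelated = 400L, nSnps = 30L,
        nGenes = 10L, exonsPerGeneRange = c(1L, 1L), nLatentFactors = 0L,
        varFamily = 0, varZygosity = 0, seed = s,
        effectGrid = rbind(
            plantedEffect("gxe_interaction", "G0002",
                          beta_interaction = 0.08),
            plantedEffect("trans_mediated", mediator_gene_id = "G0002",
                          n_trans_targets = 3L, beta_interaction = 0.1,
                          mediation_fraction = frac))))
    partials <- function(ch) {
        eff <- as.data.frame(plantedEffects(ch))
        tr <- eff[eff$kind == "trans_mediated", ]
        sm <- as.data.frame(sampleData(ch))
        x <- SummarizedExperiment::assay(expressionData(ch))
        gid <- S4Vectors::mcols(SummarizedExperiment::rowRanges(
            expressionData(ch)))$gene_id
        M <- colMeans(x[gid == "G0002", , drop = FALSE])
        S <- dosages(ch)[, tr$snp_id[1]] *
            (sm$phenotype - mean(sm$phenotype))
        vapply(tr$gene_id, function(tg) {
            y <- x[gid == tg, ]
            rY <- resid(lm(y ~ M)); rS <- resid(lm(S ~ M))
            cor(rY, rS)   # partial cor of target with SNPxP given mediator
        }, 0)
    }
    # full mediation: conditioning on the mediator removes the signal
    expect_lt(max(abs(partials(base(1, 31L)))), 0.12)
    # no mediation: the direct path survives conditioning
    expect_gt(min(abs(partials(base(0, 32L)))), 0.15)
    # invalid requests are rejected
    ch <- base(1, 33L)
    expect_error(plantTransNetwork(ch, "G0003", 2, 0.5),
                 "gxe_interaction")
    expect_error(plantTransNetwork(ch, "G0002", 2, 1.4), "\\[0, 1\\]")
})
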