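test_that("every interaction fit matches the normal-equations oracle", {
    # dual route: package QR/FWL path vs an independent closed-form
    # solve of the normal equations, on random small designs
    set.seed(70)
    for (rep in 1:200) {
        n <- sample(25:60, 1)
        md <- unrelatedMetadata(n, seed = 7000 + rep)
        g <- rbinom(n, 2, runif(1, 0.2, 0.5))
        if (var(g) == 0) next
        y <- rnorm(n)
        x <- matrix(y, 1, dimnames = list("e1", md$sample_id))
        se <- makeToySE(x, geneId = "G1", tss = 500)
        gm <- GenotypeMatrix(
            matrix(g, ncol = 1, dimnames = list(md$sample_id, "rs1")),
            data.frame(chrom = "chr1", pos = 600, ea = "A", oa = "G"))
        res <- suppressMessages(cisInteractionScan(se, gm, md,
                                                   minMaf = 0.01))
        aC <- md$age - mean(md$age)
        Pc <- md$phenotype - mean(md$phenotype)
        orc <- oracleOls(cbind(1, aC, aC^2, Pc, g, g * Pc), y)
        expect_equal(res$beta_interaction, orc$beta[6], tolerance = 1e-8)
        expect_equal(res$se_interaction, orc$se[6], tolerance = 1e-8)
        expect_equal(res$p_interaction, orc$p[6], tolerance = 1e-8)
        expect_equal(res$beta_snp, orc$beta[5], tolerance = 1e-8)
        expect_equal(res$beta_pheno, orc$beta[4], tolerance = 1e-8)
        # main-effect model (interaction dropped)
        orcM <- oracleOls(cbind(1, aC, aC^2, Pc, g), y)
        expect_equal(res$p_main, orcM$p[5], tolerance = 1e-8)
    }
})

test_that("the cis window is respected and monomorphic SNPs are skipped", {
    md <- unrelatedMetadata(40)
    x <- matrix(rnorm(40), 1, dimnames = list("e1", md$sample_id))
    se <- makeToySE(x, geneId = "G1", tss = 2e6)
    dos <- cbind(rs_in = rbinom(40, 2, 0.4),
                 rs_edge = rbinom(40, 2, 0.4),
                 rs_out = rbinom(40, 2, 0.4),
                 rs_mono = rep(0, 40))
    rownames(dos) <- md$sample_id
    gm <- GenotypeMatrix(dos, data.frame(chrom = "chr1",
        pos = c(2.5e6, 3e6, 3.5e6, 2.1e6), ea = "A", oa = "G"))
    expect_message(res <- cisInteractionScan(se, gm, md), "monomorphic")
    # SNP at TSS + 1.5 Mb is outside the 1 Mb window; boundary SNP is in
    expect_setequal(res$snp_id, c("rs_in", "rs_edge"))
})

test_that("scan results are invariant to SNP and sample order", {
    ch <- mediumCohort()
    sm <- as.data.frame(sampleData(ch))
    se <- expressionData(ch)[1:20, ]
    r1 <- suppressMessages(cisInteractionScan(se, genotypes(ch), sm))
    # shuffle SNP columns
    set.seed(71)
    o <- sample(ncol(dosages(ch)))
    g2 <- GenotypeMatrix(dosages(ch)[, o],
                         as.data.frame(snpInfo(ch))[o, ])
    r2 <- suppressMessages(cisInteractionScan(se, g2, sm))
    k <- paste(r1$meta_exon_id, r1$snp_id)
    r2 <- r2[match(k, paste(r2$meta_exon_id, r2$snp_id)), ]
    expect_equal(r1$p_interaction, r2$p_interaction, tolerance = 1e-12)
    # shuffle samples jointly
    so <- sample(nrow(sm))
    g3 <- GenotypeMatrix(dosages(ch)[so, ],
                         as.data.frame(snpInfo(ch)))
    r3 <- suppressMessages(cisInteractionScan(se[, so], g3, sm[so, ]))
    r3 <- r3[match(k, paste(r3$meta_exon_id, r3$snp_id)), ]
    expect_equal(r1$p_interaction, r3$p_interaction, tolerance = 1e-9)
})

test_that("sign-flipping interaction slopes are detected with high power", {
    # opposed slopes +/-0.05 per phenotype unit across homozygote
    # classes, i.e. an interaction coefficient of 0.05 per allele
    hits <- vapply(1:30, function(s) {
        ch <- simulateCohort(simulationConfig(nMzPairs = 120L,
            nDzPairs = 120L, nUnrelated = 220L, nSnps = 4L, nGenes = 2L,
            exonsPerGeneRange = c(1L, 1L), nLatentFactors = 0L,
            seed = 7100L + s,
            effectGrid = plantedEffect("gxe_interaction", "G0001",
                beta_pheno = 0.05, beta_interaction = -0.05)))
        eff <- as.data.frame(plantedEffects(ch))
        sm <- as.data.frame(sampleData(ch))
        fr <- familyResiduals(expressionData(ch), sm)
        res <- suppressMessages(cisInteractionScan(fr, genotypes(ch), sm))
        min(res$p_interaction[res$gene_id == "G0001" &
                              res$snp_id == eff$snp_id[1]]) < 1e-6
    }, TRUE)
    expect_gte(mean(hits), 0.8)
})

test_that("permutation FDR flags the planted interaction and nothing else", {
    ch <- mediumCohort()
    sm <- as.data.frame(sampleData(ch))
    se <- expressionData(ch)
    res <- suppressMessages(cisInteractionScan(se, genotypes(ch), sm))
    pf <- permutationFdr(res, se, genotypes(ch), sm, nPerm = 40,
                         seed = 4)
    eff <- as.data.frame(plantedEffects(ch))
    sig <- pf$results[pf$results$significant, ]
    expect_true(all(sig$gene_id == "G0005" & sig$snp_id == eff$snp_id[1]))
    expect_gte(nrow(sig), 1)
    # FDR annotated on every pair, in [0, 1], monotone within stratum
    expect_true(all(pf$results$fdr >= 0 & pf$results$fdr <= 1))
    for (s in unique(pf$results$stratum)) {
        sub <- pf$results[pf$results$stratum == s, ]
        o <- order(sub$p_interaction)
        expect_false(is.unsorted(sub$fdr[o]))
    }
    # observed p below every permuted p gives an FDR estimate of zero
    expect_equal(min(pf$results$fdr), 0)
    expect_error(permutationFdr(res, se, genotypes(ch), sm, nPerm = 10),
                 "at least 20")
})

test_that("permutation FDR is deterministic given a seed", {
    ch <- mediumCohort()
    sm <- as.data.frame(sampleData(ch))
    se <- expressionData(ch)[1:15, ]
    res <- suppressMessages(cisInteractionScan(se, genotypes(ch), sm))
    f1 <- permutationFdr(res, se, genotypes(ch), sm, nPerm = 25, seed = 9)
    f2 <- permutationFdr(res, se, genotypes(ch), sm, nPerm = 25, seed = 9)
    expect_identical(f1$results, f2$results)
})

test_that("null interaction p-values are uniform across a transcriptome-scale scan", {
    # exchangeable samples: the OLS scan must be exactly calibrated
    ch <- cachedCohort("null-ks", simulationConfig(nMzPairs = 0L,
        nDzPairs = 0L, nUnrelated = 700L, nSnps = 1000L,
        nGenes = 1000L, exonsPerGeneRange = c(1L, 20L),
        nLatentFactors = 0L, techSd = 0, seed = 77L))
    sm <- as.data.frame(sampleData(ch))
    fr <- residualize(familyResiduals(expressionData(ch), sm),
                      sm[, c("gc_content", "insert_mode")])
    res <- suppressMessages(cisInteractionScan(fr, genotypes(ch), sm))
    expect_gte(nrow(res), 10000)
    ks <- suppressWarnings(ks.test(res$p_interaction, "punif"))
    expect_gt(ks$p.value, 0.01)
})

test_that("family correction keeps the twin-cohort scan close to nominal", {
    # shrunken family-mean removal leaves the scan mildly conservative
    # (never anti-conservative); the decision rule on top of it is the
    # permutation FDR, which recalibrates empirically
    ch <- cachedCohort("null-ks-twin", simulationConfig(nMzPairs = 120L,
        nDzPairs = 120L, nUnrelated = 220L, nSnps = 1000L,
        nGenes = 1000L, exonsPerGeneRange = c(1L, 8L),
        nLatentFactors = 0L, techSd = 0, seed = 78L))
    sm <- as.data.frame(sampleData(ch))
    fr <- residualize(familyResiduals(expressionData(ch), sm),
                      sm[, c("gc_content", "insert_mode")])
    res <- suppressMessages(cisInteractionScan(fr, genotypes(ch), sm))
    frac <- mean(res$p_interaction < 0.05)
    expect_gt(frac, 0.035)
    expect_lt(frac, 0.060)
})

test_that("the trans scan applies the distance rule and the Bonferroni threshold", {
    ch <- mediumCohort()
    sm <- as.data.frame(sampleData(ch))
    se <- expressionData(ch)
    snp <- rownames(as.data.frame(snpInfo(ch)))[1]
    ts <- transInteractionScan(snp, se, genotypes(ch), sm)
    expect_equal(ts$threshold, 0.05 / (1 * nrow(se)))
    sp <- as.data.frame(snpInfo(ch))[snp, ]
    rr <- SummarizedExperiment::rowRanges(se)
    tested <- ts$results$meta_exon_id
    near <- names(rr)[as.character(GenomicRanges::seqnames(rr)) ==
                      sp$chrom &
                      abs(S4Vectors::mcols(rr)$tss - sp$pos) <= 5e6]
    expect_length(intersect(tested, near), 0)
    expect_setequal(tested, setdiff(names(rr), near))
    # empty seed list is a warned no-op
    expect_warning(e <- transInteractionScan(character(0), se,
                                             genotypes(ch), sm),
                   "no seed")
    expect_null(e$results)
})

test_that("a mediated trans network is recovered by the two-step scan", {
    ch <- cachedCohort("trans-net", simulateCohortArgsTrans())
    eff <- as.data.frame(plantedEffects(ch))
    med <- eff[eff$kind == "gxe_interaction", ]
    tr <- eff[eff$kind == "trans_mediated", ]
    sm <- as.data.frame(sampleData(ch))
    fr <- familyResiduals(expressionData(ch), sm)
    ts <- transInteractionScan(med$snp_id[1], fr, genotypes(ch), sm)
    sig <- ts$results[ts$results$significant, ]
    expect_gte(length(intersect(unique(sig$gene_id), tr$gene_id)),
               ceiling(0.5 * nrow(tr)))
})
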