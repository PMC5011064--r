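test_that("pi1 is near zero under the null and near one under saturated signal", {
    set.seed(90)
    expect_lte(estimatePi0Qvalues(runif(10000))$pi1, 0.02)
    expect_gte(estimatePi0Qvalues(rep(1e-9, 500))$pi1, 0.98)
    expect_error(estimatePi0Qvalues(c(runif(200), 1.2)), "\\[0, 1\\]")
    expect_error(estimatePi0Qvalues(runif(50)), "at least 100")
})

test_that("pi1 recovers a known alternative fraction in a mixture", {
    set.seed(91)
    est <- replicate(25, {
        p <- c(runif(7000), rbeta(3000, 0.08, 1))  # 30% alternatives
        estimatePi0Qvalues(p)$pi1
    })
    expect_lt(abs(mean(est) - 0.30), 0.05)
})

test_that("q-values are monotone and bounded", {
    set.seed(92)
    p <- c(runif(500), rbeta(200, 0.1, 1))
    qv <- estimatePi0Qvalues(p)
    expect_true(all(qv$qvalues >= 0 & qv$qvalues <= 1))
    o <- order(p)
    expect_false(is.unsorted(qv$qvalues[o]))
})

test_that("replication sharing is estimated from matched pairs", {
    set.seed(93)
    ids <- sprintf("e%04d:rs%04d", 1:2000, 1:2000)
    # no sharing: uniform replication p-values
    rep0 <- data.frame(id = ids, p = runif(2000))
    expect_lt(pi1Replication(ids, rep0)$pi1, 0.05)
    # complete sharing
    rep1 <- data.frame(id = ids, p = rbeta(2000, 0.05, 1))
    expect_gt(pi1Replication(ids, rep1)$pi1, 0.9)
    # half the effects shared
    repH <- data.frame(id = ids,
                       p = c(rbeta(1000, 0.05, 1), runif(1000)))
    piH <- pi1Replication(ids, repH)
    expect_lt(abs(piH$pi1 - 0.5), 0.1)
    expect_true(piH$stable)
    expect_warning(pi1Replication(ids[1:50], rep0), "unstable")
    expect_error(pi1Replication("nope", rep0), "no discovery pairs")
})

test_that("the mediation statistics match a hand-computed 12-sample example", {
    # normal-equations oracle computed independently of the package path
    set.seed(94)
    n <- 12
    age <- c(40, 45, 50, 55, 60, 65, 42, 47, 52, 57, 62, 67)
    P <- c(20, 24, 28, 22, 26, 30, 21, 25, 29, 23, 27, 31)
    G <- c(0, 1, 2, 0, 1, 2, 1, 0, 2, 1, 0, 2)
    E <- 0.4 * G + rnorm(n, 0, 0.3)
    y <- 0.3 * E + 0.02 * G * (P - mean(P)) + rnorm(n, 0, 0.2)
    res <- mediationTest(y, E, G, P, age)
    aC <- age - mean(age); Pc <- P - mean(P)
    X5 <- cbind(1, aC, aC^2, Pc, G, G * Pc)
    X6 <- cbind(1, E, aC, aC^2, Pc, G, G * Pc)
    o5 <- oracleOls(X5, y); o6 <- oracleOls(X6, y)
    b5 <- o5$beta[6]; s5 <- o5$se[6]
    b6 <- o6$beta[7]; s6 <- o6$se[7]
    expect_equal(res$beta_m5, b5, tolerance = 1e-10)
    expect_equal(res$se_m5, s5, tolerance = 1e-10)
    expect_equal(res$beta_m6, b6, tolerance = 1e-10)
    expect_equal(res$mediation_score, (b5 - b6) / b5, tolerance = 1e-10)
    om <- oracleOls(X5, E)           # indirect path: interaction -> E
    a <- om$beta[6]; sa <- om$se[6]
    b <- o6$beta[2]; sb <- o6$se[2]  # and E -> target
    zOracle <- (a * b) / sqrt(b^2 * sa^2 + a^2 * sb^2)
    expect_equal(res$sobel_z, zOracle, tolerance = 1e-10)
    expect_equal(res$p, 2 * pnorm(-abs(zOracle)), tolerance = 1e-10)
})

test_that("mediation score and Sobel Z are pure algebra on fitted coefficients", {
    # property over random small designs
    set.seed(95)
    for (rep in 1:1000) {
        n <- sample(12:30, 1)
        age <- runif(n, 38, 84); P <- rnorm(n, 25, 4)
        G <- rbinom(n, 2, 0.4); E <- rnorm(n); y <- rnorm(n)
        if (var(G) == 0 || qr(cbind(1, G, G * P))$rank < 3) next
        res <- mediationTest(y, E, G, P, age)
        expect_equal(res$mediation_score,
                     (res$beta_m5 - res$beta_m6) / res$beta_m5,
                     tolerance = 1e-12)
        expect_equal(res$sobel_z,
                     res$path_a * res$path_b /
                         sqrt(res$path_b^2 * res$se_a^2 +
                              res$path_a^2 * res$se_b^2),
                     tolerance = 1e-12)
        expect_true(is.finite(res$sobel_z))
    }
})

test_that("no mediation leaves the interaction coefficient unchanged", {
    set.seed(96)
    zs <- scores <- numeric(60)
    for (r in 1:60) {
        n <- 300
        age <- runif(n, 38, 84); P <- rnorm(n, 25, 4)
        G <- rbinom(n, 2, 0.3)
        E <- rnorm(n)                       # mediator unrelated to y
        y <- 0.05 * G * (P - mean(P)) + rnorm(n, 0, 0.5)
        m <- mediationTest(y, E, G, P, age)
        zs[r] <- m$sobel_z; scores[r] <- m$mediation_score
    }
    expect_lt(median(abs(zs)), 1)
    expect_lt(abs(median(scores)), 0.1)
})

test_that("full mediation is detected with a high mediation score", {
    set.seed(97)
    res <- replicate(40, {
        n <- 700
        age <- runif(n, 38, 84); P <- rnorm(n, 25, 4)
        G <- rbinom(n, 2, 0.3)
        E <- 0.3 * G + 0.04 * G * (P - mean(P)) + rnorm(n, 0, 0.3)
        y <- 1.5 * E + rnorm(n, 0, 0.3)     # all signal through E
        m <- mediationTest(y, E, G, P, age)
        c(m$mediation_score, m$p)
    })
    expect_gte(median(res[1, ]), 0.9)
    expect_gte(mean(res[2, ] <= 0.001), 0.9)
})

test_that("the RTC score is determined by the GWAS SNP rank", {
    set.seed(98)
    n <- 300; m <- 15
    dos <- matrix(rbinom(n * m, 2, 0.4), n, m,
                  dimnames = list(sprintf("s%03d", 1:n),
                                  sprintf("rs%02d", 1:m)))
    # a perfect proxy of the eQTL SNP: conditioning on it abrogates
    # everything; only the eQTL SNP itself (earlier position, tie
    # broken ascending) can outrank it
    dos[, "rs02"] <- dos[, "rs01"]
    P <- rnorm(n, 25, 4)
    y <- 0.08 * dos[, "rs01"] * (P - mean(P)) + rnorm(n, 0, 0.4)
    gm <- GenotypeMatrix(dos, data.frame(chrom = "chr1",
        pos = seq(100, by = 100, length.out = m), ea = "A", oa = "G"))
    rt <- rtcScore(y, P, gm, eqtlSnpId = "rs01", gwasSnpId = "rs02")
    expect_equal(rt$rank, 2L)
    expect_equal(rt$rtc, (m - 2) / m)
    # formula endpoint: the maximally abrogating SNP has rank 1 and
    # RTC = (N - 1)/N
    rtSelf <- rtcScore(y, P, gm, eqtlSnpId = "rs01", gwasSnpId = "rs01")
    expect_equal(rtSelf$rank, 1L)
    expect_equal(rtSelf$rtc, (m - 1) / m)
    # rank N endpoint: RTC = 0 for the least-abrogating SNP
    worst <- rt$conditional$snp_id[rt$conditional$rank == m]
    rtW <- rtcScore(y, P, gm, eqtlSnpId = "rs01", gwasSnpId = worst)
    expect_equal(rtW$rtc, 0)
    # invariance to shuffling non-GWAS SNP order
    o <- c(1, 2, sample(3:m))
    gm2 <- GenotypeMatrix(dos[, o], data.frame(chrom = "chr1",
        pos = seq(100, by = 100, length.out = m)[o], ea = "A", oa = "G"))
    rt2 <- rtcScore(y, P, gm2, eqtlSnpId = "rs01", gwasSnpId = "rs02")
    expect_equal(rt2$rtc, rt$rtc)
    expect_error(rtcScore(y, P, gm, "rs01", "rs99"), "absent")
    expect_error(rtcScore(y, P, GenotypeMatrix(dos[, 1:5],
        data.frame(chrom = "chr1", pos = 1:5, ea = "A", oa = "G")),
        "rs01", "rs02"), "at least 10")
})

test_that("RTC separates colocalized from independent signals under LD", {
    # AR(1) LD blocks; colocalized = GWAS SNP in tight LD with the
    # causal interaction variant, independent = a distant block SNP
    rtcs <- sapply(1:12, function(s) {
        ch <- simulateCohort(simulationConfig(nMzPairs = 0L,
            nDzPairs = 0L, nUnrelated = 400L, nSnps = 150L,
            nGenes = 3L, exonsPerGeneRange = c(1L, 1L), ldRho = 0.97,
            mafRange = c(0.2, 0.4),
            nLatentFactors = 0L, varFamily = 0, varZygosity = 0,
            seed = 9800L + s,
            effectGrid = plantedEffect("gxe_interaction", "G0001",
                                       beta_interaction = 0.08)))
        sm <- as.data.frame(sampleData(ch))
        eff <- as.data.frame(plantedEffects(ch))
        sn <- as.data.frame(snpInfo(ch))
        d <- dosages(ch)
        ci <- match(eff$snp_id[1], rownames(sn))
        win <- which(sn$chrom == sn$chrom[ci])
        r2 <- as.numeric(cor(d[, win], d[, ci]))^2
        names(r2) <- rownames(sn)[win]
        r2[eff$snp_id[1]] <- 0
        proxy <- names(which.max(r2))
        if (max(r2) < 0.9) return(c(NA, NA))
        far <- names(which.min(abs(r2 - median(r2[r2 < 0.2]))))
        gm <- GenotypeMatrix(d[, win], sn[win, ])
        x <- SummarizedExperiment::assay(expressionData(ch))
        gid <- S4Vectors::mcols(SummarizedExperiment::rowRanges(
            expressionData(ch)))$gene_id
        y <- x[which(gid == "G0001")[1], ]
        c(rtcScore(y, sm$phenotype, gm, eff$snp_id[1], proxy)$rtc,
          rtcScore(y, sm$phenotype, gm, eff$snp_id[1], far)$rtc)
    })
    expect_gte(median(rtcs[1, ], na.rm = TRUE), 0.9)
    expect_lt(median(rtcs[2, ], na.rm = TRUE), 0.85)
})

test_that("meta-exon matching classifies by reciprocal overlap", {
    mk <- function(s, e, g = "G1") {
        gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(s, e),
                                     gene_id = g)
        names(gr) <- sprintf("%s_E%d", g, seq_along(gr))
        gr
    }
    # identical intervals: matched with fractions 1, 1
    m1 <- matchMetaExons(mk(1, 100), mk(1, 100))
    expect_identical(m1$class, "matched")
    expect_equal(c(m1$frac_a, m1$frac_b), c(1, 1))
    # one-third containment: partial (0.33 vs 1.0)
    m2 <- matchMetaExons(mk(1, 100), mk(1, 33))
    expect_identical(m2$class, "partial")
    expect_equal(m2$frac_a, 0.33, tolerance = 0.01)
    expect_equal(m2$frac_b, 1.0)
    # disjoint: unmatched with zero overlap
    m3 <- matchMetaExons(mk(1, 100), mk(200, 300))
    expect_identical(m3$class, "unmatched")
    expect_equal(m3$frac_a, 0)
    # reciprocal threshold is strict
    m4 <- matchMetaExons(mk(1, 100), mk(1, 90))
    expect_identical(m4$class, "partial")
    m5 <- matchMetaExons(mk(1, 100), mk(1, 95))
    expect_identical(m5$class, "matched")
    # same position but different gene: no cross-gene matching
    m6 <- matchMetaExons(mk(1, 100, "G1"), mk(1, 100, "G2"))
    expect_identical(m6$class, "unmatched")
})
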