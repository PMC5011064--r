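#' @importFrom stats rbinom rnorm runif rnbinom qnorm median sd cor
#' @importFrom GenomicRanges GRanges seqnames start end strand
#' @importFrom IRanges IRanges
NULL

# ---- internal: deterministic genome layout -------------------------------

# Genes are laid out round-robin over a small set of chromosomes at 2.5 Mb
# spacing so that cis windows (1 Mb) are gene-specific while the 5 Mb trans
# exclusion still bites for near neighbours. Consumes RNG; callers seed.
.genomeLayout <- function(config) {
    nG <- config@nGenes
    nChrom <- min(22L, max(2L, ceiling(nG / 25)))
    chrom <- paste0("chr", ((seq_len(nG) - 1L) %% nChrom) + 1L)
    slot <- ((seq_len(nG) - 1L) %/% nChrom)
    tss <- 1e6 + slot * 2.5e6
    strand <- sample(c("+", "-"), nG, replace = TRUE)
    genes <- data.frame(gene_id = sprintf("G%04d", seq_len(nG)),
                        chrom = chrom, strand = strand, tss = tss)

    nE <- sample(seq(config@exonsPerGeneRange[1], config@exonsPerGeneRange[2]),
                 nG, replace = TRUE)
    recs <- vector("list", nG)
    for (g in seq_len(nG)) {
        k <- nE[g]
        st <- tss[g] + (seq_len(k) - 1L) * 1500L
        wd <- sample(100:400, k, replace = TRUE)
        s <- st; e <- st + wd - 1L
        # occasionally emit an extra overlapping record so that meta-exon
        # merging is exercised by every simulated annotation
        dup <- runif(k) < 0.3
        if (any(dup)) {
            s <- c(s, st[dup] + 40L)
            e <- c(e, st[dup] + wd[dup] + 60L)
        }
        recs[[g]] <- data.frame(gene_id = genes$gene_id[g],
                                chrom = chrom[g], start = s, end = e,
                                strand = strand[g])
    }
    recs <- do.call(rbind, recs)
    exons <- GRanges(recs$chrom, IRanges(recs$start, recs$end),
                     strand = recs$strand, gene_id = recs$gene_id)

    nS <- config@nSnps
    sgene <- c(seq_len(min(nG, nS)),
               if (nS > nG) sample(nG, nS - nG, replace = TRUE))
    pos <- pmax(1, tss[sgene] + round(runif(nS, -4.9e5, 4.9e5)))
    snps <- data.frame(snp_id = sprintf("rs%06d", seq_len(nS)),
                       chrom = chrom[sgene], pos = pos,
                       gene_id = genes$gene_id[sgene])
    snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]
    # deduplicate colliding positions deterministically
    dup <- duplicated(paste(snps$chrom, snps$pos))
    while (any(dup)) {
        snps$pos[dup] <- snps$pos[dup] + 1L
        dup <- duplicated(paste(snps$chrom, snps$pos))
    }
    rownames(snps) <- NULL
    list(genes = genes, exons = exons, snps = snps)
}

# ---- internal: twin-pair sample structure --------------------------------

.sampleStructure <- function(config) {
    nMZ <- config@nMzPairs; nDZ <- config@nDzPairs; nU <- config@nUnrelated
    n <- 2L * (nMZ + nDZ) + nU
    unit <- c(rep(seq_len(nMZ), each = 2L),
              rep(nMZ + seq_len(nDZ), each = 2L),
              nMZ + nDZ + seq_len(nU))
    type <- c(rep("MZ", 2L * nMZ), rep("DZ", 2L * nDZ), rep("U", nU))
    family <- sprintf("F%04d", unit)
    # MZ co-twins share the zygosity code; everyone else gets their own
    zyg <- integer(n)
    zyg[type == "MZ"] <- unit[type == "MZ"]
    zyg[type != "MZ"] <- max(unit) + seq_len(sum(type != "MZ"))
    data.frame(sample_id = sprintf("S%04d", seq_len(n)),
               family = family, zygosity = sprintf("Z%04d", zyg),
               unit = unit, type = type, stringsAsFactors = FALSE)
}

# ---- internal: haplotypes with optional AR(1) LD -------------------------

# AR(1) haplotype blocks by allele copying: with probability rho the
# allele at locus j is copied from locus j-1 on the same haplotype,
# otherwise drawn fresh at the locus MAF, so the correlation between
# loci k apart is rho^k and tight proxies (r^2 > 0.9) exist as they do
# in real haplotype blocks. Chains restart at chromosome boundaries.
# Copying lets the realized MAF drift toward the block average; the
# container records empirical frequencies.
.haplotypes <- function(nHap, mafs, rho, chrom) {
    m <- length(mafs)
    if (rho == 0)
        return(matrix(rbinom(nHap * m, 1L, rep(mafs, each = nHap)),
                      nrow = nHap, ncol = m))
    x <- matrix(0L, nHap, m)
    newChrom <- c(TRUE, chrom[-1] != chrom[-m])
    for (j in seq_len(m)) {
        fresh <- rbinom(nHap, 1L, mafs[j])
        if (newChrom[j]) x[, j] <- fresh
        else {
            copy <- runif(nHap) < rho
            x[, j] <- ifelse(copy, x[, j - 1L], fresh)
        }
    }
    x
}

.simulateGenotypesImpl <- function(config) {
    validObject(config)
    set.seed(config@seed)
    layout <- .genomeLayout(config)
    struct <- .sampleStructure(config)
    n <- nrow(struct); m <- config@nSnps
    mafs <- runif(m, config@mafRange[1], config@mafRange[2])
    rho <- config@ldRho
    chrom <- layout$snps$chrom

    dos <- matrix(0L, n, m)
    i <- 1L
    for (u in unique(struct$unit)) {
        idx <- which(struct$unit == u)
        ty <- struct$type[idx[1]]
        if (ty == "MZ") {
            h <- .haplotypes(2L, mafs, rho, chrom)
            g <- h[1, ] + h[2, ]
            dos[idx[1], ] <- g; dos[idx[2], ] <- g
        } else if (ty == "DZ") {
            par <- .haplotypes(4L, mafs, rho, chrom)  # m1 m2 f1 f2
            for (child in idx) {
                if (rho == 0) {
                    cm <- rbinom(m, 1L, 0.5); cf <- rbinom(m, 1L, 0.5)
                    dos[child, ] <- par[1, ] * (1L - cm) + par[2, ] * cm +
                        par[3, ] * (1L - cf) + par[4, ] * cf
                } else {
                    dos[child, ] <- par[sample(1:2, 1L), ] +
                        par[sample(3:4, 1L), ]
                }
            }
        } else {
            h <- .haplotypes(2L, mafs, rho, chrom)
            dos[idx, ] <- h[1, ] + h[2, ]
        }
        i <- i + 1L
    }
    storage.mode(dos) <- "double"
    dimnames(dos) <- list(struct$sample_id, layout$snps$snp_id)

    alle <- matrix(c("A", "G", "C", "T", "T", "C", "G", "A"), ncol = 2)
    pick <- sample(4L, m, replace = TRUE)
    snps <- S4Vectors::DataFrame(chrom = layout$snps$chrom,
        pos = layout$snps$pos, ea = alle[pick, 1], oa = alle[pick, 2],
        gene_id = layout$snps$gene_id)
    geno <- GenotypeMatrix(dos, snps)
    list(geno = geno, layout = layout, struct = struct)
}

#' Simulate twin-structured genotypes
#'
#' Draws biallelic haplotypes at the configured minor allele frequencies
#' (optionally with AR(1) linkage disequilibrium along each chromosome)
#' and assembles dosages respecting the twin structure: monozygotic
#' co-twins receive identical genotype vectors; dizygotic co-twins are
#' formed by Mendelian sampling from four simulated parental haplotypes,
#' giving an expected within-pair dosage correlation of one half.
#'
#' @param config A \linkS4class{SimulationConfig}.
#' @return A \linkS4class{GenotypeMatrix} with empirical MAFs.
#' @examples
#' g <- simulateGenotypes(simulationConfig(nMzPairs = 2, nDzPairs = 2,
#'     nUnrelated = 2, nSnps = 20, nGenes = 5, seed = 7))
#' dim(dosages(g))
#' @export
simulateGenotypes <- function(config) .simulateGenotypesImpl(config)$geno

# ---- cohort simulation ---------------------------------------------------

#' Simulate a complete twin cohort with planted effects
#'
#' Generates genotypes, a heritable continuous phenotype on a BMI-like
#' scale, technical covariates, latent confounders correlated with the
#' phenotype at configured levels, and exon-level expression carrying the
#' planted effects of \code{config@effectGrid}. Expression for meta-exon
#' \eqn{e} of gene \eqn{g} is
#' \deqn{y_e = b_A A_c + b_{A^2} A_c^2 + \beta_P P_c + \beta_{SNP} G +
#'   \beta_{P \times SNP} G P_c + \Lambda_e F + u_{fam} + u_{zyg} +
#'   tech_e + \epsilon_e,}
#' the same generative form the downstream interaction model fits.
#' Co-twins share age; monozygotic pairs additionally share the zygosity
#' random intercept and their genotypes.
#'
#' @param config A \linkS4class{SimulationConfig}.
#' @return A \linkS4class{TwinCohort}; its \code{\link{truthTable}}
#'   records every realized planted effect and the latent factor scores.
#' @examples
#' cfg <- simulationConfig(nMzPairs = 5, nDzPairs = 5, nUnrelated = 10,
#'     nSnps = 40, nGenes = 8, seed = 3,
#'     effectGrid = plantedEffect("gxe_interaction", "G0002",
#'                                beta_interaction = 0.05))
#' ch <- simulateCohort(cfg)
#' plantedEffects(ch)
#' @export
simulateCohort <- function(config) {
    sim <- .simulateGenotypesImpl(config)  # seeds RNG; stream continues
    struct <- sim$struct; layout <- sim$layout
    n <- nrow(struct)
    dos <- dosages(sim$geno)

    # ages shared within a twin pair
    ageUnit <- runif(max(struct$unit), config@ageRange[1], config@ageRange[2])
    age <- ageUnit[struct$unit]
    ageC <- age - mean(age)

    # heritable phenotype: additive genetic score shared fully within MZ,
    # half within DZ pairs
    h2 <- config@phenotypeHeritability
    nUnit <- max(struct$unit)
    shared <- rnorm(nUnit)
    A <- numeric(n)
    for (u in unique(struct$unit)) {
        idx <- which(struct$unit == u); ty <- struct$type[idx[1]]
        A[idx] <- switch(ty,
            MZ = shared[u],
            DZ = sqrt(0.5) * shared[u] + sqrt(0.5) * rnorm(length(idx)),
            U  = rnorm(1))
    }
    P <- config@phenotypeMean +
        config@phenotypeSd * (sqrt(h2) * A + sqrt(1 - h2) * rnorm(n))
    Pc <- P - mean(P)

    gc <- rnorm(n, 0.47, 0.015)
    insert <- round(rnorm(n, 280, 15))
    primer <- sprintf("P%02d", sample(12L, n, replace = TRUE))
    batch <- sprintf("B%d", sample(3L, n, replace = TRUE))

    samples <- S4Vectors::DataFrame(sample_id = struct$sample_id,
        phenotype = P, age = age, family = struct$family,
        zygosity = struct$zygosity, gc_content = gc,
        insert_mode = insert, primer_index = primer, batch = batch)

    # latent confounders
    k <- config@nLatentFactors
    if (k > 0) {
        Ps <- as.numeric(scale(P))
        FS <- vapply(seq_len(k), function(j) {
            r <- config@latentPhenotypeCorr[j]
            r * Ps + sqrt(1 - r^2) * rnorm(n)
        }, numeric(n))
        colnames(FS) <- sprintf("LF%d", seq_len(k))
    } else FS <- matrix(0, n, 0)

    metaExons <- mergeMetaExons(layout$exons)
    nf <- length(metaExons)
    exonGene <- S4Vectors::mcols(metaExons)$gene_id
    geneIds <- layout$genes$gene_id

    # resolve the effect grid against the realized layout
    eff <- .resolveEffects(config@effectGrid, layout, sim$geno)
    cis <- eff[eff$kind %in% c("main_eqtl", "gxe_interaction"), , drop = FALSE]

    # gene-level signal shared by all meta-exons of a gene
    famLev <- unique(struct$family); zygLev <- unique(struct$zygosity)
    famIdx <- match(struct$family, famLev)
    zygIdx <- match(struct$zygosity, zygLev)
    geneSig <- matrix(0, length(geneIds), n,
                      dimnames = list(geneIds, struct$sample_id))
    bAge <- rnorm(length(geneIds), 0, 0.004)
    bAge2 <- rnorm(length(geneIds), 0, 2e-4)
    sdF <- sqrt(config@varFamily); sdZ <- sqrt(config@varZygosity)
    uF <- matrix(rnorm(length(geneIds) * length(famLev), 0, sdF),
                 length(geneIds))
    uZ <- matrix(rnorm(length(geneIds) * length(zygLev), 0, sdZ),
                 length(geneIds))
    geneSig <- outer(bAge, ageC) + outer(bAge2, ageC^2) +
        uF[, famIdx, drop = FALSE] + uZ[, zygIdx, drop = FALSE]
    if (nrow(cis)) for (i in seq_len(nrow(cis))) {
        gi <- match(cis$gene_id[i], geneIds)
        g <- dos[, cis$snp_id[i]]
        geneSig[gi, ] <- geneSig[gi, ] + cis$beta_pheno[i] * Pc +
            cis$beta_snp[i] * g + cis$beta_interaction[i] * g * Pc
    }

    # per-exon layers: latent loadings, technical effects, noise
    expr <- geneSig[match(exonGene, geneIds), , drop = FALSE]
    if (k > 0) {
        L <- matrix(rnorm(nf * k), nf, k) *
            rep(config@latentFactorSd, each = nf) *
            matrix(rbinom(nf * k, 1L, config@latentLoadingDensity), nf, k)
        expr <- expr + L %*% t(FS)
    }
    gcS <- as.numeric(scale(gc)); insS <- as.numeric(scale(insert))
    tS <- config@techSd
    expr <- expr + outer(rnorm(nf, 0, tS), gcS) +
        outer(rnorm(nf, 0, tS), insS)
    primLev <- unique(primer); batchLev <- unique(batch)
    expr <- expr +
        matrix(rnorm(nf * length(primLev), 0, tS), nf)[, match(primer, primLev)] +
        matrix(rnorm(nf * length(batchLev), 0, tS), nf)[, match(batch, batchLev)]
    expr <- expr + matrix(rnorm(nf * n, 0, config@noiseSd), nf, n)
    dimnames(expr) <- list(names(metaExons), struct$sample_id)

    state <- "filtered"
    if (config@countLayer) {
        depth <- round(runif(n, 1.5e7, 4.5e7))
        baseLog <- rnorm(nf, log(500), 0.7)
        mu <- exp(baseLog + 0.5 * expr) %*% diag(depth / median(depth))
        expr <- matrix(rnbinom(nf * n, size = 20, mu = mu), nf, n,
                       dimnames = dimnames(expr))
        samples$well_mapped_reads <- depth
        state <- "raw"
    }

    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(expr = expr), rowRanges = metaExons,
        colData = S4Vectors::DataFrame(row.names = struct$sample_id))
    S4Vectors::metadata(se)$state <- state
    S4Vectors::metadata(se)$seed <- config@seed

    truth <- new("TruthTable",
        effects = as(cis, "DataFrame"), latentScores = FS)
    cohort <- new("TwinCohort", genotypes = sim$geno, expression = se,
                  samples = samples, truth = truth)

    trans <- eff[eff$kind == "trans_mediated", , drop = FALSE]
    if (nrow(trans)) for (i in seq_len(nrow(trans)))
        cohort <- .plantTrans(cohort, trans$mediator_gene_id[i],
            trans$n_trans_targets[i], trans$mediation_fraction[i],
            trans$beta_interaction[i])
    cohort
}

# validate planted-effect references and fill in NA SNPs with the cis SNP
# nearest the gene's TSS
.resolveEffects <- function(grid, layout, geno) {
    grid <- as.data.frame(grid)
    if (!nrow(grid)) return(grid)
    genes <- layout$genes; snps <- snpInfo(geno)
    for (i in seq_len(nrow(grid))) {
        if (grid$kind[i] == "trans_mediated") {
            if (!grid$mediator_gene_id[i] %in% genes$gene_id)
                stop("unknown mediator gene: ", grid$mediator_gene_id[i])
            next
        }
        gid <- grid$gene_id[i]
        if (!gid %in% genes$gene_id) stop("unknown gene id: ", gid)
        if (is.na(grid$snp_id[i])) {
            gi <- match(gid, genes$gene_id)
            cand <- which(snps$chrom == genes$chrom[gi] &
                          abs(snps$pos - genes$tss[gi]) <= 1e6)
            if (!length(cand))
                stop("no cis SNP within 1 Mb of ", gid, " to plant on")
            grid$snp_id[i] <- rownames(snps)[
                cand[which.min(abs(snps$pos[cand] - genes$tss[gi]))]]
        } else if (!grid$snp_id[i] %in% rownames(snps)) {
            stop("unknown SNP id: ", grid$snp_id[i])
        }
    }
    cis <- grid[grid$kind != "trans_mediated", , drop = FALSE]
    if (anyDuplicated(cis$gene_id))
        stop("conflicting planted cis effects on one gene")
    grid
}

# core trans-network planting, shared by simulateCohort and
# plantTransNetwork
.plantTrans <- function(cohort, mediatorGene, nTargets, mediationFraction,
                        betaInteraction = 0.08) {
    if (mediationFraction < 0 || mediationFraction > 1)
        stop("mediation_fraction must lie in [0, 1]")
    truth <- cohort@truth
    eff <- as.data.frame(truth@effects)
    med <- eff[eff$kind == "gxe_interaction" &
               eff$gene_id == mediatorGene, , drop = FALSE]
    if (!nrow(med))
        stop("mediator gene must carry a planted gxe_interaction: ",
             mediatorGene)
    if (mediationFraction > 0 && med$beta_interaction[1] == 0)
        stop("mediator interaction coefficient is zero; nothing to transmit")
    se <- cohort@expression
    if (expressionState(se) == "raw")
        stop("plantTransNetwork requires the continuous expression layer")
    expr <- .exprAssay(se)
    exonGene <- S4Vectors::mcols(SummarizedExperiment::rowRanges(se))$gene_id
    g <- dosages(cohort)[, med$snp_id[1]]
    P <- cohort@samples$phenotype
    S <- g * (P - mean(P))
    M <- colMeans(expr[exonGene == mediatorGene, , drop = FALSE])
    M <- M - mean(M)

    snps <- snpInfo(cohort)
    spos <- snps[med$snp_id[1], ]
    rr <- SummarizedExperiment::rowRanges(se)
    geneTab <- unique(data.frame(gene_id = exonGene,
        chrom = as.character(seqnames(rr)),
        tss = S4Vectors::mcols(rr)$tss))
    geneTab <- geneTab[!duplicated(geneTab$gene_id), ]
    farEnough <- geneTab$chrom != spos$chrom |
        abs(geneTab$tss - spos$pos) > 5e6
    used <- unique(c(eff$gene_id, mediatorGene))
    elig <- geneTab$gene_id[farEnough & !geneTab$gene_id %in% used]
    if (length(elig) < nTargets)
        stop("only ", length(elig), " eligible trans target genes for ",
             nTargets, " requested")
    targets <- sample(elig, nTargets)
    signs <- sample(c(-1, 1), nTargets, replace = TRUE)

    frac <- mediationFraction
    for (j in seq_along(targets)) {
        bt <- signs[j] * betaInteraction
        cM <- if (frac > 0) frac * bt / med$beta_interaction[1] else 0
        delta <- cM * M + (1 - frac) * bt * S
        rows <- exonGene == targets[j]
        expr[rows, ] <- sweep(expr[rows, , drop = FALSE], 2, delta, "+")
        eff <- rbind(eff, plantedEffect("trans_mediated",
            gene_id = targets[j], snp_id = med$snp_id[1],
            beta_interaction = bt, mediator_gene_id = mediatorGene,
            n_trans_targets = nTargets,
            mediation_fraction = frac))
    }
    SummarizedExperiment::assay(se, "expr") <- expr
    cohort@expression <- se
    cohort@truth <- new("TruthTable", effects = as(eff, "DataFrame"),
                        latentScores = truth@latentScores)
    cohort
}

#' Plant a cis-mediated trans network into a simulated cohort
#'
#' Adds a genotype-by-phenotype interaction signal to \code{nTargets}
#' distal genes (different chromosome or more than 5 Mb from the mediator
#' SNP). A fraction \code{mediationFraction} of each target's interaction
#' signal is transmitted through the mediator gene's realized expression
#' (so that conditioning on the mediator abrogates it), and the remainder
#' is wired directly to the SNP-by-phenotype product.
#'
#' @param cohort A simulated \linkS4class{TwinCohort}.
#' @param mediatorGene gene id carrying a planted \code{gxe_interaction}.
#' @param nTargets number of trans target genes.
#' @param mediationFraction fraction in [0, 1] routed through the mediator.
#' @param betaInteraction total interaction amplitude per target
#'   (expression SD per allele x phenotype unit); sign randomized per
#'   target.
#' @param seed optional integer; defaults to the cohort seed plus a fixed
#'   offset.
#' @return The updated cohort; new \code{trans_mediated} rows appear in
#'   \code{\link{truthTable}}.
#' @export
plantTransNetwork <- function(cohort, mediatorGene, nTargets,
        mediationFraction, betaInteraction = 0.08, seed = NULL) {
    if (is.null(seed)) {
        base <- S4Vectors::metadata(cohort@expression)$seed
        seed <- (if (is.null(base)) 0L else base) + 104729L
    }
    set.seed(seed)
    .plantTrans(cohort, mediatorGene, nTargets, mediationFraction,
                betaInteraction)
}
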