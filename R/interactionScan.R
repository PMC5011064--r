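#' @importFrom stats quantile
NULL

# shared covariate block for Model-2 style scans
.interactionPre <- function(ageC, Pc) {
    Z <- cbind(1, ageC, ageC^2, Pc)
    qz <- qr(Z)
    list(Q = qr.Q(qz), R = qr.R(qz), n = length(ageC))
}

# align expression / genotype / metadata sample sets (lexicographic order)
.alignSamples <- function(se, geno, metadata) {
    ids <- sort(Reduce(intersect, list(colnames(se),
        rownames(dosages(geno)), as.data.frame(metadata)$sample_id)))
    if (length(ids) < 20)
        stop("fewer than 20 samples shared across expression, genotypes ",
             "and metadata")
    md <- as.data.frame(metadata)
    list(se = se[, ids],
         dos = dosages(geno)[ids, , drop = FALSE],
         snps = snpInfo(geno),
         md = md[match(ids, md$sample_id), , drop = FALSE])
}

#' Cis genotype-by-phenotype interaction scan
#'
#' For every meta-exon, tests each SNP within \code{windowBp} of the
#' meta-exon's transcription start site under the interaction model
#' \deqn{y \sim I + \beta_A A + \beta_{A^2} A^2 + \beta_P P +
#'   \beta_{SNP} G + \beta_{P \times SNP} G P + \epsilon,}
#' reporting a Wald t-test on the interaction coefficient (equivalent to
#' the one-degree-of-freedom F test). The same pair is also fitted
#' without the interaction term to give the main-effect eQTL p-value.
#'
#' Expression is expected as residuals from the chosen correction
#' pipeline (family/technical, with or without latent factors); age and
#' phenotype are nevertheless included as covariates, matching the model
#' as specified.
#'
#' @param se expression \code{SummarizedExperiment} (residualized, or
#'   inverse-normal transformed).
#' @param geno A \linkS4class{GenotypeMatrix}.
#' @param metadata per-sample table with \code{sample_id}, the phenotype
#'   column and \code{age}.
#' @param phenotype phenotype column name.
#' @param windowBp cis window around the TSS (default 1 Mb).
#' @param minMaf SNPs below this MAF in the analyzed samples are skipped
#'   (default 0.05).
#' @return data.frame with one row per tested (meta-exon, SNP) pair:
#'   coefficients, SEs, \code{p_interaction} and \code{p_main}.
#'   Monomorphic SNPs and exons without cis SNPs are logged and skipped.
#' @export
cisInteractionScan <- function(se, geno, metadata,
        phenotype = "phenotype", windowBp = 1e6, minMaf = 0.05) {
    if (!expressionState(se) %in%
        c("residualized", "int_transformed", "filtered"))
        stop("expression must be transformed/residualized before scanning")
    al <- .alignSamples(se, geno, metadata)
    dp <- .designPieces(al$md, phenotype)
    pre <- .interactionPre(dp$ageC, dp$Pc)
    x <- .exprAssay(al$se)
    rr <- SummarizedExperiment::rowRanges(al$se)
    tss <- S4Vectors::mcols(rr)$tss
    chrom <- as.character(seqnames(rr))
    geneId <- S4Vectors::mcols(rr)$gene_id
    snps <- al$snps
    af <- colMeans(al$dos) / 2
    mafOk <- pmin(af, 1 - af) >= minMaf
    nSkipMono <- sum(!mafOk)
    if (nSkipMono)
        message("cisInteractionScan: skipping ", nSkipMono,
                " SNPs monomorphic/rare in the analyzed samples")

    # SNPs are position-sorted, so each exon's cis set is a contiguous
    # run; exons sharing a run (typically all exons of a gene) are
    # solved in one batched call
    snpChrom <- as.character(snps$chrom)
    snpPos <- snps$pos
    cisSets <- vector("list", nrow(x))
    keys <- character(nrow(x))
    for (i in seq_len(nrow(x))) {
        cis <- which(snpChrom == chrom[i] &
                     abs(snpPos - tss[i]) <= windowBp & mafOk)
        cisSets[[i]] <- cis
        keys[i] <- if (length(cis))
            sprintf("%s:%d-%d", chrom[i], cis[1], cis[length(cis)])
            else ""
    }
    nEmpty <- sum(keys == "")
    if (nEmpty)
        message("cisInteractionScan: ", nEmpty,
                " meta-exons had no SNP in the cis window")
    groups <- split(seq_len(nrow(x))[keys != ""], keys[keys != ""])
    out <- vector("list", length(groups))
    for (gidx in seq_along(groups)) {
        idx <- groups[[gidx]]
        cis <- cisSets[[idx[1]]]
        res <- .interactionScanCore(x[idx, , drop = FALSE], dp$ageC,
            dp$Pc, al$dos[, cis, drop = FALSE], pre = pre)
        keep <- res[, "ok"] > 0
        if (!any(keep)) next
        res <- res[keep, , drop = FALSE]
        snpBlock <- rep(cis, each = length(idx))[keep]
        out[[gidx]] <- data.frame(
            meta_exon_id = rownames(x)[idx[res[, "exon"]]],
            gene_id = geneId[idx[res[, "exon"]]],
            snp_id = colnames(al$dos)[snpBlock],
            res[, setdiff(colnames(res), c("exon", "ok")),
                drop = FALSE],
            exonOrd = idx[res[, "exon"]], snpOrd = snpBlock)
    }
    res <- do.call(rbind, out)
    if (is.null(res))
        return(data.frame(meta_exon_id = character(),
                          gene_id = character(), snp_id = character()))
    res <- res[order(res$exonOrd, res$snpOrd), ]
    res$exonOrd <- res$snpOrd <- NULL
    rownames(res) <- NULL
    res
}

#' Permutation-based, exon-stratified false discovery rate
#'
#' Estimates the FDR of the cis interaction scan by an approximated
#' permutation scheme: per (meta-exon, SNP) pair, expression residuals
#' with all main effects (phenotype, SNP, age) regressed out are permuted
#' across samples -- preserving the genotype structure -- and the
#' interaction p-value is recomputed for every permutation. Because genes
#' with many exons get more chances to show a small p by luck, genes are
#' binned into \code{nStrata} strata of similar expressed-exon count and
#' the FDR is computed within stratum:
#' \deqn{FDR(t) = \frac{\#\{p_{perm} \le t\}/n_{perm}}{\#\{p_{obs} \le t\}},}
#' monotonized to be non-decreasing in p. Pairs with FDR < 0.05 are
#' flagged significant.
#'
#' @param observed result of \code{\link{cisInteractionScan}} on the same
#'   inputs.
#' @param se,geno,metadata,phenotype as in
#'   \code{\link{cisInteractionScan}}.
#' @param nPerm number of permutations (default 100; at least 20).
#' @param nStrata number of exon-count strata (default 4).
#' @param fdrLevel significance threshold on the FDR (default 0.05).
#' @param seed integer seed for the permutations.
#' @return list with \code{results} (the observed table plus
#'   \code{stratum}, \code{fdr}, \code{significant}), \code{strata}
#'   (per-stratum summary), \code{nPerm}.
#' @export
permutationFdr <- function(observed, se, geno, metadata,
        phenotype = "phenotype", nPerm = 100, nStrata = 4,
        fdrLevel = 0.05, seed = 1) {
    if (nPerm < 20)
        stop("nPerm must be at least 20 for a usable FDR estimate")
    if (!nrow(observed)) stop("observed results table is empty")
    al <- .alignSamples(se, geno, metadata)
    dp <- .designPieces(al$md, phenotype)
    pre <- .interactionPre(dp$ageC, dp$Pc)
    x <- .exprAssay(al$se)
    n <- ncol(x)
    set.seed(seed)
    perms <- replicate(nPerm, sample.int(n))

    Q <- pre$Q
    Pc <- dp$Pc
    permP <- matrix(NA_real_, nrow(observed), nPerm)
    exonIdx <- match(observed$meta_exon_id, rownames(x))
    for (i in seq_len(nrow(observed))) {
        y <- x[exonIdx[i], ]
        g <- al$dos[, observed$snp_id[i]]
        gr <- g - Q %*% crossprod(Q, g)
        q5 <- gr / sqrt(sum(gr^2))
        Q5 <- cbind(Q, q5)
        W <- g * Pc
        w <- W - Q5 %*% crossprod(Q5, W)
        ww <- sum(w^2)
        r <- as.numeric(y - Q5 %*% crossprod(Q5, y))  # main effects out
        Yp <- matrix(r[perms], n, nPerm)
        A <- crossprod(cbind(w, Q5), Yp)              # 6 x nPerm
        wY <- A[1, ]
        ss5 <- sum(r^2) - colSums(A[-1, , drop = FALSE]^2)
        rss <- pmax(0, ss5 - wY^2 / ww)
        tstat <- (wY / ww) / sqrt(rss / (n - 6) / ww)
        permP[i, ] <- 2 * pt(abs(tstat), n - 6, lower.tail = FALSE)
    }

    # exon-count strata at the gene level (quantile boundaries)
    exonsPerGene <- table(S4Vectors::mcols(
        SummarizedExperiment::rowRanges(al$se))$gene_id)
    br <- unique(quantile(as.numeric(exonsPerGene),
                          probs = seq(0, 1, length.out = nStrata + 1)))
    geneStrat <- cut(as.numeric(exonsPerGene), breaks = br,
                     include.lowest = TRUE, labels = FALSE)
    names(geneStrat) <- names(exonsPerGene)
    stratum <- geneStrat[observed$gene_id]

    fdr <- rep(NA_real_, nrow(observed))
    for (s in sort(unique(stratum))) {
        sel <- which(stratum == s)
        po <- observed$p_interaction[sel]
        pp <- sort(as.numeric(permP[sel, , drop = FALSE]))
        obsCount <- rank(po, ties.method = "max")
        permMean <- findInterval(po, pp) / nPerm
        f <- pmin(1, permMean / obsCount)
        o <- order(po)
        f[o] <- rev(cummin(rev(f[o])))    # non-decreasing in p
        fdr[sel] <- f
    }
    results <- cbind(observed, stratum = as.integer(stratum), fdr = fdr,
                     significant = fdr < fdrLevel)
    strata <- data.frame(stratum = sort(unique(stratum)),
        n_pairs = as.integer(table(stratum)),
        n_significant = as.integer(tapply(results$significant, stratum,
                                          sum)))
    list(results = results, strata = strata, nPerm = nPerm,
         breaks = br)
}

#' Bonferroni threshold for the two-step trans scan
#'
#' The strict family-wise threshold used to call trans interactions:
#' \code{alpha} divided by the number of tests, i.e. seed variants times
#' expressed meta-exons. For example, four seed variants tested against
#' 116,643 exons at alpha = 0.05 give 1.1e-7 (two significant figures).
#'
#' @param nVariants number of seed variants.
#' @param nExons number of expressed meta-exons.
#' @param alpha family-wise error target (default 0.05).
#' @return The p-value threshold.
#' @examples
#' signif(bonferroniThreshold(4, 116643), 2)
#' @export
bonferroniThreshold <- function(nVariants, nExons, alpha = 0.05) {
    stopifnot(nVariants >= 1, nExons >= 1)
    alpha / (nVariants * nExons)
}

#' Two-step trans interaction scan
#'
#' Tests each seed variant (a significant cis interaction variant from a
#' scan on residuals not corrected for latent factors) against every
#' expressed meta-exon at a distance greater than \code{minDistanceBp}
#' from the variant or on a different chromosome, under the same
#' interaction model as the cis scan. Significance uses a strict
#' Bonferroni threshold of \code{alpha} divided by (number of variants
#' times number of expressed exons).
#'
#' @param seedSnpIds character vector of seed variant identifiers.
#' @param se expression \code{SummarizedExperiment} (latent-factor
#'   correction deliberately NOT applied, since it can absorb broad trans
#'   effects).
#' @param geno,metadata,phenotype as in \code{\link{cisInteractionScan}}.
#' @param minDistanceBp cis-exclusion distance (default 5 Mb).
#' @param alpha family-wise error target for the Bonferroni threshold.
#' @return list with \code{results} (per variant-exon pair), the
#'   Bonferroni \code{threshold}, \code{nVariants}, \code{nExons}.
#' @export
transInteractionScan <- function(seedSnpIds, se, geno, metadata,
        phenotype = "phenotype", minDistanceBp = 5e6, alpha = 0.05) {
    if (!length(seedSnpIds)) {
        warning("no seed variants supplied; nothing to test")
        return(list(results = NULL, threshold = NA_real_,
                    nVariants = 0L, nExons = nrow(se)))
    }
    al <- .alignSamples(se, geno, metadata)
    dp <- .designPieces(al$md, phenotype)
    pre <- .interactionPre(dp$ageC, dp$Pc)
    x <- .exprAssay(al$se)
    n <- ncol(x)
    rr <- SummarizedExperiment::rowRanges(al$se)
    tss <- S4Vectors::mcols(rr)$tss
    chrom <- as.character(seqnames(rr))
    nExons <- nrow(x)
    threshold <- bonferroniThreshold(length(seedSnpIds), nExons, alpha)

    out <- vector("list", length(seedSnpIds))
    for (v in seq_along(seedSnpIds)) {
        sid <- seedSnpIds[v]
        if (!sid %in% colnames(al$dos)) stop("unknown seed variant: ", sid)
        sp <- al$snps[sid, ]
        far <- chrom != sp$chrom | abs(tss - sp$pos) > minDistanceBp
        if (!any(far)) next
        g <- al$dos[, sid]
        gr <- g - pre$Q %*% crossprod(pre$Q, g)
        q5 <- gr / sqrt(sum(gr^2))
        Q5 <- cbind(pre$Q, q5)
        W <- g * dp$Pc
        w <- as.numeric(W - Q5 %*% crossprod(Q5, W))
        ww <- sum(w^2)
        Y <- x[far, , drop = FALSE]
        Yq <- Y %*% Q5
        wY <- as.numeric(Y %*% w)
        rss5 <- rowSums(Y^2) - rowSums(Yq^2)
        bw <- wY / ww
        rss <- pmax(0, rss5 - wY^2 / ww)
        sew <- sqrt(rss / (n - 6) / ww)
        tstat <- bw / sew
        out[[v]] <- data.frame(snp_id = sid,
            meta_exon_id = rownames(Y),
            gene_id = S4Vectors::mcols(rr)$gene_id[far],
            beta_interaction = bw, se_interaction = sew,
            p_interaction = 2 * pt(abs(tstat), n - 6, lower.tail = FALSE))
    }
    results <- do.call(rbind, out)
    if (!is.null(results)) {
        results$significant <- results$p_interaction < threshold
        rownames(results) <- NULL
    }
    list(results = results, threshold = threshold,
         nVariants = length(seedSnpIds), nExons = nExons)
}
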