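#' Storey pi0 estimation and q-values
#'
#' Estimates the proportion of true null hypotheses, \eqn{\pi_0}, from a
#' set of p-values by the Storey lambda-grid estimator
#' \eqn{\hat\pi_0(\lambda) = \#\{p > \lambda\} / (m(1-\lambda))} over
#' \eqn{\lambda = 0.05, 0.10, \ldots, 0.95}, smoothed with a cubic
#' smoothing spline (df = 3) and evaluated at the largest lambda, then
#' clipped to [0, 1]. \eqn{\pi_1 = 1 - \pi_0} measures the proportion of
#' true alternatives and hence the sharing of signal between p-value
#' sets. Q-values are \eqn{\hat\pi_0 \, p \, m / rank(p)}, monotonized.
#'
#' @param pvalues numeric vector of at least 100 p-values in [0, 1].
#' @param lambda the lambda grid.
#' @return list: \code{pi0}, \code{pi1}, \code{qvalues} (aligned with the
#'   input), \code{lambda}, \code{pi0_lambda}.
#' @examples
#' estimatePi0Qvalues(runif(2000))$pi1   # near 0 under the global null
#' @export
estimatePi0Qvalues <- function(pvalues, lambda = seq(0.05, 0.95, 0.05)) {
    p <- pvalues
    if (any(is.na(p))) stop("p-values must not be missing")
    if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
    m <- length(p)
    if (m < 100) stop("need at least 100 p-values for a stable estimate")
    pi0l <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
    fit <- smooth.spline(lambda, pi0l, df = 3)
    pi0 <- predict(fit, x = max(lambda))$y
    pi0 <- min(max(pi0, 0), 1)
    o <- order(p, decreasing = TRUE)
    q <- pi0 * p[o] * m / rank(p, ties.method = "max")[o]
    q <- pmin(1, cummin(q))
    qvalues <- numeric(m)
    qvalues[o] <- q
    list(pi0 = pi0, pi1 = 1 - pi0, qvalues = qvalues,
         lambda = lambda, pi0_lambda = pi0l)
}

# Storey estimate without the sample-size guard, for internal use on
# small scans (q-values fall back to pi0 = 1, i.e. Benjamini-Hochberg)
.storeyQvalues <- function(p, lambda = seq(0.05, 0.95, 0.05)) {
    m <- length(p)
    pi0 <- if (m >= 100) {
        pi0l <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
        min(max(predict(smooth.spline(lambda, pi0l, df = 3),
                        x = max(lambda))$y, 0), 1)
    } else 1
    o <- order(p, decreasing = TRUE)
    q <- pi0 * p[o] * m / rank(p, ties.method = "max")[o]
    q <- pmin(1, cummin(q))
    qvalues <- numeric(m)
    qvalues[o] <- q
    list(pi0 = pi0, pi1 = 1 - pi0, qvalues = qvalues)
}

#' Replication sharing via pi1
#'
#' Matches significant discovery pairs to their p-values in a replication
#' set (another tissue or cohort) and estimates the proportion of shared
#' (true) associations as \eqn{\pi_1 = 1 - \pi_0} of the matched p-value
#' set.
#'
#' @param discoveryIds character identifiers of the significant discovery
#'   pairs (e.g. \code{"<exon>:<snp>"}).
#' @param replication data.frame with columns \code{id} and \code{p}, or
#'   a named numeric vector of replication p-values.
#' @return list: \code{pi1}, \code{pi0}, \code{nMatched},
#'   \code{stable} (FALSE when fewer than 100 pairs matched).
#' @export
pi1Replication <- function(discoveryIds, replication) {
    if (is.numeric(replication))
        replication <- data.frame(id = names(replication), p = replication)
    p <- replication$p[match(discoveryIds, replication$id)]
    p <- p[!is.na(p)]
    if (!length(p)) stop("no discovery pairs matched the replication set")
    stable <- length(p) >= 100
    if (!stable)
        warning("only ", length(p),
                " matched pairs; pi1 estimate flagged unstable")
    est <- if (stable) estimatePi0Qvalues(p) else {
        # small sets: same lambda-grid estimator without BH fallback
        pi0l <- vapply(seq(0.05, 0.95, 0.05),
                       function(l) mean(p > l) / (1 - l), 0)
        fit <- smooth.spline(seq(0.05, 0.95, 0.05), pi0l, df = 3)
        pi0 <- min(max(predict(fit, x = 0.95)$y, 0), 1)
        list(pi0 = pi0, pi1 = 1 - pi0)
    }
    list(pi1 = est$pi1, pi0 = est$pi0, nMatched = length(p),
         stable = stable)
}

#' Sobel mediation test of a trans interaction through a cis mediator
#'
#' Fits the trans target expression twice by OLS:
#' \deqn{M5:\; y \sim \beta_1 A + \beta_2 A^2 + \beta_3 P + \beta_4 G +
#'   \beta_5 P \times G + \epsilon}
#' \deqn{M6:\; y \sim \beta_1 E + \beta_2 A + \beta_3 A^2 + \beta_4 P +
#'   \beta_5 G + \beta_6 P \times G + \epsilon}
#' where \eqn{E} is the cis mediator's expression. The mediation score is
#' \deqn{(\beta_{M5_5} - \beta_{M6_6}) / \beta_{M5_5}}
#' (the fraction of the interaction coefficient absorbed by conditioning
#' on the mediator). Significance is assessed by Sobel's product-of-paths
#' statistic on the indirect path: \eqn{a}, the interaction coefficient
#' of the mediator's own model \eqn{E \sim A + A^2 + P + G + P \times G},
#' times \eqn{b}, the mediator coefficient \eqn{\beta_1} of M6:
#' \deqn{Z = \frac{a\,b}{\sqrt{b^2 S_a^2 + a^2 S_b^2}},}
#' with a two-sided p-value from the standard normal. Z is large only
#' when the context-dependent signal reaches the mediator AND the
#' mediator transmits it to the target.
#'
#' @param transExpr numeric vector, trans target expression.
#' @param cisExpr numeric vector, mediator gene expression (distinct
#'   gene).
#' @param genotype numeric dosage vector of the cis variant.
#' @param phenotype,age numeric per-sample vectors.
#' @param sobelAlpha calling threshold on the Sobel p-value (default
#'   0.001).
#' @return one-row data.frame: \code{beta_m5}, \code{se_m5},
#'   \code{beta_m6}, \code{se_m6}, \code{mediation_score},
#'   \code{sobel_z}, \code{p}, \code{mediated}.
#' @export
mediationTest <- function(transExpr, cisExpr, genotype, phenotype, age,
                          sobelAlpha = 0.001) {
    n <- length(transExpr)
    stopifnot(length(cisExpr) == n, length(genotype) == n,
              length(phenotype) == n, length(age) == n)
    ageC <- age - mean(age)
    Pc <- phenotype - mean(phenotype)
    X5 <- cbind(1, ageC, ageC^2, Pc, genotype, genotype * Pc)
    colnames(X5) <- c("I", "A", "A2", "P", "G", "PxG")
    X6 <- cbind(X5[, 1, drop = FALSE], E = cisExpr, X5[, -1])
    f5 <- .olsFit(X5, transExpr)
    f6 <- .olsFit(X6, transExpr)
    fm <- .olsFit(X5, cisExpr)          # mediator's own cis model
    b5 <- f5$beta[["PxG"]]; s5 <- f5$se[[which(colnames(X5) == "PxG")]]
    b6 <- f6$beta[["PxG"]]; s6 <- f6$se[[which(colnames(X6) == "PxG")]]
    a <- fm$beta[["PxG"]]; sa <- fm$se[[which(colnames(X5) == "PxG")]]
    b <- f6$beta[["E"]]; sb <- f6$se[[which(colnames(X6) == "E")]]
    score <- if (b5 == 0) NA_real_ else (b5 - b6) / b5
    z <- (a * b) / sqrt(b^2 * sa^2 + a^2 * sb^2)
    p <- 2 * pnorm(abs(z), lower.tail = FALSE)
    data.frame(beta_m5 = b5, se_m5 = s5, beta_m6 = b6, se_m6 = s6,
               path_a = a, se_a = sa, path_b = b, se_b = sb,
               mediation_score = score, sobel_z = z, p = p,
               mediated = !is.na(p) & p <= sobelAlpha,
               degenerate = b5 == 0)
}

#' Regulatory trait concordance score for GWAS-eQTL colocalization
#'
#' Quantifies whether a GWAS variant and a regulatory (interaction or
#' main-effect) signal tag the same underlying variant, accounting for
#' local LD. For each of the \eqn{N} SNPs in the window, the target
#' expression is fitted conditional on that SNP:
#' \itemize{
#'   \item mode \code{"interaction"}: \eqn{y \sim P \times SNP_N +
#'     P \times SNP_{eQTL}}
#'   \item mode \code{"main"}: \eqn{y \sim SNP_N + P \times SNP_{eQTL}}
#' }
#' and the p-value of the eQTL interaction term is recorded. SNPs are
#' ranked so that the SNP whose conditioning most abrogates the signal
#' (largest residual p) has rank 1; then
#' \deqn{RTC = (N_{SNPs} - Rank_{GWAS\,SNP}) / N_{SNPs},}
#' so RTC approaches 1 when the GWAS SNP explains the regulatory signal
#' and is uniform on [0, 1) under independence. Ties are broken by SNP
#' position for determinism.
#'
#' @param targetExpr numeric expression vector of the regulated gene.
#' @param phenotype numeric phenotype vector.
#' @param windowGeno \linkS4class{GenotypeMatrix} restricted to the
#'   window (e.g. 250 kb centered on the GWAS index SNP); at least 10
#'   SNPs.
#' @param eqtlSnpId,gwasSnpId identifiers, both present in the window.
#' @param mode \code{"interaction"} or \code{"main"}.
#' @return list: \code{rtc}, \code{rank} (of the GWAS SNP),
#'   \code{nSnps}, \code{conditional} (per-SNP conditional p table).
#' @export
rtcScore <- function(targetExpr, phenotype, windowGeno, eqtlSnpId,
                     gwasSnpId, mode = c("interaction", "main")) {
    mode <- match.arg(mode)
    dos <- dosages(windowGeno)
    if (ncol(dos) < 10) stop("need at least 10 SNPs in the window")
    if (!eqtlSnpId %in% colnames(dos)) stop("eQTL SNP not in window")
    if (!gwasSnpId %in% colnames(dos))
        stop("GWAS SNP absent from window genotypes")
    Pc <- phenotype - mean(phenotype)
    ge <- dos[, eqtlSnpId]
    xe <- ge * Pc
    n <- length(targetExpr)
    n <- length(targetExpr)
    pcond <- vapply(seq_len(ncol(dos)), function(j) {
        gn <- dos[, j]
        xn <- if (mode == "interaction") gn * Pc else gn
        X <- cbind(1, xn, xe)
        fit <- lm.fit(X, targetExpr)
        # collinear conditioning SNP (e.g. the eQTL SNP itself, or a
        # perfect proxy): the signal is fully absorbed
        if (fit$rank < 3L) return(1)
        sigma2 <- sum(fit$residuals^2) / (n - 3L)
        XtXinv <- chol2inv(qr.R(fit$qr))
        k <- which(fit$qr$pivot == 3L)   # position of the eQTL term
        tstat <- fit$coefficients[3L] / sqrt(sigma2 * XtXinv[k, k])
        2 * pt(abs(tstat), n - 3L, lower.tail = FALSE)
    }, 0)
    pos <- snpInfo(windowGeno)$pos
    # rank 1 = conditioning abrogates the signal most (largest p)
    o <- order(-pcond, pos)
    rk <- integer(ncol(dos)); rk[o] <- seq_len(ncol(dos))
    gw <- match(gwasSnpId, colnames(dos))
    rtc <- (ncol(dos) - rk[gw]) / ncol(dos)
    list(rtc = rtc, rank = rk[gw], nSnps = ncol(dos),
         conditional = data.frame(snp_id = colnames(dos), pos = pos,
                                  p_conditional = pcond, rank = rk))
}

#' Match meta-exons between two annotation sets
#'
#' Finds, for each meta-exon of annotation A, the best-overlapping
#' meta-exon of the same gene in annotation B, and classifies the pair by
#' reciprocal overlap: \code{matched} when the overlap exceeds
#' \code{minOverlapFraction} of BOTH meta-exon lengths, \code{partial}
#' when they overlap but fail the reciprocal criterion, and
#' \code{unmatched} otherwise. Used to carry exon-level results across
#' genome builds or annotation versions for replication.
#'
#' @param a,b \code{GRanges} with a \code{gene_id} metadata column (e.g.
#'   from \code{\link{mergeMetaExons}}), on the same genome build.
#' @param minOverlapFraction reciprocal overlap threshold (default 0.90,
#'   strict inequality).
#' @return data.frame: one row per meta-exon of \code{a} with the best
#'   \code{b} match, both overlap fractions and the \code{class}.
#' @export
matchMetaExons <- function(a, b, minOverlapFraction = 0.90) {
    if (any(start(a) > end(a)) || any(start(b) > end(b)))
        stop("malformed intervals")
    ga <- S4Vectors::mcols(a)$gene_id
    gb <- S4Vectors::mcols(b)$gene_id
    hits <- GenomicRanges::findOverlaps(a, b, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    keep <- ga[qh] == gb[sh]
    qh <- qh[keep]; sh <- sh[keep]
    ov <- IRanges::width(IRanges::pintersect(
        GenomicRanges::ranges(a)[qh], GenomicRanges::ranges(b)[sh]))
    fa <- ov / IRanges::width(a)[qh]
    fb <- ov / IRanges::width(b)[sh]
    out <- data.frame(exon_a = if (is.null(names(a))) as.character(qh)
                               else names(a)[qh],
                      exon_b = if (is.null(names(b))) as.character(sh)
                               else names(b)[sh],
                      gene_id = ga[qh], frac_a = fa, frac_b = fb)
    # keep the best b exon per a exon (largest minimum fraction)
    out <- out[order(out$exon_a, -pmin(out$frac_a, out$frac_b)), ]
    out <- out[!duplicated(out$exon_a), ]
    out$class <- ifelse(out$frac_a > minOverlapFraction &
                        out$frac_b > minOverlapFraction,
                        "matched", "partial")
    allA <- if (is.null(names(a))) as.character(seq_along(a)) else names(a)
    un <- setdiff(allA, out$exon_a)
    if (length(un))
        out <- rbind(out, data.frame(exon_a = un, exon_b = NA_character_,
            gene_id = ga[match(un, allA)], frac_a = 0, frac_b = 0,
            class = "unmatched"))
    rownames(out) <- NULL
    out[order(out$gene_id, out$exon_a), ]
}
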