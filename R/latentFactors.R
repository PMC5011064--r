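#' @importFrom stats cor.test smooth.spline predict aggregate model.matrix var
NULL

#' Estimate broad-variance latent factors of an expression matrix
#'
#' Computes k latent factors maximizing captured variance from the
#' truncated singular value decomposition of the feature-standardized
#' residual matrix. This plays the role that Bayesian latent-factor
#' tools (PEER, surrogate variable analysis) play in eQTL pipelines:
#' capturing hidden confounders -- batch structure, cell-composition
#' shifts, broad biological covariates -- that inflate expression
#' variance. Factor scores are mutually orthogonal, ordered by variance
#' explained, and sign-fixed so the largest-magnitude loading of each
#' factor is positive.
#'
#' Input should already be residualized for family structure and known
#' technical covariates (see \code{\link{residualize}} and
#' \code{\link{familyResiduals}}).
#'
#' @param x \code{SummarizedExperiment} or numeric matrix
#'   (features x samples).
#' @param k number of factors (default 50); must be smaller than both
#'   dimensions.
#' @param phenotype optional numeric vector; per-factor correlation and
#'   p-value against it are reported.
#' @param scale. standardize each feature to unit variance first
#'   (default TRUE).
#' @return A \linkS4class{LatentFactorModel}.
#' @export
estimateLatentFactors <- function(x, k = 50, phenotype = NULL,
                                  scale. = TRUE) {
    m <- if (is(x, "SummarizedExperiment")) .exprAssay(x) else x
    k <- as.integer(k)
    if (k >= min(dim(m)))
        stop("k must be smaller than both matrix dimensions")
    xs <- m - rowMeans(m)
    if (scale.) {
        s <- sqrt(rowSums(xs^2) / (ncol(m) - 1))
        s[s == 0] <- 1
        xs <- xs / s
    }
    sv <- svd(t(xs), nu = k, nv = k)     # samples x features
    scores <- sv$u[, seq_len(k), drop = FALSE] *
        rep(sv$d[seq_len(k)], each = nrow(sv$u))
    loadings <- sv$v[, seq_len(k), drop = FALSE]
    for (j in seq_len(k)) {              # deterministic sign convention
        if (loadings[which.max(abs(loadings[, j])), j] < 0) {
            loadings[, j] <- -loadings[, j]
            scores[, j] <- -scores[, j]
        }
    }
    dimnames(scores) <- list(colnames(m), sprintf("F%d", seq_len(k)))
    dimnames(loadings) <- list(rownames(m), colnames(scores))
    ve <- sv$d[seq_len(k)]^2 / sum(sv$d^2)
    pc <- S4Vectors::DataFrame(r = numeric(0), p = numeric(0))
    if (!is.null(phenotype)) {
        ct <- lapply(seq_len(k), function(j)
            cor.test(scores[, j], phenotype))
        pc <- S4Vectors::DataFrame(
            factor = colnames(scores),
            r = vapply(ct, function(z) unname(z$estimate), 0),
            p = vapply(ct, function(z) z$p.value, 0))
    }
    new("LatentFactorModel", k = k, scores = scores, loadings = loadings,
        varExplained = ve, phenotypeCorr = pc)
}

#' Residualize expression on covariates and/or latent factors
#'
#' Removes, per feature, the ordinary least-squares fit on an intercept,
#' the supplied covariates, and (optionally) latent factor scores.
#' Residuals are exactly orthogonal to every regressor. Factors whose
#' absolute correlation with the phenotype exceeds
#' \code{excludeCorrThreshold} can be dropped from the design before
#' regression, the mode used when the downstream scan tests an
#' interaction with that same phenotype and collinearity must be kept in
#' check.
#'
#' @param x \code{SummarizedExperiment} or matrix (features x samples).
#' @param covariates data.frame of per-sample covariates (factors are
#'   expanded to indicators), or NULL.
#' @param factors a \linkS4class{LatentFactorModel} or score matrix, or
#'   NULL.
#' @param excludeCorrThreshold optional absolute-correlation threshold
#'   above which a factor is excluded from the design; requires
#'   \code{phenotype}.
#' @param phenotype numeric vector used for the exclusion rule.
#' @return Residualized object of the same type (state
#'   \code{residualized}); residualizing twice against the same design
#'   is a no-op.
#' @export
residualize <- function(x, covariates = NULL, factors = NULL,
                        excludeCorrThreshold = NULL, phenotype = NULL) {
    isSE <- is(x, "SummarizedExperiment")
    m <- if (isSE) .exprAssay(x) else x
    n <- ncol(m)
    design <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
    if (!is.null(covariates)) {
        cm <- model.matrix(~ ., data = as.data.frame(covariates))
        design <- cbind(design, cm[, -1, drop = FALSE])
    }
    if (!is.null(factors)) {
        fs <- if (is(factors, "LatentFactorModel")) factors@scores
              else as.matrix(factors)
        if (!is.null(excludeCorrThreshold)) {
            if (is.null(phenotype))
                stop("phenotype is required to exclude correlated factors")
            r <- abs(as.numeric(cor(fs, phenotype)))
            drop <- r > excludeCorrThreshold
            if (any(drop))
                message("residualize: excluding ", sum(drop),
                        " phenotype-correlated factor(s): ",
                        paste(colnames(fs)[drop], collapse = ", "))
            fs <- fs[, !drop, drop = FALSE]
        }
        design <- cbind(design, fs)
    }
    qrd <- qr(design)
    if (qrd$rank < ncol(design))
        stop("rank-deficient residualization design; dependent columns: ",
             paste(colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]],
                   collapse = ", "))
    Q <- qr.Q(qrd)
    res <- m - tcrossprod(m %*% Q, Q)
    if (!isSE) return(res)
    SummarizedExperiment::assay(x, "expr") <- res
    S4Vectors::metadata(x)$state <- "residualized"
    x
}

#' Remove family and zygosity structure by shrunken group means
#'
#' Per feature, estimates the family (and then zygosity) random-intercept
#' variance by the one-way ANOVA moment estimator and subtracts the
#' best-linear-unbiased-predicted group means. Unlike fixed-effect family
#' regression this shrinks singleton and small groups toward zero,
#' preserving between-family genotype contrasts -- essential when the
#' residuals feed a genotype interaction scan in a twin cohort where MZ
#' co-twins carry identical genotypes.
#'
#' @param x \code{SummarizedExperiment} or matrix (features x samples).
#' @param metadata per-sample table with \code{family} and
#'   \code{zygosity} columns.
#' @return Residualized object of the same type (rows are centered).
#' @export
familyResiduals <- function(x, metadata) {
    isSE <- is(x, "SummarizedExperiment")
    m <- if (isSE) .exprAssay(x) else x
    md <- as.data.frame(metadata)
    m <- .removeGroupBlups(m, md$family)
    m <- .removeGroupBlups(m, md$zygosity)
    if (!isSE) return(m)
    SummarizedExperiment::assay(x, "expr") <- m
    S4Vectors::metadata(x)$state <- "residualized"
    x
}

# one-way random-intercept BLUP removal, vectorized over features
.removeGroupBlups <- function(x, groups) {
    groups <- as.character(groups)
    ng <- table(groups)
    G <- length(ng); N <- ncol(x)
    if (G == N) return(x - rowMeans(x))   # all singletons: nothing shared
    xc <- x - rowMeans(x)
    gsum <- t(rowsum(t(xc), groups))           # features x G
    nvec <- as.numeric(ng[colnames(gsum)])
    gmean <- sweep(gsum, 2, nvec, "/")
    SStot <- rowSums(xc^2)
    SSB <- as.numeric(gmean^2 %*% nvec)
    SSW <- pmax(0, SStot - SSB)
    sigE <- SSW / (N - G)
    n0 <- (N - sum(nvec^2) / N) / (G - 1)
    sigF <- pmax(0, (SSB / (G - 1) - sigE) / n0)
    # shrinkage factor lambda_{feature, group}
    lam <- (sigF %o% nvec) / ((sigF %o% nvec) + sigE + 1e-300)
    blup <- lam * gmean
    xc - blup[, match(groups, colnames(gsum)), drop = FALSE]
}
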