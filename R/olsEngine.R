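#' @importFrom stats pt pchisq pnorm qnorm complete.cases lm.fit logLik
NULL

# ---- internal OLS machinery ----------------------------------------------
#
# All interaction-model fitting goes through these two routines. Single
# fits use the QR decomposition (lm.fit); batched scans use the
# Frisch-Waugh-Lovell decomposition against the shared covariate block
# [1, age_c, age_c^2, P_c], which yields coefficient, SE and p-value for
# the SNP and SNP-by-phenotype terms identical to the full-design OLS at
# a fraction of the cost.

# QR-based OLS with t-tests; X must include the intercept column.
.olsFit <- function(X, y) {
    fit <- lm.fit(X, y)
    r <- fit$rank
    if (r < ncol(X))
        stop("singular fixed-effect design; collinear columns: ",
             paste(colnames(X)[is.na(fit$coefficients)], collapse = ", "))
    df <- length(y) - r
    rss <- sum(fit$residuals^2)
    sigma2 <- rss / df
    R <- qr.R(fit$qr)
    XtXinv <- chol2inv(R[seq_len(r), seq_len(r), drop = FALSE])
    se <- sqrt(sigma2 * diag(XtXinv))[order(fit$qr$pivot[seq_len(r)])]
    beta <- fit$coefficients
    tstat <- beta / se
    list(beta = beta, se = se, t = tstat,
         p = 2 * pt(abs(tstat), df, lower.tail = FALSE),
         sigma2 = sigma2, df = df, rss = rss)
}

# Batched interaction scan of the expression rows of Y against the SNP
# columns of G:  y ~ 1 + A_c + A_c^2 + P + g + g:P.  For each SNP the
# 2x2 normal-equation block of the residualized (g, g*P) pair is shared
# by every expression row, so all exons of a gene are solved at once.
# Returns a (rows(Y) x SNPs)-long matrix, SNP-major within exon blocks
# handled by the caller; also the p-value of the SNP term in the
# main-effect model (no interaction).
.interactionScanCore <- function(Y, ageC, Pc, G, pre = NULL) {
    if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1)
    n <- ncol(Y); k <- nrow(Y); m <- ncol(G)
    if (is.null(pre)) pre <- .interactionPre(ageC, Pc)
    Q <- pre$Q
    CzG <- crossprod(Q, G)                       # 4 x m
    Gr <- G - Q %*% CzG
    W <- G * Pc
    CzW <- crossprod(Q, W)
    Wr <- W - Q %*% CzW
    a11 <- colSums(Gr * Gr)
    a12 <- colSums(Gr * Wr)
    a22 <- colSums(Wr * Wr)
    QtY <- crossprod(Q, t(Y))                    # 4 x k
    syy <- rowSums(Y^2) - colSums(QtY^2)         # per exon
    B1 <- Y %*% Gr                               # k x m
    B2 <- Y %*% Wr
    det <- a11 * a22 - a12^2
    ok <- is.finite(det) & det > 1e-10 * pmax(a11 * a22, 1e-300) &
        a11 > 1e-12
    det[!ok] <- NA_real_
    dfF <- n - 6L; dfM <- n - 5L
    out <- vector("list", m)
    for (j in seq_len(m)) {
        b1 <- B1[, j]; b2 <- B2[, j]
        bg <- (a22[j] * b1 - a12[j] * b2) / det[j]
        bw <- (a11[j] * b2 - a12[j] * b1) / det[j]
        sigma2 <- pmax(0, syy - (bg * b1 + bw * b2)) / dfF
        seg <- sqrt(sigma2 * a22[j] / det[j])
        sew <- sqrt(sigma2 * a11[j] / det[j])
        tInt <- bw / sew
        # phenotype coefficient of the full model, recovered from the
        # covariate block:  beta_Z = R^{-1}(Q'y - Q'g bg - Q'W bw)
        bZ <- backsolve(pre$R, QtY - outer(CzG[, j], bg) -
                                outer(CzW[, j], bw))
        bm <- b1 / a11[j]
        sigma2m <- pmax(0, syy - bm * b1) / dfM
        sem <- sqrt(sigma2m / a11[j])
        out[[j]] <- cbind(exon = seq_len(k),
            beta_pheno = bZ[4L, ], beta_snp = bg, se_snp = seg,
            beta_interaction = bw, se_interaction = sew,
            t_interaction = tInt,
            p_interaction = 2 * pt(abs(tInt), dfF, lower.tail = FALSE),
            beta_main = bm, se_main = sem,
            p_main = 2 * pt(abs(bm / sem), dfM, lower.tail = FALSE),
            ok = rep(ok[j], k))
    }
    do.call(rbind, out)
}

# centered age and phenotype pulled out of a metadata table
.designPieces <- function(metadata, phenotype = "phenotype") {
    md <- as.data.frame(metadata)
    if (!phenotype %in% colnames(md))
        stop("metadata lacks phenotype column '", phenotype, "'")
    P <- md[[phenotype]]
    if (mean(is.na(P)) > 0.10)
        stop("phenotype '", phenotype, "' missing for more than 10% of samples")
    list(ageC = md$age - mean(md$age, na.rm = TRUE),
         P = P, Pc = P - mean(P, na.rm = TRUE))
}
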