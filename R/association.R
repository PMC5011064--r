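#' @importFrom lme4 lmer lmerControl fixef refit
#' @importFrom stats lm resid
NULL

.lmerCtrl <- function()
    lmerControl(calc.derivs = FALSE,
                check.conv.singular = "ignore",
                check.conv.grad = "ignore",
                check.conv.hess = "ignore",
                optCtrl = list(xtol_abs = 1e-10, ftol_abs = 1e-10))

# build the model frame and formulas for the twin mixed model
.lmmDesign <- function(metadata, phenotype, fixedCovariates,
                       randomCovariates) {
    md <- as.data.frame(metadata)
    need <- c(phenotype, "age", "family", "zygosity")
    miss <- setdiff(need, colnames(md))
    if (length(miss))
        stop("metadata lacks required columns: ", paste(miss, collapse = ", "))
    if (mean(is.na(md[[phenotype]])) > 0.10)
        stop("phenotype '", phenotype,
             "' missing for more than 10% of samples")
    fixedCovariates <- intersect(fixedCovariates, colnames(md))
    randomCovariates <- intersect(randomCovariates, colnames(md))
    # grouping factors where every level is a singleton carry no shared
    # variance and are unidentifiable as random intercepts; drop them
    groupings <- c("family", "zygosity", randomCovariates)
    keepG <- vapply(groupings,
                    function(v) any(table(md[[v]]) >= 2L), TRUE)
    if (!all(keepG))
        message(".lmmDesign: dropping all-singleton grouping(s): ",
                paste(groupings[!keepG], collapse = ", "))
    groupings <- groupings[keepG]
    randomCovariates <- intersect(randomCovariates, groupings)
    ageC <- md$age - mean(md$age)
    df <- data.frame(.y = 0, .pheno = md[[phenotype]],
                     .age = ageC, .age2 = ageC^2,
                     family = factor(md$family),
                     zygosity = factor(md$zygosity))
    for (v in fixedCovariates) {
        z <- md[[v]]
        # standardize numeric technical covariates: keeps the optimizer
        # well scaled without changing the fit space or the LRT
        df[[v]] <- if (is.numeric(z) && sd(z) > 0) as.numeric(scale(z))
                   else z
    }
    for (v in randomCovariates) df[[v]] <- factor(md[[v]])
    fx <- paste(c(".age", ".age2", fixedCovariates), collapse = " + ")
    # singularity check on the fixed design before handing to lme4
    X <- stats::model.matrix(stats::as.formula(
        paste("~ .pheno +", fx)), df)
    qrX <- qr(X)
    if (qrX$rank < ncol(X))
        stop("singular fixed-effect design; collinear columns: ",
             paste(colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]],
                   collapse = ", "))
    useLm <- length(groupings) == 0L
    rnd <- if (useLm) NULL else
        paste(sprintf("(1 | %s)", groupings), collapse = " + ")
    fb <- if ("family" %in% groupings) "(1 | family)" else NULL
    mkf <- function(lhs, terms) stats::as.formula(
        paste(".y ~", paste(c(lhs, terms), collapse = " + ")))
    list(df = df, useLm = useLm,
         full = mkf(".pheno", c(fx, rnd)),
         null = mkf(NULL, c(fx, rnd)),
         fallbackFull = mkf(".pheno", c(fx, fb)),
         fallbackNull = mkf(NULL, c(fx, fb)),
         fallbackLm = is.null(fb))
}

# OLS counterpart of .lrtRow for designs without shared groupings
.lrtRowLm <- function(formFull, formNull, df) {
    f1 <- stats::lm(formFull, df); f0 <- stats::lm(formNull, df)
    n <- nrow(df)
    lrt <- max(0, n * log(sum(resid(f0)^2) / sum(resid(f1)^2)))
    sm <- summary(f1)$coefficients
    data.frame(beta = sm[".pheno", 1], se = sm[".pheno", 2], lrt = lrt,
               p = pchisq(lrt, df = 1, lower.tail = FALSE))
}

.lrtRow <- function(full, null) {
    ll1 <- as.numeric(logLik(full)); ll0 <- as.numeric(logLik(null))
    lrt <- max(0, 2 * (ll1 - ll0))
    beta <- fixef(full)[".pheno"]
    se <- sqrt(diag(as.matrix(vcov(full)))[".pheno"])
    data.frame(beta = unname(beta), se = unname(se), lrt = lrt,
               p = pchisq(lrt, df = 1, lower.tail = FALSE))
}

#' Twin-aware phenotype association for one expression trait
#'
#' Fits the linear mixed model
#' \deqn{y \sim X\beta + Zu + \epsilon}
#' with fixed effects phenotype, centered age, age squared and technical
#' covariates, and random intercepts for family, zygosity (and optionally
#' further technical groupings). The full model is compared to the same
#' model with the phenotype omitted by a one-degree-of-freedom
#' likelihood-ratio test against \eqn{\chi^2_1}. Both models are fitted
#' by maximum likelihood, as required for a fixed-effect LRT.
#'
#' The zygosity grouping shares a code only within monozygotic pairs, so
#' its variance component captures the excess resemblance of MZ over DZ
#' co-twins.
#'
#' @param y numeric expression vector (one meta-exon), aligned with
#'   \code{metadata} rows.
#' @param metadata per-sample table with \code{phenotype} (see below),
#'   \code{age}, \code{family}, \code{zygosity} and any technical
#'   covariates.
#' @param phenotype name of the phenotype column (default
#'   \code{"phenotype"}).
#' @param fixedCovariates,randomCovariates technical covariates modeled
#'   as fixed effects / extra random intercepts; silently restricted to
#'   columns present in \code{metadata}.
#' @return A one-row data.frame: \code{beta}, \code{se}, \code{lrt},
#'   \code{p}, \code{converged}, \code{fallback} (TRUE when the random
#'   effects had to be collapsed to family only).
#' @examples
#' md <- data.frame(phenotype = rnorm(40, 25, 4), age = runif(40, 38, 84),
#'                  family = rep(1:20, each = 2),
#'                  zygosity = c(rep(1:10, each = 2), 10 + 1:20))
#' fitLmmLrt(rnorm(40), md)
#' @export
fitLmmLrt <- function(y, metadata, phenotype = "phenotype",
        fixedCovariates = c("gc_content", "insert_mode"),
        randomCovariates = c("primer_index", "batch")) {
    if (length(y) < 20) stop("need at least 20 samples")
    des <- .lmmDesign(metadata, phenotype, fixedCovariates,
                      randomCovariates)
    des$df$.y <- y
    if (des$useLm)
        return(cbind(.lrtRowLm(des$full, des$null, des$df),
                     converged = TRUE, fallback = FALSE))
    ctrl <- .lmerCtrl()
    res <- tryCatch({
        full <- suppressMessages(lmer(des$full, des$df, REML = FALSE,
                                      control = ctrl))
        null <- suppressMessages(lmer(des$null, des$df, REML = FALSE,
                                      control = ctrl))
        cbind(.lrtRow(full, null), converged = TRUE, fallback = FALSE)
    }, error = function(e) NULL)
    if (is.null(res)) {
        res <- if (des$fallbackLm)
            .lrtRowLm(des$fallbackFull, des$fallbackNull, des$df)
        else {
            full <- suppressMessages(lmer(des$fallbackFull, des$df,
                                          REML = FALSE, control = ctrl))
            null <- suppressMessages(lmer(des$fallbackNull, des$df,
                                          REML = FALSE, control = ctrl))
            .lrtRow(full, null)
        }
        res <- cbind(res, converged = FALSE, fallback = TRUE)
    }
    rownames(res) <- NULL
    res
}

#' Transcriptome-wide phenotype association scan
#'
#' Applies \code{\link{fitLmmLrt}} to every meta-exon of an
#' inverse-normal transformed expression matrix, computes Storey
#' q-values across the scan, and summarizes to the gene level: a gene is
#' called associated when at least one of its meta-exons has
#' \eqn{q \le} \code{fdrLevel}.
#'
#' Model structure is estimated once and refitted per exon with new
#' responses, which makes the scan practical at transcriptome scale.
#'
#' @param se \code{SummarizedExperiment} in state \code{int_transformed}
#'   (rowRanges carry \code{gene_id}).
#' @param metadata per-sample table (see \code{\link{fitLmmLrt}}).
#' @param phenotype phenotype column name.
#' @param fdrLevel gene-level calling threshold on q (default 0.05).
#' @param fixedCovariates,randomCovariates as in \code{\link{fitLmmLrt}}.
#' @return A list with \code{results} (per meta-exon data.frame:
#'   \code{meta_exon_id}, \code{gene_id}, \code{beta}, \code{se},
#'   \code{lrt}, \code{p}, \code{q}, flags), \code{genes} (per-gene
#'   \code{associated} calls), and \code{pi0}.
#' @export
transcriptomeScan <- function(se, metadata, phenotype = "phenotype",
        fdrLevel = 0.05,
        fixedCovariates = c("gc_content", "insert_mode"),
        randomCovariates = c("primer_index", "batch")) {
    if (!expressionState(se) %in% c("int_transformed", "filtered"))
        stop("expression must be filtered and inverse-normal transformed")
    x <- .exprAssay(se)
    des <- .lmmDesign(metadata, phenotype, fixedCovariates,
                      randomCovariates)
    ctrl <- .lmerCtrl()
    rows <- vector("list", nrow(x))
    if (des$useLm) {
        for (i in seq_len(nrow(x))) {
            des$df$.y <- x[i, ]
            rows[[i]] <- cbind(.lrtRowLm(des$full, des$null, des$df),
                               converged = TRUE, fallback = FALSE)
        }
    } else {
    des$df$.y <- x[1, ]
    tmplFull <- suppressMessages(lmer(des$full, des$df, REML = FALSE,
                                      control = ctrl))
    tmplNull <- suppressMessages(lmer(des$null, des$df, REML = FALSE,
                                      control = ctrl))
    for (i in seq_len(nrow(x))) {
        yi <- x[i, ]
        rows[[i]] <- tryCatch({
            f <- suppressWarnings(suppressMessages(refit(tmplFull, yi)))
            g <- suppressWarnings(suppressMessages(refit(tmplNull, yi)))
            row <- .lrtRow(f, g)
            # warm starts occasionally strand one refit on a bad
            # optimum; a gross LRT/Wald mismatch flags it, and both
            # models are then refitted from scratch with default
            # starting values, keeping whichever likelihood is higher
            wald <- (row$beta / row$se)^2
            if (!is.finite(row$lrt) ||
                abs(row$lrt - wald) > 1 + 0.2 * wald) {
                des$df$.y <- yi
                f2 <- suppressMessages(lmer(des$full, des$df,
                                            REML = FALSE, control = ctrl))
                g2 <- suppressMessages(lmer(des$null, des$df,
                                            REML = FALSE, control = ctrl))
                if (as.numeric(logLik(f2)) > as.numeric(logLik(f))) f <- f2
                if (as.numeric(logLik(g2)) > as.numeric(logLik(g))) g <- g2
                row <- .lrtRow(f, g)
            }
            cbind(row, converged = TRUE, fallback = FALSE)
        }, error = function(e) {
            des$df$.y <- yi
            tryCatch({
                res <- if (des$fallbackLm)
                    .lrtRowLm(des$fallbackFull, des$fallbackNull, des$df)
                else {
                    f <- suppressMessages(lmer(des$fallbackFull, des$df,
                                               REML = FALSE,
                                               control = ctrl))
                    g <- suppressMessages(lmer(des$fallbackNull, des$df,
                                               REML = FALSE,
                                               control = ctrl))
                    .lrtRow(f, g)
                }
                cbind(res, converged = FALSE, fallback = TRUE)
            }, error = function(e2)
                data.frame(beta = NA_real_, se = NA_real_, lrt = NA_real_,
                           p = NA_real_, converged = FALSE,
                           fallback = TRUE))
        })
    }
    }
    res <- do.call(rbind, rows)
    res <- cbind(data.frame(meta_exon_id = rownames(x),
        gene_id = S4Vectors::mcols(
            SummarizedExperiment::rowRanges(se))$gene_id), res)
    qv <- .storeyQvalues(res$p[!is.na(res$p)])
    res$q <- NA_real_
    res$q[!is.na(res$p)] <- qv$qvalues
    genes <- stats::aggregate(q ~ gene_id, data = res,
                              FUN = function(v) min(v, na.rm = TRUE))
    genes$associated <- genes$q <= fdrLevel
    names(genes)[2] <- "min_q"
    list(results = res, genes = genes, pi0 = qv$pi0)
}
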