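#' Merge overlapping exons of each gene into meta-exons
#'
#' All overlapping (or bookended) annotated exons of a gene are collapsed
#' into their interval union, the meta-exon, which is the quantification
#' unit for all downstream models. Coordinates are 1-based inclusive
#' internally (GTF convention); BED I/O converts at the boundary.
#'
#' @param exons A \code{GRanges} with a \code{gene_id} metadata column, or
#'   a data.frame with columns \code{gene_id}, \code{chrom}, \code{start},
#'   \code{end} and optionally \code{strand}.
#' @return A named \code{GRanges} of non-overlapping meta-exons sorted by
#'   gene then position, with metadata columns \code{gene_id} and
#'   \code{tss} (the meta-exon start on the + strand, end on the -
#'   strand). Names are \code{<gene_id>_E<k>} in transcription order.
#' @examples
#' df <- data.frame(gene_id = "G1", chrom = "chr1",
#'                  start = c(100, 150), end = c(200, 250), strand = "+")
#' mergeMetaExons(df)
#' @export
mergeMetaExons <- function(exons) {
    if (is.data.frame(exons)) {
        if (any(exons$start > exons$end))
            stop("malformed annotation: start > end")
        exons <- GRanges(exons$chrom, IRanges(exons$start, exons$end),
            strand = if (is.null(exons$strand)) "*" else exons$strand,
            gene_id = exons$gene_id)
    }
    if (is.null(S4Vectors::mcols(exons)$gene_id))
        stop("exon annotation must carry a gene_id column")
    grl <- S4Vectors::split(exons, S4Vectors::mcols(exons)$gene_id)
    red <- GenomicRanges::reduce(grl)      # per-gene interval union
    out <- unlist(red, use.names = TRUE)
    gid <- names(out)
    names(out) <- NULL
    S4Vectors::mcols(out)$gene_id <- gid
    out <- out[order(gid, as.character(seqnames(out)), start(out))]
    minus <- as.character(strand(out)) == "-"
    S4Vectors::mcols(out)$tss <- ifelse(minus, end(out), start(out))
    # exon index in transcription order (reversed on the minus strand)
    idx <- unlist(lapply(split(seq_along(out),
                               S4Vectors::mcols(out)$gene_id), function(i) {
        if (length(i) > 1 && as.character(strand(out))[i[1]] == "-")
            rev(seq_along(i)) else seq_along(i)
    }), use.names = FALSE)
    names(out) <- sprintf("%s_E%d", S4Vectors::mcols(out)$gene_id, idx)
    out
}

#' Normalize quantifications for sequencing depth
#'
#' Scales each sample's read counts by the ratio of the cohort median
#' number of well-mapped reads to that sample's count, so a sample at the
#' median depth is unchanged and the zero pattern is preserved.
#'
#' @param se A raw-state expression \code{SummarizedExperiment}.
#' @param wellMappedReads numeric vector of per-sample well-mapped read
#'   counts (named by sample or in column order), all positive. Defaults
#'   to a \code{well_mapped_reads} column in \code{colData}.
#' @return The depth-normalized \code{SummarizedExperiment}.
#' @export
normalizeDepth <- function(se, wellMappedReads = NULL) {
    if (is.null(wellMappedReads))
        wellMappedReads <- SummarizedExperiment::colData(se)$well_mapped_reads
    if (is.null(wellMappedReads))
        stop("per-sample well-mapped read counts are required")
    if (!is.null(names(wellMappedReads)))
        wellMappedReads <- wellMappedReads[colnames(se)]
    if (length(wellMappedReads) != ncol(se))
        stop("need exactly one depth value per sample")
    if (any(!is.finite(wellMappedReads)) || any(wellMappedReads <= 0))
        stop("well-mapped read counts must all be positive")
    sf <- median(wellMappedReads) / wellMappedReads
    x <- .exprAssay(se)
    SummarizedExperiment::assay(se, "expr") <- sweep(x, 2, sf, "*")
    .setState(se, "depth_normalized", "raw")
}

#' Filter to meta-exons quantified in most individuals
#'
#' Retains meta-exons with a nonzero quantification in strictly more than
#' \code{minFraction} of samples; the identifiers of dropped rows are
#' reported via \code{message} and attached as an attribute.
#'
#' @param se Expression \code{SummarizedExperiment} (raw or
#'   depth-normalized).
#' @param minFraction required expressed fraction, in (0, 1]; default 0.90.
#' @return The filtered \code{SummarizedExperiment} (state
#'   \code{filtered}), with \code{metadata()$dropped} listing removed rows.
#' @export
filterExpressed <- function(se, minFraction = 0.90) {
    if (minFraction <= 0 || minFraction > 1)
        stop("minFraction must lie in (0, 1]")
    x <- .exprAssay(se)
    frac <- rowMeans(x != 0, na.rm = TRUE)
    keep <- frac > minFraction
    dropped <- rownames(se)[!keep]
    if (length(dropped))
        message("filterExpressed: dropping ", length(dropped), " of ",
                nrow(se), " meta-exons quantified in <= ",
                round(100 * minFraction), "% of samples")
    out <- se[keep, ]
    out <- .setState(out, "filtered", c("raw", "depth_normalized"))
    S4Vectors::metadata(out)$dropped <- dropped
    out
}

#' Rank-based inverse normal transformation
#'
#' Maps values to standard-normal quantiles through their ranks:
#' \eqn{\Phi^{-1}((r - 0.5)/n)} (rankit offset) or
#' \eqn{\Phi^{-1}((r - 3/8)/(n + 1/4))} (Blom), with average ranks for
#' ties. Missing entries stay missing and are excluded from \eqn{n}.
#'
#' @param x numeric vector with at least 3 non-missing values, not all
#'   tied.
#' @param offset rank offset variant, \code{"rankit"} (default) or
#'   \code{"blom"}.
#' @return Transformed vector of the same length and names.
#' @examples
#' inverseNormalTransform(c(3, 1, 2))   # qnorm(c(5, 1, 3)/6)
#' @export
inverseNormalTransform <- function(x, offset = c("rankit", "blom")) {
    offset <- match.arg(offset)
    ok <- !is.na(x)
    n <- sum(ok)
    if (n < 3) stop("need at least 3 non-missing values")
    if (length(unique(x[ok])) == 1L)
        stop("degenerate input: all values identical")
    r <- rank(x[ok], ties.method = "average")
    q <- if (offset == "rankit") (r - 0.5) / n else (r - 3 / 8) / (n + 1 / 4)
    out <- x
    out[ok] <- qnorm(q)
    out
}

#' Apply the inverse normal transformation per meta-exon
#'
#' @param se A filtered expression \code{SummarizedExperiment}.
#' @param offset passed to \code{\link{inverseNormalTransform}}.
#' @return The transformed \code{SummarizedExperiment} (state
#'   \code{int_transformed}); each row has mean ~0 and variance ~1.
#' @export
transformToNormal <- function(se, offset = c("rankit", "blom")) {
    offset <- match.arg(offset)
    x <- .exprAssay(se)
    SummarizedExperiment::assay(se, "expr") <-
        t(apply(x, 1, inverseNormalTransform, offset = offset))
    .setState(se, "int_transformed", c("filtered", "depth_normalized"))
}
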