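#' @importFrom data.table fread fwrite as.data.table
#' @importFrom utils packageVersion head
NULL

# ---- writers -------------------------------------------------------------

#' Write a cohort to standard on-disk formats
#'
#' Writes genotypes (dosage TSV, SNPs as rows and samples as columns,
#' \code{.} for missing; or VCF 4.2 with GT:DS), the expression matrix
#' (TSV, meta-exons as rows), sample metadata (TSV), the meta-exon
#' annotation (GTF, 1-based inclusive; and BED, 0-based half-open) and
#' the truth table (JSON).
#'
#' @param cohort A \linkS4class{TwinCohort}.
#' @param dir output directory (created if needed).
#' @param genotypeFormat \code{"tsv"} (default) or \code{"vcf"}.
#' @return Invisibly, the named vector of written paths.
#' @export
writeCohort <- function(cohort, dir, genotypeFormat = c("tsv", "vcf")) {
    genotypeFormat <- match.arg(genotypeFormat)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
        genotypes = file.path(dir, if (genotypeFormat == "vcf")
            "genotypes.vcf" else "dosages.tsv"),
        counts = file.path(dir, "counts.tsv"),
        metadata = file.path(dir, "metadata.tsv"),
        gtf = file.path(dir, "annotation.gtf"),
        bed = file.path(dir, "annotation.bed"),
        truth = file.path(dir, "truth.json"))

    dos <- dosages(cohort); snps <- as.data.frame(snpInfo(cohort))
    if (genotypeFormat == "tsv") {
        gt <- data.table::as.data.table(cbind(
            data.frame(snp_id = colnames(dos), chrom = snps$chrom,
                       pos = snps$pos, ea = snps$ea, oa = snps$oa),
            as.data.frame(t(dos))))
        fwrite(gt, paths["genotypes"], sep = "\t", na = ".")
    } else {
        .writeVcf(dos, snps, paths["genotypes"])
    }

    x <- .exprAssay(cohort@expression)
    fwrite(data.table::as.data.table(
        cbind(data.frame(meta_exon_id = rownames(x)), as.data.frame(x))),
        paths["counts"], sep = "\t")
    fwrite(as.data.frame(sampleData(cohort)), paths["metadata"],
           sep = "\t")

    rr <- SummarizedExperiment::rowRanges(cohort@expression)
    .writeGtf(rr, paths["gtf"])
    rtracklayer::export(rr, paths["bed"], format = "BED")

    jsonlite::write_json(list(
        effects = as.data.frame(plantedEffects(cohort)),
        state = expressionState(cohort@expression),
        seed = S4Vectors::metadata(cohort@expression)$seed),
        paths["truth"], auto_unbox = TRUE, digits = NA, na = "null")
    invisible(paths)
}

# minimal VCF 4.2 with GT (rounded) and DS (dosage) fields
.writeVcf <- function(dos, snps, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of the alternate (effect) allele\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", rownames(dos)), collapse = "\t")), con)
    gtCode <- c("0/0", "0/1", "1/1")
    for (j in seq_len(ncol(dos))) {
        d <- dos[, j]
        fld <- paste0(gtCode[pmin(2, pmax(0, round(d))) + 1], ":",
                      format(d, trim = TRUE))
        writeLines(paste(c(snps$chrom[j], snps$pos[j], colnames(dos)[j],
            snps$oa[j], snps$ea[j], ".", "PASS", ".", "GT:DS", fld),
            collapse = "\t"), con)
    }
}

.writeGtf <- function(gr, path) {
    gid <- S4Vectors::mcols(gr)$gene_id
    lines <- sprintf(
        "%s\ttwinGxE\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; exon_id \"%s\";",
        as.character(seqnames(gr)), start(gr), end(gr),
        as.character(strand(gr)), gid,
        if (is.null(names(gr))) paste0(gid, "_E", seq_along(gr))
        else names(gr))
    writeLines(lines, path)
}

# ---- readers -------------------------------------------------------------

#' Read genotype dosages from a dosage TSV or a VCF
#'
#' The dosage TSV dialect has SNPs as rows, a header row, columns
#' \code{snp_id}, \code{chrom}, \code{pos}, \code{ea}, \code{oa} followed
#' by one column per sample, and \code{.} for missing. VCF (4.x) input
#' uses the DS FORMAT field when present, otherwise dosages are derived
#' from GT as alternate-allele counts.
#'
#' @param path file path (\code{.vcf}/\code{.vcf.gz} triggers VCF
#'   parsing).
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
readGenotypes <- function(path) {
    if (grepl("\\.vcf(\\.gz)?$", path)) return(.readVcfDosages(path))
    dt <- fread(path, sep = "\t", na.strings = ".")
    meta <- c("snp_id", "chrom", "pos", "ea", "oa")
    stopifnot(all(meta %in% colnames(dt)))
    sampleCols <- setdiff(colnames(dt), meta)
    dos <- t(as.matrix(dt[, sampleCols, with = FALSE]))
    dimnames(dos) <- list(sampleCols, dt$snp_id)
    GenotypeMatrix(dos, data.frame(chrom = dt$chrom, pos = dt$pos,
                                   ea = dt$ea, oa = dt$oa))
}

.readVcfDosages <- function(path) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fx <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    ds <- suppressWarnings(vcfR::extract.gt(v, element = "DS",
                                            as.numeric = TRUE))
    if (is.null(ds) || all(is.na(ds))) {
        gt <- vcfR::extract.gt(v, element = "GT")
        ds <- matrix(vapply(gsub("\\|", "/", gt), function(g) {
            if (is.na(g)) return(NA_real_)
            sum(as.numeric(strsplit(g, "/")[[1]]))
        }, 0), nrow(gt), ncol(gt), dimnames = dimnames(gt))
    }
    dos <- t(ds)
    colnames(dos) <- fx$ID
    GenotypeMatrix(dos, data.frame(chrom = fx$CHROM,
        pos = as.integer(fx$POS), ea = fx$ALT, oa = fx$REF))
}

#' Read an expression counts TSV
#'
#' @param path TSV with a \code{meta_exon_id} column followed by one
#'   column per sample.
#' @param state processing-state flag to attach (default \code{"raw"}).
#' @return matrix (meta-exons x samples) with a \code{state} attribute.
#' @export
readCounts <- function(path, state = "raw") {
    dt <- fread(path, sep = "\t")
    stopifnot("meta_exon_id" %in% colnames(dt))
    m <- as.matrix(dt[, -"meta_exon_id"])
    rownames(m) <- dt$meta_exon_id
    attr(m, "state") <- state
    m
}

#' Read exon annotation (GTF or BED) as a GRanges
#'
#' GTF is read 1-based inclusive (native); BED is converted from 0-based
#' half-open by the importer. A \code{gene_id} column is required (for
#' BED, the \code{name} field is taken as \code{<gene_id>} or
#' \code{<gene_id>_E<k>}).
#'
#' @param path annotation file path.
#' @return \code{GRanges} with a \code{gene_id} metadata column.
#' @export
readAnnotation <- function(path) {
    if (grepl("\\.bed$", path)) {
        gr <- rtracklayer::import(path, format = "BED")
        S4Vectors::mcols(gr)$gene_id <- sub("_E\\d+$", "", gr$name)
        return(gr)
    }
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[is.na(gr$type) | gr$type == "exon"]
    if (is.null(S4Vectors::mcols(gr)$gene_id))
        stop("GTF lacks gene_id attributes")
    gr
}

#' Load and align all pipeline inputs
#'
#' Reads genotypes, expression counts, sample metadata and annotation,
#' intersects the sample sets (dropping and logging non-overlapping
#' samples) and returns containers aligned in deterministic
#' (lexicographic) sample order.
#'
#' @param genotypes,counts,metadata,annotation file paths.
#' @param countState state flag of the counts file (default
#'   \code{"raw"}).
#' @return list: \code{geno} (\linkS4class{GenotypeMatrix}), \code{se}
#'   (expression \code{SummarizedExperiment} with meta-exon rowRanges),
#'   \code{metadata} (data.frame), \code{metaExons}.
#' @export
loadInputs <- function(genotypes, counts, metadata, annotation,
                       countState = "raw") {
    geno <- readGenotypes(genotypes)
    x <- readCounts(counts, state = countState)
    md <- as.data.frame(fread(metadata, sep = "\t"))
    if (anyDuplicated(md$sample_id)) stop("duplicate sample IDs in metadata")
    ann <- readAnnotation(annotation)
    metaExons <- mergeMetaExons(ann)

    ids <- sort(Reduce(intersect,
                       list(rownames(dosages(geno)), colnames(x),
                            md$sample_id)))
    dropped <- setdiff(union(union(rownames(dosages(geno)), colnames(x)),
                             md$sample_id), ids)
    if (length(dropped))
        message("loadInputs: dropping ", length(dropped),
                " samples absent from at least one input: ",
                paste(head(dropped, 5), collapse = ", "),
                if (length(dropped) > 5) ", ...")
    if (length(ids) < 20)
        stop("fewer than 20 samples overlap across inputs")

    x <- x[, ids, drop = FALSE]
    common <- intersect(rownames(x), names(metaExons))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(expr = x[common, , drop = FALSE]),
        rowRanges = metaExons[common])
    S4Vectors::metadata(se)$state <- countState
    list(geno = GenotypeMatrix(
             dosages(geno)[ids, , drop = FALSE],
             as.data.frame(snpInfo(geno))),
         se = se,
         metadata = md[match(ids, md$sample_id), , drop = FALSE],
         metaExons = metaExons)
}
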