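#' Pipeline configuration
#'
#' Assembles and validates all parameters of the end-to-end scan.
#' Unknown keys are rejected. Paths may be NULL when the pipeline is run
#' on an in-memory \linkS4class{TwinCohort}.
#'
#' @param genotypes,counts,metadata,annotation input file paths (or
#'   NULL).
#' @param outDir output directory for result tables and the manifest
#'   (NULL = in-memory only).
#' @param phenotype phenotype column name (e.g. \code{"phenotype"},
#'   holding BMI or visceral fat).
#' @param tissue tissue label recorded in outputs.
#' @param windowBp cis window (default 1 Mb).
#' @param minDistanceBp trans exclusion distance (default 5 Mb).
#' @param k number of latent factors (default 50; capped below the
#'   matrix dimensions at run time).
#' @param nPerm permutations for the FDR (default 100).
#' @param fdrLevel FDR significance level (default 0.05).
#' @param excludeCorrThreshold optional |r| threshold for dropping
#'   phenotype-correlated latent factors before cis residualization.
#' @param stages character subset of
#'   \code{c("association", "cis", "trans", "mediation")} to run.
#' @param seed integer seed.
#' @return validated list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(genotypes = NULL, counts = NULL,
        metadata = NULL, annotation = NULL, outDir = NULL,
        phenotype = "phenotype", tissue = "tissue",
        windowBp = 1e6, minDistanceBp = 5e6, k = 50, nPerm = 100,
        fdrLevel = 0.05, excludeCorrThreshold = NULL,
        stages = c("association", "cis", "trans", "mediation"),
        seed = 1L) {
    stages <- match.arg(stages, several.ok = TRUE)
    stopifnot(windowBp > 0, minDistanceBp > 0, k >= 1, nPerm >= 20,
              fdrLevel > 0, fdrLevel < 1)
    cfg <- list(genotypes = genotypes, counts = counts,
                metadata = metadata, annotation = annotation,
                outDir = outDir, phenotype = phenotype, tissue = tissue,
                windowBp = windowBp, minDistanceBp = minDistanceBp,
                k = k, nPerm = nPerm, fdrLevel = fdrLevel,
                excludeCorrThreshold = excludeCorrThreshold,
                stages = stages, seed = as.integer(seed))
    class(cfg) <- "PipelineConfig"
    cfg
}

#' Read a pipeline configuration from YAML
#'
#' Keys map one-to-one onto \code{\link{pipelineConfig}} arguments;
#' unknown keys are an error.
#'
#' @param path YAML file path.
#' @return A \code{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
    y <- yaml::read_yaml(path)
    unknown <- setdiff(names(y), names(formals(pipelineConfig)))
    if (length(unknown))
        stop("unknown configuration keys: ",
             paste(unknown, collapse = ", "))
    do.call(pipelineConfig, y)
}

.md5obj <- function(x) {
    f <- tempfile()
    on.exit(unlink(f))
    saveRDS(x, f, version = 2, compress = FALSE)
    unname(tools::md5sum(f))
}

#' Run the full interaction-discovery pipeline
#'
#' Executes, in order: quantification (depth normalization, expression
#' filtering, inverse normal transformation, when starting from raw
#' counts); family/technical residualization (the "direct" branch, used
#' for phenotype association and everything trans); latent-factor
#' estimation and residualization (the "factor-corrected" branch, used
#' for the cis interaction scan); the transcriptome-wide phenotype
#' association; the cis scan with permutation FDR; the two-step trans
#' scan seeded by significant cis variants from the non-factor-corrected
#' branch; and Sobel mediation of trans hits through their cis mediator
#' gene. Latent-factor correction is deliberately confined to the cis
#' branch: broad trans-acting variance is exactly what the factors
#' absorb.
#'
#' @param config A \code{\link{pipelineConfig}}.
#' @param cohort optional in-memory \linkS4class{TwinCohort}; when NULL,
#'   inputs are loaded from the config paths.
#' @return list of class \code{PipelineResults}: \code{association},
#'   \code{cis}, \code{cisFdr}, \code{transSeeds}, \code{trans},
#'   \code{mediation}, \code{factors}, \code{manifest}. Each result
#'   table carries the manifest hash as attribute
#'   \code{"manifest_hash"}. When \code{outDir} is set, tables are also
#'   written as TSV together with \code{manifest.json}.
#' @export
runPipeline <- function(config, cohort = NULL) {
    stopifnot(inherits(config, "PipelineConfig"))
    stageLog <- list()
    note <- function(stage, ...) {
        msg <- sprintf(...)
        message(sprintf("[%s] %s", stage, msg))
        stageLog[[stage]] <<- c(stageLog[[stage]], msg)
    }
    run <- function(stage, expr) {
        tryCatch(expr, error = function(e)
            stop(sprintf("stage '%s' failed: %s", stage,
                         conditionMessage(e)), call. = FALSE))
    }
    checksums <- list()
    if (is.null(cohort)) {
        inp <- run("load", loadInputs(config$genotypes, config$counts,
                                      config$metadata, config$annotation))
        geno <- inp$geno; se <- inp$se; md <- inp$metadata
        checksums <- lapply(c(genotypes = config$genotypes,
                              counts = config$counts,
                              metadata = config$metadata,
                              annotation = config$annotation),
                            function(p) unname(tools::md5sum(p)))
    } else {
        geno <- genotypes(cohort)
        se <- expressionData(cohort)
        md <- as.data.frame(sampleData(cohort))
        checksums <- list(cohort = .md5obj(cohort))
    }
    phen <- config$phenotype
    if (!phen %in% colnames(md) && phen == "phenotype")
        stop("metadata lacks a 'phenotype' column")

    # --- quantification -------------------------------------------------
    if (expressionState(se) == "raw") {
        se <- run("quantify", {
            se <- normalizeDepth(se, md$well_mapped_reads)
            se <- filterExpressed(se)
            transformToNormal(se)
        })
        note("quantify", "%d meta-exons after filtering", nrow(se))
    } else if (expressionState(se) == "filtered") {
        se <- run("quantify", transformToNormal(se))
    }
    intSe <- se

    # --- residual branches ----------------------------------------------
    tech <- intersect(c("gc_content", "insert_mode", "primer_index",
                        "batch"), colnames(md))
    directSe <- run("residuals", {
        r <- familyResiduals(intSe, md)
        if (length(tech)) r <- residualize(r, md[, tech, drop = FALSE])
        r
    })
    note("residuals", "family + %d technical covariates removed",
         length(tech))

    results <- list()
    manifestHash <- NULL
    kUse <- min(config$k, nrow(directSe) - 1L, ncol(directSe) - 1L)
    factors <- run("factors", estimateLatentFactors(directSe, k = kUse,
        phenotype = md[[phen]]))
    note("factors", "k = %d, max |factor-phenotype r| = %.2f", kUse,
         if (nrow(factors@phenotypeCorr))
             max(abs(factors@phenotypeCorr$r)) else NA)
    cisSe <- run("factors", residualize(directSe, factors = factors,
        excludeCorrThreshold = config$excludeCorrThreshold,
        phenotype = md[[phen]]))

    if ("association" %in% config$stages) {
        results$association <- run("association",
            transcriptomeScan(intSe, md, phenotype = phen,
                              fdrLevel = config$fdrLevel))
        note("association", "%d/%d genes associated at q <= %.2f",
             sum(results$association$genes$associated),
             nrow(results$association$genes), config$fdrLevel)
    }

    if ("cis" %in% config$stages) {
        results$cis <- run("cis", cisInteractionScan(cisSe, geno, md,
            phenotype = phen, windowBp = config$windowBp))
        results$cisFdr <- run("cis", permutationFdr(results$cis, cisSe,
            geno, md, phenotype = phen, nPerm = config$nPerm,
            fdrLevel = config$fdrLevel, seed = config$seed))
        note("cis", "%d pairs tested, %d significant at FDR < %.2f",
             nrow(results$cis), sum(results$cisFdr$results$significant),
             config$fdrLevel)
    }

    if ("trans" %in% config$stages) {
        step1 <- run("trans", cisInteractionScan(directSe, geno, md,
            phenotype = phen, windowBp = config$windowBp))
        step1Fdr <- run("trans", permutationFdr(step1, directSe, geno,
            md, phenotype = phen, nPerm = config$nPerm,
            fdrLevel = config$fdrLevel, seed = config$seed + 1L))
        seeds <- unique(step1Fdr$results$snp_id[
            step1Fdr$results$significant])
        results$transSeeds <- step1Fdr$results[
            step1Fdr$results$significant, , drop = FALSE]
        note("trans", "%d seed variants from non-factor-corrected cis scan",
             length(seeds))
        results$trans <- run("trans", if (length(seeds))
            transInteractionScan(seeds, directSe, geno, md,
                phenotype = phen, minDistanceBp = config$minDistanceBp)
            else list(results = NULL, threshold = NA_real_,
                      nVariants = 0L, nExons = nrow(directSe)))
        if (!is.null(results$trans$results))
            note("trans", "%d trans pairs significant at p < %.2e",
                 sum(results$trans$results$significant),
                 results$trans$threshold)
    }

    if ("mediation" %in% config$stages &&
        !is.null(results$trans$results) &&
        any(results$trans$results$significant)) {
        results$mediation <- run("mediation", {
            tr <- results$trans$results[results$trans$results$significant, ]
            x <- .exprAssay(directSe)
            gid <- S4Vectors::mcols(
                SummarizedExperiment::rowRanges(directSe))$gene_id
            rows <- lapply(seq_len(nrow(tr)), function(i) {
                sid <- tr$snp_id[i]
                cisHits <- results$transSeeds[
                    results$transSeeds$snp_id == sid, ]
                medGene <- cisHits$gene_id[which.min(cisHits$p_interaction)]
                if (medGene == tr$gene_id[i]) return(NULL)
                E <- colMeans(x[gid == medGene, , drop = FALSE])
                cbind(data.frame(snp_id = sid,
                    mediator_gene = medGene, trans_gene = tr$gene_id[i],
                    meta_exon_id = tr$meta_exon_id[i]),
                    mediationTest(x[tr$meta_exon_id[i], ], E,
                        dosages(geno)[colnames(x), sid],
                        md[[phen]], md$age))
            })
            do.call(rbind, rows)
        })
        if (!is.null(results$mediation))
            note("mediation", "%d/%d trans hits mediated at Sobel p <= 0.001",
                 sum(results$mediation$mediated), nrow(results$mediation))
    }

    manifest <- list(package = "twinGxE",
        version = as.character(packageVersion("twinGxE")),
        tissue = config$tissue, phenotype = phen,
        parameters = config[c("windowBp", "minDistanceBp", "k", "nPerm",
                              "fdrLevel", "excludeCorrThreshold")],
        seed = config$seed, stages = config$stages,
        skipped = setdiff(c("association", "cis", "trans", "mediation"),
                          config$stages),
        n_samples = ncol(intSe), n_meta_exons = nrow(intSe),
        n_snps = ncol(dosages(geno)),
        input_checksums = checksums, log = stageLog)
    manifestHash <- .md5obj(manifest)
    manifest$hash <- manifestHash
    results$manifest <- manifest
    for (nm in setdiff(names(results), "manifest")) {
        if (is.data.frame(results[[nm]]))
            attr(results[[nm]], "manifest_hash") <- manifestHash
        else if (is.list(results[[nm]]) &&
                 is.data.frame(results[[nm]]$results))
            attr(results[[nm]]$results, "manifest_hash") <- manifestHash
    }

    if (!is.null(config$outDir)) {
        dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
        wt <- function(df, nm) if (!is.null(df) && nrow(df))
            fwrite(df, file.path(config$outDir, paste0(nm, ".tsv")),
                   sep = "\t")
        wt(results$association$results, "association")
        wt(if (!is.null(results$cisFdr)) results$cisFdr$results,
           "cis_interactions")
        wt(results$transSeeds, "trans_seed_variants")
        wt(if (!is.null(results$trans)) results$trans$results,
           "trans_interactions")
        wt(results$mediation, "mediation")
        jsonlite::write_json(manifest,
            file.path(config$outDir, "manifest.json"),
            auto_unbox = TRUE, digits = NA, na = "null", force = TRUE)
    }
    class(results) <- "PipelineResults"
    results
}
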