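#' @importFrom tools md5sum
NULL

defaultPipelineParams <- function() {
    list(fdrThreshold = 0.01, nPerm = 1000L, minSize = 5L, maxSize = 500L,
         lossThr = -0.25, gainThr = 0.25, fishThreshold = 50,
         bafWindow = 25L, bafDevThr = 0.15, scoreCenter = "cohort")
}

needArtifact <- function(path, stage) {
    if (!file.exists(path))
        stop("stage '", stage, "' requires missing artifact: ",
             basename(path))
    path
}

writeLongProfiles <- function(grl, path, valueCols) {
    rows <- lapply(names(grl), function(s) {
        g <- grl[[s]]
        df <- data.frame(sample = s,
                         chrom = as.character(GenomicRanges::seqnames(g)),
                         start = GenomicRanges::start(g) - 1L,
                         end = GenomicRanges::end(g))
        for (v in valueCols) df[[v]] <- S4Vectors::mcols(g)[[v]]
        df
    })
    writeTsv(do.call(rbind, rows), path)
}

readLongProfiles <- function(path, valueCols) {
    df <- read.delim(path)
    lapply(split(df, df$sample), function(d) {
        gr <- GenomicRanges::GRanges(d$chrom,
            IRanges::IRanges(start = d$start + 1L, end = d$end))
        for (v in valueCols) S4Vectors::mcols(gr)[[v]] <- d[[v]]
        gr
    })
}

#' Run the full deletion-screening pipeline
#'
#' Orchestrates the stages simulate, diffexp, score, gsea, cnv and fishcall
#' in dependency order from a single configuration, writing every
#' intermediate artifact as plain-text TSV/JSON under `outDir` together
#' with a run manifest (package version, seed, parameters, per-file MD5
#' checksums). Disabled stages read their inputs from artifacts already in
#' `outDir`; a missing upstream artifact raises an error naming the stage.
#' Re-running with the same seed reproduces all artifacts byte-identically.
#'
#' @param config a [CohortConfig-class] (or path to a YAML file accepted by
#'   [readCohortConfig()]).
#' @param outDir output directory (created if absent).
#' @param stages character subset of
#'   `c("simulate", "diffexp", "score", "gsea", "cnv", "fishcall")`.
#' @param seed optional integer overriding the config seed.
#' @param params named list overriding entries of the default parameter
#'   block (FDR threshold, permutation count, set-size bounds, CGH
#'   thresholds, FISH call threshold, BAF window/threshold, score
#'   centering).
#' @return invisibly, the manifest list.
#' @export
#' @examples
#' out <- file.path(tempdir(), "demo_run")
#' cfg <- cohortConfig(nCase = 4, nControl = 6, seed = 11)
#' mf <- runPipeline(cfg, out, stages = c("simulate", "diffexp"),
#'                   params = list(nPerm = 100L))
#' names(mf$files)
runPipeline <- function(config = cohortConfig(), outDir,
                        stages = c("simulate", "diffexp", "score", "gsea",
                                   "cnv", "fishcall"),
                        seed = NULL, params = list()) {
    if (is.character(config)) config <- readCohortConfig(config)
    stopifnot(is(config, "CohortConfig"))
    allStages <- c("simulate", "diffexp", "score", "gsea", "cnv", "fishcall")
    stages <- match.arg(stages, allStages, several.ok = TRUE)
    if (!is.null(seed)) config@seed <- as.integer(seed)
    pp <- defaultPipelineParams()
    pp[names(params)] <- params
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    art <- function(f) file.path(outDir, f)

    if ("simulate" %in% stages) {
        co <- simulateCohort(config)
        writeExpressionTsv(cohortExpression(co), art("expression.tsv"))
        labels <- setNames(co@truth$samples$group, co@truth$samples$sample)
        writeLabelsTsv(labels, art("labels.tsv"))
        writeLongProfiles(cohortCgh(co), art("cgh.tsv"),
                          c("probe", "log2ratio"))
        writeLongProfiles(cohortBaf(co), art("baf.tsv"),
                          c("snp", "baf", "het"))
        writeFishTsv(cohortFish(co), art("fish.tsv"))
        writeTruthJson(co@truth, art("truth.json"))
        writeTsv(co@truth$genes[, c("id", "chrom", "band")] |>
                     (\(d) data.frame(gene = d$id, chrom = d$chrom,
                                      band = d$band))(),
                 art("gene_bands.tsv"))
    }

    if ("diffexp" %in% stages) {
        m <- readExpressionTsv(needArtifact(art("expression.tsv"), "diffexp"))
        labels <- readLabelsTsv(needArtifact(art("labels.tsv"), "diffexp"))
        gs <- moderatedT(m, labels[colnames(m)])
        st <- geneStats(gs)
        bands <- NULL
        if (file.exists(art("gene_bands.tsv")))
            bands <- read.delim(art("gene_bands.tsv"))
        tab <- data.frame(gene = st$gene,
                          band = if (!is.null(bands))
                              bands$band[match(st$gene, bands$gene)]
                          else NA_character_,
                          t = st$t, p = st$p, adjP = st$adjP)
        writeTsv(tab, art("gene_stats.tsv"))
        sig <- selectSignature(gs, pp$fdrThreshold)
        writeTsv(data.frame(gene = signatureGenes(sig),
                            weight = unname(signatureWeights(sig)),
                            referenceMean = unname(referenceMeans(sig))),
                 art("signature.tsv"))
    }

    if ("score" %in% stages) {
        m <- readExpressionTsv(needArtifact(art("expression.tsv"), "score"))
        labels <- readLabelsTsv(needArtifact(art("labels.tsv"), "score"))
        sigTab <- read.delim(needArtifact(art("signature.tsv"), "score"))
        if (nrow(sigTab)) {
            sig <- new("Signature", genes = as.character(sigTab$gene),
                       weights = setNames(sigTab$weight, sigTab$gene),
                       referenceMeans = setNames(sigTab$referenceMean,
                                                 sigTab$gene))
            scores <- scoreSamples(m, sig, center = pp$scoreCenter)
            roc <- rocAuc(scores, labels[names(scores)])
            writeTsv(data.frame(sample = names(scores),
                                score = unname(scores)),
                     art("scores.tsv"))
            writeTsv(roc$curve, art("roc.tsv"))
            jsonlite::write_json(list(auc = roc$auc), art("score_summary.json"),
                                 auto_unbox = TRUE, digits = NA)
        } else {
            writeTsv(data.frame(sample = character(), score = numeric()),
                     art("scores.tsv"))
            jsonlite::write_json(list(auc = NULL), art("score_summary.json"),
                                 auto_unbox = TRUE)
        }
    }

    if ("gsea" %in% stages) {
        st <- read.delim(needArtifact(art("gene_stats.tsv"), "gsea"))
        bands <- read.delim(needArtifact(art("gene_bands.tsv"), "gsea"))
        ranked <- rankGenes(setNames(st$t, st$gene))
        sets <- makeBandSets(bands, genes = names(ranked),
                             minSize = pp$minSize, maxSize = pp$maxSize)
        enr <- prerankedGsea(ranked, sets, nPerm = pp$nPerm,
                             seed = config@seed)
        writeTsv(enr, art("enrichment.tsv"))
    }

    if ("cnv" %in% stages) {
        profiles <- readLongProfiles(needArtifact(art("cgh.tsv"), "cnv"),
                                     c("probe", "log2ratio"))
        labels <- readLabelsTsv(needArtifact(art("labels.tsv"), "cnv"))
        called <- lapply(profiles, callProbes, lossThr = pp$lossThr,
                         gainThr = pp$gainThr)
        callDf <- do.call(rbind, lapply(names(called), function(s) {
            g <- called[[s]]
            data.frame(sample = s,
                       chrom = as.character(GenomicRanges::seqnames(g)),
                       start = GenomicRanges::start(g) - 1L,
                       end = GenomicRanges::end(g), probe = g$probe,
                       log2ratio = g$log2ratio, call = as.character(g$call))
        }))
        writeTsv(callDf, art("cgh_calls.tsv"))
        for (grp in unique(labels)) {
            inGrp <- names(called)[labels[names(called)] == grp]
            fr <- cumulativeFrequency(called[inGrp])
            writeTsv(data.frame(
                chrom = as.character(GenomicRanges::seqnames(fr)),
                start = GenomicRanges::start(fr) - 1L,
                end = GenomicRanges::end(fr), probe = fr$probe,
                gainFreq = fr$gainFreq, lossFreq = fr$lossFreq),
                art(paste0("frequency_", grp, ".tsv")))
        }
        caseProfiles <- called[names(called)[
            labels[names(called)] == "BRCA2"]]
        if (length(caseProfiles)) {
            cro <- commonRegionOverlap(caseProfiles)
            writeRegionsTsv(cro, art("common_regions.tsv"))
        }
        if (file.exists(art("baf.tsv"))) {
            bafs <- readLongProfiles(art("baf.tsv"), c("snp", "baf", "het"))
            bafDf <- do.call(rbind, lapply(names(bafs), function(s) {
                reg <- bafImbalance(bafs[[s]], window = pp$bafWindow,
                                    devThr = pp$bafDevThr)
                if (!length(reg)) return(NULL)
                data.frame(sample = s,
                           chrom = as.character(GenomicRanges::seqnames(reg)),
                           start = GenomicRanges::start(reg) - 1L,
                           end = GenomicRanges::end(reg))
            }))
            if (is.null(bafDf))
                bafDf <- data.frame(sample = character(), chrom = character(),
                                    start = integer(), end = integer())
            writeTsv(bafDf, art("baf_regions.tsv"))
        }
    }

    if ("fishcall" %in% stages) {
        fish <- readFishTsv(needArtifact(art("fish.tsv"), "fishcall"))
        labels <- readLabelsTsv(needArtifact(art("labels.tsv"), "fishcall"))
        calls <- fishDeletionCalls(fish, threshold = pp$fishThreshold)
        writeTsv(calls, art("fish_calls.tsv"))
        scopes <- c(unique(fish$chrom), "both")
        summ <- lapply(scopes, function(sc) {
            tab <- buildContingency(calls, labels, scope = sc)
            dm <- diagnosticMetrics(tab)
            list(scope = sc, table = as.vector(tab),
                 p = fisherExactTwoSided(tab),
                 sensitivity = dm$sensitivity,
                 specificity = dm$specificity)
        })
        names(summ) <- scopes
        jsonlite::write_json(summ, art("fish_summary.json"),
                             auto_unbox = TRUE, digits = NA)
    }

    files <- list.files(outDir, full.names = TRUE)
    files <- files[basename(files) != "manifest.json"]
    manifest <- list(
        package = "brca2del",
        version = as.character(utils::packageVersion("brca2del")),
        seed = config@seed,
        stages = stages,
        params = pp,
        files = as.list(setNames(unname(md5sum(files)), basename(files))))
    jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE)
    invisible(manifest)
}
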