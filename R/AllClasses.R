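#' @import methods
NULL

#' Configuration of a synthetic two-group cohort
#'
#' Describes the genome layout (ordered cytogenetic bands with gene, CGH-probe
#' and SNP counts per band), the deletion architecture (contiguous band spans
#' carried by case tumors with a given penetrance), the biological and
#' technical effect sizes, and the per-modality assay parameters used by
#' [simulateCohort()].
#'
#' @slot nCase,nControl number of case (BRCA2-like) and control (BRCAX-like)
#'   samples.
#' @slot genome `data.frame` with columns `chrom`, `band`, `nGenes`,
#'   `nProbes`, `nSnps`; row order defines genomic order within a chromosome.
#' @slot deletedRegions `data.frame` with columns `chrom`, `bandStart`,
#'   `bandEnd` naming contiguous band spans lost hemizygously in carrier
#'   tumors.
#' @slot penetrance probability that a case tumor carries each deleted
#'   region.
#' @slot tumorFractionRange interval in (0, 1] from which each sample's
#'   tumor-cell fraction is drawn uniformly.
#' @slot exprEffect expected log2 expression shift for a fully hemizygous
#'   gene at tumor fraction 1 (negative for loss).
#' @slot exprNoiseSd,cghNoiseSd,bafNoiseSd Gaussian noise SDs on the log2
#'   expression, log2-ratio and BAF scales.
#' @slot fishNucleiPerSample nuclei scored per sample and chromosome.
#' @slot fishDetectionEff probability that a true probe copy yields a visible
#'   spot.
#' @slot seed integer seed; one global stream is split per modality in the
#'   documented order expression, CGH, BAF, FISH.
#'
#' @seealso [cohortConfig()] for the validated constructor.
#' @export
setClass("CohortConfig",
    representation(
        nCase = "integer",
        nControl = "integer",
        genome = "data.frame",
        deletedRegions = "data.frame",
        penetrance = "numeric",
        tumorFractionRange = "numeric",
        exprEffect = "numeric",
        exprNoiseSd = "numeric",
        cghNoiseSd = "numeric",
        bafNoiseSd = "numeric",
        fishNucleiPerSample = "integer",
        fishDetectionEff = "numeric",
        seed = "integer"
    )
)

setValidity("CohortConfig", function(object) {
    msg <- character()
    num <- c(penetrance = object@penetrance,
             exprEffect = object@exprEffect,
             exprNoiseSd = object@exprNoiseSd,
             cghNoiseSd = object@cghNoiseSd,
             bafNoiseSd = object@bafNoiseSd,
             fishDetectionEff = object@fishDetectionEff,
             tumorFractionRange = object@tumorFractionRange)
    if (any(!is.finite(num)))
        msg <- c(msg, "all numeric configuration values must be finite")
    if (object@nCase < 1L || object@nControl < 1L)
        msg <- c(msg, "nCase and nControl must be >= 1")
    if (object@penetrance < 0 || object@penetrance > 1)
        msg <- c(msg, "penetrance must lie in [0, 1]")
    tfr <- object@tumorFractionRange
    if (length(tfr) != 2L || any(tfr <= 0) || any(tfr > 1) || tfr[1] > tfr[2])
        msg <- c(msg, "tumorFractionRange must be an interval within (0, 1]")
    if (object@exprNoiseSd < 0 || object@cghNoiseSd < 0 ||
        object@bafNoiseSd < 0)
        msg <- c(msg, "noise SDs must be >= 0")
    if (object@fishDetectionEff <= 0 || object@fishDetectionEff > 1)
        msg <- c(msg, "fishDetectionEff must lie in (0, 1]")
    if (object@fishNucleiPerSample < 1L)
        msg <- c(msg, "fishNucleiPerSample must be >= 1")
    need <- c("chrom", "band", "nGenes", "nProbes", "nSnps")
    if (!all(need %in% names(object@genome)))
        msg <- c(msg, "genome must have columns chrom, band, nGenes, nProbes, nSnps")
    else if (anyDuplicated(object@genome$band))
        msg <- c(msg, "genome band labels must be unique")
    needDel <- c("chrom", "bandStart", "bandEnd")
    if (!all(needDel %in% names(object@deletedRegions)))
        msg <- c(msg, "deletedRegions must have columns chrom, bandStart, bandEnd")
    else if (all(need %in% names(object@genome))) {
        known <- object@genome$band
        bad <- !(object@deletedRegions$bandStart %in% known) |
            !(object@deletedRegions$bandEnd %in% known)
        if (any(bad))
            msg <- c(msg, "deletedRegions refer to bands absent from the genome")
    }
    if (length(msg)) msg else TRUE
})

#' Synthetic cohort with multi-modality assays and ground truth
#'
#' Container returned by [simulateCohort()] bundling the expression
#' SummarizedExperiment, per-sample CGH probe profiles and BAF tracks
#' (GRangesList), per-nucleus FISH spot counts, the generating configuration
#' and the ground truth (per-sample tumor fraction and carried deletions,
#' per-gene tumor-cell copy number, true region boundaries).
#'
#' @slot expression [SummarizedExperiment::SummarizedExperiment] of log2
#'   intensities with `rowData` gene annotation and `colData` group labels.
#' @slot cgh,baf `GRangesList` keyed by sample.
#' @slot fish `data.frame` with columns `sample`, `chrom`, `nucleus`,
#'   `green`, `red`.
#' @slot truth list; see [cohortTruth()].
#' @slot config the generating [CohortConfig-class].
#' @export
setClass("SyntheticCohort",
    representation(
        expression = "ANY",
        cgh = "ANY",
        baf = "ANY",
        fish = "data.frame",
        truth = "list",
        config = "CohortConfig"
    )
)

#' Per-gene moderated two-group test statistics
#'
#' Result of [moderatedT()]: per-gene group means, pooled residual variance
#' with its degrees of freedom, the empirical-Bayes posterior variance, the
#' moderated t-statistic and raw/BH-adjusted two-sided p-values, plus the
#' fitted prior degrees of freedom `d0` and prior variance `s02` shared
#' across genes.
#'
#' @slot stats `data.frame` with one row per gene (columns `gene`,
#'   `meanCase`, `meanControl`, `meanAll`, `s2`, `df`, `s2Post`, `t`, `p`,
#'   `adjP`, `zeroVar`).
#' @slot d0 prior degrees of freedom (may be `Inf`).
#' @slot s02 prior variance.
#' @slot nCase,nControl group sizes.
#' @export
setClass("GeneStats",
    representation(
        stats = "data.frame",
        d0 = "numeric",
        s02 = "numeric",
        nCase = "integer",
        nControl = "integer"
    )
)

setValidity("GeneStats", function(object) {
    st <- object@stats
    need <- c("gene", "meanCase", "meanControl", "meanAll", "s2", "df",
              "s2Post", "t", "p", "adjP", "zeroVar")
    if (!all(need %in% names(st)))
        return(paste("stats must contain columns:", paste(need, collapse = ", ")))
    if (any(st$adjP < st$p - 1e-12, na.rm = TRUE))
        return("adjusted p-values must not be smaller than raw p-values")
    TRUE
})

#' Weighted gene-expression signature
#'
#' A set of discriminating genes with their moderated-t weights and the
#' per-gene centering means of the cohort in which they were discovered
#' (used to freeze training-set centering when scoring a validation cohort).
#'
#' @slot genes character vector of unique gene identifiers, ordered by
#'   adjusted p then decreasing |t|.
#' @slot weights named numeric weights (the moderated t-statistics).
#' @slot referenceMeans named numeric per-gene centering means.
#' @export
setClass("Signature",
    representation(
        genes = "character",
        weights = "numeric",
        referenceMeans = "numeric"
    )
)

setValidity("Signature", function(object) {
    if (anyDuplicated(object@genes))
        return("signature genes must be unique")
    if (length(object@weights) != length(object@genes) ||
        length(object@referenceMeans) != length(object@genes))
        return("weights and referenceMeans must match genes in length")
    if (length(object@weights) && any(!is.finite(object@weights)))
        return("weights must be finite")
    if (length(object@referenceMeans) && any(!is.finite(object@referenceMeans)))
        return("referenceMeans must be finite")
    TRUE
})

setMethod("show", "CohortConfig", function(object) {
    cat("CohortConfig:", object@nCase, "case +", object@nControl,
        "control samples\n")
    cat("  genome: ", nrow(object@genome), " bands on ",
        length(unique(object@genome$chrom)), " chromosomes (",
        sum(object@genome$nGenes), " genes, ", sum(object@genome$nProbes),
        " CGH probes, ", sum(object@genome$nSnps), " SNPs)\n", sep = "")
    if (nrow(object@deletedRegions)) {
        spans <- paste0(object@deletedRegions$bandStart, "-",
                        object@deletedRegions$bandEnd)
        cat("  deleted regions:", paste(spans, collapse = ", "),
            sprintf("(penetrance %.2f)\n", object@penetrance))
    } else cat("  deleted regions: none\n")
    cat(sprintf("  tumor fraction U[%.2f, %.2f]; expr effect %.2f (sd %.2f); cgh sd %.2f; baf sd %.3f\n",
        object@tumorFractionRange[1], object@tumorFractionRange[2],
        object@exprEffect, object@exprNoiseSd, object@cghNoiseSd,
        object@bafNoiseSd))
    cat(sprintf("  FISH: %d nuclei/sample, detection eff %.2f; seed %d\n",
        object@fishNucleiPerSample, object@fishDetectionEff, object@seed))
})

setMethod("show", "SyntheticCohort", function(object) {
    se <- object@expression
    cat("SyntheticCohort:", ncol(se), "samples,", nrow(se), "genes\n")
    cat("  modalities: expression, CGH (", length(object@cgh),
        " profiles), BAF (", length(object@baf), " tracks), FISH (",
        nrow(object@fish), " nuclei rows)\n", sep = "")
})

setMethod("show", "GeneStats", function(object) {
    cat("GeneStats for", nrow(object@stats), "genes (",
        object@nCase, "case vs", object@nControl, "control)\n")
    cat(sprintf("  prior df d0 = %s, prior variance s0^2 = %.4g\n",
        format(object@d0, digits = 4), object@s02))
    cat("  genes at BH-adjusted p < 0.01:",
        sum(object@stats$adjP < 0.01, na.rm = TRUE), "\n")
})

setMethod("show", "Signature", function(object) {
    cat("Signature of", length(object@genes), "genes\n")
    if (length(object@genes)) {
        neg <- sum(object@weights < 0)
        cat("  ", neg, " negative-weight (reduced-expression) genes\n",
            sep = "")
    }
})
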