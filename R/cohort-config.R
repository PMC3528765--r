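#' Default synthetic genome layout
#'
#' A compact karyotype of 26 cytogenetic bands emulating the chromosomes that
#' matter for a 13q/14q deletion study: the full long arms of chromosomes 13
#' and 14 at band resolution, plus unaffected bands from chromosomes 1, 4, 17
#' and 19 serving as the enrichment background. Each band carries genes, CGH
#' probes and SNPs; bands are laid out consecutively at 10 Mb per band.
#'
#' @return `data.frame` with columns `chrom`, `band`, `nGenes`, `nProbes`,
#'   `nSnps`.
#' @export
#' @examples
#' head(defaultGenome())
defaultGenome <- function() {
    band <- function(chrom, bands, nGenes = 15L) {
        data.frame(chrom = chrom, band = bands, nGenes = nGenes,
                   nProbes = 8L, nSnps = 40L)
    }
    rbind(
        band("chr1", c("1p36", "1p13", "1q21", "1q32")),
        band("chr4", c("4p16", "4q12", "4q35")),
        band("chr13", c("13q12", "13q13", "13q14", "13q21", "13q22",
                        "13q31", "13q34"),
             nGenes = c(15L, 15L, 20L, 15L, 15L, 15L, 15L)),
        band("chr14", c("14q11", "14q21", "14q23", "14q24", "14q31",
                        "14q32"),
             nGenes = c(15L, 15L, 15L, 20L, 15L, 20L)),
        band("chr17", c("17p13", "17p11", "17q21", "17q25")),
        band("chr19", c("19p13", "19q13"))
    )
}

#' Default deleted regions
#'
#' The contiguous band spans hemizygously lost in carrier case tumors,
#' emulating common 13q and 14q deletion regions.
#'
#' @return `data.frame` with columns `chrom`, `bandStart`, `bandEnd`.
#' @export
defaultDeletedRegions <- function() {
    data.frame(chrom = c("chr13", "chr14"),
               bandStart = c("13q13", "14q24"),
               bandEnd = c("13q14", "14q32"))
}

#' Construct a validated synthetic-cohort configuration
#'
#' Defaults follow the training-cohort design of a familial breast-tumor
#' study: 7 case (BRCA2-like) versus 24 control (BRCAX-like) tumors, tumor
#' cell fractions spread uniformly over 50--95%, and hemizygous deletions of
#' 13q13--13q14 and 14q24--14q32 carried by every case tumor. The expression
#' effect of a fully hemizygous gene defaults to -0.7 log2 units
#' (hemizygosity under partial dosage compensation).
#'
#' @param nCase,nControl group sizes.
#' @param genome band table, see [defaultGenome()].
#' @param deletedRegions band spans, see [defaultDeletedRegions()].
#' @param penetrance probability a case tumor carries each deleted region.
#' @param tumorFractionRange length-2 interval in (0, 1].
#' @param exprEffect log2 expression shift for a hemizygous gene at tumor
#'   fraction 1.
#' @param exprNoiseSd,cghNoiseSd,bafNoiseSd Gaussian noise SDs.
#' @param fishNucleiPerSample nuclei scored per sample and chromosome.
#' @param fishDetectionEff per-copy spot detection probability in (0, 1].
#' @param seed integer seed.
#' @return a [CohortConfig-class] object.
#' @export
#' @examples
#' cfg <- cohortConfig(seed = 1)
#' cfg
cohortConfig <- function(nCase = 7L, nControl = 24L,
                         genome = defaultGenome(),
                         deletedRegions = defaultDeletedRegions(),
                         penetrance = 1,
                         tumorFractionRange = c(0.5, 0.95),
                         exprEffect = -0.7,
                         exprNoiseSd = 0.3,
                         cghNoiseSd = 0.1,
                         bafNoiseSd = 0.04,
                         fishNucleiPerSample = 100L,
                         fishDetectionEff = 0.95,
                         seed = 1L) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    new("CohortConfig",
        nCase = as.integer(nCase), nControl = as.integer(nControl),
        genome = as.data.frame(genome),
        deletedRegions = as.data.frame(deletedRegions),
        penetrance = as.numeric(penetrance),
        tumorFractionRange = as.numeric(tumorFractionRange),
        exprEffect = as.numeric(exprEffect),
        exprNoiseSd = as.numeric(exprNoiseSd),
        cghNoiseSd = as.numeric(cghNoiseSd),
        bafNoiseSd = as.numeric(bafNoiseSd),
        fishNucleiPerSample = as.integer(fishNucleiPerSample),
        fishDetectionEff = as.numeric(fishDetectionEff),
        seed = as.integer(seed))
}

#' Read a cohort configuration from a YAML file
#'
#' Flat keys map 1:1 to [cohortConfig()] arguments; `genome` and
#' `deletedRegions` are given as lists of records with the same column
#' names. Missing keys fall back to the defaults.
#'
#' @param path path to a YAML file.
#' @return a [CohortConfig-class] object.
#' @export
readCohortConfig <- function(path) {
    raw <- yaml::read_yaml(path)
    args <- list()
    scalarKeys <- c("nCase", "nControl", "penetrance", "tumorFractionRange",
                    "exprEffect", "exprNoiseSd", "cghNoiseSd", "bafNoiseSd",
                    "fishNucleiPerSample", "fishDetectionEff", "seed")
    for (k in intersect(scalarKeys, names(raw)))
        args[[k]] <- unlist(raw[[k]])
    if (!is.null(raw$genome))
        args$genome <- do.call(rbind, lapply(raw$genome, as.data.frame))
    if (!is.null(raw$deletedRegions))
        args$deletedRegions <- do.call(rbind,
            lapply(raw$deletedRegions, as.data.frame))
    do.call(cohortConfig, args)
}

# Band coordinate layout: bands occupy consecutive 10 Mb blocks per
# chromosome, in genome-table order (0-based half-open).
bandCoordinates <- function(genome, bandWidth = 1e7) {
    out <- do.call(rbind, lapply(split(genome, genome$chrom), function(g) {
        g <- g[order(match(g$band, genome$band)), , drop = FALSE]
        n <- nrow(g)
        data.frame(chrom = g$chrom, band = g$band,
                   start = (seq_len(n) - 1) * bandWidth,
                   end = seq_len(n) * bandWidth)
    }))
    rownames(out) <- NULL
    out[order(match(out$band, genome$band)), , drop = FALSE]
}

# Expand deleted band spans into the set of member band labels.
deletedBandLabels <- function(config) {
    genome <- config@genome
    regions <- config@deletedRegions
    if (!nrow(regions)) return(character())
    unlist(lapply(seq_len(nrow(regions)), function(i) {
        onChrom <- genome$band[genome$chrom == regions$chrom[i]]
        i0 <- match(regions$bandStart[i], onChrom)
        i1 <- match(regions$bandEnd[i], onChrom)
        if (i0 > i1) stop("deleted region bandStart after bandEnd")
        onChrom[i0:i1]
    }))
}
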