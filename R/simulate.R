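#' @importFrom stats rnorm runif rbinom setNames
NULL

# Evaluate expr under a fixed seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (hadSeed) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (hadSeed) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

# One global stream split per data modality in a fixed, documented order
# (truth, expression, cgh, baf, fish), so adding a modality never perturbs
# another's draws.
modalitySeeds <- function(seed) {
    withSeed(seed, setNames(sample.int(.Machine$integer.max - 1L, 5L),
                            c("truth", "expression", "cgh", "baf", "fish")))
}

#' Ground truth of a synthetic cohort
#'
#' Draws the sample-level truth (group label, tumor-cell fraction, carried
#' deletions) and lays out the gene, CGH-probe and SNP maps implied by the
#' genome table. Genes inside a carried deleted region have tumor-cell copy
#' number 1; all others 2.
#'
#' @param config a [CohortConfig-class].
#' @return a list with elements
#'   \describe{
#'     \item{samples}{`data.frame(sample, group, tumorFraction)` with group
#'       in `{BRCA2, BRCAX}` (case/control).}
#'     \item{carried}{logical matrix, samples x deleted regions.}
#'     \item{genes, probes, snps}{feature maps with `chrom`, `band`,
#'       coordinates and a `deleted` flag marking membership in a deleted
#'       band span.}
#'     \item{regions}{[GenomicRanges::GRanges] of the true deleted-region
#'       boundaries.}
#'     \item{deletedBands}{band labels covered by the deleted regions.}
#'   }
#' @export
#' @examples
#' tr <- cohortTruth(cohortConfig(seed = 7))
#' head(tr$samples)
cohortTruth <- function(config) {
    stopifnot(is(config, "CohortConfig"))
    validObject(config)
    seeds <- modalitySeeds(config@seed)
    genome <- config@genome
    coords <- bandCoordinates(genome)
    delBands <- deletedBandLabels(config)

    layoutFeatures <- function(countCol, prefix, width) {
        rows <- lapply(seq_len(nrow(genome)), function(i) {
            n <- genome[[countCol]][i]
            b <- coords[coords$band == genome$band[i], ]
            # features spread evenly inside the band
            starts <- b$start + round((seq_len(n) - 0.5) / n *
                                      (b$end - b$start - width))
            data.frame(chrom = genome$chrom[i], band = genome$band[i],
                       start = starts, end = starts + width)
        })
        out <- do.call(rbind, rows)
        out$id <- sprintf("%s%04d", prefix, seq_len(nrow(out)))
        out$deleted <- out$band %in% delBands
        out[, c("id", "chrom", "band", "start", "end", "deleted")]
    }
    genes <- layoutFeatures("nGenes", "G", 1e4)
    probes <- layoutFeatures("nProbes", "P", 1e5)
    snps <- layoutFeatures("nSnps", "S", 1L)

    nCase <- config@nCase; nControl <- config@nControl
    samples <- data.frame(
        sample = sprintf("S%03d", seq_len(nCase + nControl)),
        group = rep(c("BRCA2", "BRCAX"), c(nCase, nControl)),
        stringsAsFactors = FALSE)
    nRegion <- nrow(config@deletedRegions)
    truthDraws <- withSeed(seeds["truth"], {
        f <- runif(nrow(samples), config@tumorFractionRange[1],
                   config@tumorFractionRange[2])
        carried <- matrix(FALSE, nrow(samples), max(nRegion, 1L))
        if (nRegion > 0L)
            carried[samples$group == "BRCA2", seq_len(nRegion)] <-
                runif(nCase * nRegion) < config@penetrance
        list(f = f, carried = carried[, seq_len(max(nRegion, 0L)),
                                      drop = FALSE])
    })
    samples$tumorFraction <- truthDraws$f
    carried <- truthDraws$carried
    rownames(carried) <- samples$sample
    if (nRegion > 0L)
        colnames(carried) <- paste0(config@deletedRegions$bandStart, "-",
                                    config@deletedRegions$bandEnd)

    regionGr <- GenomicRanges::GRanges()
    if (nRegion > 0L) {
        rs <- vapply(seq_len(nRegion), function(i)
            coords$start[coords$band == config@deletedRegions$bandStart[i]],
            numeric(1))
        re <- vapply(seq_len(nRegion), function(i)
            coords$end[coords$band == config@deletedRegions$bandEnd[i]],
            numeric(1))
        regionGr <- GenomicRanges::GRanges(config@deletedRegions$chrom,
            IRanges::IRanges(start = rs + 1L, end = re))
        names(regionGr) <- colnames(carried)
    }

    list(samples = samples, carried = carried, genes = genes,
         probes = probes, snps = snps, regions = regionGr,
         deletedBands = delBands,
         regionChrom = as.character(config@deletedRegions$chrom))
}

# Feature-by-sample logical matrix: is the feature hemizygously lost in the
# tumor cells of that sample?
lossMatrix <- function(truth, features) {
    carried <- truth$carried
    nRegion <- ncol(carried)
    out <- matrix(FALSE, nrow(features), nrow(truth$samples),
                  dimnames = list(features$id, truth$samples$sample))
    if (is.null(nRegion) || nRegion == 0L) return(out)
    for (r in seq_len(nRegion)) {
        gr <- truth$regions[r]
        inReg <- features$chrom == as.character(GenomicRanges::seqnames(gr)) &
            features$start >= (GenomicRanges::start(gr) - 1L) &
            features$end <= GenomicRanges::end(gr)
        out[inReg, carried[, r]] <- TRUE
    }
    out
}

#' Simulate a log2 expression matrix
#'
#' Gene baselines are drawn once per gene from Normal(7, 1.5) on the log2
#' scale (typical intensity range of RMA-normalized arrays). A gene
#' hemizygously deleted in the tumor cells of sample j is shifted by
#' `f_j * exprEffect`, where `f_j` is the sample's tumor-cell fraction;
#' Gaussian noise with SD `exprNoiseSd` is added everywhere. Deterministic
#' for a fixed config seed.
#'
#' @param config a [CohortConfig-class].
#' @param truth optional precomputed [cohortTruth()]; regenerated from the
#'   config when omitted.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `exprs`, gene annotation in `rowData`, sample annotation (group, tumor
#'   fraction) in `colData`, and the truth list in `metadata(se)$truth`.
#' @export
#' @examples
#' se <- simulateExpression(cohortConfig(nCase = 3, nControl = 3, seed = 1))
#' dim(se)
simulateExpression <- function(config, truth = cohortTruth(config)) {
    seeds <- modalitySeeds(config@seed)
    genes <- truth$genes
    samples <- truth$samples
    del <- lossMatrix(truth, genes)
    x <- withSeed(seeds["expression"], {
        mu <- rnorm(nrow(genes), mean = 7, sd = 1.5)
        shift <- del * rep(samples$tumorFraction, each = nrow(genes)) *
            config@exprEffect
        mu + shift + matrix(rnorm(nrow(genes) * nrow(samples),
                                  sd = config@exprNoiseSd),
                            nrow(genes), nrow(samples))
    })
    dimnames(x) <- list(genes$id, samples$sample)
    SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = x),
        rowData = S4Vectors::DataFrame(genes[, c("chrom", "band", "start",
                                                 "end", "deleted")],
                                       row.names = genes$id),
        colData = S4Vectors::DataFrame(
            group = samples$group,
            tumorFraction = samples$tumorFraction,
            row.names = samples$sample),
        metadata = list(truth = truth))
}

#' Simulate per-sample array-CGH probe profiles
#'
#' Each probe's log2 tumor/normal ratio is
#' `log2((f*c + 2*(1-f)) / 2) + Normal(0, cghNoiseSd)` where `c` is the
#' tumor-cell copy number (1 inside carried deleted regions, else 2) and `f`
#' the tumor-cell fraction, so hemizygous losses are attenuated toward 0 by
#' normal-cell contamination.
#'
#' @inheritParams simulateExpression
#' @return a [GenomicRanges::GRangesList], one genomically ordered probe
#'   profile per sample with mcols `probe` and `log2ratio`.
#' @export
simulateCgh <- function(config, truth = cohortTruth(config)) {
    seeds <- modalitySeeds(config@seed)
    probes <- truth$probes
    samples <- truth$samples
    del <- lossMatrix(truth, probes)
    ratios <- withSeed(seeds["cgh"], {
        cn <- 2 - del   # tumor-cell copies
        f <- rep(samples$tumorFraction, each = nrow(probes))
        log2((f * cn + 2 * (1 - f)) / 2) +
            matrix(rnorm(length(cn), sd = config@cghNoiseSd),
                   nrow(probes), nrow(samples))
    })
    gr0 <- GenomicRanges::GRanges(probes$chrom,
        IRanges::IRanges(start = probes$start + 1L, end = probes$end))
    grl <- lapply(seq_len(nrow(samples)), function(j) {
        g <- gr0
        S4Vectors::mcols(g) <- S4Vectors::DataFrame(
            probe = probes$id, log2ratio = unname(ratios[, j]))
        sort(g)
    })
    names(grl) <- samples$sample
    GenomicRanges::GRangesList(grl)
}

#' Simulate per-sample B-allele frequency tracks
#'
#' Each SNP is heterozygous in the germline with probability `hetRate`.
#' Homozygous SNPs sit at BAF 0 or 1; heterozygous SNPs in copy-neutral
#' regions at 0.5; heterozygous SNPs in a hemizygously deleted region split
#' symmetrically into bands at `1/(2-f)` (B allele retained) and
#' `(1-f)/(2-f)` (B allele lost), the allele-ratio of a one-copy tumor
#' diluted by `1-f` normal cells. Gaussian noise with SD `bafNoiseSd` is
#' added and values clipped to [0, 1].
#'
#' @inheritParams simulateExpression
#' @param hetRate germline heterozygosity rate per SNP.
#' @return a [GenomicRanges::GRangesList], one SNP track per sample with
#'   mcols `snp`, `baf` and the germline truth flag `het`.
#' @export
simulateBaf <- function(config, truth = cohortTruth(config), hetRate = 0.35) {
    seeds <- modalitySeeds(config@seed)
    snps <- truth$snps
    samples <- truth$samples
    del <- lossMatrix(truth, snps)
    nS <- nrow(snps); nJ <- nrow(samples)
    sim <- withSeed(seeds["baf"], {
        het <- matrix(runif(nS * nJ) < hetRate, nS, nJ)
        bLost <- matrix(runif(nS * nJ) < 0.5, nS, nJ)  # which allele lost
        homB <- matrix(runif(nS * nJ) < 0.5, nS, nJ)
        f <- rep(samples$tumorFraction, each = nS)
        baf <- matrix(NA_real_, nS, nJ)
        baf[!het] <- ifelse(homB[!het], 1, 0)
        neutralHet <- het & !del
        baf[neutralHet] <- 0.5
        delHet <- het & del
        a <- ifelse(bLost, 0, 1)
        baf[delHet] <- ((f * a + (1 - f)) / (2 - f))[delHet]
        baf <- baf + matrix(rnorm(nS * nJ, sd = config@bafNoiseSd), nS, nJ)
        list(baf = pmin(pmax(baf, 0), 1), het = het)
    })
    gr0 <- GenomicRanges::GRanges(snps$chrom,
        IRanges::IRanges(start = snps$start + 1L, width = 1L))
    grl <- lapply(seq_len(nJ), function(j) {
        g <- gr0
        S4Vectors::mcols(g) <- S4Vectors::DataFrame(snp = snps$id,
                                                    baf = sim$baf[, j],
                                                    het = sim$het[, j])
        sort(g)
    })
    names(grl) <- samples$sample
    GenomicRanges::GRangesList(grl)
}

#' Simulate two-color FISH spot counts
#'
#' Emulates touch-imprint FISH with a pericentromeric green probe and a red
#' probe inside the commonly deleted region of each assayed chromosome. Each
#' scored nucleus is a tumor cell with probability `f` (the tumor-cell
#' fraction; normal cells contaminate imprints at rate `1-f`). Green spots
#' are Binomial(2, eff); red spots Binomial(c, eff) with c = 1 in tumor
#' cells of samples carrying a deletion on that chromosome, else 2.
#'
#' @inheritParams simulateExpression
#' @param chroms chromosomes assayed; defaults to the chromosomes of the
#'   configured deleted regions.
#' @return `data.frame` with columns `sample`, `chrom`, `nucleus`, `green`,
#'   `red`.
#' @export
simulateFish <- function(config, truth = cohortTruth(config),
                         chroms = unique(truth$regionChrom)) {
    seeds <- modalitySeeds(config@seed)
    samples <- truth$samples
    if (!length(chroms)) chroms <- c("chr13", "chr14")
    nNuc <- config@fishNucleiPerSample
    eff <- config@fishDetectionEff
    carriedOnChrom <- vapply(chroms, function(ch) {
        idx <- which(truth$regionChrom == ch)
        if (!length(idx)) return(rep(FALSE, nrow(samples)))
        as.logical(rowSums(truth$carried[, idx, drop = FALSE]) > 0)
    }, logical(nrow(samples)))
    withSeed(seeds["fish"], {
        rows <- lapply(seq_len(nrow(samples)), function(j) {
            do.call(rbind, lapply(seq_along(chroms), function(k) {
                tumor <- runif(nNuc) < samples$tumorFraction[j]
                cRed <- ifelse(tumor & carriedOnChrom[j, k], 1L, 2L)
                data.frame(sample = samples$sample[j], chrom = chroms[k],
                           nucleus = seq_len(nNuc),
                           green = rbinom(nNuc, 2L, eff),
                           red = rbinom(nNuc, cRed, eff))
            }))
        })
        do.call(rbind, rows)
    })
}

#' Simulate a complete multi-modality cohort
#'
#' Runs [cohortTruth()] once, then the four modality generators on the same
#' truth, each on its own split of the configured RNG stream.
#'
#' @param config a [CohortConfig-class].
#' @return a [SyntheticCohort-class].
#' @export
#' @examples
#' co <- simulateCohort(cohortConfig(nCase = 3, nControl = 4, seed = 2))
#' co
simulateCohort <- function(config) {
    truth <- cohortTruth(config)
    new("SyntheticCohort",
        expression = simulateExpression(config, truth),
        cgh = simulateCgh(config, truth),
        baf = simulateBaf(config, truth),
        fish = simulateFish(config, truth),
        truth = truth,
        config = config)
}

#' Accessors for SyntheticCohort components
#'
#' @param x a [SyntheticCohort-class].
#' @return the corresponding component.
#' @name cohort-accessors
NULL

#' @rdname cohort-accessors
#' @export
cohortExpression <- function(x) x@expression
#' @rdname cohort-accessors
#' @export
cohortCgh <- function(x) x@cgh
#' @rdname cohort-accessors
#' @export
cohortBaf <- function(x) x@baf
#' @rdname cohort-accessors
#' @export
cohortFish <- function(x) x@fish
#' @rdname cohort-accessors
#' @export
cohortTruthOf <- function(x) x@truth
#' @rdname cohort-accessors
#' @export
cohortConfigOf <- function(x) x@config
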