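#' @importFrom GenomicRanges GRanges seqnames start end sort mcols
#' @importFrom S4Vectors mcols<- DataFrame
NULL

checkProfile <- function(profile) {
    if (!is(profile, "GRanges"))
        stop("a probe profile must be a GRanges")
    if (!"log2ratio" %in% names(S4Vectors::mcols(profile)))
        stop("probe profile needs a 'log2ratio' metadata column")
    if (any(!is.finite(profile$log2ratio)))
        stop("log2ratio values must be finite")
    invisible(profile)
}

#' Threshold-based gain/loss calling on probe log2 ratios
#'
#' A probe is called `loss` when its log2 ratio is at or below `lossThr`,
#' `gain` at or above `gainThr`, otherwise `neutral`. The default +/-0.25
#' log2 thresholds are conventional BAC-CGH practice.
#'
#' @param profile [GenomicRanges::GRanges] probe profile with a `log2ratio`
#'   metadata column.
#' @param lossThr,gainThr calling thresholds on the log2-ratio scale.
#' @return the profile with an added factor column `call` in
#'   `{gain, neutral, loss}`.
#' @export
callProbes <- function(profile, lossThr = -0.25, gainThr = 0.25) {
    checkProfile(profile)
    stopifnot(lossThr < gainThr)
    lr <- profile$log2ratio
    call <- rep("neutral", length(lr))
    call[lr <= lossThr] <- "loss"
    call[lr >= gainThr] <- "gain"
    profile$call <- factor(call, levels = c("gain", "neutral", "loss"))
    profile
}

# Validate that all profiles share one probe layout; returns the template.
sharedLayout <- function(profiles) {
    if (!length(profiles)) stop("empty profile group")
    ref <- profiles[[1]]
    for (p in profiles[-1]) {
        if (length(p) != length(ref) ||
            !all(as.character(seqnames(p)) == as.character(seqnames(ref))) ||
            !all(start(p) == start(ref)))
            stop("profiles must share an identical probe layout")
    }
    ref
}

#' Cumulative gain/loss frequencies across a sample group
#'
#' Per probe, the fraction of samples called gain and called loss; for a
#' signed rendering losses are conventionally plotted as negative (a lost
#' fraction of 1 plots at -1, meaning every tumor lost that probe).
#'
#' @param profiles list/GRangesList of called probe profiles sharing one
#'   probe layout (see [callProbes()]).
#' @return GRanges with metadata columns `gainFreq` and `lossFreq`.
#' @export
cumulativeFrequency <- function(profiles) {
    profiles <- as.list(profiles)
    ref <- sharedLayout(profiles)
    calls <- vapply(profiles, function(p) {
        if (!"call" %in% names(S4Vectors::mcols(p)))
            stop("profiles must carry probe calls; run callProbes() first")
        as.character(p$call)
    }, character(length(ref)))
    out <- GRanges(seqnames(ref), IRanges::ranges(ref))
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
        probe = ref$probe,
        gainFreq = rowMeans(calls == "gain"),
        lossFreq = rowMeans(calls == "loss"))
    out
}

#' Common region of overlap of deletions
#'
#' Maximal runs of consecutive probes called `loss` in 100% of the supplied
#' samples, merged into genomic intervals whose bounds are the outermost
#' probe bounds of the run. By default a single non-loss probe breaks a
#' run; `gapTolerance` allows runs separated by at most that many non-loss
#' probes to be bridged.
#'
#' @param profiles list/GRangesList of called probe profiles sharing one
#'   probe layout.
#' @param gapTolerance number of interior non-loss probes tolerated inside
#'   a run (default 0).
#' @return GRanges of the common deletion intervals (possibly empty).
#' @export
commonRegionOverlap <- function(profiles, gapTolerance = 0L) {
    profiles <- as.list(profiles)
    ref <- sharedLayout(profiles)
    lostAll <- Reduce(`&`, lapply(profiles, function(p) {
        if (!"call" %in% names(S4Vectors::mcols(p)))
            stop("profiles must carry probe calls; run callProbes() first")
        as.character(p$call) == "loss"
    }))
    chroms <- as.character(seqnames(ref))
    pieces <- lapply(unique(chroms), function(ch) {
        i <- which(chroms == ch)
        mask <- lostAll[i]
        if (gapTolerance > 0L) {
            # interior non-loss runs short enough to bridge (rle alternates,
            # so interior FALSE runs are flanked by loss runs)
            r <- rle(mask)
            nr <- length(r$lengths)
            bridge <- !r$values & r$lengths <= gapTolerance &
                seq_len(nr) > 1L & seq_len(nr) < nr
            r$values[bridge] <- TRUE
            mask <- inverse.rle(r)
        }
        r <- rle(mask)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        runs <- which(r$values)
        if (!length(runs)) return(NULL)
        data.frame(chrom = ch,
                   start = start(ref)[i[starts[runs]]],
                   end = end(ref)[i[ends[runs]]])
    })
    pieces <- do.call(rbind, pieces)
    if (is.null(pieces)) return(GRanges())
    GRanges(pieces$chrom, IRanges::IRanges(start = pieces$start,
                                           end = pieces$end))
}

#' Flag allelic imbalance from a B-allele frequency track
#'
#' Scans consecutive non-overlapping windows of `window` SNPs per
#' chromosome; a window is flagged when the mean absolute deviation of its
#' heterozygous SNPs' BAF from 0.5 exceeds `devThr`. Adjacent flagged
#' windows are merged into regions bounded by their outermost SNPs. A
#' window larger than a chromosome's track yields a single whole-track
#' decision.
#'
#' Heterozygous SNPs are taken from (in order of preference) the `het`
#' argument, a paired-normal BAF classified by `hetBand`, a `het` metadata
#' column on the track, or a density fallback that treats SNPs with BAF in
#' (0.1, 0.9) as heterozygous. The fallback cannot see pure LOH (tumor
#' fraction 1 pushes hets to 0/1); supply germline het status for that
#' regime.
#'
#' @param baf [GenomicRanges::GRanges] with a `baf` metadata column.
#' @param window window size in SNPs.
#' @param devThr flagging threshold on mean |BAF - 0.5|.
#' @param hetBand baseline BAF interval calling a SNP heterozygous in the
#'   paired normal.
#' @param normalBaf optional numeric baseline BAF per SNP.
#' @param het optional logical vector of germline het status per SNP.
#' @return GRanges of flagged allelic-imbalance regions.
#' @export
bafImbalance <- function(baf, window = 25L, devThr = 0.15,
                         hetBand = c(0.3, 0.7), normalBaf = NULL,
                         het = NULL) {
    stopifnot(is(baf, "GRanges"), "baf" %in% names(S4Vectors::mcols(baf)))
    b <- baf$baf
    if (is.null(het)) {
        het <- if (!is.null(normalBaf))
            normalBaf > hetBand[1] & normalBaf < hetBand[2]
        else if ("het" %in% names(S4Vectors::mcols(baf)))
            baf$het
        else b > 0.1 & b < 0.9
    }
    stopifnot(length(het) == length(baf))
    chroms <- as.character(seqnames(baf))
    pieces <- lapply(unique(chroms), function(ch) {
        i <- which(chroms == ch)
        n <- length(i)
        win <- ceiling(seq_len(n) / window)
        flagged <- vapply(split(seq_len(n), win), function(k) {
            hk <- k[het[i[k]]]
            if (!length(hk)) return(FALSE)
            mean(abs(b[i[hk]] - 0.5)) > devThr
        }, logical(1))
        r <- rle(flagged)
        ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
        runs <- which(r$values)
        if (!length(runs)) return(NULL)
        winIdx <- split(seq_len(n), win)
        data.frame(chrom = ch,
                   start = vapply(runs, function(k)
                       start(baf)[i[winIdx[[starts[k]]][1]]], numeric(1)),
                   end = vapply(runs, function(k) {
                       kk <- winIdx[[ends[k]]]
                       end(baf)[i[kk[length(kk)]]]
                   }, numeric(1)))
    })
    pieces <- do.call(rbind, pieces)
    if (is.null(pieces)) return(GRanges())
    GRanges(pieces$chrom, IRanges::IRanges(start = pieces$start,
                                           end = pieces$end))
}

#' Annotate regions with cytogenetic band spans
#'
#' Maps each interval to the bands it overlaps in a cytoband table (UCSC
#' `cytoBand` dialect), returning the first and last overlapped band.
#'
#' @param regions GRanges of intervals.
#' @param cytoband `data.frame` with columns `chrom`, `start`, `end`,
#'   `band` (0-based half-open, as read by [readCytobandTsv()]).
#' @return `data.frame(chrom, start, end, bandStart, bandEnd)`.
#' @export
annotateBands <- function(regions, cytoband) {
    cb <- GRanges(cytoband$chrom,
                  IRanges::IRanges(start = cytoband$start + 1L,
                                   end = cytoband$end))
    hits <- GenomicRanges::findOverlaps(regions, cb)
    out <- data.frame(chrom = as.character(seqnames(regions)),
                      start = start(regions) - 1L, end = end(regions),
                      bandStart = NA_character_, bandEnd = NA_character_)
    for (i in seq_along(regions)) {
        j <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]
        if (length(j)) {
            out$bandStart[i] <- cytoband$band[min(j)]
            out$bandEnd[i] <- cytoband$band[max(j)]
        }
    }
    out
}
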