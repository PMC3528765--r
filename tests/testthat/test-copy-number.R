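test_that("threshold calling assigns gain, neutral and loss correctly", {
    p <- handProfile(c(0, -1, 0.5, -0.25, 0.25, -0.1))
    called <- callProbes(p)
    expect_equal(as.character(called$call),
                 c("neutral", "loss", "gain", "loss", "gain", "neutral"))
    allZero <- callProbes(handProfile(rep(0, 4)))
    expect_true(all(allZero$call == "neutral"))
    expect_error(callProbes(handProfile(c(0, NA))), "finite")
})

test_that("loss calls are monotone in the loss threshold", {
    set.seed(91)
    p <- handProfile(rnorm(50, sd = 0.4))
    strict <- callProbes(p, lossThr = -0.4)
    relaxed <- callProbes(p, lossThr = -0.15)
    expect_true(all(which(strict$call == "loss") %in%
                    which(relaxed$call == "loss")))
})

test_that("cumulative frequency equals the per-probe column mean", {
    set.seed(92)
    profiles <- lapply(1:6, function(i) callProbes(handProfile(rnorm(30))))
    fr <- cumulativeFrequency(profiles)
    callMat <- sapply(profiles, function(p) as.character(p$call))
    expect_equal(fr$gainFreq, rowMeans(callMat == "gain"))
    expect_equal(fr$lossFreq, rowMeans(callMat == "loss"))
    # a probe lost in every sample reaches fraction 1 (rendered as -1)
    allLost <- lapply(1:4, function(i) callProbes(handProfile(c(-1, 0))))
    expect_equal(cumulativeFrequency(allLost)$lossFreq, c(1, 0))
    expect_error(cumulativeFrequency(list()), "empty")
})

test_that("common region of overlap intersects loss runs across samples", {
    # probes at 1..8; sample A lost probes 2-5, sample B lost 4-7
    a <- callProbes(handProfile(c(0, -1, -1, -1, -1, 0, 0, 0)))
    b <- callProbes(handProfile(c(0, 0, 0, -1, -1, -1, -1, 0)))
    cro <- commonRegionOverlap(list(a, b))
    expect_length(cro, 1)
    expect_equal(GenomicRanges::start(cro), GenomicRanges::start(a)[4])
    expect_equal(GenomicRanges::end(cro), GenomicRanges::end(a)[5])
    # one sample: its loss runs verbatim
    solo <- commonRegionOverlap(list(a))
    expect_equal(GenomicRanges::start(solo), GenomicRanges::start(a)[2])
    expect_equal(GenomicRanges::end(solo), GenomicRanges::end(a)[5])
    # disjoint runs: empty result
    c2 <- callProbes(handProfile(c(-1, 0, 0, 0, 0, 0, 0, -1)))
    expect_length(commonRegionOverlap(list(a, c2)), 0)
})

test_that("adding a sample never grows the common region", {
    set.seed(93)
    for (i in 1:10) {
        profs <- lapply(1:4, function(j)
            callProbes(handProfile(sample(c(-1, 0), 40, replace = TRUE,
                                          prob = c(0.6, 0.4)))))
        base <- commonRegionOverlap(profs[1:3])
        more <- commonRegionOverlap(profs)
        ov <- GenomicRanges::intersect(base, more)
        expect_equal(sum(GenomicRanges::width(more)),
                     sum(GenomicRanges::width(ov)))
    }
})

test_that("a gap tolerance bridges single interrupting probes", {
    a <- callProbes(handProfile(c(-1, -1, 0, -1, -1)))
    expect_length(commonRegionOverlap(list(a)), 2)
    bridged <- commonRegionOverlap(list(a), gapTolerance = 1)
    expect_length(bridged, 1)
    expect_equal(GenomicRanges::start(bridged), 1L)
})

test_that("noise-free simulated calls equal the ground-truth deletion mask", {
    cfg <- smallConfig(cghNoiseSd = 0, tumorFractionRange = c(0.8, 0.8),
                       penetrance = 1)
    tr <- cohortTruth(cfg)
    cgh <- simulateCgh(cfg, tr)
    for (s in tr$samples$sample[tr$samples$group == "BRCA2"][1:2]) {
        called <- callProbes(cgh[[s]])
        truthMask <- tr$probes$deleted[match(called$probe, tr$probes$id)]
        expect_equal(as.character(called$call),
                     ifelse(truthMask, "loss", "neutral"))
    }
})

test_that("BAF imbalance flags deleted windows and respects degenerate input", {
    # all hets exactly at 0.5: nothing flagged
    n <- 60
    flat <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(seq_len(n) * 100, width = 1))
    flat$snp <- paste0("s", seq_len(n))
    flat$baf <- 0.5
    flat$het <- TRUE
    expect_length(bafImbalance(flat, window = 20), 0)
    # window larger than the track: one whole-track decision
    skew <- flat; skew$baf <- 0.8
    wide <- bafImbalance(skew, window = 1000, devThr = 0.15)
    expect_length(wide, 1)
    expect_equal(GenomicRanges::start(wide), 100L)
    expect_equal(GenomicRanges::end(wide), n * 100L)
})

test_that("simulated hemizygous deletions are recovered from BAF tracks", {
    cfg <- smallConfig(tumorFractionRange = c(0.8, 0.8), penetrance = 1,
                       seed = 3)
    tr <- cohortTruth(cfg)
    baf <- simulateBaf(cfg, tr)
    carrier <- tr$samples$sample[tr$samples$group == "BRCA2"][1]
    flagged <- bafImbalance(baf[[carrier]], window = 25, devThr = 0.15)
    # every true deleted region, shrunk by one window at each edge, is covered
    snps <- tr$snps
    windowBp <- 25 / 40 * 1e7   # 25 SNPs at 40 per 10 Mb band
    for (i in seq_along(tr$regions)) {
        reg <- tr$regions[i]
        core <- GenomicRanges::GRanges(
            GenomicRanges::seqnames(reg),
            IRanges::IRanges(GenomicRanges::start(reg) + windowBp,
                             GenomicRanges::end(reg) - windowBp))
        ov <- GenomicRanges::intersect(flagged, core)
        expect_equal(sum(GenomicRanges::width(ov)),
                     sum(GenomicRanges::width(core)))
    }
})

test_that("regions map back to cytogenetic band spans", {
    cyto <- data.frame(chrom = "chr13",
                       start = c(0, 1e7, 2e7), end = c(1e7, 2e7, 3e7),
                       band = c("13q12", "13q13", "13q14"),
                       stain = "gneg")
    reg <- GenomicRanges::GRanges("chr13",
        IRanges::IRanges(start = 1.2e7, end = 2.8e7))
    ann <- annotateBands(reg, cyto)
    expect_equal(ann$bandStart, "13q13")
    expect_equal(ann$bandEnd, "13q14")
})
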