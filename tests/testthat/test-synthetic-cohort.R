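test_that("noise-free expression reproduces the deterministic shift model", {
    cfg <- smallConfig(exprNoiseSd = 0, tumorFractionRange = c(1, 1),
                       exprEffect = -1, penetrance = 1)
    se <- simulateExpression(cfg)
    tr <- S4Vectors::metadata(se)$truth
    x <- SummarizedExperiment::assay(se)
    grp <- SummarizedExperiment::colData(se)$group
    del <- SummarizedExperiment::rowData(se)$deleted
    # controls carry no deletion: per gene a single baseline value
    ctl <- x[, grp == "BRCAX", drop = FALSE]
    expect_true(all(apply(ctl, 1, function(v) diff(range(v)) == 0)))
    # deleted genes in case samples sit exactly one log2 unit below baseline
    cas <- x[del, grp == "BRCA2", drop = FALSE]
    expect_equal(unname(cas), unname(ctl[del, rep(1, ncol(cas))] - 1))
    # non-deleted genes are unshifted in cases
    expect_equal(unname(x[!del, grp == "BRCA2", drop = FALSE]),
                 unname(ctl[!del, rep(1, sum(grp == "BRCA2"))]))
})

test_that("penetrance zero yields an exchangeable null with no carried deletions", {
    cfg <- smallConfig(penetrance = 0)
    tr <- cohortTruth(cfg)
    expect_false(any(tr$carried))
    se <- simulateExpression(cfg, tr)
    # group label carries no signal: moderated t finds nothing at FDR 0.01
    gs <- moderatedT(se)
    expect_length(signatureGenes(selectSignature(gs)), 0)
})

test_that("mean case-control difference of deleted genes matches f * effect", {
    cfg <- cohortConfig(nCase = 20, nControl = 20, exprEffect = -1,
                        tumorFractionRange = c(0.8, 0.8), exprNoiseSd = 0.3,
                        seed = 4)
    se <- simulateExpression(cfg)
    x <- SummarizedExperiment::assay(se)
    grp <- SummarizedExperiment::colData(se)$group
    del <- SummarizedExperiment::rowData(se)$deleted
    diffs <- rowMeans(x[del, grp == "BRCA2"]) - rowMeans(x[del, grp == "BRCAX"])
    # closed-form expectation f * effect; SE of the grand mean over genes
    se3 <- 3 * 0.3 * sqrt(1 / 20 + 1 / 20) / sqrt(sum(del))
    expect_lt(abs(mean(diffs) - (-0.8)), se3)
})

test_that("CGH log ratios follow the contamination-diluted copy formula", {
    for (f in c(1, 0.5)) {
        cfg <- smallConfig(cghNoiseSd = 0, tumorFractionRange = c(f, f),
                           penetrance = 1)
        tr <- cohortTruth(cfg)
        cgh <- simulateCgh(cfg, tr)
        carrier <- tr$samples$sample[tr$samples$group == "BRCA2"][1]
        p <- cgh[[carrier]]
        delProbe <- tr$probes$deleted[match(p$probe, tr$probes$id)]
        expect_equal(unique(p$log2ratio[delProbe]), log2((f + 2 * (1 - f)) / 2))
        expect_equal(unique(p$log2ratio[!delProbe]), 0)
    }
    # f = 1 hemizygous loss is exactly -1; f = 0.5 is log2(0.75)
    expect_equal(log2((1 + 0) / 2), -1)
    expect_equal(log2((0.5 + 1) / 2), log2(0.75))
})

test_that("BAF splits heterozygous SNPs into the allele-ratio bands", {
    cfg <- smallConfig(bafNoiseSd = 0, tumorFractionRange = c(0.5, 0.5),
                       penetrance = 1)
    tr <- cohortTruth(cfg)
    baf <- simulateBaf(cfg, tr)
    carrier <- tr$samples$sample[tr$samples$group == "BRCA2"][1]
    b <- baf[[carrier]]
    delSnp <- tr$snps$deleted[match(b$snp, tr$snps$id)]
    hetDel <- b$baf[b$het & delSnp]
    expect_setequal(round(unique(hetDel), 10), round(c(1 / 1.5, 0.5 / 1.5), 10))
    expect_equal(unique(b$baf[b$het & !delSnp]), 0.5)
    # full tumor fraction: LOH pushes het BAF to 0/1
    cfg1 <- smallConfig(bafNoiseSd = 0, tumorFractionRange = c(1, 1))
    tr1 <- cohortTruth(cfg1)
    b1 <- simulateBaf(cfg1, tr1)[[tr1$samples$sample[1]]]
    del1 <- tr1$snps$deleted[match(b1$snp, tr1$snps$id)]
    expect_true(all(b1$baf[b1$het & del1] %in% c(0, 1)))
})

test_that("FISH spot counts are exact in the noise-free limit", {
    cfg <- smallConfig(fishDetectionEff = 1, tumorFractionRange = c(1, 1),
                       penetrance = 1, fishNucleiPerSample = 20)
    tr <- cohortTruth(cfg)
    fish <- simulateFish(cfg, tr)
    carrier <- tr$samples$sample[tr$samples$group == "BRCA2"][1]
    ctl <- tr$samples$sample[tr$samples$group == "BRCAX"][1]
    fc <- fish[fish$sample == carrier, ]
    expect_true(all(fc$green == 2 & fc$red == 1))
    f0 <- fish[fish$sample == ctl, ]
    expect_true(all(f0$green == 2 & f0$red == 2))
})

test_that("observed FISH deletion percentage matches the binomial-mixture expectation", {
    f <- 0.9; eff <- 0.95
    cfg <- cohortConfig(nCase = 1, nControl = 1, fishDetectionEff = eff,
                        tumorFractionRange = c(f, f), penetrance = 1,
                        fishNucleiPerSample = 200, seed = 6)
    tr <- cohortTruth(cfg)
    fish <- simulateFish(cfg, tr)
    carrier <- tr$samples$sample[1]
    sub <- fish[fish$sample == carrier & fish$chrom == "chr13", ]
    expect_equal(modalGreen(sub$green), 2)
    # exact enumeration of the (tumor, green, red) mixture for modal green 2
    dG <- stats::dbinom(0:2, 2, eff)
    pRedT <- stats::dbinom(0:1, 1, eff)     # tumor cell, one red copy
    pRedN <- stats::dbinom(0:2, 2, eff)     # normal cell, two red copies
    pDen <- dG[3] + dG[2] * (f * pRedT[2] + (1 - f) * pRedN[2])  # g=2 or (1,1)
    pNum <- dG[3] * (f * (pRedT[1] + pRedT[2]) + (1 - f) * (pRedN[1] + pRedN[2])) +
        dG[2] * (f * pRedT[2] + (1 - f) * pRedN[2])
    expected <- 100 * pNum / pDen
    obs <- deletionPercentage(sub$green, sub$red)
    nDen <- sum(sub$green == 2 | (sub$green == 1 & sub$red == 1))
    se3 <- 3 * 100 * sqrt((pNum / pDen) * (1 - pNum / pDen) / nDen)
    expect_lt(abs(obs - expected), se3)
})

test_that("a fixed seed reproduces the cohort and modalities are independent streams", {
    cfg <- smallConfig(seed = 11)
    co1 <- simulateCohort(cfg)
    co2 <- simulateCohort(cfg)
    expect_identical(SummarizedExperiment::assay(cohortExpression(co1)),
                     SummarizedExperiment::assay(cohortExpression(co2)))
    expect_identical(cohortFish(co1), cohortFish(co2))
    expect_identical(cohortCgh(co1)[[1]]$log2ratio,
                     cohortCgh(co2)[[1]]$log2ratio)
    # changing a FISH-only parameter must not perturb the expression draws
    cfg2 <- smallConfig(seed = 11, fishNucleiPerSample = 7L)
    expect_identical(SummarizedExperiment::assay(simulateExpression(cfg)),
                     SummarizedExperiment::assay(simulateExpression(cfg2)))
})

test_that("invalid configurations are rejected", {
    expect_error(smallConfig(penetrance = 1.5), "penetrance")
    expect_error(smallConfig(tumorFractionRange = c(0, 0.5)),
                 "tumorFractionRange")
    expect_error(smallConfig(exprNoiseSd = -1), "noise")
    expect_error(smallConfig(exprEffect = NaN), "finite")
    expect_error(smallConfig(fishDetectionEff = 0), "fishDetectionEff")
    expect_error(cohortConfig(nCase = 0), "nCase")
})

test_that("signature selection recovers deleted genes on strong-signal cohorts", {
    hits <- fps <- numeric(10)
    for (s in 1:10) {
        cfg <- cohortConfig(nCase = 20, nControl = 20, penetrance = 1,
                            exprEffect = -1, tumorFractionRange = c(0.8, 0.95),
                            exprNoiseSd = 0.3, seed = 100 + s)
        se <- simulateExpression(cfg)
        tr <- S4Vectors::metadata(se)$truth
        sig <- selectSignature(moderatedT(se), 0.01)
        truly <- tr$genes$id[tr$genes$deleted]
        hits[s] <- mean(truly %in% signatureGenes(sig))
        fps[s] <- mean(!signatureGenes(sig) %in% truly)
    }
    expect_gte(mean(hits), 0.9)
    expect_lt(mean(fps), 0.05)
})
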