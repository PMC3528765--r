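test_that("probeset collapse keeps the most variable probeset per gene", {
    m <- rbind(p1 = c(1, 2, 3), p2 = c(0, 4, 8), p3 = c(5, 5, 6))
    map <- data.frame(probe = c("p1", "p2", "p3"),
                      gene = c("A", "A", "B"))
    out <- collapseProbesets(m, map)
    expect_equal(rownames(out), c("A", "B"))
    expect_equal(unname(out["A", ]), c(0, 4, 8))   # SD 4 beats SD 1
    expect_equal(unname(attr(out, "probe")["B"]), "p3")  # singleton unchanged
    expect_error(collapseProbesets(m, data.frame(probe = "px", gene = "C")),
                 "no overlap")
})

test_that("probeset collapse equals the brute-force argmax-SD oracle", {
    set.seed(21)
    m <- matrix(rnorm(10 * 6, sd = rep(runif(10, 0.2, 3), 6)), 10,
                dimnames = list(paste0("p", 1:10), NULL))
    map <- data.frame(probe = paste0("p", 1:10),
                      gene = sample(c("A", "B", "C"), 10, replace = TRUE))
    out <- collapseProbesets(m, map)
    for (g in unique(map$gene)) {
        probes <- map$probe[map$gene == g]
        best <- probes[which.max(apply(m[probes, , drop = FALSE], 1, sd))]
        expect_equal(unname(out[g, ]), unname(m[best, ]))
    }
})

test_that("moderated t with d0 = 0 equals the pooled two-sample t", {
    set.seed(31)
    m <- matrix(rnorm(50 * 12), 50, dimnames = list(paste0("g", 1:50), NULL))
    grp <- rep(c("case", "ctl"), each = 6)
    gs <- moderatedT(m, grp, case = "case", d0 = 0)
    expect_equal(geneStats(gs)$t, unname(pooledT(m, grp == "case")),
                 tolerance = 1e-10)
})

test_that("identical gene variances are a fixed point of moderation", {
    # every gene: same within-group spread, different means
    base <- c(-1, 1)
    m <- rbind(g1 = c(base, base + 5), g2 = c(base + 2, base - 1),
               g3 = c(base - 3, base))
    grp <- rep(c("case", "ctl"), each = 2)
    gs <- moderatedT(m, grp, case = "case")
    st <- geneStats(gs)
    expect_equal(st$s2Post, st$s2, tolerance = 1e-12)
    expect_equal(st$t, unname(pooledT(m, grp == "case")), tolerance = 1e-12)
})

test_that("equal group means give t = 0 and p = 1", {
    m <- rbind(g1 = c(1, 3, 1, 3), g2 = c(0, 2, 4, 6))
    gs <- moderatedT(m, rep(c("case", "ctl"), each = 2), case = "case")
    expect_equal(geneStats(gs)$t[1], 0)
    expect_equal(geneStats(gs)$p[1], 1)
    expect_equal(sign(geneStats(gs)$t[2]),
                 sign(geneStats(gs)$meanCase[2] - geneStats(gs)$meanControl[2]))
})

test_that("moderated t matches the reference empirical-Bayes implementation", {
    skip_if_not_installed("limma")
    set.seed(33)
    m <- matrix(rnorm(300 * 9, sd = rep(sqrt(0.05 * 4 / rchisq(300, 4)), 9)),
                300, dimnames = list(paste0("g", 1:300), NULL))
    grp <- rep(c("ctl", "case"), c(4, 5))
    gs <- moderatedT(m, grp, case = "case")
    fit <- limma::eBayes(limma::lmFit(m,
        stats::model.matrix(~ factor(grp, levels = c("ctl", "case")))))
    expect_equal(geneStats(gs)$t, unname(fit$t[, 2]), tolerance = 1e-10)
    expect_equal(geneStats(gs)$p, unname(fit$p.value[, 2]), tolerance = 1e-10)
    expect_equal(priorDf(gs), fit$df.prior, tolerance = 1e-8)
    expect_equal(priorVar(gs), fit$s2.prior, tolerance = 1e-8)
})

test_that("moment matching recovers the variance prior", {
    d0s <- s02s <- numeric(10)
    for (s in 1:10) {
        set.seed(100 + s)
        nG <- 2000; d0 <- 4; s02 <- 0.09
        sigma2 <- s02 * d0 / stats::rchisq(nG, d0)
        m <- matrix(rnorm(nG * 6, sd = rep(sqrt(sigma2), 6)), nG,
                    dimnames = list(paste0("g", 1:nG), NULL))
        gs <- moderatedT(m, rep(c("case", "ctl"), each = 3), case = "case")
        d0s[s] <- priorDf(gs); s02s[s] <- priorVar(gs)
    }
    expect_true(all(d0s >= 2.5 & d0s <= 6))
    expect_true(all(abs(s02s / 0.09 - 1) < 0.25))
})

test_that("moderated t is invariant to per-gene constants and has the d0 -> Inf limit", {
    set.seed(34)
    m <- matrix(rnorm(40 * 8), 40, dimnames = list(paste0("g", 1:40), NULL))
    grp <- rep(c("case", "ctl"), each = 4)
    gs1 <- moderatedT(m, grp, case = "case")
    gs2 <- moderatedT(m + 100, grp, case = "case")
    expect_equal(geneStats(gs1)$t, geneStats(gs2)$t, tolerance = 1e-9)
    s02 <- 0.7
    gsInf <- moderatedT(m, grp, case = "case", d0 = Inf, s02 = s02)
    st <- geneStats(gsInf)
    expect_equal(st$t,
                 (st$meanCase - st$meanControl) / (sqrt(s02) * sqrt(1/4 + 1/4)),
                 tolerance = 1e-12)
})

test_that("all-constant genes are flagged, not poisoning the prior fit", {
    set.seed(35)
    m <- matrix(rnorm(30 * 6), 30, dimnames = list(paste0("g", 1:30), NULL))
    m[1, ] <- 5                       # constant everywhere
    m[2, ] <- rep(c(1, 2), each = 3)  # constant within groups, means differ
    grp <- rep(c("case", "ctl"), each = 3)
    gs <- moderatedT(m, grp, case = "case")
    st <- geneStats(gs)
    expect_true(all(st$zeroVar[1:2]))
    expect_equal(st$t[1], 0); expect_equal(st$p[1], 1)
    expect_equal(st$t[2], -Inf); expect_equal(st$p[2], 0)
    expect_true(is.finite(priorDf(gs)) || is.infinite(priorDf(gs)))
    expect_true(priorVar(gs) > 0)
    expect_error(moderatedT(m[, 1:4], c("case", "ctl", "ctl", "ctl"),
                            case = "case"), "at least 2")
})

test_that("BH adjustment matches hand computation and the step-up definition", {
    expect_equal(bhAdjust(0.04), 0.04)
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    set.seed(41)
    for (i in 1:20) {
        p <- runif(sample(1:50, 1))^sample(1:3, 1)
        adj <- bhAdjust(p)
        expect_equal(adj, bruteForceBH(p), tolerance = 1e-12)
        expect_true(all(adj >= p - 1e-15))
        expect_true(all(adj <= 1))
    }
})

test_that("signature selection is monotone in the FDR threshold", {
    set.seed(51)
    se <- simulateExpression(cohortConfig(nCase = 8, nControl = 8, seed = 51))
    gs <- moderatedT(se)
    all <- selectSignature(gs, 1.0000001)
    expect_equal(length(signatureGenes(all)), nrow(geneStats(gs)))
    prev <- signatureGenes(all)
    for (thr in c(0.5, 0.05, 0.01, 0.001, 1e-8)) {
        cur <- signatureGenes(selectSignature(gs, thr))
        expect_true(all(cur %in% prev))
        prev <- cur
    }
    empty <- selectSignature(gs, 0)
    expect_length(signatureGenes(empty), 0)
    expect_s4_class(empty, "Signature")
})

test_that("centroid clustering merges the most correlated rows first", {
    x <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(4, 3, 2, 1))
    cl <- centroidCluster(x, cluster = "rows")
    # identical rows a, b merge first (distance 0)
    expect_equal(sort(cl$rowHclust$merge[1, ]), c(-2, -1))
    set.seed(61)
    base <- rnorm(6)
    y <- rbind(r1 = base + rnorm(6, sd = 0.05),
               r2 = base + rnorm(6, sd = 0.05),
               r3 = -base + rnorm(6, sd = 0.05))
    cl2 <- centroidCluster(y, cluster = "rows")
    d <- 1 - cor(t(y))
    pair <- which(d == min(d[upper.tri(d)]), arr.ind = TRUE)[1, ]
    expect_setequal(-cl2$rowHclust$merge[1, ], unname(pair))
    # single row: order of length 1, no merges
    cl3 <- centroidCluster(y[1, , drop = FALSE], cluster = "rows")
    expect_equal(cl3$rowOrder, 1L)
    expect_null(cl3$rowHclust)
})
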