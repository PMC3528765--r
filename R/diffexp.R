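#' @importFrom stats sd var cor pt p.adjust hclust as.dist
NULL

# Extract a plain matrix + group factor from a matrix or SummarizedExperiment.
exprInput <- function(x, group = NULL) {
    if (is(x, "SummarizedExperiment")) {
        m <- SummarizedExperiment::assay(x)
        if (is.null(group)) group <- SummarizedExperiment::colData(x)$group
    } else {
        m <- as.matrix(x)
    }
    if (!is.numeric(m) || any(!is.finite(m)))
        stop("expression values must be finite numerics")
    if (is.null(rownames(m))) stop("expression matrix must have gene IDs")
    list(m = m, group = group)
}

#' Collapse probesets to gene symbols by maximal standard deviation
#'
#' When several probesets map to the same gene symbol, the most variable
#' probeset (largest SD across the entire dataset) is retained as that
#' gene's measurement; probesets without a mapping are dropped.
#'
#' @param x probeset-level matrix (rows named by probeset) or
#'   SummarizedExperiment.
#' @param probeToGene `data.frame` with columns `probe` and `gene` (each
#'   probe mapping to at most one symbol); extra columns such as `band` are
#'   carried through to the result's attributes.
#' @return gene-level matrix with rows named by gene symbol, with the
#'   retained probeset IDs in `attr(, "probe")` and any `band` column in
#'   `attr(, "band")`.
#' @export
#' @examples
#' m <- rbind(p1 = c(1, 2, 3), p2 = c(0, 4, 8), p3 = c(5, 5, 5))
#' collapseProbesets(m, data.frame(probe = c("p1", "p2"), gene = "GENEA"))
collapseProbesets <- function(x, probeToGene) {
    m <- exprInput(x)$m
    stopifnot(all(c("probe", "gene") %in% names(probeToGene)))
    if (anyDuplicated(probeToGene$probe))
        stop("each probe must map to at most one gene symbol")
    map <- probeToGene[probeToGene$probe %in% rownames(m) &
                       !is.na(probeToGene$gene) & probeToGene$gene != "", ,
                       drop = FALSE]
    if (!nrow(map))
        stop("no overlap between expression matrix rows and probe mapping")
    sds <- apply(m[map$probe, , drop = FALSE], 1, sd)
    keep <- unlist(lapply(split(seq_len(nrow(map)), map$gene), function(i) {
        i[which.max(sds[i])]
    }))
    out <- m[map$probe[keep], , drop = FALSE]
    rownames(out) <- map$gene[keep]
    attr(out, "probe") <- setNames(map$probe[keep], map$gene[keep])
    if ("band" %in% names(map))
        attr(out, "band") <- setNames(map$band[keep], map$gene[keep])
    out
}

# Solve trigamma(x) = y by Newton iteration (monotone decreasing trigamma).
trigammaInverse <- function(y, tol = 1e-8, maxIter = 50L) {
    vapply(y, function(yi) {
        if (!is.finite(yi) || yi <= 0) return(Inf)
        if (yi > 1e7) return(1 / sqrt(yi))
        x <- 0.5 + 1 / yi
        for (i in seq_len(maxIter)) {
            tri <- trigamma(x)
            dif <- tri * (1 - tri / yi) / psigamma(x, deriv = 2L)
            x <- x + dif
            if (abs(dif) / x < tol) break
        }
        x
    }, numeric(1))
}

# Moment-matching fit of the scaled inverse-chi-square prior on gene
# variances: log s^2 moments against digamma/trigamma identities.
fitVariancePrior <- function(s2, df) {
    s2 <- s2[is.finite(s2) & s2 > 0]
    if (!length(s2)) return(list(d0 = Inf, s02 = NA_real_))
    z <- log(s2)
    e <- z - digamma(df / 2) + log(df / 2)
    emean <- mean(e)
    n <- length(e)
    if (n < 2L) return(list(d0 = Inf, s02 = exp(emean)))
    evar <- mean((e - emean)^2) * n / (n - 1) - trigamma(df / 2)
    if (!is.finite(evar) || evar <= 0) {
        # underdispersed sample variances: infinite prior df, full shrinkage;
        # the prior reduces to the geometric mean of the s2 so that identical
        # gene variances are a fixed point of the moderation
        return(list(d0 = Inf, s02 = exp(mean(z))))
    }
    d0 <- 2 * trigammaInverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    list(d0 = d0, s02 = s02)
}

#' Empirical-Bayes moderated two-group t-statistics
#'
#' For each gene the pooled two-group residual variance `s2` (on
#' `df = n1 + n2 - 2` degrees of freedom) is shrunk toward a prior variance
#' `s02` with prior degrees of freedom `d0`, both estimated across genes by
#' moment matching of `log s2` via digamma/trigamma identities:
#' `s2Post = (d0*s02 + df*s2) / (d0 + df)`. The moderated t is
#' `(meanCase - meanControl) / sqrt(s2Post * (1/n1 + 1/n2))` with two-sided
#' p-values on `d0 + df` degrees of freedom, so t > 0 means higher
#' expression in the case group. Benjamini-Hochberg adjusted p-values are
#' included.
#'
#' Genes with zero sample variance are excluded from the prior fit; their t
#' is +/-Inf with p = 0 when the group means differ (0 and 1 otherwise) and
#' they are flagged in the `zeroVar` column.
#'
#' @param x matrix (genes x samples) or SummarizedExperiment with a `group`
#'   column in `colData`.
#' @param group two-level factor/character of per-sample labels.
#' @param case the label of the case group (defaults to `"BRCA2"` when
#'   present, else the second factor level).
#' @param d0 optional forced prior degrees of freedom: `0` gives the
#'   ordinary pooled t-test, `Inf` shrinks every variance to `s02`.
#' @param s02 optional forced prior variance (used with forced `d0`).
#' @return a [GeneStats-class].
#' @export
#' @examples
#' se <- simulateExpression(cohortConfig(nCase = 5, nControl = 5, seed = 3))
#' gs <- moderatedT(se)
#' gs
moderatedT <- function(x, group = NULL, case = NULL, d0 = NULL, s02 = NULL) {
    inp <- exprInput(x, group)
    m <- inp$m; group <- as.character(inp$group)
    if (is.null(group) || length(group) != ncol(m))
        stop("a per-sample group label is required")
    lev <- unique(group)
    if (length(lev) != 2L) stop("exactly two groups are required")
    if (is.null(case)) case <- if ("BRCA2" %in% lev) "BRCA2" else lev[2]
    if (!case %in% lev) stop("case level '", case, "' not found in group")
    ctrl <- setdiff(lev, case)
    i1 <- group == case; i2 <- group == ctrl
    n1 <- sum(i1); n2 <- sum(i2)
    if (n1 < 2L || n2 < 2L)
        stop("each group needs at least 2 samples for variance estimation")

    mean1 <- rowMeans(m[, i1, drop = FALSE])
    mean2 <- rowMeans(m[, i2, drop = FALSE])
    meanAll <- rowMeans(m)
    ss1 <- rowSums((m[, i1, drop = FALSE] - mean1)^2)
    ss2 <- rowSums((m[, i2, drop = FALSE] - mean2)^2)
    df <- n1 + n2 - 2L
    s2 <- (ss1 + ss2) / df
    zeroVar <- s2 <= 0

    if (is.null(d0)) {
        prior <- fitVariancePrior(s2[!zeroVar], df)
        d0 <- prior$d0
        s02 <- prior$s02
    } else if (is.null(s02)) {
        s02 <- fitVariancePrior(s2[!zeroVar], df)$s02
    }

    s2Post <- if (is.infinite(d0)) rep(s02, length(s2))
              else (d0 * s02 + df * s2) / (d0 + df)
    s2Post[zeroVar & is.finite(d0) & d0 == 0] <- 0
    diff <- mean1 - mean2
    denom <- sqrt(s2Post * (1 / n1 + 1 / n2))
    tstat <- diff / denom
    dfTotal <- d0 + df
    p <- 2 * pt(-abs(tstat), df = dfTotal)
    # degenerate all-constant genes
    bad <- zeroVar
    if (any(bad)) {
        tstat[bad] <- sign(diff[bad]) * Inf
        tstat[bad & diff == 0] <- 0
        p[bad] <- ifelse(diff[bad] == 0, 1, 0)
    }
    adjP <- bhAdjust(p)
    st <- data.frame(gene = rownames(m), meanCase = mean1,
                     meanControl = mean2, meanAll = meanAll, s2 = s2,
                     df = df, s2Post = s2Post, t = tstat, p = p,
                     adjP = adjP, zeroVar = zeroVar,
                     row.names = NULL, stringsAsFactors = FALSE)
    new("GeneStats", stats = st, d0 = as.numeric(d0), s02 = as.numeric(s02),
        nCase = as.integer(n1), nControl = as.integer(n2))
}

#' GeneStats accessors
#'
#' @param object a [GeneStats-class].
#' @return `geneStats()` the per-gene table; `priorDf()`/`priorVar()` the
#'   fitted prior degrees of freedom and prior variance.
#' @name genestats-accessors
NULL

#' @rdname genestats-accessors
#' @export
geneStats <- function(object) object@stats
#' @rdname genestats-accessors
#' @export
priorDf <- function(object) object@d0
#' @rdname genestats-accessors
#' @export
priorVar <- function(object) object@s02

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")`: the order-preserving
#' step-up `adj_(i) = min_{j >= i} m * p_(j) / j`, capped at 1.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values, componentwise `>=` the input.
#' @export
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03))
bhAdjust <- function(p) p.adjust(p, method = "BH")

#' Select a weighted signature at an FDR threshold
#'
#' Genes with BH-adjusted p below the threshold form the signature; each
#' carries its moderated t as weight and the gene's overall training-cohort
#' mean as centering reference. Genes are ordered by adjusted p, ties broken
#' by decreasing |t|. An empty selection is returned as an empty signature,
#' not an error.
#'
#' @param stats a [GeneStats-class].
#' @param fdrThreshold adjusted-p cutoff (default 0.01).
#' @return a [Signature-class].
#' @export
selectSignature <- function(stats, fdrThreshold = 0.01) {
    st <- geneStats(stats)
    sel <- st[st$adjP < fdrThreshold, , drop = FALSE]
    sel <- sel[order(sel$adjP, -abs(sel$t)), , drop = FALSE]
    new("Signature", genes = sel$gene,
        weights = setNames(sel$t, sel$gene),
        referenceMeans = setNames(sel$meanAll, sel$gene))
}

#' Signature accessors
#'
#' @param object a [Signature-class].
#' @name signature-accessors
NULL

#' @rdname signature-accessors
#' @export
signatureGenes <- function(object) object@genes
#' @rdname signature-accessors
#' @export
signatureWeights <- function(object) object@weights
#' @rdname signature-accessors
#' @export
referenceMeans <- function(object) object@referenceMeans

#' Centroid-linkage hierarchical clustering for heatmap ordering
#'
#' Agglomerative clustering of rows and columns with centroid linkage on the
#' centered-Pearson correlation distance `1 - r`, the combination used by
#' classic microarray heatmap tools. Returns the dendrogram leaf orders for
#' rendering. Constant rows/columns (undefined correlation) get distance 1
#' to everything. Note centroid linkage on a non-Euclidean distance is a
#' heuristic and may produce inversions; orderings remain deterministic.
#'
#' @param x matrix or SummarizedExperiment.
#' @param cluster which dimensions to cluster (`"both"`, `"rows"`,
#'   `"columns"`).
#' @return list with `rowOrder`, `colOrder` (integer leaf orders) and the
#'   underlying `hclust` objects (`NULL` for dimensions of size < 2).
#' @export
centroidCluster <- function(x, cluster = c("both", "rows", "columns")) {
    cluster <- match.arg(cluster)
    m <- exprInput(x)$m
    corDist <- function(mm) {
        r <- suppressWarnings(cor(t(mm)))
        r[!is.finite(r)] <- 0
        d <- 1 - r
        diag(d) <- 0
        as.dist(d)
    }
    clusterDim <- function(mm) {
        if (nrow(mm) < 2L)
            return(list(order = seq_len(nrow(mm)), hclust = NULL))
        hc <- hclust(corDist(mm), method = "centroid")
        list(order = hc$order, hclust = hc)
    }
    rows <- if (cluster %in% c("both", "rows")) clusterDim(m)
            else list(order = seq_len(nrow(m)), hclust = NULL)
    cols <- if (cluster %in% c("both", "columns")) clusterDim(t(m))
            else list(order = seq_len(ncol(m)), hclust = NULL)
    list(rowOrder = rows$order, colOrder = cols$order,
         rowHclust = rows$hclust, colHclust = cols$hclust)
}
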