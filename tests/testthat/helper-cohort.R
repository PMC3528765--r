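# Small cohort configurations reused across test files.

smallConfig <- function(seed = 1L, ...) {
    cohortConfig(nCase = 5L, nControl = 5L, seed = seed, ...)
}

# Probe profile built by hand: one chromosome, unit-spaced probes with the
# given log2 ratios (0-based half-open starts 0, 10, 20, ...).
handProfile <- function(log2ratio, chrom = "chr1", width = 10L) {
    n <- length(log2ratio)
    gr <- GenomicRanges::GRanges(chrom,
        IRanges::IRanges(start = seq(1L, by = width, length.out = n),
                         width = width))
    gr$probe <- sprintf("p%02d", seq_len(n))
    gr$log2ratio <- log2ratio
    gr
}

# Independent quadratic-time BH definition: adj_i = min over j with
# p_(j) >= p_i of m * p_(j) / rank_j, capped at 1.
bruteForceBH <- function(p) {
    m <- length(p)
    o <- order(p)
    ranks <- integer(m); ranks[o] <- seq_len(m)
    vapply(seq_len(m), function(i) {
        j <- which(p >= p[i] - 1e-15)
        min(1, min(m * p[j] / ranks[j]))
    }, numeric(1))
}

# Independent O(N * |set|) running-sum enrichment score.
bruteForceES <- function(ranked, set, exponent = 1) {
    genes <- names(ranked)
    hit <- genes %in% set
    N <- length(genes); m <- sum(hit)
    w <- abs(ranked)^exponent
    if (sum(w[hit]) == 0) w <- rep(1, N)
    dev <- vapply(seq_len(N), function(i) {
        sum(w[seq_len(i)][hit[seq_len(i)]]) / sum(w[hit]) -
            sum(!hit[seq_len(i)]) / (N - m)
    }, numeric(1))
    dev[which.max(abs(dev))]
}

# Trapezoidal area under the empirical ROC, built independently of rocAuc().
trapezoidAuc <- function(scores, labels, case) {
    pos <- labels == case
    thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
    tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
    fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
    sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Full-lattice enumeration of the two-sided Fisher exact p-value.
enumerateFisherP <- function(tab) {
    r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
    support <- max(0L, c1 - r2):min(r1, c1)
    prob <- vapply(support, function(a) {
        choose(r1, a) * choose(r2, c1 - a) / choose(r1 + r2, c1)
    }, numeric(1))
    pObs <- prob[match(tab[1, 1], support)]
    sum(prob[prob <= pObs * (1 + 1e-7)])
}

# Ordinary pooled-variance two-sample t computed from first principles.
pooledT <- function(m, case) {
    x1 <- m[, case, drop = FALSE]; x2 <- m[, !case, drop = FALSE]
    n1 <- ncol(x1); n2 <- ncol(x2)
    sp2 <- (rowSums((x1 - rowMeans(x1))^2) + rowSums((x2 - rowMeans(x2))^2)) /
        (n1 + n2 - 2)
    (rowMeans(x1) - rowMeans(x2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}
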