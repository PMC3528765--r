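#' Build positional gene sets from a band annotation
#'
#' One gene set per cytogenetic band label (e.g. `"13q14"`). Genes absent
#' from the supplied universe (typically the ranked list) are removed before
#' size filtering, so set sizes reflect the genes actually scored.
#'
#' @param annotation `data.frame` with columns `gene` and `band` (a `chrom`
#'   column is allowed and ignored here).
#' @param genes optional character universe to intersect with.
#' @param minSize,maxSize inclusive set-size bounds after filtering.
#' @return named list of character vectors, one per retained band.
#' @export
#' @examples
#' ann <- data.frame(gene = paste0("g", 1:12),
#'                   band = rep(c("13q14", "1p36"), each = 6))
#' lengths(makeBandSets(ann, minSize = 5))
makeBandSets <- function(annotation, genes = NULL, minSize = 5L,
                         maxSize = 500L) {
    stopifnot(all(c("gene", "band") %in% names(annotation)))
    ann <- annotation[!is.na(annotation$band) & annotation$band != "", ]
    sets <- split(as.character(ann$gene), as.character(ann$band))
    sets <- lapply(sets, unique)
    if (!is.null(genes))
        sets <- lapply(sets, intersect, y = genes)
    keep <- lengths(sets) >= minSize & lengths(sets) <= maxSize
    sets[keep]
}

#' Build a ranked gene list from moderated-t statistics
#'
#' Genes ordered by decreasing t (case-vs-control), ties broken by input
#' order so the ranking is deterministic.
#'
#' @param stats a [GeneStats-class] or a named numeric vector of ranking
#'   statistics.
#' @return named numeric vector sorted in decreasing order.
#' @export
rankGenes <- function(stats) {
    r <- if (is(stats, "GeneStats")) {
        st <- geneStats(stats)
        setNames(st$t, st$gene)
    } else stats
    if (is.null(names(r)) || anyDuplicated(names(r)))
        stop("ranking statistics must be uniquely named by gene")
    r[order(-r)]   # stable sort: ties keep input order
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list accumulating `|r|^exponent` weight at set members
#' (P_hit) against a uniform step at non-members (P_miss); the enrichment
#' score is the signed maximal deviation of `P_hit - P_miss`. With all
#' in-set weights zero the unweighted statistic (`exponent = 0`) is used as
#' a fallback.
#'
#' @param ranked named numeric vector sorted in decreasing order (see
#'   [rankGenes()]).
#' @param set character vector of gene IDs; must intersect the ranked list
#'   and must not cover it entirely.
#' @param exponent weighting exponent on `|r|` (classic default 1).
#' @return list with `es` and `profile`, the running `P_hit - P_miss` at
#'   every rank position.
#' @export
#' @examples
#' r <- setNames(c(5, 4, 3, 2, 1), paste0("g", 1:5))
#' enrichmentScore(r, c("g4", "g5"))$es  # -1
enrichmentScore <- function(ranked, set, exponent = 1) {
    genes <- names(ranked)
    N <- length(ranked)
    hit <- genes %in% set
    m <- sum(hit)
    if (m == 0L) stop("gene set does not intersect the ranked list")
    if (m == N) stop("gene set covers the entire ranked list (degenerate)")
    w <- abs(ranked)^exponent
    if (sum(w[hit]) == 0) w <- rep(1, N)   # unweighted fallback
    pHit <- cumsum(ifelse(hit, w, 0)) / sum(w[hit])
    pMiss <- cumsum(!hit) / (N - m)
    profile <- pHit - pMiss
    es <- profile[which.max(abs(profile))]
    list(es = unname(es), profile = unname(profile))
}

# Fast ES for a set given by rank positions (no profile); same statistic as
# enrichmentScore(): extrema occur just before or at hit positions.
esAtPositions <- function(absW, N, idx, totalNonSet = NULL) {
    idx <- sort.int(idx)
    m <- length(idx)
    wHit <- absW[idx]
    tot <- sum(wHit)
    if (tot == 0) { wHit <- rep(1, m); tot <- m }
    cumHit <- cumsum(wHit) / tot
    denomMiss <- N - m
    k <- seq_len(m)
    devAt <- cumHit - (idx - k) / denomMiss            # at hit position
    devBefore <- c(0, cumHit[-m]) - (idx - k) / denomMiss  # just before hit
    cand <- c(devAt, devBefore)
    unname(cand[which.max(abs(cand))])
}

#' Preranked gene-set enrichment with a gene-permutation null
#'
#' For each set, the null distribution of the enrichment score is obtained
#' by drawing `nPerm` random gene sets of the same size from the ranked
#' list. The normalized enrichment score divides the observed ES by the
#' mean magnitude of sign-matched null scores; the nominal p is the
#' fraction of sign-matched null scores at least as extreme, floored at
#' `1/(nPerm + 1)` so it is never exactly zero; the family-wise error rate
#' is the fraction of permutations in which the most extreme sign-matched
#' normalized null statistic across all sets exceeds the observed |NES|
#' (also floored).
#'
#' @param ranked named numeric vector sorted decreasing (see [rankGenes()]).
#' @param sets named list of gene sets (see [makeBandSets()]).
#' @param nPerm number of random-set permutations (default 1000).
#' @param seed optional integer seed for the permutation draws.
#' @param exponent weighting exponent passed to the enrichment score.
#' @return `data.frame` with one row per set: `set`, `size`, `es`, `nes`,
#'   `p`, `fwer`, ordered by `nes`.
#' @export
prerankedGsea <- function(ranked, sets, nPerm = 1000L, seed = NULL,
                          exponent = 1) {
    if (!length(sets)) stop("no gene sets supplied")
    genes <- names(ranked)
    N <- length(ranked)
    absW <- abs(ranked)^exponent
    obs <- vapply(sets, function(s)
        enrichmentScore(ranked, s, exponent)$es, numeric(1))
    sizes <- vapply(sets, function(s) sum(genes %in% s), integer(1))

    runPerms <- function() {
        uniq <- sort(unique(sizes))
        nullBySize <- lapply(uniq, function(m) {
            vapply(seq_len(nPerm), function(b)
                esAtPositions(absW, N, sample.int(N, m)), numeric(1))
        })
        names(nullBySize) <- as.character(uniq)
        nullBySize
    }
    nullBySize <- if (is.null(seed)) runPerms() else withSeed(seed, runPerms())

    nes <- p <- numeric(length(sets))
    normNull <- matrix(NA_real_, length(sets), nPerm)
    for (i in seq_along(sets)) {
        nul <- nullBySize[[as.character(sizes[i])]]
        posMean <- mean(nul[nul > 0]); negMean <- mean(abs(nul[nul < 0]))
        es <- obs[i]
        if (es == 0) {
            nes[i] <- 0; p[i] <- 1
        } else if (es > 0) {
            same <- nul[nul >= 0]
            p[i] <- if (length(same)) mean(same >= es) else 0
            nes[i] <- if (is.finite(posMean) && posMean > 0) es / posMean
                      else 0
        } else {
            same <- nul[nul <= 0]
            p[i] <- if (length(same)) mean(abs(same) >= abs(es)) else 0
            nes[i] <- if (is.finite(negMean) && negMean > 0) es / negMean
                      else 0
        }
        nn <- rep(NA_real_, nPerm)
        if (is.finite(posMean) && posMean > 0)
            nn[nul > 0] <- nul[nul > 0] / posMean
        if (is.finite(negMean) && negMean > 0)
            nn[nul < 0] <- nul[nul < 0] / negMean
        nn[nul == 0] <- 0
        normNull[i, ] <- nn
    }
    floorP <- 1 / (nPerm + 1)
    p <- pmin(pmax(p, floorP), 1)

    fwer <- vapply(seq_along(sets), function(i) {
        if (nes[i] == 0) return(1)
        if (nes[i] > 0) {
            extreme <- suppressWarnings(apply(normNull, 2, max, na.rm = TRUE))
            fr <- mean(extreme[is.finite(extreme)] >= nes[i])
        } else {
            extreme <- suppressWarnings(apply(normNull, 2, min, na.rm = TRUE))
            fr <- mean(extreme[is.finite(extreme)] <= nes[i])
        }
        min(max(fr, floorP), 1)
    }, numeric(1))

    out <- data.frame(set = names(sets), size = sizes, es = obs, nes = nes,
                      p = p, fwer = fwer, row.names = NULL,
                      stringsAsFactors = FALSE)
    out[order(out$nes), , drop = FALSE]
}
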