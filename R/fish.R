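#' @importFrom stats dhyper
NULL

#' Modal green (centromeric) spot count
#'
#' The most frequent green spot count over the scored nuclei of a sample;
#' ties are broken toward the larger count, so partial centromeric dropout
#' does not spuriously lower the inferred ploidy.
#'
#' @param green integer vector of per-nucleus green spot counts.
#' @return the modal count.
#' @export
#' @examples
#' modalGreen(c(1, 1, 2, 2))  # 2 by the tie rule
modalGreen <- function(green) {
    stopifnot(length(green) >= 1L, all(green >= 0))
    tab <- table(green)
    cnt <- as.integer(names(tab))
    best <- cnt[tab == max(tab)]
    max(best)
}

#' Per-sample FISH deletion percentage
#'
#' Percentage of informative nuclei indicating loss of the red (deletion)
#' probe. The denominator is the nuclei carrying the modal green count,
#' plus nuclei with single green and single red spots; the numerator is the
#' modal-green nuclei with fewer red spots than the modal count, plus the
#' same (1, 1) nuclei (monosomy of both probes counts as loss, and when the
#' modal count is 1 those nuclei already sit in the denominator). Nuclei
#' with more green spots than the mode (aneuploid doublets/overlaps) are
#' excluded. With `allNuclei = TRUE` the denominator is instead every
#' scored nucleus, an alternative scoring convention kept behind a flag.
#'
#' @param green,red integer vectors of per-nucleus spot counts.
#' @param allNuclei use all nuclei as denominator instead of the
#'   modal-green nuclei.
#' @return percentage in [0, 100].
#' @export
#' @examples
#' deletionPercentage(green = rep(2, 10), red = c(rep(1, 6), rep(2, 4)))
deletionPercentage <- function(green, red, allNuclei = FALSE) {
    stopifnot(length(green) == length(red), length(green) >= 1L,
              all(green >= 0), all(red >= 0))
    modal <- modalGreen(green)
    isModal <- green == modal
    single <- green == 1L & red == 1L
    num <- sum((isModal & red < modal) | single)
    den <- if (allNuclei) length(green) else sum(isModal | single)
    if (den == 0L) stop("no informative nuclei")
    100 * num / den
}

#' Call loss from a deletion percentage
#'
#' @param percent deletion percentage in [0, 100].
#' @param threshold call threshold; `loss` when `percent >= threshold`
#'   (default 50).
#' @return character vector in `{loss, other}` (vectorized).
#' @export
#' @examples
#' callDeletion(c(84, 7, 50))
callDeletion <- function(percent, threshold = 50) {
    stopifnot(all(percent >= 0 & percent <= 100))
    ifelse(percent >= threshold, "loss", "other")
}

#' Per-sample deletion percentages from nucleus-level FISH counts
#'
#' Reduces a long-format spot-count table to one row per sample with the
#' deletion percentage and loss/other call per chromosome plus the combined
#' call (loss only when every scored chromosome is lost).
#'
#' @param fish `data.frame` with columns `sample`, `chrom`, `green`, `red`
#'   (e.g. from [simulateFish()] or [readFishTsv()]).
#' @param threshold calling threshold passed to [callDeletion()].
#' @param allNuclei see [deletionPercentage()].
#' @return `data.frame` with one row per sample: `sample`, one
#'   `pct.<chrom>` and `call.<chrom>` column pair per chromosome, and
#'   `call.combined`.
#' @export
fishDeletionCalls <- function(fish, threshold = 50, allNuclei = FALSE) {
    stopifnot(all(c("sample", "chrom", "green", "red") %in% names(fish)))
    chroms <- unique(as.character(fish$chrom))
    samples <- unique(as.character(fish$sample))
    out <- data.frame(sample = samples, stringsAsFactors = FALSE)
    callMat <- matrix(NA_character_, length(samples), length(chroms))
    for (k in seq_along(chroms)) {
        pct <- vapply(samples, function(s) {
            sub <- fish[fish$sample == s & fish$chrom == chroms[k], ]
            if (!nrow(sub)) stop("sample ", s, " has no nuclei for ",
                                 chroms[k])
            deletionPercentage(sub$green, sub$red, allNuclei = allNuclei)
        }, numeric(1))
        cl <- callDeletion(pct, threshold)
        out[[paste0("pct.", chroms[k])]] <- unname(pct)
        out[[paste0("call.", chroms[k])]] <- unname(cl)
        callMat[, k] <- cl
    }
    out$call.combined <- ifelse(rowSums(callMat == "loss") == length(chroms),
                                "loss", "other")
    out
}

#' Build a 2x2 mutation-status by FISH-call contingency table
#'
#' Rows are mutation status (BRCA2 then BRCAX), columns the FISH call
#' (other then loss). The scope selects which call is tabulated: one
#' chromosome, or `both` requiring loss on every scored chromosome.
#'
#' @param calls output of [fishDeletionCalls()] or any `data.frame` with
#'   `sample` and the relevant `call.*` column.
#' @param labels named character vector (or `data.frame(sample, status)`)
#'   of mutation labels in `{BRCA2, BRCAX}`.
#' @param scope `"both"` or a chromosome name matching a `call.<chrom>`
#'   column.
#' @return 2x2 integer matrix with dimnames
#'   `list(c("BRCA2", "BRCAX"), c("other", "loss"))`.
#' @export
buildContingency <- function(calls, labels, scope = "both") {
    if (is.data.frame(labels))
        labels <- setNames(as.character(labels$status),
                           as.character(labels$sample))
    if (!nrow(calls)) stop("empty cohort")
    col <- if (scope == "both") "call.combined" else paste0("call.", scope)
    if (!col %in% names(calls))
        stop("no call column for scope '", scope, "'")
    status <- labels[as.character(calls$sample)]
    if (any(is.na(status))) stop("missing mutation labels for some samples")
    if (!all(status %in% c("BRCA2", "BRCAX")))
        stop("labels must be BRCA2 or BRCAX")
    cl <- factor(calls[[col]], levels = c("other", "loss"))
    st <- factor(status, levels = c("BRCA2", "BRCAX"))
    tab <- table(st, cl)
    matrix(as.integer(tab), 2, 2,
           dimnames = list(c("BRCA2", "BRCAX"), c("other", "loss")))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' With all margins fixed, the p-value is the sum of hypergeometric
#' probabilities of every table whose probability does not exceed that of
#' the observed table (the probability-ordering two-sided definition, as in
#' `stats::fisher.test`). Computed from the closed-form hypergeometric mass
#' over the support of the top-left cell.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return the two-sided p-value.
#' @export
#' @examples
#' fisherExactTwoSided(matrix(c(0, 8, 9, 1), 2))  # ~0.000411
fisherExactTwoSided <- function(table) {
    stopifnot(is.matrix(table), all(dim(table) == 2L),
              all(table >= 0), all(table == round(table)))
    r1 <- sum(table[1, ]); r2 <- sum(table[2, ])
    c1 <- sum(table[, 1])
    n <- r1 + r2
    if (n == 0L) return(1)
    support <- max(0L, c1 - r2):min(r1, c1)
    probs <- dhyper(support, r1, r2, c1)
    pObs <- dhyper(table[1, 1], r1, r2, c1)
    # relative tolerance guards against FP ties, as in stats::fisher.test
    min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

#' Sensitivity and specificity of the FISH screen
#'
#' Treating FISH loss as the positive screening result for BRCA2 mutation:
#' sensitivity is the fraction of BRCA2-mutant tumors called loss,
#' specificity the fraction of BRCAX tumors called other. Exact fractions
#' are returned alongside display percentages rounded to integers.
#'
#' @param table 2x2 matrix as built by [buildContingency()] (rows BRCA2,
#'   BRCAX; columns other, loss).
#' @return list with `sensitivity`, `specificity` (fractions) and
#'   `sensitivityPct`, `specificityPct` (rounded percentages).
#' @export
diagnosticMetrics <- function(table) {
    stopifnot(is.matrix(table), all(dim(table) == 2L))
    sens <- table["BRCA2", "loss"] / sum(table["BRCA2", ])
    spec <- table["BRCAX", "other"] / sum(table["BRCAX", ])
    list(sensitivity = sens, specificity = spec,
         sensitivityPct = round(100 * sens),
         specificityPct = round(100 * spec))
}

#' Published FISH deletion percentages
#'
#' The 18-sample two-chromosome FISH screening table shipped with the
#' package (9 BRCA2-mutant, 9 BRCAX tumors; percentage of informative
#' nuclei indicating loss of the 13q and 14q deletion probes).
#'
#' @return `data.frame(sample, status, chr13, chr14)`.
#' @export
#' @examples
#' head(fishScreenTable())
fishScreenTable <- function() {
    utils::read.delim(system.file("extdata",
        "fish_deletion_percentages.tsv", package = "brca2del"),
        colClasses = c("character", "character", "numeric", "numeric"))
}

#' Published 66-gene signature table
#'
#' The discovery signature shipped with the package: probeset, gene symbol,
#' cytogenetic band, moderated t-statistic and BH-adjusted p-value for the
#' 66 genes separating BRCA2-mutant from BRCAX tumors at FDR < 0.01.
#'
#' @return `data.frame(probeset, gene, band, t, p)`.
#' @export
#' @examples
#' nrow(brca2SignatureGenes())  # 66
brca2SignatureGenes <- function() {
    utils::read.delim(system.file("extdata", "brca2_signature_genes.tsv",
                                  package = "brca2del"),
                      colClasses = c("character", "character", "character",
                                     "numeric", "numeric"))
}
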