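#' Score samples with a weighted signature
#'
#' The per-sample score is the weighted sum of mean-centered expression
#' values, `S_j = sum_g w_g * (x_gj - m_g)`, with weights the signature's
#' moderated t-statistics. Because reduced-expression genes carry negative
#' weights, samples in which those genes are lost obtain positive scores:
#' higher score means more case-like.
#'
#' @param x matrix (genes x samples) or SummarizedExperiment; all signature
#'   genes must be present (missing genes raise an error listing them).
#' @param sig a [Signature-class].
#' @param center `"cohort"` (default) centers each gene at the scored
#'   cohort's own mean, the natural choice for a within-set analysis;
#'   `"reference"` freezes the training-cohort means stored in the
#'   signature, for scoring an external validation cohort.
#' @return named numeric vector of per-sample scores.
#' @export
#' @examples
#' m <- rbind(A = c(1, -1), B = c(0, 2))
#' sig <- new("Signature", genes = c("A", "B"),
#'            weights = c(A = 2, B = -1), referenceMeans = c(A = 0, B = 0))
#' scoreSamples(m, sig, center = "reference")
scoreSamples <- function(x, sig, center = c("cohort", "reference")) {
    center <- match.arg(center)
    m <- exprInput(x)$m
    genes <- signatureGenes(sig)
    if (!length(genes)) return(setNames(rep(0, ncol(m)), colnames(m)))
    missing <- setdiff(genes, rownames(m))
    if (length(missing))
        stop("signature genes absent from the matrix: ",
             paste(missing, collapse = ", "))
    sub <- m[genes, , drop = FALSE]
    ctr <- if (center == "reference") referenceMeans(sig)[genes]
           else rowMeans(sub)
    setNames(as.numeric(crossprod(sub - ctr, signatureWeights(sig)[genes])),
             colnames(m))
}

#' ROC curve and AUC for a two-group score
#'
#' The AUC is computed in the Mann-Whitney rank-sum form, i.e. the
#' probability that a random case scores above a random control with ties
#' counted 1/2; this equals the trapezoidal area under the empirical ROC
#' curve.
#'
#' @param scores numeric per-sample scores (higher = more case-like).
#' @param labels per-sample group labels.
#' @param case label of the positive class (defaults to `"BRCA2"` when
#'   present, else the second unique label).
#' @return list with `auc` and `curve`, a `data.frame(fpr, tpr)` starting at
#'   (0, 0) and ending at (1, 1), monotone nondecreasing in both
#'   coordinates (tied scores are collapsed into single diagonal steps).
#' @export
#' @examples
#' rocAuc(c(0.9, 0.8, 0.4, 0.7, 0.3, 0.1),
#'        rep(c("BRCA2", "BRCAX"), each = 3))$auc
rocAuc <- function(scores, labels, case = NULL) {
    labels <- as.character(labels)
    stopifnot(length(scores) == length(labels), all(is.finite(scores)))
    lev <- unique(labels)
    if (is.null(case)) case <- if ("BRCA2" %in% lev) "BRCA2" else lev[2]
    pos <- labels == case
    nPos <- sum(pos); nNeg <- sum(!pos)
    if (nPos == 0L || nNeg == 0L)
        stop("both classes must be non-empty")
    r <- rank(scores, ties.method = "average")
    auc <- (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
    # empirical ROC, sweeping the threshold down through unique scores
    thr <- sort(unique(scores), decreasing = TRUE)
    tpr <- vapply(thr, function(t) sum(pos & scores >= t) / nPos, numeric(1))
    fpr <- vapply(thr, function(t) sum(!pos & scores >= t) / nNeg, numeric(1))
    curve <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
    list(auc = auc, curve = curve)
}
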