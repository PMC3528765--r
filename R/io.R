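#' @importFrom utils read.delim write.table
NULL

#' Tab-separated readers and writers for the pipeline's plain-text formats
#'
#' Expression matrices are written with a `gene` ID first column and one
#' column per sample; labels as `sample`/`status` pairs; probe profiles in
#' BED-like form (`chrom`, `start`, `end`, `probe`, `log2ratio`, 0-based
#' half-open, plus `call` when present); BAF tracks as `chrom`, `pos`,
#' `snp`, `baf`, `het`; FISH counts as `sample`, `chrom`, `nucleus`,
#' `green`, `red`.
#'
#' @param x object to write.
#' @param path file path.
#' @name tsv-io
NULL

writeTsv <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname tsv-io
#' @export
writeExpressionTsv <- function(x, path) {
    m <- exprInput(x)$m
    writeTsv(data.frame(gene = rownames(m), m, check.names = FALSE), path)
}

#' @rdname tsv-io
#' @export
readExpressionTsv <- function(path) {
    df <- read.delim(path, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
}

#' @rdname tsv-io
#' @export
writeLabelsTsv <- function(x, path) {
    if (!is.data.frame(x))
        x <- data.frame(sample = names(x), status = as.character(x))
    writeTsv(x, path)
}

#' @rdname tsv-io
#' @export
readLabelsTsv <- function(path) {
    df <- read.delim(path, colClasses = "character")
    setNames(df$status, df$sample)
}

#' @rdname tsv-io
#' @export
writeProbeTsv <- function(x, path) {
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(x)),
                     start = GenomicRanges::start(x) - 1L,
                     end = GenomicRanges::end(x),
                     probe = x$probe,
                     log2ratio = x$log2ratio)
    if ("call" %in% names(S4Vectors::mcols(x)))
        df$call <- as.character(x$call)
    writeTsv(df, path)
}

#' @rdname tsv-io
#' @export
readProbeTsv <- function(path) {
    df <- read.delim(path)
    gr <- GenomicRanges::GRanges(df$chrom,
        IRanges::IRanges(start = df$start + 1L, end = df$end))
    gr$probe <- df$probe
    gr$log2ratio <- df$log2ratio
    if ("call" %in% names(df))
        gr$call <- factor(df$call, levels = c("gain", "neutral", "loss"))
    gr
}

#' @rdname tsv-io
#' @export
writeBafTsv <- function(x, path) {
    writeTsv(data.frame(chrom = as.character(GenomicRanges::seqnames(x)),
                        pos = GenomicRanges::start(x),
                        snp = x$snp, baf = x$baf, het = x$het), path)
}

#' @rdname tsv-io
#' @export
readBafTsv <- function(path) {
    df <- read.delim(path)
    gr <- GenomicRanges::GRanges(df$chrom,
        IRanges::IRanges(start = df$pos, width = 1L))
    gr$snp <- df$snp
    gr$baf <- df$baf
    gr$het <- as.logical(df$het)
    gr
}

#' @rdname tsv-io
#' @export
writeFishTsv <- function(x, path) writeTsv(x, path)

#' @rdname tsv-io
#' @export
readFishTsv <- function(path) {
    df <- read.delim(path)
    df$sample <- as.character(df$sample)
    df$chrom <- as.character(df$chrom)
    df
}

#' @rdname tsv-io
#' @export
writeRegionsTsv <- function(x, path) {
    writeTsv(data.frame(chrom = as.character(GenomicRanges::seqnames(x)),
                        start = GenomicRanges::start(x) - 1L,
                        end = GenomicRanges::end(x)), path)
}

#' @rdname tsv-io
#' @export
readRegionsTsv <- function(path) {
    df <- read.delim(path)
    GenomicRanges::GRanges(df$chrom,
        IRanges::IRanges(start = df$start + 1L, end = df$end))
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated set name, description,
#' then member genes.
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    sets <- lapply(lines, function(l) {
        parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
        parts[-(1:2)]
    })
    names(sets) <- vapply(lines, function(l)
        strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
    sets
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors.
#' @param path file path.
#' @param description per-set description column (recycled).
#' @export
writeGmt <- function(sets, path, description = "na") {
    description <- rep_len(description, length(sets))
    lines <- vapply(seq_along(sets), function(i)
        paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"),
        character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read a UCSC-dialect cytoband table
#'
#' Five tab-separated columns without header: chrom, start, end, band,
#' stain (0-based half-open coordinates).
#'
#' @param path file path.
#' @return `data.frame(chrom, start, end, band, stain)`.
#' @export
readCytobandTsv <- function(path) {
    df <- read.delim(path, header = FALSE,
                     col.names = c("chrom", "start", "end", "band", "stain"))
    df
}

#' Write/read ground truth as JSON
#'
#' Serializes the sample-level truth (group, tumor fraction, carried
#' regions) and true region boundaries of a [cohortTruth()] list.
#'
#' @param truth a [cohortTruth()] list.
#' @param path file path.
#' @name truth-io
#' @export
writeTruthJson <- function(truth, path) {
    obj <- list(
        samples = truth$samples,
        carried = as.data.frame(truth$carried),
        regions = data.frame(
            chrom = as.character(GenomicRanges::seqnames(truth$regions)),
            start = GenomicRanges::start(truth$regions) - 1L,
            end = GenomicRanges::end(truth$regions)),
        deletedBands = truth$deletedBands)
    jsonlite::write_json(obj, path, digits = NA, pretty = TRUE)
    invisible(path)
}
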