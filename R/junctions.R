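#' Read a STAR SJ.out.tab splice-junction table
#'
#' Parses the aligner's 9-column, header-less, tab-separated junction table:
#' chromosome, intron start and end (1-based, first/last intronic base),
#' strand code (0 undefined, 1 +, 2 -), intron motif code (0-6), annotation
#' flag, uniquely-mapping read count, multi-mapping read count, maximum
#' spliced-alignment overhang.  Downstream analyses use the unique read
#' counts only; multi-mapped reads are ignored.
#'
#' @param path path to an SJ.out.tab file.
#' @return A [GenomicRanges::GRanges] of junctions (range = intron) with
#'   metadata columns `strandCode`, `motif`, `annotated`, `uniqueReads`,
#'   `multiReads`, `maxOverhang`.
#' @export
readSJTab <- function(path) {
    if (!file.exists(path)) stopData("cannot read SJ file: ", path)
    lines <- readLines(path)
    if (!length(lines)) {
        warning("empty SJ.out.tab file: ", path)
        return(GRanges(strandCode = integer(0), motif = integer(0),
                       annotated = logical(0), uniqueReads = integer(0),
                       multiReads = integer(0), maxOverhang = integer(0)))
    }
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 9L)
    if (length(bad))
        stopData("expected 9 tab-separated columns at line ", bad[1],
                 " of ", path)
    f <- matrix(unlist(parts), ncol = 9L, byrow = TRUE)
    num <- suppressWarnings(apply(f[, 2:9, drop = FALSE], 2, as.integer))
    num <- matrix(num, ncol = 8L)
    if (anyNA(num))
        stopData("non-integer numeric field in ", path)
    strandCode <- num[, 3]
    gr <- GRanges(f[, 1],
                  IRanges(num[, 1], num[, 2]),
                  strand = c("*", "+", "-")[strandCode + 1L])
    mcols(gr) <- DataFrame(strandCode = strandCode, motif = num[, 4],
                           annotated = num[, 5] == 1L,
                           uniqueReads = num[, 6], multiReads = num[, 7],
                           maxOverhang = num[, 8])
    if (any(start(gr) > end(gr)))
        stopData("intron start > end in ", path)
    gr
}

.junctionKey <- function(gr) {
    paste(as.character(GenomicRanges::seqnames(gr)), start(gr), end(gr),
          mcols(gr)$strandCode, sep = ":")
}

#' Build a unified junction-read matrix over samples
#'
#' Takes one parsed junction table per sample and forms the union of all
#' junction keys (chromosome, intron start, intron end, strand code — two
#' junctions identical in coordinates but differing in strand are distinct).
#' Each cell holds the sample's unique-read count for that junction, 0 where
#' the sample did not report it.
#'
#' @param samples named list of `GRanges` from [readSJTab()] (>= 2 samples).
#' @return A \linkS4class{JunctionExperiment} in state `"raw"`, rows sorted
#'   by chromosome, start, end, strand code.
#' @export
buildUnifiedMatrix <- function(samples) {
    if (length(samples) < 2L || is.null(names(samples)))
        stopData("need a named list of >= 2 samples")
    keyList <- lapply(samples, .junctionKey)
    for (s in names(samples))
        if (anyDuplicated(keyList[[s]]))
            stopData("duplicate junction key within sample ", s)
    keys <- unique(unlist(keyList, use.names = FALSE))
    parts <- do.call(rbind, strsplit(keys, ":", fixed = TRUE))
    o <- order(parts[, 1], as.integer(parts[, 2]), as.integer(parts[, 3]),
               as.integer(parts[, 4]))
    keys <- keys[o]
    parts <- parts[o, , drop = FALSE]
    mat <- matrix(0, nrow = length(keys), ncol = length(samples),
                  dimnames = list(keys, names(samples)))
    for (s in names(samples)) {
        idx <- match(keyList[[s]], keys)
        mat[idx, s] <- mcols(samples[[s]])$uniqueReads
    }
    strandCode <- as.integer(parts[, 4])
    rr <- GRanges(parts[, 1],
                  IRanges(as.integer(parts[, 2]), as.integer(parts[, 3])),
                  strand = c("*", "+", "-")[strandCode + 1L],
                  strandCode = strandCode)
    names(rr) <- keys
    se <- SummarizedExperiment(assays = list(reads = mat), rowRanges = rr)
    metadata(se)$state <- "raw"
    new("JunctionExperiment", se)
}

#' Read a sample sheet and assemble the raw junction matrix
#'
#' @param sheet data.frame (or CSV path) with columns `sample_id`, `path`,
#'   `genotype`.
#' @return list with the raw \linkS4class{JunctionExperiment} (`matrix`) and
#'   the named `sample -> genotype` vector (`groups`).
#' @export
loadJunctionSamples <- function(sheet) {
    if (is.character(sheet))
        sheet <- utils::read.csv(sheet, stringsAsFactors = FALSE)
    need <- c("sample_id", "path", "genotype")
    if (!all(need %in% colnames(sheet)))
        stopData("sample sheet needs columns: ", paste(need, collapse = ", "))
    samples <- lapply(stats::setNames(sheet$path, sheet$sample_id), readSJTab)
    list(matrix = buildUnifiedMatrix(samples),
         groups = stats::setNames(sheet$genotype, sheet$sample_id))
}

#' Normalize junction reads to counts per million
#'
#' Divides each sample's junction-read vector by that sample's total unique
#' junction reads within the unified matrix and multiplies by 10^6, so every
#' column with positive total sums to one million.
#'
#' @param x a raw \linkS4class{JunctionExperiment}.
#' @return The matrix in state `"normalized"`.
#' @export
normalizeCPM <- function(x) {
    stopifnot(is(x, "JunctionExperiment"))
    if (junctionState(x) != "raw")
        stopData("normalizeCPM expects a raw matrix, got state '",
                 junctionState(x), "'")
    m <- assay(x, "reads")
    tot <- colSums(m)
    if (any(tot == 0))
        stopData("cannot normalize zero-total sample(s): ",
                 paste(colnames(m)[tot == 0], collapse = ", "))
    assay(x, "reads") <- sweep(m, 2, tot, "/") * 1e6
    metadata(x)$state <- "normalized"
    x
}

#' Average normalized junction vectors within genotypes
#'
#' @param x a normalized \linkS4class{JunctionExperiment}.
#' @param groups named character vector mapping every sample to a genotype.
#' @return Matrix with one column per genotype (arithmetic mean over its
#'   samples), state `"averaged"`.
#' @export
averageByGenotype <- function(x, groups) {
    stopifnot(is(x, "JunctionExperiment"))
    if (junctionState(x) != "normalized")
        stopData("averageByGenotype expects a normalized matrix, got '",
                 junctionState(x), "'")
    m <- assay(x, "reads")
    unassigned <- setdiff(colnames(m), names(groups))
    if (length(unassigned))
        stopData("sample(s) without genotype assignment: ",
                 paste(unassigned, collapse = ", "))
    g <- as.character(groups[colnames(m)])
    genos <- unique(g)
    avg <- vapply(genos,
                  function(gg) rowMeans(m[, g == gg, drop = FALSE]),
                  numeric(nrow(m)))
    avg <- matrix(avg, nrow = nrow(m), dimnames = list(rownames(m), genos))
    se <- SummarizedExperiment(assays = list(reads = avg),
                               rowRanges = rowRanges(x))
    metadata(se)$state <- "averaged"
    new("JunctionExperiment", se)
}

#' Drop junctions with low total normalized reads
#'
#' A junction is kept iff the sum of its normalized values across all
#' genotype columns is at least `threshold`; totals strictly smaller are
#' excluded (a total of exactly `threshold` is retained).
#'
#' @param x an averaged \linkS4class{JunctionExperiment}.
#' @param threshold total-normalized-reads cutoff (default 10).
#' @return Matrix in state `"filtered"`.
#' @export
filterLowTotal <- function(x, threshold = 10) {
    stopifnot(is(x, "JunctionExperiment"))
    if (junctionState(x) != "averaged")
        stopData("filterLowTotal expects an averaged matrix, got '",
                 junctionState(x), "'")
    keep <- rowSums(assay(x, "reads")) >= threshold
    out <- x[keep, ]
    metadata(out)$state <- "filtered"
    out
}

# Pearson r with the t-transform significance the correlation-panel tools
# use: t = r * sqrt(df) / sqrt(1 - r^2), df = n - 2, two-sided p.
.pearsonWithT <- function(a, b) {
    n <- length(a)
    if (stats::sd(a) == 0 || stats::sd(b) == 0)
        return(list(r = NA_real_, t = NA_real_, df = n - 2L, p = NA_real_))
    r <- stats::cor(a, b)
    df <- n - 2L
    tstat <- r * sqrt(df) / sqrt(max(1 - r^2, .Machine$double.eps))
    list(r = r, t = tstat, df = df,
         p = min(1, 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)))
}

#' Pairwise Pearson correlation of genotype junction-usage vectors
#'
#' In `"direct"` mode the filtered genotype columns are correlated as-is.
#' In `"delta"` mode each non-control genotype is reduced to its difference
#' vector against the control column (the altered-splicing signal) and the
#' differences are correlated — the view that asks whether two perturbations
#' changed the same junctions in the same direction.  Significance is the
#' two-sided t transform with `df = n_junctions - 2`.
#'
#' @param x a filtered \linkS4class{JunctionExperiment} (>= 3 junctions).
#' @param mode `"direct"` or `"delta"`.
#' @param control control genotype label; required for `"delta"`.
#' @return `DataFrame` of genotype pairs with columns `a`, `b`, `r`,
#'   `nJunctions`, `t`, `df`, `p`; the full symmetric correlation matrix is
#'   in `metadata(result)$rMatrix`.  A zero-variance column yields `NA`
#'   entries with a warning.
#' @export
pairwisePearson <- function(x, mode = c("direct", "delta"), control = NULL) {
    stopifnot(is(x, "JunctionExperiment"))
    mode <- match.arg(mode)
    if (junctionState(x) != "filtered")
        stopData("pairwisePearson expects a filtered matrix, got '",
                 junctionState(x), "'")
    m <- assay(x, "reads")
    if (nrow(m) < 3L)
        stopData("need >= 3 junctions after filtering, have ", nrow(m))
    if (mode == "delta") {
        if (is.null(control) || !control %in% colnames(m))
            stopData("delta mode requires a control genotype present in the ",
                     "matrix")
        m <- m[, setdiff(colnames(m), control), drop = FALSE] -
            m[, control]
    }
    if (ncol(m) < 2L)
        stopData("need >= 2 genotype columns to correlate")
    cols <- colnames(m)
    pairs <- utils::combn(cols, 2)
    res <- apply(pairs, 2, function(pr) .pearsonWithT(m[, pr[1]], m[, pr[2]]))
    if (any(vapply(res, function(z) is.na(z$r), TRUE)))
        warning("zero-variance column(s): correlation reported as NA")
    out <- DataFrame(a = pairs[1, ], b = pairs[2, ],
                     r = vapply(res, `[[`, 0, "r"),
                     nJunctions = nrow(m),
                     t = vapply(res, `[[`, 0, "t"),
                     df = vapply(res, function(z) as.integer(z$df), 0L),
                     p = vapply(res, `[[`, 0, "p"))
    rmat <- diag(1, length(cols))
    dimnames(rmat) <- list(cols, cols)
    for (j in seq_len(ncol(pairs))) {
        rmat[pairs[1, j], pairs[2, j]] <- out$r[j]
        rmat[pairs[2, j], pairs[1, j]] <- out$r[j]
    }
    metadata(out) <- list(mode = mode, control = control, rMatrix = rmat)
    out
}

#' Run the junction-concordance chain in one call
#'
#' Convenience wrapper: unify, CPM-normalize, average by genotype, apply the
#' low-total filter, correlate.
#'
#' @inheritParams buildUnifiedMatrix
#' @inheritParams averageByGenotype
#' @inheritParams filterLowTotal
#' @inheritParams pairwisePearson
#' @param log2p1 correlate on the `log2(x + 1)` scale (off by default; the
#'   chain is defined on the normalized scale).
#' @return The [pairwisePearson()] report.
#' @export
junctionConcordance <- function(samples, groups, threshold = 10,
                                mode = c("direct", "delta"),
                                control = NULL, log2p1 = FALSE) {
    raw <- if (is(samples, "JunctionExperiment")) samples
           else buildUnifiedMatrix(samples)
    filt <- filterLowTotal(averageByGenotype(normalizeCPM(raw), groups),
                           threshold)
    if (log2p1)
        assay(filt, "reads") <- log2(assay(filt, "reads") + 1)
    pairwisePearson(filt, match.arg(mode), control)
}
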