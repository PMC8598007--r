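# Fixture builders shared across the suite.  Everything is generated in
# code; nothing is read from static data files.

suppressPackageStartupMessages({
    library(S4Vectors)
    library(IRanges)
    library(GenomicRanges)
    library(SummarizedExperiment)
})

# A junction GRanges in the shape readSJTab() returns.
jgr <- function(start, uniqueReads, chrom = "chr1", width = 100,
                strandCode = 1L) {
    n <- length(start)
    gr <- GRanges(rep(chrom, length.out = n),
                  IRanges(start, start + width - 1),
                  strand = c("*", "+", "-")[rep(strandCode,
                                                length.out = n) + 1L])
    mcols(gr) <- DataFrame(strandCode = rep(strandCode, length.out = n),
                           motif = rep(2L, n),
                           annotated = rep(TRUE, n),
                           uniqueReads = as.integer(uniqueReads),
                           multiReads = rep(0L, n),
                           maxOverhang = rep(40L, n))
    gr
}

# Four samples over six junctions with exact per-sample totals of 1e5, so
# CPM values are 10x the raw counts.  Genotypes: g1 = {s1a, s1b}, g2, g3.
# Junction j4 has a post-averaging total of exactly 10 (the filter
# boundary); j5 totals 5 and must be dropped at the default threshold.
junctionOracleFixture <- function() {
    starts <- c(1000, 2000, 3000, 4000, 5000, 6000)
    counts <- list(
        s1a = c(5000, 200,   0, 1, 1, 94798),
        s1b = c(5200, 180,   0, 1, 0, 94619),
        s2  = c(4000, 300, 700, 0, 0, 95000),
        s3  = c(6000, 100, 650, 0, 0, 93250))
    stopifnot(all(vapply(counts, sum, 0) == 1e5))
    samples <- lapply(counts, function(cc) jgr(starts, cc))
    groups <- c(s1a = "g1", s1b = "g1", s2 = "g2", s3 = "g3")
    list(samples = samples, groups = groups, starts = starts,
         counts = counts)
}

# Independent brute-force recomputation of the junction chain from the raw
# per-sample count lists (plain arithmetic, no package calls).
junctionChainOracle <- function(counts, groups, starts, threshold = 10) {
    m <- do.call(cbind, counts)
    rownames(m) <- paste0("chr1:", starts, ":", starts + 99, ":1")
    cpm <- sweep(m, 2, colSums(m), "/") * 1e6
    genos <- unique(groups)
    avg <- sapply(genos, function(g)
        rowMeans(cpm[, names(groups)[groups == g], drop = FALSE]))
    avg[rowSums(avg) >= threshold, , drop = FALSE]
}

# Minimal rMATS-format TSV for a given category.
writeRmatsFixture <- function(pvalue, fdr, dpsi, category = "SE",
                              path = tempfile(fileext = ".txt"),
                              chrom = "chr1", strand = "+",
                              startOffset = 0L) {
    n <- length(pvalue)
    coordCols <- switch(category,
        SE = c("exonStart_0base", "exonEnd", "upstreamES", "upstreamEE",
               "downstreamES", "downstreamEE"),
        RI = c("riExonStart_0base", "riExonEnd", "upstreamES", "upstreamEE",
               "downstreamES", "downstreamEE"),
        A5SS = ,
        A3SS = c("longExonStart_0base", "longExonEnd", "shortES", "shortEE",
                 "flankingES", "flankingEE"),
        MXE = c("1stExonStart_0base", "1stExonEnd", "2ndExonStart_0base",
                "2ndExonEnd", "upstreamES", "upstreamEE", "downstreamES",
                "downstreamEE"))
    df <- data.frame(ID = seq_len(n) - 1L,
                     GeneID = sprintf("ENSG%06d", seq_len(n)),
                     geneSymbol = sprintf("G%04d", seq_len(n)),
                     chr = rep(chrom, length.out = n),
                     strand = rep(strand, length.out = n),
                     check.names = FALSE)
    for (j in seq_along(coordCols))
        df[[coordCols[j]]] <- startOffset + 1000L * seq_len(n) + 10L * j
    df$PValue <- pvalue
    df$FDR <- fdr
    df$IncLevelDifference <- dpsi
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
}

readRmatsFixture <- function(pvalue, fdr, dpsi, category = "SE", ...) {
    suppressMessages(
        readRmatsTable(writeRmatsFixture(pvalue, fdr, dpsi, category, ...),
                       category))
}

# A filtered JunctionExperiment with prescribed genotype columns, for
# correlation tests that need exact column vectors.
filteredJE <- function(m) {
    n <- nrow(m)
    rr <- GRanges(rep("chr1", n), IRanges(1000 * seq_len(n),
                                          1000 * seq_len(n) + 99),
                  strand = rep("+", n), strandCode = rep(1L, n))
    names(rr) <- paste0("j", seq_len(n))
    rownames(m) <- names(rr)
    se <- SummarizedExperiment(assays = list(reads = m), rowRanges = rr)
    metadata(se)$state <- "filtered"
    new("JunctionExperiment", se)
}

tinyScreen <- function(nTarget = 5, nOther = 15, nCompounds = 3,
                       seed = 42, noiseSd = 0.5) {
    withr::with_seed(seed, {
        lines <- sprintf("L%02d", seq_len(nTarget + nOther))
        m <- matrix(rnorm(nCompounds * length(lines), 0, noiseSd),
                    nrow = nCompounds,
                    dimnames = list(sprintf("c%02d", seq_len(nCompounds)),
                                    lines))
        ScreenExperiment(m, setNames(c(rep("neuroblastoma", nTarget),
                                       rep("other", nOther)), lines))
    })
}
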