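# Category-specific coordinate columns (rMATS headers, 0-based half-open).
.rmatsCoordCols <- function(category) {
    switch(category,
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
}

.eventKeys <- function(category, df) {
    if (nrow(df) == 0L) return(character(0))
    coords <- do.call(paste, c(df[.rmatsCoordCols(category)], sep = ":"))
    paste(category, df$chr, df$strand, coords, sep = ":")
}

.newEventTable <- function(df, category, provenance = list()) {
    ev <- DataFrame(
        geneId = df$GeneID, geneSymbol = df$geneSymbol, chrom = df$chr,
        strand = df$strand, pValue = df$PValue, fdr = df$FDR,
        incLevelDiff = df$IncLevelDifference,
        eventKey = .eventKeys(category, df))
    for (cc in .rmatsCoordCols(category)) ev[[cc]] <- df[[cc]]
    new("SpliceEventTable", events = ev, category = category,
        provenance = provenance)
}

#' Read an rMATS differential-splicing result table
#'
#' Parses one category's tab-separated result file (standard rMATS headers:
#' `GeneID`, `geneSymbol`, `chr`, `strand`, the category's coordinate
#' columns, `PValue`, `FDR`, `IncLevelDifference`).  Events whose inclusion
#' difference is `NA` are retained but flagged; filtering and correlation
#' drop them with a logged count.
#'
#' @param path path to the TSV.
#' @param category one of `"SE"`, `"A5SS"`, `"A3SS"`, `"MXE"`, `"RI"`.
#' @return A \linkS4class{SpliceEventTable}.
#' @export
readRmatsTable <- function(path, category = rmatsCategories()) {
    category <- match.arg(category)
    if (!file.exists(path)) stopData("cannot read rMATS table: ", path)
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE, na.strings = "NA")
    need <- c("GeneID", "geneSymbol", "chr", "strand", "PValue", "FDR",
              "IncLevelDifference", .rmatsCoordCols(category))
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stopData("rMATS table missing required column(s): ",
                 paste(miss, collapse = ", "))
    message("parsed ", nrow(df), " ", category, " events (",
            sum(is.na(df$IncLevelDifference)), " with missing deltaPSI)")
    .newEventTable(df, category)
}

#' Filter events to the significant set
#'
#' Keeps events with `fdr < fdrMax` and `|incLevelDiff| > dpsiMin` — both
#' bounds strictly exclusive, so an event at exactly the cutoff is dropped.
#' Events with missing inclusion difference cannot be assessed and are
#' dropped with their count recorded in the table's provenance.
#'
#' @param x a \linkS4class{SpliceEventTable}.
#' @param fdrMax FDR cutoff in (0, 1] (default 0.05).
#' @param dpsiMin minimum absolute inclusion-level difference in [0, 1)
#'   (default 0.1).
#' @param inclusive keep events at exactly the cutoffs (non-default variant).
#' @return The filtered table, provenance updated.
#' @export
filterSignificant <- function(x, fdrMax = 0.05, dpsiMin = 0.1,
                              inclusive = FALSE) {
    stopifnot(is(x, "SpliceEventTable"))
    if (fdrMax <= 0 || fdrMax > 1) stopConfig("fdrMax must be in (0, 1]")
    if (dpsiMin < 0 || dpsiMin >= 1) stopConfig("dpsiMin must be in [0, 1)")
    ev <- x@events
    missing <- is.na(ev$incLevelDiff)
    ev <- ev[!missing, , drop = FALSE]
    keep <- if (inclusive) {
        ev$fdr <= fdrMax & abs(ev$incLevelDiff) >= dpsiMin
    } else {
        ev$fdr < fdrMax & abs(ev$incLevelDiff) > dpsiMin
    }
    prov <- x@provenance
    prov$significance <- list(fdrMax = fdrMax, dpsiMin = dpsiMin,
                              inclusive = inclusive,
                              droppedMissingDpsi = sum(missing))
    new("SpliceEventTable", events = ev[keep, , drop = FALSE],
        category = x@category, provenance = prov)
}

#' Significant-event counts per category
#'
#' @param tables named list of \linkS4class{SpliceEventTable} objects (names
#'   are ignored; categories come from the tables).  Categories with no
#'   table count 0.
#' @return named integer vector over all five categories (SE, A5SS, A3SS,
#'   MXE, RI) — the per-category bar-plot numbers.
#' @export
countByCategory <- function(tables) {
    counts <- stats::setNames(integer(length(rmatsCategories())),
                              rmatsCategories())
    for (tb in tables) {
        stopifnot(is(tb, "SpliceEventTable"))
        counts[tb@category] <- counts[tb@category] + nrow(tb@events)
    }
    counts
}

#' Overlap of splicing events between two comparisons
#'
#' Event identity is the coordinate tuple (category, chromosome, strand,
#' exon/intron boundaries), never the run-local numeric ID, so events are
#' comparable across rMATS runs.
#'
#' @param a,b \linkS4class{SpliceEventTable} objects of the same category.
#' @return list with `shared`, `onlyA`, `onlyB` (counts partitioning the
#'   union) and `sharedKeys`.
#' @export
overlapEvents <- function(a, b) {
    stopifnot(is(a, "SpliceEventTable"), is(b, "SpliceEventTable"))
    if (a@category != b@category)
        stopData("cannot overlap tables of different categories: ",
                 a@category, " vs ", b@category)
    ka <- unique(a@events$eventKey)
    kb <- unique(b@events$eventKey)
    shared <- intersect(ka, kb)
    list(shared = length(shared), onlyA = length(setdiff(ka, kb)),
         onlyB = length(setdiff(kb, ka)), sharedKeys = shared)
}

#' Rank correlation of inclusion differences over shared events
#'
#' Spearman correlation of the two comparisons' deltaPSI values over the
#' events present in both tables with a non-missing inclusion difference;
#' ties receive average ranks, p is two-sided.
#'
#' @param a,b \linkS4class{SpliceEventTable} objects of the same category
#'   (>= 3 shared events required).
#' @return list with `rho`, `p`, `nShared`.
#' @export
correlateDpsi <- function(a, b) {
    ov <- overlapEvents(a, b)
    da <- a@events$incLevelDiff[match(ov$sharedKeys, a@events$eventKey)]
    db <- b@events$incLevelDiff[match(ov$sharedKeys, b@events$eventKey)]
    ok <- !is.na(da) & !is.na(db)
    if (sum(ok) < 3L)
        stopData("need >= 3 shared events with deltaPSI in both tables, ",
                 "have ", sum(ok))
    ct <- suppressWarnings(
        stats::cor.test(da[ok], db[ok], method = "spearman", exact = FALSE))
    list(rho = unname(ct$estimate), p = ct$p.value, nShared = sum(ok))
}
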