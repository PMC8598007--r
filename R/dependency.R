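#' Construct a DependencyExperiment
#'
#' @param scores numeric matrix of dependency scores, genes in rows, cell
#'   lines in columns (more negative = more dependent).
#' @param lineage named character vector or `cell_line_id,lineage`
#'   data.frame; lines without an annotation are kept with lineage `NA` and
#'   excluded from summaries.
#' @return A \linkS4class{DependencyExperiment}.
#' @export
DependencyExperiment <- function(scores, lineage) {
    scores <- as.matrix(scores)
    if (is.data.frame(lineage))
        lineage <- stats::setNames(as.character(lineage$lineage),
                                   lineage$cell_line_id)
    idx <- match(foldLabel(colnames(scores)), foldLabel(names(lineage)))
    lab <- ifelse(is.na(idx), NA_character_, foldLabel(lineage[idx]))
    se <- SummarizedExperiment(
        assays = list(score = scores),
        colData = DataFrame(lineage = lab, row.names = colnames(scores)))
    new("DependencyExperiment", se)
}

#' Load a dependency score matrix and lineage table from CSV
#'
#' @param path genes x cell-lines CSV, first column gene IDs.
#' @param lineagePath CSV with columns `cell_line_id`, `lineage`.
#' @return A \linkS4class{DependencyExperiment}.
#' @export
loadDependency <- function(path, lineagePath) {
    mat <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
    storage.mode(mat) <- "double"
    lin <- utils::read.csv(lineagePath, stringsAsFactors = FALSE)
    DependencyExperiment(mat, lin)
}

.geneScores <- function(x, gene) {
    if (!gene %in% rownames(x)) stopData("unknown gene: ", gene)
    v <- assay(x, "score")[gene, ]
    lin <- lineages(x)
    keep <- !is.na(v) & !is.na(lin) & lin != "NA"
    split(v[keep], lin[keep])
}

#' Per-lineage dependency summary for one gene
#'
#' Mean and SD of the gene's dependency score within each lineage with at
#' least one scored line, sorted by mean ascending (most dependent lineage
#' first) — the per-lineage mean +/- SD panel view.
#'
#' @param x a \linkS4class{DependencyExperiment}.
#' @param gene gene identifier present in `x`.
#' @return data.frame with columns `lineage`, `n`, `mean`, `sd` (sample SD;
#'   `NA` for singleton lineages).
#' @export
lineageSummary <- function(x, gene) {
    stopifnot(is(x, "DependencyExperiment"))
    by <- .geneScores(x, gene)
    out <- data.frame(
        lineage = names(by),
        n = vapply(by, length, 0L),
        mean = vapply(by, mean, 0),
        sd = vapply(by, stats::sd, 0),
        row.names = NULL)
    out[order(out$mean), , drop = FALSE]
}

#' Test one lineage's dependency against all others
#'
#' Two-sided test of the target lineage's scores for `gene` against the
#' pooled scores of every other lineage.  Default is Welch's
#' unequal-variance t test; a Wilcoxon rank-sum alternative is available.
#' P-values are reported unadjusted.
#'
#' @param x a \linkS4class{DependencyExperiment}.
#' @param gene gene identifier.
#' @param target target lineage label (>= 2 scored lines required, as for
#'   the rest).
#' @param method `"welch_t"` or `"rank_sum"`.
#' @return one-row data.frame: `geneId`, `target`, `nTarget`, `nRest`,
#'   `meanTarget`, `meanRest`, `meanDiff`, `statistic`, `pValue`, `method`.
#' @export
targetVsRestTest <- function(x, gene, target,
                             method = c("welch_t", "rank_sum")) {
    method <- match.arg(method)
    target <- foldLabel(target)
    by <- .geneScores(x, gene)
    if (!target %in% names(by)) stopData("unknown lineage: ", target)
    tv <- by[[target]]
    rv <- unlist(by[setdiff(names(by), target)], use.names = FALSE)
    if (length(tv) < 2L || length(rv) < 2L)
        stopData("need >= 2 scored lines in the target lineage and the rest")
    ht <- if (method == "welch_t") {
        stats::t.test(tv, rv, var.equal = FALSE)
    } else {
        stats::wilcox.test(tv, rv, exact = FALSE)
    }
    data.frame(geneId = gene, target = target,
               nTarget = length(tv), nRest = length(rv),
               meanTarget = mean(tv), meanRest = mean(rv),
               meanDiff = mean(tv) - mean(rv),
               statistic = unname(ht$statistic), pValue = ht$p.value,
               method = method, row.names = NULL)
}

#' Target-vs-rest tests across a gene panel
#'
#' Runs [targetVsRestTest()] for each gene and appends a Benjamini-Hochberg
#' adjusted p-value across the panel.  Genes absent from the matrix are
#' skipped with a warning.
#'
#' @inheritParams targetVsRestTest
#' @param genes non-empty character vector of gene identifiers.
#' @return data.frame, one row per tested gene, ordered by raw p-value, with
#'   an extra `pAdjBH` column.
#' @export
panelCompare <- function(x, genes, target,
                         method = c("welch_t", "rank_sum")) {
    method <- match.arg(method)
    if (!length(genes)) stopData("genes must be non-empty")
    missing <- setdiff(genes, rownames(x))
    if (length(missing))
        warning("skipping gene(s) absent from matrix: ",
                paste(missing, collapse = ", "))
    genes <- intersect(genes, rownames(x))
    if (!length(genes)) {
        warning("no panel genes present in the matrix")
        return(data.frame(geneId = character(0), target = character(0),
                          nTarget = integer(0), nRest = integer(0),
                          meanTarget = numeric(0), meanRest = numeric(0),
                          meanDiff = numeric(0), statistic = numeric(0),
                          pValue = numeric(0), method = character(0),
                          pAdjBH = numeric(0)))
    }
    out <- do.call(rbind, lapply(genes, targetVsRestTest,
                                 x = x, target = target, method = method))
    out$pAdjBH <- stats::p.adjust(out$pValue, method = "BH")
    out[order(out$pValue), , drop = FALSE]
}
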