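#' Construct a ScreenExperiment from a response matrix
#'
#' @param response numeric matrix, compounds in rows, cell lines in columns;
#'   `NA` marks missing measurements.
#' @param lineage named character vector (or data.frame with columns
#'   `cell_line_id`, `lineage`) mapping cell line to lineage.  Matching is
#'   exact after case-folding and whitespace trimming; lines without an
#'   annotation are dropped with a message.
#' @param screenKind `"log2fc"` or `"auc"`.
#' @return A \linkS4class{ScreenExperiment}.
#' @examples
#' m <- matrix(rnorm(6), 2, 3,
#'             dimnames = list(c("cpdA", "cpdB"), c("L1", "L2", "L3")))
#' ScreenExperiment(m, c(L1 = "neuroblastoma", L2 = "lung", L3 = "lung"))
#' @export
ScreenExperiment <- function(response, lineage,
                             screenKind = c("log2fc", "auc")) {
    screenKind <- match.arg(screenKind)
    response <- as.matrix(response)
    if (is.null(rownames(response)) || is.null(colnames(response)))
        stopData("response matrix must have compound and cell line names")
    if (anyDuplicated(colnames(response)))
        stopData("duplicated cell line identifiers in response matrix")
    if (anyDuplicated(rownames(response)))
        stopData("duplicated compound identifiers in response matrix")
    if (is.data.frame(lineage)) {
        if (!all(c("cell_line_id", "lineage") %in% colnames(lineage)))
            stopData("lineage table needs columns cell_line_id, lineage")
        if (anyDuplicated(lineage$cell_line_id))
            stopData("duplicated cell_line_id in lineage table")
        lineage <- stats::setNames(as.character(lineage$lineage),
                                   lineage$cell_line_id)
    }
    idx <- match(foldLabel(colnames(response)), foldLabel(names(lineage)))
    if (all(is.na(idx)))
        stopData("no overlap between lineage table and matrix cell line IDs")
    if (anyNA(idx)) {
        message(sum(is.na(idx)),
                " cell line(s) without lineage annotation dropped")
        response <- response[, !is.na(idx), drop = FALSE]
        idx <- idx[!is.na(idx)]
    }
    se <- SummarizedExperiment(
        assays = list(response = response),
        colData = DataFrame(lineage = foldLabel(lineage[idx]),
                            row.names = colnames(response)))
    metadata(se)$screenKind <- screenKind
    new("ScreenExperiment", se)
}

#' Load a wide pooled-screen CSV with a lineage annotation table
#'
#' Reads a compounds x cell-lines (or cell-lines x compounds; the orientation
#' is resolved against the lineage table) CSV of responses plus a two-column
#' `cell_line_id,lineage` CSV, and assembles a \linkS4class{ScreenExperiment}.
#' Missing entries are kept as `NA`.
#'
#' @param path CSV of responses; first column holds row identifiers.
#' @param lineagePath CSV with columns `cell_line_id`, `lineage`.
#' @param screenKind `"log2fc"` or `"auc"`.
#' @param orientation `"auto"` (match the axis that overlaps the lineage
#'   table), `"compounds_by_lines"`, or `"lines_by_compounds"`.
#' @return A \linkS4class{ScreenExperiment}.
#' @export
loadScreen <- function(path, lineagePath,
                       screenKind = c("log2fc", "auc"),
                       orientation = c("auto", "compounds_by_lines",
                                       "lines_by_compounds")) {
    screenKind <- match.arg(screenKind)
    orientation <- match.arg(orientation)
    if (!file.exists(path)) stopData("cannot read screen file: ", path)
    if (!file.exists(lineagePath))
        stopData("cannot read lineage file: ", lineagePath)
    raw <- utils::read.csv(path, row.names = 1, check.names = FALSE)
    mat <- as.matrix(raw)
    storage.mode(mat) <- "double"
    lin <- utils::read.csv(lineagePath, stringsAsFactors = FALSE)
    if (orientation == "auto") {
        hitCols <- sum(foldLabel(colnames(mat)) %in% foldLabel(lin$cell_line_id))
        hitRows <- sum(foldLabel(rownames(mat)) %in% foldLabel(lin$cell_line_id))
        if (hitRows > hitCols) mat <- t(mat)
    } else if (orientation == "lines_by_compounds") {
        mat <- t(mat)
    }
    se <- ScreenExperiment(mat, lin, screenKind)
    message("loaded screen: ", nrow(se), " compounds x ", ncol(se),
            " cell lines (", screenKind, ")")
    se
}

#' Remove cell lines flagged as failed
#'
#' Drops every cell line whose identifier contains the failure marker
#' substring (the screen distributor flags failed lines by suffixing their
#' IDs, e.g. `ACH-000010_FAILED_STR`).
#'
#' @param x a \linkS4class{ScreenExperiment}.
#' @param marker non-empty marker substring, matched fixed (not as a regex).
#' @return The screen without the flagged lines.
#' @export
filterFailedLines <- function(x, marker = "FAILED_STR") {
    stopifnot(is(x, "ScreenExperiment"))
    if (!nzchar(marker)) stopData("marker must be non-empty")
    bad <- grepl(marker, colnames(x), fixed = TRUE)
    if (any(bad))
        message("removed ", sum(bad), " failed cell line(s)")
    out <- x[, !bad]
    if (ncol(out) == 0L)
        warning("all cell lines matched the failure marker; screen is empty")
    out
}

#' Pivot long-format secondary-screen records into a ScreenExperiment
#'
#' Dose-response AUC files report one row per (cell line, compound, screen);
#' the distributor's documentation recommends a preferred screen when a pair
#' was measured more than once.  Rows from the preferred screen are kept; if
#' it is entirely absent the fallback screens are tried in order.
#'
#' @param records data.frame with columns `cell_line_id`, `compound_id`,
#'   `screen_id`, `auc` (and optionally `lineage`).
#' @param lineage lineage annotation as in [ScreenExperiment()].
#' @param preferred preferred `screen_id` (default `"MTS010"`).
#' @param fallback character vector of screens to try, in order, when the
#'   preferred screen has no rows.
#' @return A \linkS4class{ScreenExperiment} with `screenKind = "auc"`.
#' @export
selectSecondaryScreen <- function(records, lineage, preferred = "MTS010",
                                  fallback = character()) {
    need <- c("cell_line_id", "compound_id", "screen_id", "auc")
    miss <- setdiff(need, colnames(records))
    if (length(miss))
        stopData("records missing columns: ", paste(miss, collapse = ", "))
    for (sid in c(preferred, fallback)) {
        keep <- records[records$screen_id == sid, , drop = FALSE]
        if (nrow(keep)) {
            if (sid != preferred)
                warning("preferred screen '", preferred,
                        "' absent; using fallback '", sid, "'")
            mat <- with(keep, tapply(auc, list(compound_id, cell_line_id),
                                     function(v) v[1]))
            return(ScreenExperiment(mat, lineage, "auc"))
        }
    }
    stopData("no rows for preferred screen '", preferred,
             "' and no usable fallback")
}
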