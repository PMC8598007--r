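# Synthetic-data generators.  Every generator is a pure function of its
# parameters and seed (byte-identical reruns) and returns a ground-truth
# ledger alongside the data, so recovery tests read truth only from the
# ledger.

.defaultLineageSizes <- function() {
    # mirrors a pooled screen with a small target lineage: 5 target lines
    # among 541 with coverage, the remainder spread over 8 other lineages
    c(neuroblastoma = 5,
      stats::setNames(rep(67L, 8), paste0("lineage", 1:8)))
}

#' Simulate a pooled viability screen with planted selective compounds
#'
#' Responses are `Normal(0, noiseSd)` on the log2 fold-change scale, plus a
#' negative shift `effectSize` for planted selective compounds restricted to
#' the target lineage.  Entries are masked missing (`NA`) independently at
#' `missingRate`.
#'
#' @param nCompounds number of compounds (default 50).
#' @param lineageSizes named integer vector of lines per lineage; the
#'   default plants 5 target lines among 541 total.
#' @param targetLineage name of the (small) target lineage.
#' @param nSelective number of planted selective compounds (default 1).
#' @param effectSize planted shift in log2 fold-change units (default -1.3,
#'   the scale of a strongly lineage-selective compound).
#' @param noiseSd response noise SD (default 0.5).
#' @param missingRate independent missingness probability in [0, 1).
#' @param seed integer seed.
#' @param dir if non-NULL, the screen CSV, lineage CSV and truth JSON are
#'   written there.
#' @return list with `screen` (\linkS4class{ScreenExperiment}), `truth`
#'   (selective compound IDs, effect size, target lineage) and, when `dir`
#'   is given, `files`.
#' @export
simulateScreen <- function(nCompounds = 50,
                           lineageSizes = .defaultLineageSizes(),
                           targetLineage = names(lineageSizes)[1],
                           nSelective = 1, effectSize = -1.3,
                           noiseSd = 0.5, missingRate = 0, seed = 1,
                           dir = NULL) {
    if (nSelective > nCompounds)
        stopConfig("nSelective must not exceed nCompounds")
    if (missingRate < 0 || missingRate >= 1)
        stopConfig("missingRate must be in [0, 1)")
    if (!targetLineage %in% names(lineageSizes))
        stopConfig("targetLineage must name an entry of lineageSizes")
    nLines <- sum(lineageSizes)
    withSeed(seed, {
        lines <- sprintf("LINE%04d", seq_len(nLines))
        lineage <- rep(names(lineageSizes), lineageSizes)
        compounds <- sprintf("CPD%04d", seq_len(nCompounds))
        selective <- if (nSelective > 0) compounds[seq_len(nSelective)]
                     else character(0)
        m <- matrix(stats::rnorm(nCompounds * nLines, 0, noiseSd),
                    nrow = nCompounds,
                    dimnames = list(compounds, lines))
        isTarget <- lineage == targetLineage
        m[compounds %in% selective, isTarget] <-
            m[compounds %in% selective, isTarget] + effectSize
        if (missingRate > 0)
            m[stats::runif(length(m)) < missingRate] <- NA
        screen <- ScreenExperiment(m, stats::setNames(lineage, lines),
                                   "log2fc")
        truth <- list(selectiveCompounds = selective,
                      effectSize = effectSize,
                      targetLineage = foldLabel(targetLineage),
                      noiseSd = noiseSd, seed = seed)
        files <- NULL
        if (!is.null(dir)) {
            dir.create(dir, recursive = TRUE, showWarnings = FALSE)
            files <- file.path(dir, c("screen.csv", "lineage.csv",
                                      "screen_truth.json"))
            utils::write.csv(data.frame(compound_id = compounds, m,
                                        check.names = FALSE),
                             files[1], row.names = FALSE, na = "")
            utils::write.csv(data.frame(cell_line_id = lines,
                                        lineage = lineage),
                             files[2], row.names = FALSE)
            jsonlite::write_json(truth, files[3], auto_unbox = TRUE)
        }
        list(screen = screen, truth = truth, files = files)
    })
}

#' Simulate a gene-dependency matrix with planted lineage shifts
#'
#' Scores are `Normal(baseline_g, noiseSd)` with a per-gene baseline drawn
#' once, plus `shift` for planted (gene, lineage) cells.
#'
#' @param nGenes number of genes.
#' @param lineageSizes named integer vector of lines per lineage (default
#'   25 lineages of 8-40 lines).
#' @param planted data.frame with columns `gene`, `lineage`, `shift`
#'   (indices into the simulated gene set are written as `GENE####`).
#' @param noiseSd score noise SD (default 0.3).
#' @param seed integer seed.
#' @param dir optional output directory (score CSV + lineage CSV + truth).
#' @return list with `dependency` (\linkS4class{DependencyExperiment}),
#'   `truth`, and optional `files`.
#' @export
simulateDependency <- function(nGenes = 20,
                               lineageSizes = NULL,
                               planted = data.frame(gene = character(0),
                                                    lineage = character(0),
                                                    shift = numeric(0)),
                               noiseSd = 0.3, seed = 1, dir = NULL) {
    if (is.null(lineageSizes))
        lineageSizes <- withSeed(seed + 17, c(
            neuroblastoma = 12L,
            stats::setNames(sample(8:40, 24, replace = TRUE),
                            paste0("lineage", 1:24))))
    bad <- setdiff(planted$lineage, names(lineageSizes))
    if (length(bad))
        stopConfig("planted lineage(s) absent: ", paste(bad, collapse = ", "))
    nLines <- sum(lineageSizes)
    withSeed(seed, {
        genes <- sprintf("GENE%04d", seq_len(nGenes))
        lines <- sprintf("DLINE%04d", seq_len(nLines))
        lineage <- rep(names(lineageSizes), lineageSizes)
        baseline <- stats::rnorm(nGenes, -0.2, 0.2)
        m <- matrix(stats::rnorm(nGenes * nLines, 0, noiseSd) + baseline,
                    nrow = nGenes, dimnames = list(genes, lines))
        for (i in seq_len(nrow(planted))) {
            g <- planted$gene[i]
            if (!g %in% genes) stopConfig("planted gene absent: ", g)
            m[g, lineage == planted$lineage[i]] <-
                m[g, lineage == planted$lineage[i]] + planted$shift[i]
        }
        dep <- DependencyExperiment(m, stats::setNames(lineage, lines))
        truth <- list(planted = planted, noiseSd = noiseSd, seed = seed)
        files <- NULL
        if (!is.null(dir)) {
            dir.create(dir, recursive = TRUE, showWarnings = FALSE)
            files <- file.path(dir, c("dependency.csv",
                                      "dependency_lineage.csv"))
            utils::write.csv(data.frame(gene_id = genes, m,
                                        check.names = FALSE),
                             files[1], row.names = FALSE)
            utils::write.csv(data.frame(cell_line_id = lines,
                                        lineage = lineage),
                             files[2], row.names = FALSE)
        }
        list(dependency = dep, truth = truth, files = files)
    })
}

#' Construct perturbed-junction index sets with a given shared fraction
#'
#' Builds two subsets of `nPerturbed` junctions each from a universe of
#' `nJunctions`, sharing exactly `round(f * nPerturbed)` members — the
#' design used to study how concordance grows with the overlap of two
#' perturbations' splicing footprints.
#'
#' @param nJunctions size of the junction universe.
#' @param nPerturbed perturbed-set size per genotype.
#' @param f shared fraction in [0, 1].
#' @param seed integer seed.
#' @return list with integer index vectors `a` and `b`.
#' @export
sharedPerturbedSets <- function(nJunctions, nPerturbed, f, seed = 1) {
    if (f < 0 || f > 1) stopConfig("f must be in [0, 1]")
    nShared <- round(f * nPerturbed)
    need <- 2 * nPerturbed - nShared
    if (need > nJunctions)
        stopConfig("universe too small for the requested sets")
    withSeed(seed, {
        pool <- sample.int(nJunctions, need)
        list(a = sort(pool[seq_len(nPerturbed)]),
             b = sort(pool[c(seq_len(nShared),
                             (nPerturbed + 1):need)]))
    })
}

#' Simulate STAR-style splice-junction tables
#'
#' A universe of junctions receives log-normal abundance weights; per-sample
#' unique read counts are negative binomial (overdispersed, as RNA-seq
#' junction counts are) around `depth` times the junction's relative weight,
#' with a multiplicative fold-change applied to each genotype's perturbed
#' junctions.  The fold direction (up `foldChange` or down `1/foldChange`)
#' is a fixed property of the junction, so genotypes sharing a perturbed
#' junction move it the same way.
#'
#' @param nJunctions junction universe size (default 1000).
#' @param genotypes named integer vector of replicate counts per genotype.
#' @param depth expected total junction reads per sample (default 2e5).
#' @param mu,tau log-normal abundance parameters (default 3, 1.5).
#' @param dispersion negative-binomial overdispersion (default 0.05;
#'   `size = 1/dispersion`).
#' @param perturbed named list: genotype -> integer indices of perturbed
#'   junctions (genotypes absent from the list are unperturbed).
#' @param foldChange multiplicative perturbation magnitude (> 1).
#' @param seed integer seed.
#' @param dir if non-NULL, one `<sample>.SJ.out.tab` file per sample plus a
#'   sample sheet CSV are written there.
#' @return list with `samples` (named list of junction `GRanges`, one per
#'   sample, as [readSJTab()] returns), `groups` (sample -> genotype),
#'   `truth` (perturbed keys per genotype, fold directions), and optional
#'   `files`.
#' @export
simulateJunctions <- function(nJunctions = 1000,
                              genotypes = c(control = 3, shKD = 3,
                                            degrader = 3),
                              depth = 2e5, mu = 3, tau = 1.5,
                              dispersion = 0.05,
                              perturbed = list(), foldChange = 4,
                              seed = 1, dir = NULL) {
    if (depth <= 0) stopConfig("depth must be positive")
    bad <- setdiff(names(perturbed), names(genotypes))
    if (length(bad))
        stopConfig("perturbed genotype(s) absent: ", paste(bad, collapse = ", "))
    for (idx in perturbed)
        if (length(idx) && (min(idx) < 1 || max(idx) > nJunctions))
            stopConfig("perturbed indices outside the junction universe")
    withSeed(seed, {
        chrom <- paste0("chr", sample(1:22, nJunctions, replace = TRUE))
        st <- sample.int(1e7, nJunctions) + 1000L
        en <- st + sample(80:5000, nJunctions, replace = TRUE)
        strandCode <- sample(1:2, nJunctions, replace = TRUE)
        motif <- sample(0:5, nJunctions, replace = TRUE)
        annotated <- sample(c(TRUE, FALSE), nJunctions, replace = TRUE,
                            prob = c(0.8, 0.2))
        w <- stats::rlnorm(nJunctions, mu, tau)
        foldDir <- ifelse(stats::runif(nJunctions) < 0.5,
                          foldChange, 1 / foldChange)
        template <- GRanges(chrom, IRanges(st, en),
                            strand = c("*", "+", "-")[strandCode + 1L])
        keys <- paste(chrom, st, en, strandCode, sep = ":")
        samples <- list()
        groups <- character(0)
        for (g in names(genotypes)) {
            fold <- rep(1, nJunctions)
            pj <- perturbed[[g]]
            if (length(pj)) fold[pj] <- foldDir[pj]
            lam <- depth * (w * fold) / sum(w * fold)
            for (r in seq_len(genotypes[[g]])) {
                sid <- paste0(g, "_rep", r)
                cnt <- stats::rnbinom(nJunctions, mu = lam,
                                      size = 1 / dispersion)
                gr <- template
                mcols(gr) <- DataFrame(strandCode = strandCode,
                                       motif = motif, annotated = annotated,
                                       uniqueReads = cnt,
                                       multiReads = stats::rpois(nJunctions,
                                                                 2),
                                       maxOverhang = sample(20:90, nJunctions,
                                                            replace = TRUE))
                samples[[sid]] <- gr
                groups[sid] <- g
            }
        }
        truth <- list(perturbedKeys = lapply(perturbed,
                                             function(i) keys[sort(i)]),
                      foldDirections = foldDir, keys = keys, seed = seed)
        files <- NULL
        if (!is.null(dir)) {
            dir.create(dir, recursive = TRUE, showWarnings = FALSE)
            files <- vapply(names(samples), function(sid) {
                p <- file.path(dir, paste0(sid, ".SJ.out.tab"))
                writeSJTab(samples[[sid]], p)
                p
            }, "")
            sheet <- file.path(dir, "samples.csv")
            utils::write.csv(data.frame(sample_id = names(samples),
                                        path = unname(files),
                                        genotype = unname(groups)),
                             sheet, row.names = FALSE)
            files <- c(files, samples.csv = sheet)
        }
        list(samples = samples, groups = groups, truth = truth,
             files = files)
    })
}

#' Write a junction GRanges back to the 9-column SJ.out.tab dialect
#'
#' @param gr junction `GRanges` as returned by [readSJTab()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSJTab <- function(gr, path) {
    mc <- mcols(gr)
    df <- data.frame(as.character(GenomicRanges::seqnames(gr)),
                     start(gr), end(gr), mc$strandCode, mc$motif,
                     as.integer(mc$annotated), mc$uniqueReads,
                     mc$multiReads, mc$maxOverhang)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

# Monotone map from a standard-normal draw to a significant deltaPSI in
# +/-(0.1, 0.95]; rank correlation of the underlying normals is preserved.
.zToDpsi <- function(z) {
    q <- stats::pnorm(z)
    sign(q - 0.5) * (0.1 + 0.85 * abs(2 * q - 1))
}

#' Simulate paired rMATS-style differential-splicing tables
#'
#' For each category, a shared universe of events is generated; a planted
#' fraction is significant in each of two comparisons (A and B) with a
#' controlled overlap, and the deltaPSI values of shared significant events
#' are drawn from a Gaussian copula calibrated so their Spearman rank
#' correlation is `dpsiCorrelation`.  Significant events have tiny p-values
#' and |deltaPSI| > 0.1; background events have p >= 0.1 and |deltaPSI| <
#' 0.1, so the planted significant set is exactly the set that survives the
#' standard FDR < 0.05, |deltaPSI| > 0.1 filter.  FDR columns are the
#' Benjamini-Hochberg transform of the simulated p-values.
#'
#' @param nEvents named integer vector of universe sizes per category.
#' @param fracSignificant fraction planted significant per comparison.
#' @param overlapFraction fraction of each comparison's significant events
#'   shared with the other.
#' @param dpsiCorrelation target Spearman correlation of shared deltaPSI.
#' @param naRate fraction of background events with missing deltaPSI.
#' @param seed integer seed.
#' @param dir if non-NULL, `<category>_{A,B}.txt` TSVs are written there.
#' @return list with `tables` (per category: list of `SpliceEventTable` `a`,
#'   `b`), `truth` (per category: significant keys in A and B, shared count)
#'   and optional `files`.
#' @export
simulateRmatsTables <- function(nEvents = c(SE = 300, A5SS = 80, A3SS = 80,
                                            MXE = 60, RI = 120),
                                fracSignificant = 0.2,
                                overlapFraction = 0.6,
                                dpsiCorrelation = 0.7,
                                naRate = 0.02, seed = 1, dir = NULL) {
    if (fracSignificant < 0 || fracSignificant > 0.5)
        stopConfig("fracSignificant must be in [0, 0.5] so both comparisons fit")
    if (overlapFraction < 0 || overlapFraction > 1)
        stopConfig("overlapFraction must be in [0, 1]")
    if (abs(dpsiCorrelation) > 1)
        stopConfig("dpsiCorrelation must be in [-1, 1]")
    bad <- setdiff(names(nEvents), rmatsCategories())
    if (length(bad))
        stopConfig("unknown categories: ", paste(bad, collapse = ", "))
    rhoPearson <- 2 * sin(pi * dpsiCorrelation / 6)
    tables <- list()
    truth <- list()
    files <- character(0)
    if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (cat in names(nEvents)) {
        n <- nEvents[[cat]]
        res <- withSeed(substreamSeed(seed, cat), {
            coordCols <- .rmatsCoordCols(cat)
            st <- sort(sample.int(5e7, n))
            coords <- lapply(seq_along(coordCols), function(j)
                st + 200L * (j - 1L) + sample(0:50, n, replace = TRUE))
            names(coords) <- coordCols
            df0 <- data.frame(
                ID = seq_len(n) - 1L,
                GeneID = sprintf("ENSG%08d", seq_len(n)),
                geneSymbol = sprintf("G%s%04d", cat, seq_len(n)),
                chr = paste0("chr", sample(1:22, n, replace = TRUE)),
                strand = sample(c("+", "-"), n, replace = TRUE),
                check.names = FALSE)
            for (cc in coordCols) df0[[cc]] <- coords[[cc]]
            m <- as.integer(round(fracSignificant * n))
            s <- as.integer(round(overlapFraction * m))
            sigA <- seq_len(m)
            sigB <- if (m > 0) c(seq_len(s),
                                 seq.int(m + 1, length.out = m - s)) else integer(0)
            z <- matrix(stats::rnorm(2 * n), ncol = 2)
            z[, 2] <- rhoPearson * z[, 1] +
                sqrt(1 - rhoPearson^2) * z[, 2]
            mkTable <- function(sig, zcol) {
                p <- stats::runif(n, 0.1, 1)
                p[sig] <- stats::runif(length(sig), 0, 1e-6)
                dpsi <- stats::runif(n, -0.08, 0.08)
                dpsi[sig] <- .zToDpsi(zcol[sig])
                bg <- setdiff(seq_len(n), sig)
                nNA <- round(naRate * length(bg))
                if (nNA > 0) dpsi[sample(bg, nNA)] <- NA
                df <- df0
                df$PValue <- p
                df$FDR <- stats::p.adjust(p, method = "BH")
                df$IncLevelDifference <- dpsi
                df
            }
            dfA <- mkTable(sigA, z[, 1])
            dfB <- mkTable(sigB, z[, 2])
            keys <- .eventKeys(cat, df0)
            list(a = .newEventTable(dfA, cat), b = .newEventTable(dfB, cat),
                 dfA = dfA, dfB = dfB,
                 truth = list(sigKeysA = keys[sigA], sigKeysB = keys[sigB],
                              nSignificant = m, nShared = s,
                              dpsiCorrelation = dpsiCorrelation))
        })
        tables[[cat]] <- list(a = res$a, b = res$b)
        truth[[cat]] <- res$truth
        if (!is.null(dir)) {
            fa <- file.path(dir, paste0(cat, "_A.txt"))
            fb <- file.path(dir, paste0(cat, "_B.txt"))
            utils::write.table(res$dfA, fa, sep = "\t", quote = FALSE,
                               row.names = FALSE)
            utils::write.table(res$dfB, fb, sep = "\t", quote = FALSE,
                               row.names = FALSE)
            files <- c(files, fa, fb)
        }
    }
    list(tables = tables, truth = truth,
         files = if (length(files)) files else NULL)
}
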