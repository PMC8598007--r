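# Pipeline orchestration: YAML run configuration, staged execution with a
# manifest of parameters and file digests, digest-based reuse of stage
# outputs.

.configDefaults <- function() list(
    seed = 1L,
    outDir = "glueSelect_run",
    stages = c("simulate", "screen", "junctions", "rmats", "dependency"),
    screen = list(targetLineage = "neuroblastoma", nDraws = 100000L,
                  alternative = "less", minTargetN = 2L, minOtherN = 2L,
                  responsePath = NULL, lineagePath = NULL,
                  screenKind = "log2fc", failedMarker = "FAILED_STR"),
    junctions = list(threshold = 10, mode = "direct", control = NULL,
                     sampleSheet = NULL, log2p1 = FALSE),
    rmats = list(fdrMax = 0.05, dpsiMin = 0.1, tables = NULL),
    dependency = list(genes = NULL, targetLineage = "neuroblastoma",
                      method = "welch_t", scorePath = NULL,
                      lineagePath = NULL),
    simulate = list(screen = list(), junctions = list(), rmats = list(),
                    dependency = list()))

.mergeBlock <- function(defaults, user, block) {
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown))
        stopConfig("unknown key(s) in '", block, "': ",
                   paste(unknown, collapse = ", "))
    defaults[names(user)] <- user
    defaults
}

#' Validate a YAML run configuration
#'
#' Reads the run configuration, rejects unknown keys (named individually),
#' fills defaults (permutation draws 1e5, FDR cutoff 0.05, minimum
#' |deltaPSI| 0.1, junction low-total threshold 10), checks parameter
#' ranges, and verifies that every referenced input path exists.
#'
#' @param path YAML file, or a list already in memory.
#' @return the fully-resolved configuration (a list) with class
#'   `"glueSelectConfig"`.
#' @export
validateConfig <- function(path) {
    user <- if (is.list(path)) path else yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    defs <- .configDefaults()
    cfg <- .mergeBlock(defs, user[setdiff(names(user),
                                          c("screen", "junctions", "rmats",
                                            "dependency", "simulate"))],
                       "top level")
    for (blk in c("screen", "junctions", "rmats", "dependency", "simulate"))
        if (!is.null(user[[blk]]))
            cfg[[blk]] <- .mergeBlock(defs[[blk]], user[[blk]], blk)
    cfg$seed <- as.integer(cfg$seed)
    bad <- character(0)
    if (cfg$screen$nDraws < 1) bad <- c(bad, "screen.nDraws must be >= 1")
    if (!cfg$screen$alternative %in% c("less", "greater", "two_sided"))
        bad <- c(bad, "screen.alternative invalid")
    if (cfg$rmats$fdrMax <= 0 || cfg$rmats$fdrMax > 1)
        bad <- c(bad, "rmats.fdrMax must be in (0, 1]")
    if (cfg$rmats$dpsiMin < 0 || cfg$rmats$dpsiMin >= 1)
        bad <- c(bad, "rmats.dpsiMin must be in [0, 1)")
    if (cfg$junctions$threshold < 0)
        bad <- c(bad, "junctions.threshold must be >= 0")
    unknownStages <- setdiff(cfg$stages, defs$stages)
    if (length(unknownStages))
        bad <- c(bad, paste("unknown stage(s):",
                            paste(unknownStages, collapse = ", ")))
    for (p in c(cfg$screen$responsePath, cfg$screen$lineagePath,
                cfg$junctions$sampleSheet, cfg$dependency$scorePath,
                cfg$dependency$lineagePath, unlist(cfg$rmats$tables)))
        if (!is.null(p) && !file.exists(p))
            bad <- c(bad, paste("input path does not exist:", p))
    if (length(bad))
        stopConfig("invalid configuration:\n  ",
                   paste(bad, collapse = "\n  "))
    structure(cfg, class = "glueSelectConfig")
}

.digests <- function(paths) {
    paths <- paths[file.exists(paths)]
    if (!length(paths)) return(list())
    as.list(tools::md5sum(paths))
}

.stageUpToDate <- function(manifest, stage, inputs, outputs) {
    rec <- manifest$stages[[stage]]
    if (is.null(rec)) return(FALSE)
    identical(rec$inputs, .digests(inputs)) &&
        all(file.exists(outputs)) &&
        identical(rec$outputs, .digests(outputs))
}

#' Run the configured pipeline stages
#'
#' Executes the selected stages (synthetic-data generation, screen
#' selectivity, junction concordance, rMATS post-processing, dependency
#' comparison) into a run directory.  All randomness derives from the global
#' seed through per-stage substreams, so any stage is reproducible in
#' isolation; the manifest records effective parameters and md5 digests of
#' every stage's inputs and outputs, and a stage whose inputs and outputs
#' both match the manifest is reused rather than recomputed (a corrupted
#' intermediate is detected by digest mismatch and recomputed).
#'
#' @param config a validated configuration ([validateConfig()]), or a path
#'   /list to validate.
#' @return the run directory path, invisibly; outputs are TSV/JSON files
#'   plus `manifest.json`.
#' @export
runPipeline <- function(config) {
    if (!inherits(config, "glueSelectConfig"))
        config <- validateConfig(config)
    out <- config$outDir
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    manifestPath <- file.path(out, "manifest.json")
    manifest <- if (file.exists(manifestPath))
        jsonlite::read_json(manifestPath) else list(stages = list())
    manifest$seed <- config$seed
    manifest$package <- as.character(utils::packageVersion("glueSelect"))
    manifest$parameters <- unclass(config)
    record <- function(stage, inputs, outputs) {
        manifest$stages[[stage]] <<- list(inputs = .digests(inputs),
                                          outputs = .digests(outputs))
    }
    simDir <- file.path(out, "inputs")
    if ("simulate" %in% config$stages) {
        outputs <- file.path(simDir, c("screen.csv", "lineage.csv",
                                       "samples.csv", "dependency.csv",
                                       "dependency_lineage.csv"))
        if (!.stageUpToDate(manifest, "simulate", character(0), outputs)) {
            message("[simulate] generating synthetic inputs")
            do.call(simulateScreen,
                    c(list(seed = substreamSeed(config$seed, "screen"),
                           dir = simDir), config$simulate$screen))
            do.call(simulateJunctions,
                    c(list(seed = substreamSeed(config$seed, "junctions"),
                           dir = simDir), config$simulate$junctions))
            do.call(simulateDependency,
                    c(list(seed = substreamSeed(config$seed, "dependency"),
                           dir = simDir), config$simulate$dependency))
            do.call(simulateRmatsTables,
                    c(list(seed = substreamSeed(config$seed, "rmats"),
                           dir = simDir), config$simulate$rmats))
        } else message("[simulate] up to date, reusing")
        record("simulate", character(0), outputs)
    }
    if ("screen" %in% config$stages) {
        sc <- config$screen
        respPath <- sc$responsePath %||% file.path(simDir, "screen.csv")
        linPath <- sc$lineagePath %||% file.path(simDir, "lineage.csv")
        outputs <- file.path(out, c("selectivity.tsv", "selectivity.json"))
        if (!.stageUpToDate(manifest, "screen", c(respPath, linPath),
                            outputs)) {
            message("[screen] selectivity ranking")
            screen <- loadScreen(respPath, linPath, sc$screenKind)
            screen <- filterFailedLines(screen, sc$failedMarker)
            cfg <- PermutationConfig(
                nDraws = sc$nDraws,
                seed = substreamSeed(config$seed, "screen"),
                alternative = sc$alternative,
                minTargetN = sc$minTargetN, minOtherN = sc$minOtherN)
            res <- selectivityScreen(screen, sc$targetLineage, cfg)
            utils::write.table(as.data.frame(res), outputs[1], sep = "\t",
                               quote = FALSE, row.names = FALSE)
            jsonlite::write_json(
                list(targetLineage = sc$targetLineage, nDraws = sc$nDraws,
                     seed = config$seed, nCompounds = nrow(res),
                     nRanked = sum(res$status == "ok")),
                outputs[2], auto_unbox = TRUE)
        } else message("[screen] up to date, reusing")
        record("screen", c(respPath, linPath), outputs)
    }
    if ("junctions" %in% config$stages) {
        jc <- config$junctions
        sheet <- jc$sampleSheet %||% file.path(simDir, "samples.csv")
        outputs <- file.path(out, c("junction_correlations.tsv",
                                    "junction_correlations.json"))
        sheetDf <- utils::read.csv(sheet, stringsAsFactors = FALSE)
        inputs <- c(sheet, sheetDf$path)
        if (!.stageUpToDate(manifest, "junctions", inputs, outputs)) {
            message("[junctions] concordance analysis")
            loaded <- loadJunctionSamples(sheetDf)
            corr <- junctionConcordance(loaded$matrix, loaded$groups,
                                        threshold = jc$threshold,
                                        mode = jc$mode, control = jc$control,
                                        log2p1 = isTRUE(jc$log2p1))
            utils::write.table(as.data.frame(corr), outputs[1], sep = "\t",
                               quote = FALSE, row.names = FALSE)
            jsonlite::write_json(
                list(mode = jc$mode, threshold = jc$threshold,
                     nJunctions = corr$nJunctions[1],
                     pairs = as.data.frame(corr)),
                outputs[2], auto_unbox = TRUE, digits = NA)
        } else message("[junctions] up to date, reusing")
        record("junctions", inputs, outputs)
    }
    if ("rmats" %in% config$stages) {
        rm <- config$rmats
        tabs <- rm$tables
        if (is.null(tabs)) {
            cats <- rmatsCategories()
            tabs <- lapply(stats::setNames(cats, cats), function(cc)
                list(a = file.path(simDir, paste0(cc, "_A.txt")),
                     b = file.path(simDir, paste0(cc, "_B.txt"))))
            tabs <- Filter(function(tt) file.exists(tt$a), tabs)
        }
        inputs <- unlist(tabs, use.names = FALSE)
        outputs <- file.path(out, c("splice_event_counts.tsv",
                                    "splice_overlap.json"))
        if (!.stageUpToDate(manifest, "rmats", inputs, outputs)) {
            message("[rmats] event filtering, overlap, correlation")
            sig <- lapply(names(tabs), function(cc) {
                a <- filterSignificant(readRmatsTable(tabs[[cc]]$a, cc),
                                       rm$fdrMax, rm$dpsiMin)
                b <- filterSignificant(readRmatsTable(tabs[[cc]]$b, cc),
                                       rm$fdrMax, rm$dpsiMin)
                list(a = a, b = b)
            })
            names(sig) <- names(tabs)
            counts <- countByCategory(lapply(sig, `[[`, "a"))
            utils::write.table(
                data.frame(category = names(counts), n = as.integer(counts)),
                outputs[1], sep = "\t", quote = FALSE, row.names = FALSE)
            summ <- lapply(sig, function(tt) {
                ov <- overlapEvents(tt$a, tt$b)
                cd <- if (ov$shared >= 3)
                    correlateDpsi(tt$a, tt$b) else NULL
                list(shared = ov$shared, onlyA = ov$onlyA, onlyB = ov$onlyB,
                     spearmanRho = cd$rho, spearmanP = cd$p)
            })
            jsonlite::write_json(summ, outputs[2], auto_unbox = TRUE,
                                 digits = NA)
        } else message("[rmats] up to date, reusing")
        record("rmats", inputs, outputs)
    }
    if ("dependency" %in% config$stages) {
        dp <- config$dependency
        scorePath <- dp$scorePath %||% file.path(simDir, "dependency.csv")
        linPath <- dp$lineagePath %||% file.path(simDir,
                                                 "dependency_lineage.csv")
        outputs <- file.path(out, "dependency_compare.tsv")
        if (!.stageUpToDate(manifest, "dependency", c(scorePath, linPath),
                            outputs)) {
            message("[dependency] lineage comparison")
            dep <- loadDependency(scorePath, linPath)
            genes <- dp$genes %||% rownames(dep)
            res <- panelCompare(dep, genes, dp$targetLineage, dp$method)
            utils::write.table(res, outputs, sep = "\t", quote = FALSE,
                               row.names = FALSE)
        } else message("[dependency] up to date, reusing")
        record("dependency", c(scorePath, linPath), outputs)
    }
    jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                         digits = NA, null = "null")
    invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
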