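depFixture <- function() {
    m <- matrix(c(0, 2, -3, -1, -1, -1, -1),
                nrow = 1, dimnames = list("GENEX", paste0("L", 1:7)))
    DependencyExperiment(m, setNames(c("a", "a", "b", "b", "c", "c", "c"),
                                     paste0("L", 1:7)))
}

test_that("lineageSummary reports n, mean, sample sd sorted by mean", {
    s <- lineageSummary(depFixture(), "GENEX")
    expect_identical(s$lineage, c("b", "c", "a"))
    expect_equal(s[s$lineage == "a", c("n", "mean", "sd")],
                 data.frame(n = 2L, mean = 1, sd = sqrt(2)),
                 ignore_attr = TRUE)
    expect_equal(s[s$lineage == "b", c("n", "mean", "sd")],
                 data.frame(n = 2L, mean = -2, sd = sqrt(2)),
                 ignore_attr = TRUE)
    expect_equal(s[s$lineage == "c", "sd"], 0)  # constant scores
    expect_error(lineageSummary(depFixture(), "NOPE"), "unknown gene")
})

test_that("a planted lineage shift surfaces as the minimum lineage mean", {
    sim <- simulateDependency(
        nGenes = 3,
        planted = data.frame(gene = "GENE0002", lineage = "neuroblastoma",
                             shift = -0.5),
        seed = 6)
    s <- lineageSummary(sim$dependency, "GENE0002")
    expect_identical(s$lineage[1], "neuroblastoma")
})

test_that("targetVsRestTest is calibrated under the null and symmetric", {
    reps <- 200
    ps <- vapply(seq_len(reps), function(i) {
        sim <- simulateDependency(nGenes = 1,
                                  lineageSizes = c(a = 50, b = 500),
                                  seed = 1000 + i)
        targetVsRestTest(sim$dependency, "GENE0001", "a")$pValue
    }, 0)
    expect_gt(median(ps), 0.35)
    expect_lt(median(ps), 0.65)
    rej <- mean(ps < 0.05)
    halfWidth <- 2.576 * sqrt(0.05 * 0.95 / reps)
    expect_gt(rej, 0.05 - halfWidth - 1e-9)
    expect_lt(rej, 0.05 + halfWidth)
    # swapping target and rest flips the statistic, p unchanged
    sim <- simulateDependency(nGenes = 1, lineageSizes = c(a = 20, b = 30),
                              seed = 77)
    ta <- targetVsRestTest(sim$dependency, "GENE0001", "a")
    tb <- targetVsRestTest(sim$dependency, "GENE0001", "b")
    expect_equal(ta$statistic, -tb$statistic)
    expect_equal(ta$pValue, tb$pValue)
})

test_that("a planted -1.0 shift is detected overwhelmingly", {
    sim <- simulateDependency(
        nGenes = 2, lineageSizes = c(neuroblastoma = 20, a = 100, b = 100),
        planted = data.frame(gene = "GENE0001", lineage = "neuroblastoma",
                             shift = -1.0),
        noiseSd = 0.5, seed = 99)
    t1 <- targetVsRestTest(sim$dependency, "GENE0001", "neuroblastoma")
    expect_lt(t1$pValue, 1e-6)
    expect_lt(t1$meanDiff, -0.5)
    # rank-sum route agrees on the call
    t2 <- targetVsRestTest(sim$dependency, "GENE0001", "neuroblastoma",
                           method = "rank_sum")
    expect_lt(t2$pValue, 1e-6)
})

test_that("degenerate equality gives t = 0, p = 1", {
    m <- matrix(c(1, 1, 1, 0, 2, 1, 1),
                nrow = 1, dimnames = list("G", paste0("L", 1:7)))
    dep <- DependencyExperiment(m, setNames(c("t", "t", "t", "r", "r", "r",
                                              "r"), paste0("L", 1:7)))
    res <- targetVsRestTest(dep, "G", "t")
    expect_equal(res$statistic, 0)
    expect_equal(res$pValue, 1)
})

test_that("panelCompare reduces to the single test and ranks planted genes", {
    sim <- simulateDependency(
        nGenes = 10, lineageSizes = c(neuroblastoma = 15, a = 60, b = 60),
        planted = data.frame(gene = c("GENE0003", "GENE0006", "GENE0009"),
                             lineage = "neuroblastoma",
                             shift = -0.6),
        noiseSd = 0.3, seed = 31)
    single <- targetVsRestTest(sim$dependency, "GENE0001", "neuroblastoma")
    panel1 <- panelCompare(sim$dependency, "GENE0001", "neuroblastoma")
    expect_equal(panel1$pValue, single$pValue)
    expect_equal(panel1$pAdjBH, single$pValue)  # BH of a single p
    panel <- panelCompare(sim$dependency, rownames(sim$dependency),
                          "neuroblastoma")
    expect_setequal(panel$geneId[1:3], sim$truth$planted$gene)
    # BH-adjusted p are monotone in raw p
    expect_true(all(diff(panel$pAdjBH[order(panel$pValue)]) >= -1e-12))
    expect_warning(panelCompare(sim$dependency, c("GENE0001", "NOPE"),
                                "neuroblastoma"), "NOPE")
    empty <- suppressWarnings(panelCompare(sim$dependency, "NOPE",
                                           "neuroblastoma"))
    expect_identical(nrow(empty), 0L)
})

test_that("planted shifts are recovered within 2 SE across replicates", {
    reps <- 100
    d <- vapply(seq_len(reps), function(i) {
        sim <- simulateDependency(
            nGenes = 1, lineageSizes = c(t = 15, r = 80),
            planted = data.frame(gene = "GENE0001", lineage = "t",
                                 shift = -0.5),
            noiseSd = 0.3, seed = 5000 + i)
        targetVsRestTest(sim$dependency, "GENE0001", "t")$meanDiff
    }, 0)
    se <- sd(d) / sqrt(reps)
    expect_lt(abs(mean(d) - (-0.5)), 2 * se)
})

test_that("adding a constant to all scores changes no statistic", {
    sim <- simulateDependency(nGenes = 2, lineageSizes = c(a = 10, b = 40),
                              seed = 3)
    shifted <- sim$dependency
    assay(shifted, "score") <- assay(shifted, "score") + 5
    expect_equal(targetVsRestTest(shifted, "GENE0001", "a")$pValue,
                 targetVsRestTest(sim$dependency, "GENE0001", "a")$pValue)
})
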