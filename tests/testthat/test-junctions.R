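test_that("readSJTab parses the 9-column STAR dialect exactly", {
    f <- withr::local_tempfile()
    writeLines(c("chr1\t14830\t14969\t2\t2\t1\t25\t3\t38",
                 "chr2\t500\t900\t1\t1\t0\t7\t0\t21"), f)
    gr <- readSJTab(f)
    expect_length(gr, 2)
    expect_identical(as.character(seqnames(gr)[1]), "chr1")
    expect_identical(start(gr)[1], 14830L)
    expect_identical(end(gr)[1], 14969L)
    expect_identical(as.character(strand(gr)[1]), "-")
    expect_identical(mcols(gr)$motif[1], 2L)
    expect_true(mcols(gr)$annotated[1])
    expect_identical(mcols(gr)$uniqueReads, c(25L, 7L))
    # empty file: empty result with a warning
    empty <- withr::local_tempfile()
    file.create(empty)
    expect_warning(gr0 <- readSJTab(empty), "empty")
    expect_length(gr0, 0)
    # malformed rows are fatal with a line number
    bad <- withr::local_tempfile()
    writeLines(c("chr1\t1\t2\t1\t1\t0\t5\t0\t10", "chr1\t1\t2"), bad)
    expect_error(readSJTab(bad), "line 2")
    nonint <- withr::local_tempfile()
    writeLines("chr1\t1\t2\t1\t1\t0\tfive\t0\t10", nonint)
    expect_error(readSJTab(nonint), "non-integer")
})

test_that("writeSJTab and readSJTab round-trip simulator output", {
    sim <- simulateJunctions(nJunctions = 40,
                             genotypes = c(control = 1, kd = 1), seed = 2)
    f <- withr::local_tempfile()
    writeSJTab(sim$samples$control_rep1, f)
    back <- readSJTab(f)
    expect_identical(mcols(back)$uniqueReads,
                     as.integer(mcols(sim$samples$control_rep1)$uniqueReads))
    expect_identical(start(back), start(sim$samples$control_rep1))
})

test_that("buildUnifiedMatrix takes the union with zero fill", {
    a <- jgr(c(100, 200), c(5, 3))
    b <- jgr(c(200, 300), c(2, 7))
    m <- buildUnifiedMatrix(list(A = a, B = b))
    expect_identical(junctionState(m), "raw")
    expect_identical(dim(m), c(3L, 2L))
    mat <- assay(m, "reads")
    expect_equal(mat[, "A"], c(5, 3, 0), ignore_attr = TRUE)
    expect_equal(mat[, "B"], c(0, 2, 7), ignore_attr = TRUE)
    # identical samples give identical columns
    m2 <- buildUnifiedMatrix(list(A = a, B = a))
    expect_identical(assay(m2)[, "A"], assay(m2)[, "B"])
    # same coordinates on opposite strands are distinct junctions
    m3 <- buildUnifiedMatrix(list(A = jgr(100, 5, strandCode = 1L),
                                  B = jgr(100, 9, strandCode = 2L)))
    expect_identical(nrow(m3), 2L)
    # duplicate key within one sample is fatal
    expect_error(buildUnifiedMatrix(list(A = jgr(c(100, 100), c(1, 2)),
                                         B = b)),
                 "duplicate junction key")
})

test_that("normalizeCPM scales columns to one million with guards", {
    fix <- junctionOracleFixture()
    norm <- normalizeCPM(buildUnifiedMatrix(fix$samples))
    expect_identical(junctionState(norm), "normalized")
    expect_equal(colSums(assay(norm)), rep(1e6, 4), ignore_attr = TRUE,
                 tolerance = 1e-9)
    # forced arithmetic: count 200 in a 1e5-read sample -> 2000 per million
    expect_equal(assay(norm)["chr1:2000:2099:1", "s1a"], 2000)
    # scalar-multiple samples normalize identically
    sc <- buildUnifiedMatrix(list(A = jgr(c(1, 2), c(10, 30)),
                                  B = jgr(c(1, 2), c(20, 60))))
    nsc <- normalizeCPM(sc)
    expect_equal(assay(nsc)[, "A"], assay(nsc)[, "B"])
    # zero-total sample is an error naming the sample
    z <- buildUnifiedMatrix(list(A = jgr(1, 5), Z = jgr(1, 0)))
    expect_error(normalizeCPM(z), "Z")
    # state machine refuses double normalization
    expect_error(normalizeCPM(norm), "raw")
})

test_that("averageByGenotype means replicate columns", {
    two <- buildUnifiedMatrix(list(r1 = jgr(c(1, 2), c(10, 90)),
                                   r2 = jgr(c(1, 2), c(20, 80))))
    norm <- normalizeCPM(two)
    avg <- averageByGenotype(norm, c(r1 = "g", r2 = "g"))
    expect_identical(junctionState(avg), "averaged")
    expect_equal(assay(avg)[, "g"],
                 rowMeans(assay(norm)), ignore_attr = TRUE)
    # genotype with one sample: column copied
    solo <- averageByGenotype(norm, c(r1 = "x", r2 = "y"))
    expect_equal(assay(solo)[, "x"], assay(norm)[, "r1"])
    expect_error(averageByGenotype(norm, c(r1 = "x")), "without genotype")
})

test_that("filterLowTotal keeps the boundary and is monotone", {
    fix <- junctionOracleFixture()
    avg <- averageByGenotype(normalizeCPM(buildUnifiedMatrix(fix$samples)),
                             fix$groups)
    filt <- filterLowTotal(avg, 10)
    expect_identical(junctionState(filt), "filtered")
    # j4 (start 4000) totals exactly 10 across genotypes: retained
    expect_true("chr1:4000:4099:1" %in% rownames(filt))
    # j5 (start 5000) totals 5: excluded
    expect_false("chr1:5000:5099:1" %in% rownames(filt))
    # threshold 0 is the identity
    expect_identical(nrow(filterLowTotal(avg, 0)), nrow(avg))
    # raising the threshold never increases retained rows
    kept <- vapply(c(0, 5, 10, 50, 1000, 1e7),
                   function(th) nrow(filterLowTotal(avg, th)), 0L)
    expect_true(all(diff(kept) <= 0))
})

test_that("pairwisePearson matches the hand-computed t transform", {
    m <- cbind(g1 = c(1, 2, 3, 4, 5), g2 = c(2, 1, 4, 3, 5),
               g3 = c(1, 2, 3, 4, 5))
    rep <- pairwisePearson(filteredJE(m))
    r12 <- rep[rep$a == "g1" & rep$b == "g2", ]
    expect_equal(r12$r, 0.8)
    expect_equal(r12$t, 0.8 * sqrt(3) / sqrt(1 - 0.64))
    expect_identical(r12$df, 3L)
    expect_equal(r12$p, 0.104088, tolerance = 1e-4)
    # independent route: stats::cor.test agrees
    ct <- cor.test(m[, 1], m[, 2])
    expect_equal(r12$r, unname(ct$estimate))
    expect_equal(r12$p, ct$p.value)
    # identical columns correlate at exactly 1
    expect_equal(rep[rep$a == "g1" & rep$b == "g3", "r"], 1)
    # mirrored columns (after centering) at exactly -1
    m2 <- cbind(a = c(1, 2, 3), b = c(3, 2, 1), cc = c(1, 1, 2))
    rep2 <- pairwisePearson(filteredJE(m2))
    expect_equal(rep2[rep2$a == "a" & rep2$b == "b", "r"], -1)
    # symmetric unit-diagonal r matrix
    rmat <- metadata(rep)$rMatrix
    expect_identical(rmat, t(rmat))
    expect_equal(diag(rmat), c(g1 = 1, g2 = 1, g3 = 1))
})

test_that("zero-variance columns yield NA correlations with a warning", {
    m <- cbind(a = c(1, 2, 3, 4), b = c(2, 2, 2, 2), cc = c(4, 3, 2, 1))
    expect_warning(rep <- pairwisePearson(filteredJE(m)), "zero-variance")
    expect_true(is.na(rep[rep$a == "a" & rep$b == "b", "r"]))
    expect_false(anyNA(rep[rep$a == "a" & rep$b == "cc", "r"]))
})

test_that("delta mode correlates perturbation minus control vectors", {
    ctl <- c(10, 10, 10, 10, 10)
    m <- cbind(control = ctl, x = ctl + c(5, -5, 0, 3, -3),
               y = ctl + c(5, -5, 0, 3, -3), z = ctl + c(-5, 5, 0, -3, 3))
    rep <- pairwisePearson(filteredJE(m), mode = "delta",
                           control = "control")
    expect_setequal(unique(c(rep$a, rep$b)), c("x", "y", "z"))
    expect_equal(rep[rep$a == "x" & rep$b == "y", "r"], 1)
    expect_equal(rep[rep$a == "x" & rep$b == "z", "r"], -1)
    expect_error(pairwisePearson(filteredJE(m), mode = "delta"),
                 "control")
    expect_error(pairwisePearson(filteredJE(m[1:2, ])), ">= 3 junctions")
})

test_that("the full chain equals the brute-force oracle", {
    fix <- junctionOracleFixture()
    oracle <- junctionChainOracle(fix$counts, fix$groups, fix$starts,
                                  threshold = 10)
    filt <- filterLowTotal(
        averageByGenotype(normalizeCPM(buildUnifiedMatrix(fix$samples)),
                          fix$groups), 10)
    got <- assay(filt, "reads")
    expect_setequal(rownames(got), rownames(oracle))
    expect_equal(got[rownames(oracle), colnames(oracle)], oracle)
})

test_that("the pipeline is invariant to sample and row order", {
    sim <- simulateJunctions(nJunctions = 120,
                             genotypes = c(control = 2, kd = 2),
                             perturbed = list(kd = 1:20), seed = 14)
    rep1 <- junctionConcordance(sim$samples, sim$groups)
    shuffled <- withr::with_seed(1, lapply(sim$samples,
                                           function(g) g[sample(length(g))]))
    rep2 <- junctionConcordance(rev(shuffled), sim$groups)
    key <- function(r) paste(pmin(r$a, r$b), pmax(r$a, r$b))
    o <- match(key(rep1), key(rep2))
    expect_equal(rep1$r, rep2$r[o])
    # optional log2(x+1) scale changes r but stays a valid correlation
    repLog <- junctionConcordance(sim$samples, sim$groups, log2p1 = TRUE)
    expect_false(identical(repLog$r, rep1$r))
    expect_true(all(abs(repLog$r) <= 1))
})
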