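test_that("meanDifference is the plain difference of group means", {
    expect_identical(meanDifference(c(1, 1), c(1, 1, 1)), 0)
    expect_identical(meanDifference(c(-2, -1), c(0, 1)), -2)
    expect_error(meanDifference(numeric(0), 1), "insufficient")
    expect_error(meanDifference(c(1, NA), c(0, 1)), "finite")
})

test_that("exhaustive permutation enumerates every assignment exactly", {
    cfg <- PermutationConfig(nDraws = 10, seed = 1)
    # pooled {1,2,3,4}, k = 1: null diffs are {-2, -2/3, +2/3, +2}
    pt <- permutationTest(c(1, 2, 3, 4), 1, -2, cfg)
    expect_identical(pt$mode, "exhaustive")
    expect_identical(pt$p, 0.25)
    # constant data: every null diff equals the observed 0
    pt0 <- permutationTest(c(5, 5, 5, 5), 2, 0, cfg)
    expect_identical(pt0$p, 1)
    # 'greater' mirrors the tail; two_sided doubles and caps
    expect_identical(
        permutationTest(c(1, 2, 3, 4), 1, 2,
                        PermutationConfig(alternative = "greater"))$p, 0.25)
    expect_identical(
        permutationTest(c(1, 2, 3, 4), 1, -2,
                        PermutationConfig(alternative = "two_sided"))$p, 0.5)
})

test_that("sampled p uses the add-one estimator, never 0, reproducibly", {
    x <- withr::with_seed(3, rnorm(60))
    cfg <- PermutationConfig(nDraws = 500, seed = 9, exhaustiveLimit = 1)
    pt1 <- permutationTest(x, 5, -10, cfg)  # observed below every null diff
    expect_identical(pt1$mode, "sampled")
    expect_identical(pt1$p, 1 / 501)
    pt2 <- permutationTest(x, 5, -10, cfg)
    expect_identical(pt1$p, pt2$p)
    expect_false(identical(
        permutationTest(x, 5, -0.1, cfg)$p,
        permutationTest(x, 5, -0.1,
                        PermutationConfig(nDraws = 500, seed = 10,
                                          exhaustiveLimit = 1))$p))
    expect_error(permutationTest(x, 0, 0, cfg), "nTarget")
    expect_error(permutationTest(x, 60, 0, cfg), "nTarget")
})

test_that("sampled p converges to the exhaustive tail fraction", {
    x <- withr::with_seed(11, rnorm(8))
    exact <- permutationTest(x, 3, quantile(x, 0.4), PermutationConfig())
    expect_identical(exact$mode, "exhaustive")
    B <- 20000
    samp <- permutationTest(x, 3, quantile(x, 0.4),
                            PermutationConfig(nDraws = B, seed = 2,
                                              exhaustiveLimit = 1))
    tol <- 3 * sqrt(exact$p * (1 - exact$p) / B) + 2 / B
    expect_lt(abs(samp$p - exact$p), tol)
})

test_that("selectivity is location-invariant and scale-equivariant", {
    sim <- simulateScreen(nCompounds = 6,
                          lineageSizes = c(neuroblastoma = 4, other = 26),
                          nSelective = 1, effectSize = -1.5, seed = 8)
    cfg <- PermutationConfig(nDraws = 400, seed = 5, exhaustiveLimit = 1)
    base <- selectivityScreen(sim$screen, "neuroblastoma", cfg)
    shifted <- sim$screen
    assay(shifted, "response") <- assay(shifted, "response") + 7
    resS <- selectivityScreen(shifted, "neuroblastoma", cfg)
    expect_equal(resS$meanDiff, base$meanDiff)
    expect_identical(resS$pEmpirical, base$pEmpirical)
    scaled <- sim$screen
    assay(scaled, "response") <- assay(scaled, "response") * 3
    resK <- selectivityScreen(scaled, "neuroblastoma", cfg)
    expect_equal(resK$meanDiff, 3 * base$meanDiff)
    expect_identical(resK$pEmpirical, base$pEmpirical)
})

test_that("per-compound substreams make results order-independent", {
    sim <- simulateScreen(nCompounds = 8,
                          lineageSizes = c(neuroblastoma = 4, other = 30),
                          nSelective = 2, effectSize = -1, seed = 21)
    cfg <- PermutationConfig(nDraws = 300, seed = 13, exhaustiveLimit = 1)
    fwd <- selectivityScreen(sim$screen, "neuroblastoma", cfg)
    rev <- selectivityScreen(sim$screen[rev(seq_len(nrow(sim$screen))), ],
                             "neuroblastoma", cfg)
    o <- match(fwd$compoundId, rev$compoundId)
    expect_identical(fwd$pEmpirical, rev$pEmpirical[o])
    expect_identical(fwd$rank, rev$rank[o])
})

test_that("ranking is a permutation of ok compounds, most toxic first", {
    sim <- simulateScreen(nCompounds = 12,
                          lineageSizes = c(neuroblastoma = 5, other = 40),
                          nSelective = 2, effectSize = -2, seed = 4)
    res <- selectivityScreen(sim$screen, "neuroblastoma",
                             PermutationConfig(nDraws = 300, seed = 4))
    ok <- res$status == "ok"
    expect_setequal(res$rank[ok], seq_len(sum(ok)))
    expect_identical(res$compoundId[which(ok)[which.min(res$meanDiff[ok])]],
                     res$compoundId[ok][res$rank[ok] == 1])
    expect_error(selectivityScreen(sim$screen, "no_such_lineage"),
                 "unknown lineage")
})

test_that("all-constant responses give zero diffs, p = 1, tie-broken ranks", {
    m <- matrix(2, nrow = 3, ncol = 10,
                dimnames = list(c("b", "a", "c"), sprintf("L%02d", 1:10)))
    se <- ScreenExperiment(m, setNames(c(rep("neuroblastoma", 4),
                                         rep("other", 6)),
                                       colnames(m)))
    res <- selectivityScreen(se, "neuroblastoma",
                             PermutationConfig(nDraws = 100, seed = 1))
    expect_true(all(res$meanDiff == 0))
    expect_true(all(res$pEmpirical == 1))
    # ties fall back to lexicographic compound IDs
    expect_identical(res$compoundId[order(res$rank)], c("a", "b", "c"))
})

test_that("sparse compounds are flagged instead of ranked", {
    m <- matrix(rnorm(20), 2, 10,
                dimnames = list(c("dense", "sparse"), sprintf("L%02d", 1:10)))
    m["sparse", 1:9] <- NA  # one non-missing value only
    se <- ScreenExperiment(m, setNames(c(rep("neuroblastoma", 4),
                                         rep("other", 6)), colnames(m)))
    res <- selectivityScreen(se, "neuroblastoma",
                             PermutationConfig(nDraws = 100, seed = 1))
    expect_identical(res$status, c("ok", "insufficient_data"))
    expect_identical(is.na(res$rank), c(FALSE, TRUE))
})
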