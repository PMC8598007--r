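#' Target-vs-rest mean difference
#'
#' The lineage-selectivity statistic: mean response of the target-lineage
#' cell lines minus the mean response of all other lines.  On the log2
#' fold-change (or AUC) scale a negative difference means the compound is
#' more toxic to the target lineage.
#'
#' @param targetValues,otherValues non-empty numeric vectors of finite
#'   responses.
#' @return `mean(targetValues) - mean(otherValues)`.
#' @examples
#' meanDifference(c(-2, -1), c(0, 1))   # -2
#' @export
meanDifference <- function(targetValues, otherValues) {
    if (!length(targetValues) || !length(otherValues))
        stopData("insufficient data: both groups must be non-empty")
    if (!all(is.finite(targetValues)) || !all(is.finite(otherValues)))
        stopData("responses must be finite")
    mean(targetValues) - mean(otherValues)
}

# Null mean-difference statistics for k-subsets of x taken as the target
# group.  The statistic is a monotone function of the subset sum:
#   diff(s) = s/k - (S - s)/(n - k).
.nullDiffsExhaustive <- function(x, k) {
    n <- length(x)
    S <- sum(x)
    sums <- if (k == 1L) x else colSums(matrix(x[utils::combn(n, k)], nrow = k))
    sums / k - (S - sums) / (n - k)
}

.nullDiffsSampled <- function(x, k, B) {
    n <- length(x)
    S <- sum(x)
    sums <- vapply(seq_len(B),
                   function(i) sum(x[sample.int(n, k)]), numeric(1))
    sums / k - (S - sums) / (n - k)
}

#' Permutation test for a mean-difference statistic
#'
#' Builds the null distribution of the target-vs-rest mean difference by
#' assigning random k-subsets of the pooled responses to the target group
#' (sampling without replacement within the compound's own values).  When
#' `choose(n, k)` is at most `config@exhaustiveLimit` every assignment is
#' enumerated and the exact tail fraction is returned; otherwise
#' `config@nDraws` Monte-Carlo draws are taken and the add-one estimator
#' `(1 + #\{null <= observed\}) / (1 + nDraws)` is used (for
#' `alternative = "less"`; mirrored for `"greater"`, doubled and capped at 1
#' for `"two_sided"`), so a sampled p-value is never 0.
#'
#' @param pooledValues all responses for the compound (target and rest).
#' @param nTarget target group size k, with `1 <= k < length(pooledValues)`.
#' @param observedDiff the observed mean difference.
#' @param config a [PermutationConfig()].
#' @return list with `p` (empirical p-value) and `mode` (`"sampled"` or
#'   `"exhaustive"`).
#' @examples
#' cfg <- PermutationConfig(nDraws = 1000, seed = 7)
#' permutationTest(c(1, 2, 3, 4), 1, -2, cfg)  # exact: p = 0.25
#' @export
permutationTest <- function(pooledValues, nTarget, observedDiff,
                            config = PermutationConfig()) {
    stopifnot(is(config, "PermutationConfig"))
    n <- length(pooledValues)
    k <- as.integer(nTarget)
    if (k < 1L || k >= n)
        stopData("nTarget must satisfy 1 <= nTarget < length(pooledValues)")
    if (!all(is.finite(pooledValues)) || !is.finite(observedDiff))
        stopData("values and observed difference must be finite")
    exhaustive <- choose(n, k) <= config@exhaustiveLimit
    if (exhaustive) {
        null <- .nullDiffsExhaustive(pooledValues, k)
        pLess <- sum(null <= observedDiff) / length(null)
        pGreater <- sum(null >= observedDiff) / length(null)
    } else {
        null <- withSeed(config@seed,
                         .nullDiffsSampled(pooledValues, k, config@nDraws))
        B <- config@nDraws
        pLess <- (1 + sum(null <= observedDiff)) / (1 + B)
        pGreater <- (1 + sum(null >= observedDiff)) / (1 + B)
    }
    p <- switch(config@alternative,
                less = pLess,
                greater = pGreater,
                two_sided = min(1, 2 * min(pLess, pGreater)))
    list(p = p, mode = if (exhaustive) "exhaustive" else "sampled")
}

#' Rank compounds by lineage-selective toxicity
#'
#' For every compound, computes the target-vs-rest mean difference over its
#' non-missing responses and an empirical p-value from the permutation null
#' ([permutationTest()]), then ranks compounds by ascending mean difference
#' (rank 1 = most negative = most selectively toxic).  Ties are broken by
#' smaller empirical p, then lexicographic compound ID.  Compounds with fewer
#' than `config@minTargetN` target or `config@minOtherN` other values get
#' `status = "insufficient_data"` and no rank.  Each compound uses an RNG
#' substream derived from `(config@seed, compound_id)`, so results do not
#' depend on compound order.
#'
#' @param x a \linkS4class{ScreenExperiment}.
#' @param targetLineage lineage label present in the annotation (matched
#'   after case-folding and trimming).
#' @param config a [PermutationConfig()].
#' @return `DataFrame` with one row per compound: `compoundId`, `nTarget`,
#'   `nOther`, `meanTarget`, `meanOther`, `meanDiff`, `pEmpirical`, `rank`,
#'   `mode`, `status`.
#' @export
selectivityScreen <- function(x, targetLineage,
                              config = PermutationConfig()) {
    stopifnot(is(x, "ScreenExperiment"))
    lin <- lineages(x)
    targetLineage <- foldLabel(targetLineage)
    if (!targetLineage %in% lin)
        stopData("unknown lineage label: ", targetLineage)
    resp <- assay(x, "response")
    isTarget <- lin == targetLineage
    ids <- rownames(resp)
    one <- function(i) {
        v <- resp[i, ]
        ok <- !is.na(v)
        tv <- v[ok & isTarget]
        ov <- v[ok & !isTarget]
        if (length(tv) < config@minTargetN || length(ov) < config@minOtherN)
            return(list(nT = length(tv), nO = length(ov), mT = NA_real_,
                        mO = NA_real_, d = NA_real_, p = NA_real_,
                        mode = NA_character_, status = "insufficient_data"))
        d <- meanDifference(tv, ov)
        cfg <- config
        cfg@seed <- substreamSeed(config@seed, ids[i])
        pt <- permutationTest(c(tv, ov), length(tv), d, cfg)
        list(nT = length(tv), nO = length(ov), mT = mean(tv), mO = mean(ov),
             d = d, p = pt$p, mode = pt$mode, status = "ok")
    }
    res <- lapply(seq_along(ids), one)
    out <- DataFrame(
        compoundId = ids,
        nTarget = vapply(res, `[[`, 0L, "nT"),
        nOther = vapply(res, `[[`, 0L, "nO"),
        meanTarget = vapply(res, `[[`, 0, "mT"),
        meanOther = vapply(res, `[[`, 0, "mO"),
        meanDiff = vapply(res, `[[`, 0, "d"),
        pEmpirical = vapply(res, `[[`, 0, "p"),
        rank = NA_integer_,
        mode = vapply(res, `[[`, "", "mode"),
        status = vapply(res, `[[`, "", "status"))
    ok <- out$status == "ok"
    if (any(ok)) {
        o <- order(out$meanDiff[ok], out$pEmpirical[ok], out$compoundId[ok])
        out$rank[which(ok)[o]] <- seq_len(sum(ok))
    }
    metadata(out) <- list(targetLineage = targetLineage,
                          nDraws = config@nDraws, seed = config@seed,
                          alternative = config@alternative)
    out
}
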