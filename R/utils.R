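# Internal helpers: deterministic seeding, RNG hygiene, shared constants.

rmatsCategories <- function() c("SE", "A5SS", "A3SS", "MXE", "RI")

# Evaluate expr under a fixed seed without disturbing the caller's RNG stream.
withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(expr)
}

# Deterministic 31-bit substream seed from (seed, label), so per-compound /
# per-stage streams are independent of iteration order.  Polynomial string
# hash mod (2^31 - 1), mixed with the global seed.
substreamSeed <- function(seed, label) {
    m <- 2147483647
    h <- 0
    for (code in utf8ToInt(as.character(label)))
        h <- (h * 31 + code) %% m
    as.integer((h + (as.numeric(seed) %% m) * 2654435) %% m)
}

# Case-folded, whitespace-trimmed label matching for lineages.
foldLabel <- function(x) tolower(trimws(as.character(x)))

stopData <- function(...) {
    stop(errorCondition(paste0(...), class = c("glueSelectDataError", "error")))
}

stopConfig <- function(...) {
    stop(errorCondition(paste0(...), class = c("glueSelectConfigError", "error")))
}
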