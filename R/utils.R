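## internal helpers

## Derive a per-stage seed from a stage name and the global seed, so that
## adding a stage never perturbs the random stream of earlier stages.
## Polynomial string hash folded with the seed, kept below 2^31 - 1
## (exact in double arithmetic: all intermediates < 2^53).
stableSeed <- function(stage, seed) {
    stopifnot(is.character(stage), length(stage) == 1L)
    m <- 2147483647
    h <- 17
    for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% m
    as.integer((h + (as.numeric(seed) %% m) * 31) %% m)
}

## run expr with a temporary seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
    withr::with_seed(as.integer(seed), expr)
}

assertCount <- function(x, name, positive = TRUE) {
    if (length(x) != 1L || is.na(x) || x != as.integer(x) ||
        (positive && x < 1) || (!positive && x < 0))
        stop(sprintf("'%s' must be a %s integer", name,
                     if (positive) "positive" else "non-negative"),
             call. = FALSE)
    as.integer(x)
}

assertProb <- function(x, name) {
    if (length(x) != 1L || is.na(x) || x < 0 || x > 1)
        stop(sprintf("'%s' must be a probability in [0, 1]", name),
             call. = FALSE)
    as.numeric(x)
}
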