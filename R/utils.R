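# Internal helpers shared across modules.

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG
# state afterwards so generators are pure functions of (design, seed).
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    expr
}

# Deterministic sub-seed derivation; kept well below .Machine$integer.max.
subSeed <- function(seed, k) (as.integer(seed) * 1000L + as.integer(k)) %% 2147483629L

writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

readTsv <- function(path, ...) {
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, check.names = FALSE, ...)
}

# Format numbers for TSV output without scientific notation drift.
fmtNum <- function(x) formatC(x, format = "g", digits = 15)
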