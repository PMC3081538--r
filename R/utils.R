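# Internal helpers: seeding, formatting.

#' Derive a per-run random seed
#'
#' Mixes a base seed, a subset bitmask and a run index into a single seed in
#' \code{[0, 2^31)} via \code{(base + 131071 * mask + 1000003 * run) mod 2^31},
#' computed in double precision (exact well below 2^53). For a fixed base seed
#' and mask the map is injective in the run index (1000003 is odd and runs
#' number far fewer than 2^31 / 1000003), so repeated splits never collide.
#'
#' @param baseSeed integer base seed.
#' @param mask integer subset bitmask (0 when splits are shared across subsets).
#' @param runIndex integer run index (1-based).
#' @return A single integer seed.
#' @keywords internal
mixSeed <- function(baseSeed, mask = 0L, runIndex = 0L) {
    s <- (as.numeric(baseSeed) + 131071 * as.numeric(mask) +
          1000003 * as.numeric(runIndex)) %% 2^31
    as.integer(s)
}

# Evaluate `code` under a temporary RNG seed, restoring global RNG state.
withSeed <- function(seed, code) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        stats::runif(1)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
    code
}

# Shortest decimal representation that parses back to the identical double.
formatExact <- function(v) {
    s <- sprintf("%.15g", v)
    widen <- !is.na(v) & (is.na(suppressWarnings(as.numeric(s))) |
                          suppressWarnings(as.numeric(s)) != v)
    s[widen] <- sprintf("%.17g", v[widen])
    s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
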