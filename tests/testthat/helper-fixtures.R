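# Fixture builders shared across test files. Everything is generated in code.

# tiny hand-built table: 2 tools x 6 proteins, one missing cell
toyFeatureSet <- function() {
    sc <- rbind(alpha = c(0.9, 0.8, 1.0, 0.1, 0.0, NA),
                beta  = c(1.0, 1.0, 0.0, 0.0, 0.1, 0.2))
    colnames(sc) <- paste0("P", 1:6)
    FeatureSet(sc, label = c(1, 1, 1, 0, 0, 0))
}

# single perfect predictor plus a random and an anti-informative column
designedScenario <- function(seed = 1L, nPos = 40L, nNeg = 120L) {
    profiles <- rbind(
        predictorProfiles("perfect", 1, 0, 1, NA, 0, "strong"),
        predictorProfiles("coin", 0.5, 0.5, 1, NA, 0, "noise"),
        predictorProfiles("weak", 0.3, 0.05, 1, NA, 0, "moderate"))
    scenarioConfig(profiles, nPos = nPos, nNeg = nNeg,
                   latentStrength = 0, seed = seed)
}

# the desk-scale evaluation profile used by the heavier acceptance checks:
# the packaged 11-tool scenario at 1500 proteins, an 8-tool roster
# (3 strong + 1 moderate + the 4 detrimental tools -> 255 subsets),
# 10 runs with test sets of 50 positives / 315 negatives
deskRoster <- c("MITODOMAIN", "TargetP", "MITOPRED", "MitoProtII",
                "YeastHomology", "Induction", "RickettsiaOrth",
                "Coexpression")

deskTable <- function(seed = 1L) {
    imputeMissing(generateDataset(
        paradoxScenario(seed, nPos = 150L, nNeg = 1350L)))
}

deskSplitSpec <- function(seed = 1L) {
    splitSpec(nTestPos = 50L, nTestNeg = 315L, nRuns = 10L, baseSeed = seed)
}

# the desk sweep is reused by several acceptance checks; run it once
.deskCache <- new.env(parent = emptyenv())
deskSweep <- function(seed = 1L) {
    key <- as.character(seed)
    if (is.null(.deskCache[[key]])) {
        fs <- deskTable(seed)[deskRoster, ]
        .deskCache[[key]] <- runSweep(fs, deskSplitSpec(seed))
    }
    .deskCache[[key]]
}

# independent mean/sd oracle: Welford streaming algorithm
welfordOracle <- function(v) {
    m <- 0; s <- 0; n <- 0
    for (x in v) {
        n <- n + 1
        d <- x - m
        m <- m + d / n
        s <- s + d * (x - m)
    }
    c(mean = m, sd = if (n > 1) sqrt(s / (n - 1)) else NA_real_)
}

# brute-force subset enumeration oracle via utils::combn
powersetOracle <- function(n) {
    masks <- unlist(lapply(seq_len(n), function(k) {
        apply(utils::combn(n, k), 2L, function(ix) sum(2^(ix - 1)))
    }))
    sizes <- vapply(masks, function(m) sum(as.integer(intToBits(m))),
                    numeric(1L))
    as.integer(masks[order(sizes, masks)])
}
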