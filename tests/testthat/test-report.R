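# compact fake summaries builder: one row per mask over nTools tools
fakeSummaries <- function(nTools, meanSens, toolNames = letters[seq_len(nTools)],
                          nRuns = 10L, sdSens = 0.05) {
    masks <- enumerateSubsets(nTools)
    stopifnot(length(meanSens) == length(masks))
    df <- data.frame(
        mask = masks,
        tool_names = vapply(masks, function(m)
            paste(maskToTools(m, toolNames), collapse = "+"), character(1L)),
        size = maskSize(masks),
        mean_sens = meanSens, sd_sens = sdSens,
        mean_spec = 0.99, sd_spec = 0.01,
        mean_fdr = 0.1, sd_fdr = 0.01,
        mean_cfdr = 0.2, sd_cfdr = 0.02,
        n_overfit_runs = 0L, n_runs = nRuns,
        stringsAsFactors = FALSE)
    attr(df, "toolNames") <- toolNames
    df
}

test_that("ranking sorts by mean metric with the documented tie-break", {
    set.seed(10)
    s <- fakeSummaries(8, runif(255))
    r <- rankCombinations(s, "sensitivity")
    expect_true(all(diff(r$mean_sens) <= 0))
    oracle <- s[order(-s$mean_sens, s$size, s$mask), ]
    expect_identical(r$mask, oracle$mask)
    # ties resolved by smaller size, then smaller mask
    tied <- fakeSummaries(3, c(0.5, 0.5, 0.8, 0.5, 0.5, 0.5, 0.5))
    rt <- rankCombinations(tied, "sensitivity")
    expect_identical(rt$mask[1L], 4L)              # the 0.8 singleton
    expect_identical(rt$mask[-1L], c(1L, 2L, 3L, 5L, 6L, 7L))
    # ascending ranking and metric name validation
    ra <- rankCombinations(s, "fdr", decreasing = FALSE)
    expect_true(all(diff(ra$mean_fdr) >= 0))
    expect_error(rankCombinations(s, "accuracy"), "arg")
})

test_that("top-k contribution counts subset membership", {
    # k = all subsets of 11 tools: every tool appears in 1024 of 2047
    s <- fakeSummaries(11, seq_len(2047) / 2047,
                       toolNames = paste0("T", 1:11))
    ct <- contributionTopK(s, "sensitivity", k = 2047L)
    expect_equal(ct$probability, rep(1024 / 2047, 11L), tolerance = 1e-15)
    # a tool in every top-k subset scores 1; rarer tools score their share
    # (means follow enumeration order: masks 1,2,4,3,5,6,7)
    s3 <- fakeSummaries(3, c(0.1, 0.2, 0.9, 0.3, 0.85, 0.8, 0.95))
    top3 <- contributionTopK(s3, "sensitivity", k = 3L)
    # top 3 masks: 7 (0.95), 4 (0.90), 5 (0.85) -> c in all, a in 2, b in 1
    expect_identical(top3$probability[top3$tool == "c"], 1)
    expect_equal(top3$probability[top3$tool == "a"], 2 / 3,
                 tolerance = 1e-15)
    expect_equal(top3$probability[top3$tool == "b"], 1 / 3,
                 tolerance = 1e-15)
    only1 <- contributionTopK(s3, "sensitivity", k = 1L)
    expect_identical(only1$probability, c(1, 1, 1))  # mask 7 contains all
    expect_error(contributionTopK(s3, "sensitivity", k = 0L), "k")
    expect_error(contributionTopK(s3, "sensitivity", k = 8L), "k")
})

test_that("binned contribution uses per-bin denominators", {
    s3 <- fakeSummaries(3, c(0.1, 0.2, 0.9, 0.3, 0.85, 0.8, 0.95))
    # one bin covering everything reproduces top-k with k = all
    one <- contributionBinned(s3, "sensitivity", c(0, 1))
    all7 <- contributionTopK(s3, "sensitivity", k = 7L)
    expect_equal(one$probability, all7$probability, tolerance = 1e-15)
    # bins isolating single combinations give 0/1 membership indicators
    hi <- s3[s3$mean_sens > 0.88, ]
    iso <- contributionBinned(hi, "sensitivity", c(0.88, 0.92, 0.99),
                              toolNames = c("a", "b", "c"))
    expect_identical(iso$probability[iso$bin == 1L], c(0, 0, 1))  # mask 4
    expect_identical(iso$probability[iso$bin == 2L], c(1, 1, 1))  # mask 7
    # per-bin tool sums equal the mean subset size in the bin
    edges <- c(0, 0.5, 1)
    cb <- contributionBinned(s3, "sensitivity", edges)
    for (b in 1:2) {
        members <- s3$size[s3$mean_sens >= edges[b] &
                           (s3$mean_sens < edges[b + 1L] | b == 2L)]
        expect_equal(sum(cb$probability[cb$bin == b]), mean(members),
                     tolerance = 1e-15)
    }
    # empty bins report NA, not zero
    sp <- fakeSummaries(3, c(0.1, 0.1, 0.1, 0.1, 0.9, 0.9, 0.9))
    e <- contributionBinned(sp, "sensitivity", c(0, 0.4, 0.6, 1))
    expect_true(all(is.na(e$probability[e$bin == 2L])))
    expect_identical(unique(e$n[e$bin == 2L]), 0L)
    expect_error(contributionBinned(s3, "sensitivity", c(0.5, 0.5)),
                 "strictly increasing")
    expect_error(contributionBinned(s3, "sensitivity", c(0.3, 1)),
                 "cover")
    expect_length(defaultBinEdges(c(0, 1)), 21L)
})

test_that("best-vs-full comparison reproduces the printed-scale arithmetic", {
    # two groups shaped like the published best-7 vs all-11 summaries
    s <- fakeSummaries(11, rep(50, 2047), toolNames = paste0("T", 1:11),
                       nRuns = 100L)
    best <- which(s$size == 7L)[1L]
    s$mean_sens[best] <- 64.14; s$sd_sens[best] <- 5.22
    s$mean_sens[s$mask == 2047L] <- 52.51
    s$sd_sens[s$mask == 2047L] <- 5.80
    cmp <- compareBestVsFull(s, maxSize = 7L)
    expect_identical(cmp$best_size, 7L)
    expect_equal(cmp$difference, 11.63, tolerance = 1e-12)
    expect_equal(cmp$z, 11.63 / sqrt(5.22^2 / 100 + 5.80^2 / 100),
                 tolerance = 1e-12)
    expect_true(cmp$paradox)
    # degenerate case: the full set is itself the best -> no paradox
    s2 <- fakeSummaries(3, c(0.1, 0.1, 0.4, 0.1, 0.45, 0.5, 0.9))
    cmp2 <- compareBestVsFull(s2, maxSize = 3L)
    expect_false(cmp2$paradox)
    expect_true(is.na(cmp2$z))
    expect_identical(cmp2$difference, 0)
    s2m <- s2[s2$mask != 7L, ]
    attr(s2m, "toolNames") <- attr(s2, "toolNames")
    expect_error(compareBestVsFull(s2m), "full tool set")
})

test_that("predictWithSubset labels new proteins from a fitted subset", {
    fs <- imputeMissing(generateDataset(designedScenario(seed = 12L)))
    m <- toolsToMask("perfect", toolNames(fs))
    labs <- predictWithSubset(fs, m, fs)
    expect_length(labs, nProteins(fs))
    expect_identical(unname(labs), unname(proteinLabels(fs)))
    # agrees with the evaluation pipeline given the identical split
    ss <- splitSpec(nTestPos = 8L, nTestNeg = 24L, nRuns = 2L, baseSeed = 3L)
    res <- evaluateCombination(fs, m, ss)
    sp <- stratifiedSplit(fs, ss, runIndex = 2L, mask = m)
    manual <- predictWithSubset(sp$test, m, sp$train)
    cc <- confusionCounts(proteinLabels(sp$test), manual)
    expect_identical(unname(cc),
                     unname(unlist(res$runs[2L, c("tp", "fp", "tn", "fn")])))
    expect_error(predictWithSubset(fs["coin", ], m, fs), "lacks tool")
})
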