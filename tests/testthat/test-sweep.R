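test_that("stratified splits hit exact per-class counts and are disjoint", {
    fs <- imputeMissing(generateDataset(designedScenario(seed = 2L,
                                                         nPos = 30L,
                                                         nNeg = 80L)))
    ss <- splitSpec(nTestPos = 5L, nTestNeg = 10L, nRuns = 4L, baseSeed = 3L)
    sp <- stratifiedSplit(fs, ss, runIndex = 1L)
    expect_identical(nProteins(sp$test), 15L)
    expect_identical(sum(proteinLabels(sp$test) == 1L), 5L)
    expect_identical(sum(proteinLabels(sp$test) == 0L), 10L)
    expect_identical(nProteins(sp$train), 95L)
    expect_length(intersect(proteinIds(sp$train), proteinIds(sp$test)), 0L)
    expect_setequal(c(proteinIds(sp$train), proteinIds(sp$test)),
                    proteinIds(fs))
    # determinism per (table, spec, runIndex); distinct runs differ
    again <- stratifiedSplit(fs, ss, runIndex = 1L)
    expect_identical(proteinIds(again$test), proteinIds(sp$test))
    run2 <- stratifiedSplit(fs, ss, runIndex = 2L)
    expect_false(identical(proteinIds(run2$test), proteinIds(sp$test)))
    # the subset mask shifts the seed unless splits are shared
    masked <- stratifiedSplit(fs, ss, runIndex = 1L, mask = 3L)
    expect_false(identical(proteinIds(masked$test), proteinIds(sp$test)))
    expect_error(stratifiedSplit(fs, splitSpec(30L, 10L, 1L, 1L), 1L),
                 "positive proteins")
})

test_that("a perfect single tool is recovered with errorless runs", {
    fs <- imputeMissing(generateDataset(designedScenario(seed = 4L)))
    ss <- splitSpec(nTestPos = 8L, nTestNeg = 24L, nRuns = 5L, baseSeed = 1L)
    m <- toolsToMask("perfect", toolNames(fs))
    res <- evaluateCombination(fs, m, ss)
    expect_identical(res$summary$mean_sens, 1)
    expect_identical(res$summary$mean_spec, 1)
    expect_identical(res$summary$sd_sens, 0)
    expect_identical(res$summary$mean_fdr, 0)
})

test_that("run-level counts conserve the test composition", {
    fs <- imputeMissing(generateDataset(designedScenario(seed = 5L)))
    ss <- splitSpec(nTestPos = 8L, nTestNeg = 24L, nRuns = 5L, baseSeed = 2L)
    res <- evaluateCombination(fs, toolsToMask("coin", toolNames(fs)), ss)
    expect_true(all(res$runs$tp + res$runs$fn == 8L))
    expect_true(all(res$runs$tn + res$runs$fp == 24L))
    expect_true(all(res$runs$train_size == nProteins(fs) - 32L))
    # stored metrics are consistent with their own confusion counts
    expect_equal(res$runs$sens, res$runs$tp / (res$runs$tp + res$runs$fn),
                 tolerance = 1e-15)
    expect_equal(res$runs$spec, res$runs$tn / (res$runs$tn + res$runs$fp),
                 tolerance = 1e-15)
    expect_equal(res$runs$fdr,
                 ifelse(res$runs$fp + res$runs$tp == 0, 0,
                        res$runs$fp / (res$runs$fp + res$runs$tp)),
                 tolerance = 1e-15)
    expect_identical(res$runs$overfit,
                     res$runs$sv_count / res$runs$train_size >= 0.1)
})

test_that("summary statistics equal hand-computed aggregates of the runs", {
    fs <- imputeMissing(generateDataset(designedScenario(seed = 6L)))
    ss <- splitSpec(nTestPos = 8L, nTestNeg = 24L, nRuns = 3L, baseSeed = 9L)
    res <- evaluateCombination(fs, toolsToMask(c("perfect", "coin"),
                                               toolNames(fs)), ss)
    expect_equal(res$summary$mean_sens, mean(res$runs$sens),
                 tolerance = 1e-15)
    expect_equal(res$summary$sd_sens, sd(res$runs$sens), tolerance = 1e-15)
    expect_equal(res$summary$mean_cfdr, mean(res$runs$cfdr),
                 tolerance = 1e-15)
    expect_identical(res$summary$n_runs, 3L)
    sparse <- generateDataset(scenarioConfig(
        predictorProfiles("patchy", 0.6, 0.05, coverage = 0.5),
        nPos = 40L, nNeg = 120L, seed = 7L))
    expect_error(evaluateCombination(sparse, 1L, ss), "missing cells")
})

test_that("the sweep covers every subset in enumeration order", {
    fs <- imputeMissing(generateDataset(designedScenario(seed = 7L)))
    ss <- splitSpec(nTestPos = 6L, nTestNeg = 18L, nRuns = 2L, baseSeed = 4L)
    s <- runSweep(fs, ss)
    expect_identical(nrow(s), 7L)  # 2^3 - 1
    expect_identical(s$mask, enumerateSubsets(3L))
    expect_identical(attr(s, "toolNames"), toolNames(fs))
    expect_identical(s$tool_names[s$mask == 5L], "perfect+weak")
    # the subset holding the perfect tool dominates every subset without it
    withPerfect <- bitwAnd(s$mask, 1L) > 0L
    expect_true(min(s$mean_sens[withPerfect & s$size == 1L]) >=
                max(s$mean_sens[!withPerfect]))
})

test_that("sweeps are deterministic and order-independent", {
    fs <- imputeMissing(generateDataset(designedScenario(seed = 8L)))
    ss <- splitSpec(nTestPos = 6L, nTestNeg = 18L, nRuns = 3L, baseSeed = 5L)
    s1 <- runSweep(fs, ss)
    s2 <- runSweep(fs, ss)
    expect_identical(s1, s2)
    # parallel workers produce the identical result
    s3 <- runSweep(fs, ss, cores = 2L)
    expect_identical(s3, s1)
    # evaluating masks in reverse order leaves each summary unchanged
    s4 <- runSweep(fs, ss, masks = rev(enumerateSubsets(3L)))
    expect_identical(s4[nrow(s4):1L, ]$mean_sens, s1$mean_sens)
    # byte-identical CSV serialization
    p1 <- withr::local_tempfile(fileext = ".csv")
    p2 <- withr::local_tempfile(fileext = ".csv")
    writeSummaries(s1, p1); writeSummaries(s3, p2)
    expect_identical(readLines(p1), readLines(p2))
    back <- readSummaries(p1, toolNames = toolNames(fs))
    expect_equal(back$mean_sens, s1$mean_sens, tolerance = 1e-15)
    expect_identical(back$mask, s1$mask)
})

test_that("shared splits reuse one split sequence across subsets", {
    fs <- imputeMissing(generateDataset(designedScenario(seed = 9L)))
    ss <- splitSpec(nTestPos = 6L, nTestNeg = 18L, nRuns = 2L, baseSeed = 6L)
    # with sharedSplits the perfect tool stays errorless under any companion
    r1 <- evaluateCombination(fs, 1L, ss, sharedSplits = TRUE)
    r2 <- evaluateCombination(fs, 5L, ss, sharedSplits = TRUE)
    expect_identical(r1$runs$tp + r1$runs$fn, r2$runs$tp + r2$runs$fn)
    spA <- stratifiedSplit(fs, ss, 1L, mask = 0L)
    spB <- stratifiedSplit(fs, ss, 1L, mask = 0L)
    expect_identical(proteinIds(spA$test), proteinIds(spB$test))
})
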