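#' Construct a SplitSpec
#'
#' @param nTestPos,nTestNeg exact per-class test-set sizes (defaults 100 and
#'   630).
#' @param nRuns number of independent splits (default 100).
#' @param baseSeed integer base seed for the per-run seed derivation.
#' @return A \linkS4class{SplitSpec}.
#' @export
splitSpec <- function(nTestPos = 100L, nTestNeg = 630L, nRuns = 100L,
                      baseSeed = 1L) {
    obj <- methods::new("SplitSpec", nTestPos = as.integer(nTestPos),
                        nTestNeg = as.integer(nTestNeg),
                        nRuns = as.integer(nRuns),
                        baseSeed = as.integer(baseSeed))
    methods::validObject(obj)
    obj
}

setMethod("show", "SplitSpec", function(object) {
    cat(sprintf("SplitSpec: %d runs, test = %d pos + %d neg, base seed %d\n",
                object@nRuns, object@nTestPos, object@nTestNeg,
                object@baseSeed))
    invisible(NULL)
})

#' One stratified train/test split
#'
#' Draws, without replacement, a test set with exactly \code{nTestPos}
#' mitochondrial and \code{nTestNeg} non-mitochondrial proteins; the
#' complement is the training set. The RNG seed is
#' \code{mixSeed(baseSeed, mask, runIndex)}, so a split depends only on
#' (table, spec, mask, runIndex) and is reproducible in isolation.
#'
#' @param x a \linkS4class{FeatureSet}; each class must exceed its test
#'   count.
#' @param spec a \linkS4class{SplitSpec}.
#' @param runIndex 1-based run index.
#' @param mask subset bitmask mixed into the seed; leave at 0 to share the
#'   same run splits across all subsets.
#' @return List with elements \code{train} and \code{test}, both
#'   \linkS4class{FeatureSet}s preserving the original protein order.
#' @export
stratifiedSplit <- function(x, spec, runIndex, mask = 0L) {
    lab <- proteinLabels(x)
    posIdx <- which(lab == 1L)
    negIdx <- which(lab == 0L)
    if (length(posIdx) <= spec@nTestPos)
        stop(sprintf("need > %d positive proteins, have %d",
                     spec@nTestPos, length(posIdx)))
    if (length(negIdx) <= spec@nTestNeg)
        stop(sprintf("need > %d negative proteins, have %d",
                     spec@nTestNeg, length(negIdx)))
    seed <- mixSeed(spec@baseSeed, mask, runIndex)
    withSeed(seed, {
        testIdx <- sort(c(sample(posIdx, spec@nTestPos),
                          sample(negIdx, spec@nTestNeg)))
        list(train = x[, setdiff(seq_len(ncol(x)), testIdx)],
             test = x[, testIdx])
    })
}

#' Evaluate one tool combination by repeated train/test
#'
#' For each of \code{nRuns} splits: restrict the feature table to the
#' subset's tools, train the SVM on the training proteins, predict the test
#' proteins, record confusion counts, the support-vector count and the
#' overfitting flag, and compute sensitivity, specificity, FDR and cFDR.
#' Metrics are kept on the \code{[0, 1]} scale.
#'
#' @param x an imputed \linkS4class{FeatureSet} (missing cells are a hard
#'   error).
#' @param mask subset bitmask over \code{toolNames(x)}.
#' @param spec a \linkS4class{SplitSpec}.
#' @param svm an \linkS4class{SVMConfig}.
#' @param sharedSplits logical; if \code{TRUE} the run splits ignore the
#'   mask, so every combination sees the identical sequence of splits. The
#'   default redraws splits per combination.
#' @param priorFraction class prior passed to \code{\link{cfdr}}.
#' @return List with \code{summary} (one-row data.frame: mask, tool_names,
#'   size, mean/sd of the four metrics, n_overfit_runs, n_runs) and
#'   \code{runs} (one row per run with counts, sv_count, train_size,
#'   overfit and per-run metrics).
#' @export
evaluateCombination <- function(x, mask, spec, svm = svmConfig(),
                                sharedSplits = FALSE,
                                priorFraction = 1500 / 21000) {
    if (anyNA(SummarizedExperiment::assay(x, "score")))
        stop("feature table has missing cells; run imputeMissing() first")
    tools <- maskToTools(mask, toolNames(x))
    runs <- vector("list", spec@nRuns)
    for (r in seq_len(spec@nRuns)) {
        sp <- stratifiedSplit(x, spec, r, if (sharedSplits) 0L else mask)
        Xtr <- featureMatrix(sp$train)[, tools, drop = FALSE]
        Xte <- featureMatrix(sp$test)[, tools, drop = FALSE]
        model <- trainSVM(Xtr, proteinLabels(sp$train), svm)
        pred <- predictSVM(model, Xte)
        cc <- confusionCounts(proteinLabels(sp$test), pred)
        sn <- sensitivity(cc); sp_ <- specificity(cc)
        runs[[r]] <- data.frame(
            mask = mask, run = r,
            tp = cc[["tp"]], fp = cc[["fp"]], tn = cc[["tn"]], fn = cc[["fn"]],
            sv_count = model@nSV, train_size = model@trainSize,
            overfit = !svGate(model, svm@svFractionLimit),
            sens = sn, spec = sp_, fdr = fdr(cc),
            cfdr = cfdr(sn, sp_, priorFraction))
    }
    runs <- do.call(rbind, runs)
    agg <- function(v) aggregateRuns(v)
    s <- c(agg(runs$sens), agg(runs$spec), agg(runs$fdr), agg(runs$cfdr))
    summary <- data.frame(
        mask = mask, tool_names = paste(tools, collapse = "+"),
        size = maskSize(mask),
        mean_sens = s[[1L]], sd_sens = s[[2L]],
        mean_spec = s[[3L]], sd_spec = s[[4L]],
        mean_fdr = s[[5L]], sd_fdr = s[[6L]],
        mean_cfdr = s[[7L]], sd_cfdr = s[[8L]],
        n_overfit_runs = sum(runs$overfit), n_runs = spec@nRuns,
        stringsAsFactors = FALSE)
    list(summary = summary, runs = runs)
}

#' Exhaustive combination sweep
#'
#' Evaluates every requested tool subset (by default all non-empty subsets
#' of the table's tools) with \code{\link{evaluateCombination}}. Because
#' per-run seeds depend only on (baseSeed, mask, runIndex), the result is
#' independent of execution order: serial and parallel runs are identical.
#'
#' @inheritParams evaluateCombination
#' @param masks integer bitmasks to evaluate; default
#'   \code{enumerateSubsets(nTools(x))}.
#' @param cores number of worker processes (forked via
#'   \code{parallel::mclapply} when > 1).
#' @param keepRuns logical; also return the per-run results.
#' @return A data.frame of combination summaries, one row per mask in input
#'   order, with the tool roster attached as
#'   \code{attr(, "toolNames")}. With \code{keepRuns = TRUE}, a list
#'   \code{list(summaries = , runs = )}.
#' @export
runSweep <- function(x, spec, svm = svmConfig(), masks = NULL, cores = 1L,
                     sharedSplits = FALSE, priorFraction = 1500 / 21000,
                     keepRuns = FALSE) {
    if (is.null(masks)) masks <- enumerateSubsets(nTools(x))
    fun <- function(m) evaluateCombination(x, m, spec, svm,
                                           sharedSplits = sharedSplits,
                                           priorFraction = priorFraction)
    res <- if (cores > 1L) {
        parallel::mclapply(masks, fun, mc.cores = cores, mc.preschedule = TRUE)
    } else {
        lapply(masks, fun)
    }
    failed <- vapply(res, function(r) !is.list(r) || is.null(r$summary),
                     logical(1L))
    if (any(failed))
        stop("evaluation failed for mask(s): ",
             paste(masks[failed], collapse = ", "))
    summaries <- do.call(rbind, lapply(res, `[[`, "summary"))
    rownames(summaries) <- NULL
    attr(summaries, "toolNames") <- toolNames(x)
    if (keepRuns) {
        runs <- do.call(rbind, lapply(res, `[[`, "runs"))
        rownames(runs) <- NULL
        list(summaries = summaries, runs = runs)
    } else {
        summaries
    }
}

#' Write / read combination summaries as CSV
#'
#' The CSV carries one row per combination with the columns of
#' \code{\link{runSweep}} output; numeric values are rendered with the
#' shortest exact decimal representation so identical sweeps produce
#' byte-identical files. The tool roster is not stored in the file; pass it
#' back via \code{toolNames} when reading if contribution analyses are to
#' follow.
#'
#' @param summaries data.frame from \code{\link{runSweep}}.
#' @param path CSV path.
#' @param toolNames optional roster to attach on read.
#' @return \code{writeSummaries}: invisibly, \code{path};
#'   \code{readSummaries}: the summaries data.frame.
#' @export
writeSummaries <- function(summaries, path) {
    out <- summaries
    num <- vapply(out, is.double, logical(1L))
    out[num] <- lapply(out[num], formatExact)
    data.table::fwrite(data.table::as.data.table(out), path,
                       sep = ",", quote = FALSE)
    invisible(path)
}

#' @rdname writeSummaries
#' @export
readSummaries <- function(path, toolNames = NULL) {
    df <- as.data.frame(data.table::fread(path, sep = ","))
    attr(df, "toolNames") <- toolNames
    df
}
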