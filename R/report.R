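.metricColumn <- function(metric) {
    metric <- match.arg(metric,
                        c("sensitivity", "specificity", "fdr", "cfdr"))
    c(sensitivity = "mean_sens", specificity = "mean_spec",
      fdr = "mean_fdr", cfdr = "mean_cfdr")[[metric]]
}

.rosterOf <- function(summaries, toolNames) {
    tn <- toolNames %||% attr(summaries, "toolNames")
    if (is.null(tn))
        stop("tool roster unknown; pass 'toolNames' or use runSweep() output")
    tn
}

#' Rank combinations by a mean metric
#'
#' Stable sort of combination summaries by the mean of one metric
#' (descending by default); ties are broken by smaller subset size, then
#' smaller mask.
#'
#' @param summaries data.frame from \code{\link{runSweep}}.
#' @param metric one of \code{"sensitivity"}, \code{"specificity"},
#'   \code{"fdr"}, \code{"cfdr"} (partial matching allowed).
#' @param decreasing sort direction (default \code{TRUE}: best first; note
#'   that for fdr/cfdr "best" means smallest, so pass \code{FALSE}).
#' @return The reordered summaries data.frame.
#' @export
rankCombinations <- function(summaries, metric = "sensitivity",
                             decreasing = TRUE) {
    col <- .metricColumn(metric)
    v <- summaries[[col]]
    ord <- order(if (decreasing) -v else v, summaries$size, summaries$mask)
    out <- summaries[ord, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "toolNames") <- attr(summaries, "toolNames")
    out
}

#' Per-tool contribution probability among the top-k combinations
#'
#' For each tool, the proportion of the k best combinations (by the chosen
#' mean metric) whose subset includes that tool — the bar-chart form of the
#' contribution analysis. With k equal to all subsets of n tools every
#' probability is \code{2^(n-1) / (2^n - 1)}, just over one half.
#'
#' @inheritParams rankCombinations
#' @param k number of top combinations, in \code{[1, nrow(summaries)]}.
#' @param toolNames tool roster; defaults to the attribute attached by
#'   \code{\link{runSweep}}.
#' @return data.frame with columns \code{tool} and \code{probability};
#'   attributes \code{metric} and \code{k}.
#' @export
contributionTopK <- function(summaries, metric = "sensitivity", k,
                             toolNames = NULL) {
    tn <- .rosterOf(summaries, toolNames)
    if (length(k) != 1L || is.na(k) || k < 1L || k > nrow(summaries))
        stop("'k' must be in [1, number of summaries]")
    top <- utils::head(rankCombinations(summaries, metric), k)
    prob <- vapply(seq_along(tn), function(i) {
        mean(bitwAnd(as.integer(top$mask), bitwShiftL(1L, i - 1L)) > 0L)
    }, numeric(1L))
    out <- data.frame(tool = tn, probability = prob, stringsAsFactors = FALSE)
    attr(out, "metric") <- metric
    attr(out, "k") <- as.integer(k)
    out
}

#' Per-tool contribution probability by metric bin
#'
#' The heat-map form of the contribution analysis: combinations are binned
#' by their mean metric, and within each bin the probability of a tool is
#' the proportion of that bin's combinations including it (the denominator
#' is per-bin). Empty bins are reported with \code{NA} probabilities, not
#' zero. Bins are \code{[e_i, e_{i+1})}, the last closed on the right.
#'
#' @inheritParams contributionTopK
#' @param binEdges strictly increasing numeric vector covering the observed
#'   metric range.
#' @return Long data.frame with columns \code{bin}, \code{lower},
#'   \code{upper}, \code{n}, \code{tool}, \code{probability}.
#' @export
contributionBinned <- function(summaries, metric = "sensitivity", binEdges,
                               toolNames = NULL) {
    tn <- .rosterOf(summaries, toolNames)
    if (length(binEdges) < 2L || any(diff(binEdges) <= 0))
        stop("'binEdges' must be strictly increasing with >= 2 edges")
    v <- summaries[[.metricColumn(metric)]]
    if (any(v < binEdges[1L] | v > binEdges[length(binEdges)]))
        stop("'binEdges' must cover the observed metric range")
    bin <- findInterval(v, binEdges, rightmost.closed = TRUE)
    nb <- length(binEdges) - 1L
    out <- do.call(rbind, lapply(seq_len(nb), function(b) {
        inBin <- summaries$mask[bin == b]
        prob <- if (length(inBin) == 0L) {
            rep(NA_real_, length(tn))
        } else {
            vapply(seq_along(tn), function(i) {
                mean(bitwAnd(as.integer(inBin), bitwShiftL(1L, i - 1L)) > 0L)
            }, numeric(1L))
        }
        data.frame(bin = b, lower = binEdges[b], upper = binEdges[b + 1L],
                   n = length(inBin), tool = tn, probability = prob,
                   stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}

#' Default equal-width bin edges
#'
#' @param values observed metric values.
#' @param nBins number of bins (default 20).
#' @return Numeric vector of \code{nBins + 1} edges spanning the range.
#' @export
defaultBinEdges <- function(values, nBins = 20L) {
    r <- range(values)
    if (r[1L] == r[2L]) r <- r + c(-1e-9, 1e-9)
    seq(r[1L], r[2L], length.out = nBins + 1L)
}

#' Compare the best small combination against the full tool set
#'
#' Finds the combination with the highest mean sensitivity among subsets of
#' at most \code{maxSize} tools and compares it with the full set via a
#' Welch z test on the run-level summaries. A positive, significant
#' difference is the combination paradox: a carefully chosen small subset
#' beats the union of all tools. If the full set itself is the best
#' eligible combination the comparison degenerates (\code{paradox = FALSE},
#' \code{z = NA}).
#'
#' @param summaries data.frame from \code{\link{runSweep}}; must include
#'   the full-roster subset.
#' @param maxSize size cap for the "best" search (default 7).
#' @param nRuns runs per combination; defaults to the \code{n_runs} column.
#' @return List with the best subset's mask/tools/size, mean/sd sensitivity
#'   of best and full (on the \code{[0, 1]} scale), \code{difference},
#'   \code{z}, \code{p}, \code{n_runs} and logical \code{paradox}.
#' @export
compareBestVsFull <- function(summaries, maxSize = 7L, nRuns = NULL) {
    roster <- attr(summaries, "toolNames")
    nT <- if (is.null(roster)) max(summaries$size) else length(roster)
    fullMask <- as.integer(2^nT - 1)
    fullRow <- summaries[summaries$mask == fullMask, , drop = FALSE]
    if (nrow(fullRow) != 1L)
        stop("summaries must include the full tool set (mask ",
             fullMask, ")")
    n <- nRuns %||% summaries$n_runs[1L]
    eligible <- summaries[summaries$size <= maxSize, , drop = FALSE]
    if (nrow(eligible) == 0L)
        stop("no combination of size <= ", maxSize)
    best <- utils::head(rankCombinations(eligible, "sensitivity"), 1L)
    if (best$mask == fullMask) {
        return(list(best_mask = best$mask, best_tools = best$tool_names,
                    best_size = best$size,
                    best_mean_sens = best$mean_sens,
                    best_sd_sens = best$sd_sens,
                    full_mean_sens = fullRow$mean_sens,
                    full_sd_sens = fullRow$sd_sens,
                    difference = 0, z = NA_real_, p = NA_real_,
                    n_runs = n, paradox = FALSE))
    }
    w <- welchZ(best$mean_sens, best$sd_sens, n,
                fullRow$mean_sens, fullRow$sd_sens, n)
    list(best_mask = best$mask, best_tools = best$tool_names,
         best_size = best$size,
         best_mean_sens = best$mean_sens, best_sd_sens = best$sd_sens,
         full_mean_sens = fullRow$mean_sens, full_sd_sens = fullRow$sd_sens,
         difference = w$difference, z = w$z, p = w$p,
         n_runs = n, paradox = isTRUE(w$difference > 0))
}

#' Train on one table and label another
#'
#' Trains the SVM on the training table restricted to a tool subset and
#' labels every protein of \code{newdata} — the mechanism behind applying a
#' chosen combination genome-wide.
#'
#' @param newdata \linkS4class{FeatureSet} to label; must share the
#'   subset's tool columns with \code{trainingTable}.
#' @param mask subset bitmask over the training table's tools.
#' @param trainingTable imputed labelled \linkS4class{FeatureSet}.
#' @param svm an \linkS4class{SVMConfig}.
#' @return Named integer vector of 0/1 labels, one per row of
#'   \code{newdata}.
#' @export
predictWithSubset <- function(newdata, mask, trainingTable,
                              svm = svmConfig()) {
    tools <- maskToTools(mask, toolNames(trainingTable))
    if (!all(tools %in% toolNames(newdata)))
        stop("'newdata' lacks tool column(s): ",
             paste(setdiff(tools, toolNames(newdata)), collapse = ", "))
    model <- trainSVM(featureMatrix(trainingTable)[, tools, drop = FALSE],
                      proteinLabels(trainingTable), svm)
    predictSVM(model, featureMatrix(newdata)[, tools, drop = FALSE])
}
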