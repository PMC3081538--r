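#' FeatureSet: labelled per-protein predictor outputs
#'
#' A \code{FeatureSet} stores the outputs of localization prediction tools for
#' a set of proteins, together with a binary localization label per protein
#' (1 = mitochondrial, 0 = non-mitochondrial; this polarity is fixed
#' throughout the package, so sensitivity always means recall of
#' mitochondrial proteins). It extends
#' \linkS4class{SummarizedExperiment}: prediction tools are the rows
#' (features) and proteins the columns (samples). The single assay
#' \code{"score"} holds values in \code{[0, 1]}; \code{NA} marks cells where a
#' tool made no call (limited coverage), and doubles as the missingness mask.
#'
#' @slot .. inherited from \code{SummarizedExperiment}; the label lives in
#'   \code{colData(x)$label}.
#' @seealso \code{\link{FeatureSet}} (constructor),
#'   \code{\link{readFeatureTable}}, \code{\link{generateDataset}}
#' @name FeatureSet-class
#' @aliases FeatureSet-class
#' @exportClass FeatureSet
setClass("FeatureSet", contains = "SummarizedExperiment")

setValidity("FeatureSet", function(object) {
    msg <- character()
    if (!"score" %in% SummarizedExperiment::assayNames(object))
        return("assay 'score' is required")
    sc <- SummarizedExperiment::assay(object, "score")
    if (!is.numeric(sc))
        msg <- c(msg, "assay 'score' must be numeric")
    if (nrow(object) < 1L)
        msg <- c(msg, "at least one prediction tool (row) is required")
    tn <- rownames(object)
    if (is.null(tn) || anyDuplicated(tn) || any(!nzchar(tn)))
        msg <- c(msg, "tool names (rownames) must be unique non-empty strings")
    pid <- colnames(object)
    if (is.null(pid) || any(!nzchar(pid)))
        msg <- c(msg, "protein ids (colnames) must be non-empty strings")
    if (!is.null(pid) && anyDuplicated(pid))
        msg <- c(msg, sprintf("duplicate protein id: '%s'",
                              pid[duplicated(pid)][1L]))
    if (!"label" %in% colnames(SummarizedExperiment::colData(object))) {
        msg <- c(msg, "colData must contain a 'label' column")
    } else {
        lab <- SummarizedExperiment::colData(object)$label
        if (anyNA(lab) || !all(lab %in% c(0L, 1L)))
            msg <- c(msg, "labels must be 0 (non-mitochondrial) or 1 (mitochondrial)")
    }
    bad <- !is.na(sc) & (sc < 0 | sc > 1)
    if (any(bad))
        msg <- c(msg, "scores must lie in [0, 1] or be NA")
    if (length(msg)) msg else TRUE
})

#' SVM configuration
#'
#' Hyperparameters for the radial-basis-function (RBF) soft-margin SVM used
#' to fuse tool outputs, together with the support-vector-fraction limit of
#' the overfitting gate. The defaults (\code{cost = 10}, \code{gamma = 0.1},
#' RBF kernel, support vectors below 10\% of the training set) reproduce the
#' reference evaluation protocol of this package; see the vignette for the reasoning behind
#' the termination tolerance default.
#'
#' @slot cost numeric, margin-violation penalty C (> 0); larger values
#'   penalise training errors more.
#' @slot gamma numeric, RBF kernel width parameter (> 0).
#' @slot tolerance numeric, optimizer termination tolerance (> 0).
#' @slot svFractionLimit numeric in (0, 1]; a trained model whose support
#'   vectors are not fewer than this fraction of the training set is flagged
#'   as overfit.
#' @seealso \code{\link{svmConfig}}, \code{\link{trainSVM}}, \code{\link{svGate}}
#' @name SVMConfig-class
#' @aliases SVMConfig-class
#' @exportClass SVMConfig
setClass("SVMConfig",
    representation(cost = "numeric", gamma = "numeric",
                   tolerance = "numeric", svFractionLimit = "numeric"),
    prototype(cost = 10, gamma = 0.1, tolerance = 0.001,
              svFractionLimit = 0.1))

setValidity("SVMConfig", function(object) {
    msg <- character()
    for (s in c("cost", "gamma", "tolerance", "svFractionLimit")) {
        v <- slot(object, s)
        if (length(v) != 1L || !is.finite(v) || v <= 0)
            msg <- c(msg, sprintf("'%s' must be a single positive number", s))
    }
    if (length(object@svFractionLimit) == 1L &&
        is.finite(object@svFractionLimit) && object@svFractionLimit > 1)
        msg <- c(msg, "'svFractionLimit' must be in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' A trained SVM model
#'
#' Wraps a fitted kernel SVM together with the bookkeeping the evaluation
#' pipeline needs: the ordered tool (feature) names it was trained on, the
#' support vector count and the training-set size.
#'
#' @slot fit the underlying fitted model object.
#' @slot toolNames character, feature columns in training order.
#' @slot nSV integer, number of support vectors.
#' @slot trainSize integer, number of training examples.
#' @seealso \code{\link{trainSVM}}, \code{\link{predictSVM}}, \code{\link{svGate}}
#' @name TrainedSVM-class
#' @aliases TrainedSVM-class
#' @exportClass TrainedSVM
setClass("TrainedSVM",
    representation(fit = "ANY", toolNames = "character",
                   nSV = "integer", trainSize = "integer"))

setValidity("TrainedSVM", function(object) {
    if (object@nSV < 1L || object@nSV > object@trainSize)
        return("support vector count must be in [1, training size]")
    TRUE
})

#' Repeated stratified split specification
#'
#' Describes the resampling protocol: each run draws, without replacement, a
#' test set with exactly \code{nTestPos} mitochondrial and \code{nTestNeg}
#' non-mitochondrial proteins (the remainder trains), repeated \code{nRuns}
#' times. The defaults (100 positive / 630 negative test proteins, 100 runs)
#' suit a 467/6352 table: test sets of 730 leaving
#' 6089 proteins for training, roughly a 90/10 split.
#'
#' @slot nTestPos integer, positives per test set.
#' @slot nTestNeg integer, negatives per test set.
#' @slot nRuns integer, number of independent splits.
#' @slot baseSeed integer, base seed from which per-run seeds are derived
#'   (see \code{\link{mixSeed}}).
#' @seealso \code{\link{splitSpec}}, \code{\link{stratifiedSplit}}
#' @name SplitSpec-class
#' @aliases SplitSpec-class
#' @exportClass SplitSpec
setClass("SplitSpec",
    representation(nTestPos = "integer", nTestNeg = "integer",
                   nRuns = "integer", baseSeed = "integer"),
    prototype(nTestPos = 100L, nTestNeg = 630L, nRuns = 100L, baseSeed = 1L))

setValidity("SplitSpec", function(object) {
    msg <- character()
    if (object@nTestPos < 1L) msg <- c(msg, "'nTestPos' must be >= 1")
    if (object@nTestNeg < 1L) msg <- c(msg, "'nTestNeg' must be >= 1")
    if (object@nRuns < 1L) msg <- c(msg, "'nRuns' must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Synthetic scenario configuration
#'
#' Generative parameters for a synthetic labelled feature table: one
#' predictor profile per tool (name, true/false positive rates of the binary
#' core call, coverage, optional correlation group, score jitter), the class
#' sizes, the within-group correlation strength and a seed. The default class
#' sizes, 467 mitochondrial and 6352 non-mitochondrial proteins, match the
#' study design this generator emulates.
#'
#' @slot profiles data.frame with columns \code{name}, \code{tpr}, \code{fpr},
#'   \code{coverage}, \code{group}, \code{noiseSd}, \code{role}.
#' @slot nPos integer, number of positive (mitochondrial) proteins.
#' @slot nNeg integer, number of negative proteins.
#' @slot latentStrength numeric in [0, 1]: probability that, for a given
#'   protein, all tools in a correlation group replace their independent
#'   draws by one shared draw.
#' @slot seed integer RNG seed; the same configuration always generates a
#'   byte-identical table.
#' @seealso \code{\link{scenarioConfig}}, \code{\link{predictorProfiles}},
#'   \code{\link{generateDataset}}, \code{\link{paradoxScenario}}
#' @name ScenarioConfig-class
#' @aliases ScenarioConfig-class
#' @exportClass ScenarioConfig
setClass("ScenarioConfig",
    representation(profiles = "data.frame", nPos = "integer",
                   nNeg = "integer", latentStrength = "numeric",
                   seed = "integer"))

setValidity("ScenarioConfig", function(object) {
    msg <- character()
    pr <- object@profiles
    need <- c("name", "tpr", "fpr", "coverage", "group", "noiseSd", "role")
    if (!all(need %in% names(pr)))
        return(sprintf("profiles must have columns: %s",
                       paste(need, collapse = ", ")))
    if (nrow(pr) < 1L) msg <- c(msg, "at least one profile is required")
    if (anyDuplicated(pr$name)) msg <- c(msg, "profile names must be unique")
    for (cl in c("tpr", "fpr", "coverage")) {
        v <- pr[[cl]]
        if (anyNA(v) || any(v < 0 | v > 1))
            msg <- c(msg, sprintf("'%s' must lie in [0, 1]", cl))
    }
    if (anyNA(pr$noiseSd) || any(pr$noiseSd < 0))
        msg <- c(msg, "'noiseSd' must be >= 0")
    grp <- table(pr$group[!is.na(pr$group)])
    if (any(grp < 2L))
        msg <- c(msg, "every correlation group must contain >= 2 profiles")
    if (object@nPos < 2L || object@nNeg < 2L)
        msg <- c(msg, "need at least 2 proteins of each class")
    if (length(object@latentStrength) != 1L || is.na(object@latentStrength) ||
        object@latentStrength < 0 || object@latentStrength > 1)
        msg <- c(msg, "'latentStrength' must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})
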