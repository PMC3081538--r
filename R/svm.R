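#' Construct an SVM configuration
#'
#' @param cost margin-violation penalty C (> 0); default 10.
#' @param gamma RBF kernel width (> 0); default 0.1.
#' @param tolerance optimizer termination tolerance; default 0.001.
#' @param svFractionLimit overfitting-gate threshold in (0, 1]: a model
#'   passes the gate when its support vectors number strictly fewer than
#'   this fraction of the training set; default 0.1.
#' @return An \linkS4class{SVMConfig}.
#' @export
svmConfig <- function(cost = 10, gamma = 0.1, tolerance = 0.001,
                      svFractionLimit = 0.1) {
    obj <- methods::new("SVMConfig", cost = cost, gamma = gamma,
                        tolerance = tolerance,
                        svFractionLimit = svFractionLimit)
    methods::validObject(obj)
    obj
}

#' Train the RBF soft-margin SVM
#'
#' Fits a C-classification SVM (libsvm backend, RBF kernel, no feature
#' scaling, no class weighting) on a feature matrix or a
#' \linkS4class{FeatureSet}. Training data must be fully observed — impute
#' first — and contain both classes. Given identical inputs in identical
#' order the fit is deterministic.
#'
#' @param x a \linkS4class{FeatureSet} (labels taken from the object) or a
#'   numeric matrix, proteins as rows, tools as columns (colnames required).
#' @param label 0/1 labels, required when \code{x} is a matrix.
#' @param config an \linkS4class{SVMConfig}.
#' @return A \linkS4class{TrainedSVM}.
#' @examples
#' X <- cbind(score = c(1, 1, 0, 0, 1, 0))
#' rownames(X) <- paste0("P", 1:6)
#' m <- trainSVM(X, c(1, 1, 0, 0, 1, 0))
#' predictSVM(m, X)
#' @export
trainSVM <- function(x, label = NULL, config = svmConfig()) {
    if (methods::is(x, "FeatureSet")) {
        label <- proteinLabels(x)
        x <- featureMatrix(x)
    }
    if (is.null(colnames(x)))
        stop("feature matrix must have column (tool) names")
    if (anyNA(x))
        stop("training features contain missing values; impute first")
    if (!all(is.finite(x)))
        stop("training features must be finite")
    y <- as.integer(label)
    if (length(unique(y)) < 2L)
        stop("training data must contain both classes")
    fit <- e1071::svm(x, factor(y, levels = c("0", "1")),
                      type = "C-classification", kernel = "radial",
                      cost = config@cost, gamma = config@gamma,
                      tolerance = config@tolerance, scale = FALSE)
    methods::new("TrainedSVM", fit = fit, toolNames = colnames(x),
                 nSV = as.integer(fit$tot.nSV),
                 trainSize = as.integer(nrow(x)))
}

#' Decision scores of a trained SVM
#'
#' Returns the signed decision value per protein, oriented so that positive
#' scores favour the mitochondrial class.
#'
#' @param model a \linkS4class{TrainedSVM}.
#' @param x a \linkS4class{FeatureSet} or numeric matrix whose columns match
#'   the model's training columns in name and order (a mismatch is a hard
#'   error).
#' @return Named numeric vector of decision values.
#' @export
decisionScores <- function(model, x) {
    if (methods::is(x, "FeatureSet")) x <- featureMatrix(x)
    if (!identical(colnames(x), model@toolNames))
        stop("feature columns do not match the model's training columns ",
             "(need: ", paste(model@toolNames, collapse = ", "), ")")
    if (anyNA(x))
        stop("features contain missing values; impute first")
    pred <- stats::predict(model@fit, x, decision.values = TRUE)
    dv <- attr(pred, "decision.values")
    # libsvm orients decision values towards the first label it saw in
    # training; the column name "A/B" records that orientation
    first <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1L]][1L]
    out <- if (identical(first, "1")) dv[, 1L] else -dv[, 1L]
    stats::setNames(out, rownames(x))
}

#' Predict class labels with a trained SVM
#'
#' A protein is called mitochondrial (1) iff its decision score is strictly
#' positive; a score of exactly 0 yields the negative class (fixed
#' tie-break). Predictions are row-wise independent.
#'
#' @inheritParams decisionScores
#' @return Named integer vector of 0/1 labels.
#' @export
predictSVM <- function(model, x) {
    dv <- decisionScores(model, x)
    stats::setNames(.labelFromScore(dv), names(dv))
}

# fixed convention: strictly positive score => mitochondrial; 0 => negative
.labelFromScore <- function(dv) as.integer(dv > 0)

#' Support-vector overfitting gate
#'
#' A model with many support vectors relative to its training set is closely
#' tailored to that set and generalizes poorly; a common rule of thumb
#' flags models whose support vectors reach 10\% of the training examples.
#'
#' @param object a \linkS4class{TrainedSVM}.
#' @param limit fraction in (0, 1].
#' @param ... unused.
#' @return \code{TRUE} iff \code{nSV / trainSize < limit}.
#' @rdname svGate
#' @export
setMethod("svGate", "TrainedSVM", function(object, limit = 0.1, ...) {
    if (length(limit) != 1L || is.na(limit) || limit <= 0 || limit > 1)
        stop("'limit' must be in (0, 1]")
    object@nSV / object@trainSize < limit
})

setMethod("show", "TrainedSVM", function(object) {
    cat(sprintf("TrainedSVM: %d features, %d training examples, %d support vectors (%.1f%%)\n",
                length(object@toolNames), object@trainSize, object@nSV,
                100 * object@nSV / object@trainSize))
    invisible(NULL)
})
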