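#' Construct a FeatureSet
#'
#' @param score numeric matrix of tool outputs in \code{[0, 1]} (or
#'   \code{NA} for no call), with prediction tools as rows and proteins as
#'   columns; both dimnames are required and must be unique.
#' @param label integer (or coercible) vector of per-protein class labels,
#'   one per column of \code{score}: 1 = mitochondrial, 0 = non-mitochondrial.
#' @return A \linkS4class{FeatureSet}.
#' @examples
#' sc <- rbind(TargetP = c(0.9, 0.1, 0.8), Pfam = c(1, 0, 0))
#' colnames(sc) <- c("P1", "P2", "P3")
#' fs <- FeatureSet(sc, label = c(1, 0, 1))
#' featureMatrix(fs)
#' @export
FeatureSet <- function(score, label) {
    if (!is.matrix(score)) score <- as.matrix(score)
    storage.mode(score) <- "double"
    if (length(label) != ncol(score))
        stop("'label' must have one entry per protein (column of 'score')")
    lab <- as.integer(label)
    obj <- methods::new("FeatureSet",
        SummarizedExperiment::SummarizedExperiment(
            assays = list(score = score),
            colData = S4Vectors::DataFrame(label = lab,
                                           row.names = colnames(score))))
    methods::validObject(obj)
    obj
}

#' @rdname mitoCombine-generics
#' @export
setMethod("toolNames", "FeatureSet", function(x) rownames(x))

#' @rdname mitoCombine-generics
#' @export
setMethod("proteinIds", "FeatureSet", function(x) colnames(x))

#' @rdname mitoCombine-generics
#' @export
setMethod("proteinLabels", "FeatureSet", function(x) {
    stats::setNames(SummarizedExperiment::colData(x)$label, colnames(x))
})

# proteins x tools orientation, as fed to the SVM
#' @rdname mitoCombine-generics
#' @export
setMethod("featureMatrix", "FeatureSet", function(x) {
    t(SummarizedExperiment::assay(x, "score"))
})

#' @rdname mitoCombine-generics
#' @export
setMethod("isMissing", "FeatureSet", function(x) {
    is.na(SummarizedExperiment::assay(x, "score"))
})

#' @rdname mitoCombine-generics
#' @export
setMethod("nTools", "FeatureSet", function(x) nrow(x))

#' @rdname mitoCombine-generics
#' @export
setMethod("nProteins", "FeatureSet", function(x) ncol(x))

#' Replace missing tool calls by a constant
#'
#' Tools with limited coverage make no call for many proteins; before SVM
#' training every cell must hold a value. Missing cells are replaced by
#' \code{fill} (default 0, the no-evidence point of the \code{[0, 1]} scale);
#' observed cells are untouched.
#'
#' @param x a \linkS4class{FeatureSet}.
#' @param fill replacement value in \code{[0, 1]}.
#' @return A \linkS4class{FeatureSet} with no missing cells.
#' @rdname imputeMissing
#' @export
setMethod("imputeMissing", "FeatureSet", function(x, fill = 0) {
    if (length(fill) != 1L || is.na(fill) || fill < 0 || fill > 1)
        stop("'fill' must be a single value in [0, 1]")
    sc <- SummarizedExperiment::assay(x, "score")
    sc[is.na(sc)] <- fill
    SummarizedExperiment::assay(x, "score") <- sc
    x
})

setMethod("show", "FeatureSet", function(object) {
    lab <- SummarizedExperiment::colData(object)$label
    miss <- mean(is.na(SummarizedExperiment::assay(object, "score")))
    cat(sprintf("FeatureSet: %d tools x %d proteins (%d mitochondrial, %d non-mitochondrial)\n",
                nrow(object), ncol(object), sum(lab == 1L), sum(lab == 0L)))
    cat("tools:", paste(utils::head(rownames(object), 11L), collapse = ", "),
        if (nrow(object) > 11L) "..." else "", "\n")
    cat(sprintf("missing cells: %.1f%%\n", 100 * miss))
    invisible(NULL)
})
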