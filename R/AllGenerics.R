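#' @name mitoCombine-generics
#' @title Generics for FeatureSet accessors and pipeline verbs
#' @description Accessor and verb generics; see the methods for
#'   \linkS4class{FeatureSet} and \linkS4class{TrainedSVM}.
#' @param x,object a \linkS4class{FeatureSet} (or, for \code{svGate}, a
#'   \linkS4class{TrainedSVM}).
#' @param ... passed to methods.
#' @return See individual methods.
NULL

#' @rdname mitoCombine-generics
#' @export
setGeneric("toolNames", function(x) standardGeneric("toolNames"))

#' @rdname mitoCombine-generics
#' @export
setGeneric("proteinIds", function(x) standardGeneric("proteinIds"))

#' @rdname mitoCombine-generics
#' @export
setGeneric("proteinLabels", function(x) standardGeneric("proteinLabels"))

#' @rdname mitoCombine-generics
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname mitoCombine-generics
#' @export
setGeneric("isMissing", function(x) standardGeneric("isMissing"))

#' @rdname mitoCombine-generics
#' @export
setGeneric("nTools", function(x) standardGeneric("nTools"))

#' @rdname mitoCombine-generics
#' @export
setGeneric("nProteins", function(x) standardGeneric("nProteins"))

#' @rdname mitoCombine-generics
#' @export
setGeneric("imputeMissing",
           function(x, ...) standardGeneric("imputeMissing"))

#' @rdname mitoCombine-generics
#' @export
setGeneric("generateDataset",
           function(config, ...) standardGeneric("generateDataset"))

#' @rdname mitoCombine-generics
#' @export
setGeneric("svGate", function(object, ...) standardGeneric("svGate"))
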