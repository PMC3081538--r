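#' Read a labelled feature table from TSV
#'
#' The expected dialect is tab-separated UTF-8 text with no quoting, a '.'
#' decimal separator and a header line \code{id<TAB>label<TAB><tool1>...}.
#' The label column must contain only 0/1; tool columns hold decimal values
#' in \code{[0, 1]} or \code{missingToken}. The reader validates rather than
#' coerces: a duplicate protein id, a non-binary label, an unparseable cell
#' or a value outside \code{[0, 1]} is a hard error naming the offending
#' row/column.
#'
#' @param path path to a TSV file.
#' @param missingToken string marking a cell where the tool made no call.
#' @return A \linkS4class{FeatureSet}.
#' @seealso \code{\link{writeFeatureTable}} for the exact inverse.
#' @export
readFeatureTable <- function(path, missingToken = "NA") {
    if (!file.exists(path)) stop("file not found: ", path)
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            colClasses = "character", na.strings = NULL,
                            quote = "", encoding = "UTF-8")
    if (ncol(dt) < 3L)
        stop("feature table needs at least columns: id, label, one tool")
    ids <- dt[[1L]]
    if (anyDuplicated(ids))
        stop(sprintf("duplicate protein id: '%s'", ids[duplicated(ids)][1L]))
    labChr <- dt[[2L]]
    badLab <- !labChr %in% c("0", "1")
    if (any(badLab))
        stop(sprintf("non-binary label '%s' at row %d",
                     labChr[badLab][1L], which(badLab)[1L]))
    tools <- names(dt)[-(1:2)]
    score <- matrix(NA_real_, nrow = length(tools), ncol = length(ids),
                    dimnames = list(tools, ids))
    for (j in seq_along(tools)) {
        v <- dt[[j + 2L]]
        miss <- v == missingToken
        num <- suppressWarnings(as.numeric(v))
        badParse <- !miss & is.na(num)
        if (any(badParse))
            stop(sprintf("unparseable value '%s' at row %d, column '%s'",
                         v[badParse][1L], which(badParse)[1L], tools[j]))
        badRange <- !miss & (num < 0 | num > 1)
        if (any(badRange))
            stop(sprintf("value %s outside [0, 1] at row %d, column '%s'",
                         v[badRange][1L], which(badRange)[1L], tools[j]))
        num[miss] <- NA_real_
        score[j, ] <- num
    }
    FeatureSet(score, as.integer(labChr))
}

#' Write a feature table to TSV
#'
#' Inverse of \code{\link{readFeatureTable}}: writes the header
#' \code{id<TAB>label<TAB><tools>} followed by one row per protein. Values
#' are rendered with the shortest decimal representation that parses back to
#' the identical double, so write-then-read round trips are bit-exact;
#' missing cells are serialized as \code{missingToken}. Column order is
#' preserved.
#'
#' @param x a valid \linkS4class{FeatureSet}.
#' @param path output path; an unwritable path is a hard error.
#' @param missingToken string used for missing cells.
#' @return Invisibly, \code{path}.
#' @export
writeFeatureTable <- function(x, path, missingToken = "NA") {
    methods::validObject(x)
    sc <- SummarizedExperiment::assay(x, "score")
    cols <- c(list(id = colnames(x),
                   label = as.character(proteinLabels(x))),
              stats::setNames(lapply(seq_len(nrow(sc)), function(j) {
                  s <- formatExact(sc[j, ])
                  s[is.na(sc[j, ])] <- missingToken
                  s
              }), rownames(sc)))
    dt <- data.table::as.data.table(cols)
    data.table::fwrite(dt, path, sep = "\t", quote = FALSE, na = missingToken)
    invisible(path)
}
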