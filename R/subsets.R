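# Tool subsets are plain integer bitmasks: bit i-1 set <=> tool i included.

#' Enumerate all non-empty tool subsets
#'
#' Returns the \code{2^nTools - 1} non-empty subsets of \code{nTools}
#' prediction tools as integer bitmasks, ordered by subset size then mask.
#' Eleven tools give the 2047 combinations of the exhaustive sweep.
#'
#' @param nTools number of tools, between 1 and 24 (the guard keeps the
#'   enumeration in memory-safe territory).
#' @return Integer vector of bitmasks.
#' @examples
#' length(enumerateSubsets(11))  # 2047
#' @export
enumerateSubsets <- function(nTools) {
    if (length(nTools) != 1L || is.na(nTools) || nTools < 1 || nTools > 24)
        stop("'nTools' must be a single integer in [1, 24]")
    nTools <- as.integer(nTools)
    masks <- seq_len(2L^nTools - 1L)
    masks[order(maskSize(masks), masks)]
}

#' Size of a tool subset
#'
#' @param mask integer bitmask(s).
#' @return Integer popcount(s).
#' @export
maskSize <- function(mask) {
    sz <- integer(length(mask))
    m <- as.integer(mask)
    while (any(m > 0L)) {
        sz <- sz + (m %% 2L)
        m <- m %/% 2L
    }
    sz
}

#' Tools included in a subset
#'
#' @param mask a single non-zero integer bitmask, \code{mask < 2^length(toolNames)}.
#' @param toolNames ordered character vector of tool names.
#' @return Character vector of the included tool names, in roster order.
#' @export
maskToTools <- function(mask, toolNames) {
    if (length(mask) != 1L || is.na(mask) || mask < 1 ||
        mask > 2^length(toolNames) - 1)
        stop("'mask' must be a single bitmask in [1, 2^nTools - 1]")
    toolNames[bitwAnd(as.integer(mask), bitwShiftL(1L, seq_along(toolNames) - 1L)) > 0L]
}

#' Bitmask for a set of tools
#'
#' @param tools character vector of tool names (non-empty, no duplicates).
#' @param toolNames ordered roster of all tool names.
#' @return Integer bitmask.
#' @export
toolsToMask <- function(tools, toolNames) {
    idx <- match(tools, toolNames)
    if (anyNA(idx))
        stop("unknown tool(s): ", paste(tools[is.na(idx)], collapse = ", "))
    if (length(idx) < 1L) stop("a subset must contain at least one tool")
    if (anyDuplicated(idx)) stop("duplicate tools in subset")
    as.integer(sum(2^(idx - 1)))
}
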