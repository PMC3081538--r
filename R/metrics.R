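#' Confusion counts for binary predictions
#'
#' @param truth,predicted 0/1 vectors of equal length (1 = mitochondrial).
#' @return Named integer vector with elements \code{tp}, \code{fp},
#'   \code{tn}, \code{fn}.
#' @export
confusionCounts <- function(truth, predicted) {
    if (length(truth) != length(predicted))
        stop("'truth' and 'predicted' must have equal length")
    t <- as.integer(truth); p <- as.integer(predicted)
    if (anyNA(t) || anyNA(p) || !all(t %in% 0:1) || !all(p %in% 0:1))
        stop("labels must be 0 or 1")
    c(tp = sum(t == 1L & p == 1L), fp = sum(t == 0L & p == 1L),
      tn = sum(t == 0L & p == 0L), fn = sum(t == 1L & p == 0L))
}

.counts <- function(counts) {
    counts <- unlist(counts)
    if (!all(c("tp", "fp", "tn", "fn") %in% names(counts)))
        stop("counts must contain tp, fp, tn, fn")
    if (any(counts[c("tp", "fp", "tn", "fn")] < 0))
        stop("counts must be non-negative")
    counts
}

#' Sensitivity (recall of mitochondrial proteins)
#'
#' \code{TP / (TP + FN)}.
#'
#' @param counts named vector or list with \code{tp}, \code{fp}, \code{tn},
#'   \code{fn} (see \code{\link{confusionCounts}}).
#' @return A value in \code{[0, 1]}.
#' @export
sensitivity <- function(counts) {
    counts <- .counts(counts)
    d <- counts[["tp"]] + counts[["fn"]]
    if (d == 0) stop("sensitivity undefined: no positives in the test set")
    counts[["tp"]] / d
}

#' Specificity (recall of non-mitochondrial proteins)
#'
#' \code{TN / (TN + FP)}.
#'
#' @inheritParams sensitivity
#' @return A value in \code{[0, 1]}.
#' @export
specificity <- function(counts) {
    counts <- .counts(counts)
    d <- counts[["tn"]] + counts[["fp"]]
    if (d == 0) stop("specificity undefined: no negatives in the test set")
    counts[["tn"]] / d
}

#' False discovery rate
#'
#' \code{FP / (FP + TP)}, the fraction of positive predictions that are
#' wrong; defined as 0 when there are no positive predictions (convention,
#' so that aggregates over many resampling runs are never poisoned).
#'
#' @inheritParams sensitivity
#' @return A value in \code{[0, 1]}.
#' @export
fdr <- function(counts) {
    counts <- .counts(counts)
    d <- counts[["fp"]] + counts[["tp"]]
    if (d == 0) return(0)
    counts[["fp"]] / d
}

#' Corrected false discovery rate (cFDR)
#'
#' The FDR observed on a test set reflects that set's class balance. When
#' the evaluation set is far richer in mitochondrial proteins than the
#' genome (roughly 1500 mitochondrial of 21,000 nuclear genes), the raw FDR
#' understates the genome-wide error. The corrected FDR rescales to the
#' genome prior:
#' \deqn{cFDR = (1 - spec) / ((1 - spec) + sens \cdot \pi)}
#' with \eqn{\pi} the prior fraction of mitochondrial genes (default
#' 1500/21000). When specificity is 1 and sensitivity 0 the ratio is 0/0;
#' it is defined as 0 (no false positives are made).
#'
#' @param sens,spec sensitivity and specificity in \code{[0, 1]}.
#' @param priorFraction prior fraction in (0, 1).
#' @return A value in \code{[0, 1]}.
#' @examples
#' cfdr(0.64, 0.99)  # ~0.179
#' @export
cfdr <- function(sens, spec, priorFraction = 1500 / 21000) {
    if (any(sens < 0 | sens > 1) || any(spec < 0 | spec > 1))
        stop("'sens' and 'spec' must lie in [0, 1]")
    if (any(priorFraction <= 0 | priorFraction >= 1))
        stop("'priorFraction' must lie in (0, 1)")
    num <- 1 - spec
    den <- num + sens * priorFraction
    ifelse(den == 0, 0, num / den)
}

#' Mean and sample standard deviation of run-level values
#'
#' @param values numeric vector of at least one value; the SD uses the
#'   n - 1 denominator (run values are a sample from the resampling
#'   distribution) and is \code{NA} for a single value.
#' @return Named numeric vector \code{c(mean = , sd = )}.
#' @export
aggregateRuns <- function(values) {
    if (length(values) < 1L) stop("'values' must contain at least one value")
    c(mean = mean(values),
      sd = if (length(values) >= 2L) stats::sd(values) else NA_real_)
}

#' Welch-type z comparison of two run-level means
#'
#' Compares the mean of a metric over two sets of resampling runs with a
#' two-sided Gaussian z test using the Welch standard error
#' \eqn{\sqrt{sd_1^2/n_1 + sd_2^2/n_2}}.
#'
#' @param mean1,sd1,n1 summary of group 1 (n1 >= 2).
#' @param mean2,sd2,n2 summary of group 2 (n2 >= 2).
#' @return List with \code{difference} (mean1 - mean2), \code{z} and the
#'   two-sided \code{p}. Two identical degenerate groups (both SDs zero,
#'   equal means) are a hard error; zero SEs with distinct means give
#'   \code{z = +/-Inf}, \code{p = 0}.
#' @examples
#' welchZ(64.14, 5.22, 100, 52.51, 5.80, 100)  # z ~ 14.9
#' @export
welchZ <- function(mean1, sd1, n1, mean2, sd2, n2) {
    if (n1 < 2L || n2 < 2L) stop("both groups need n >= 2")
    if (sd1 < 0 || sd2 < 0) stop("standard deviations must be >= 0")
    diff <- mean1 - mean2
    se <- sqrt(sd1^2 / n1 + sd2^2 / n2)
    if (se == 0) {
        if (diff == 0)
            stop("z undefined: both groups degenerate and equal")
        return(list(difference = diff, z = sign(diff) * Inf, p = 0))
    }
    z <- diff / se
    list(difference = diff, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Gaussian confidence-interval half-width
#'
#' Half-width of a two-sided Gaussian interval for a quantity with the given
#' standard deviation; with the typical run-to-run SD of ~5 percentage
#' points seen in repeated SVM evaluations, the 95\% half-width rounds to
#' 10 points.
#'
#' @param sd standard deviation.
#' @param level confidence level (default 0.95).
#' @return \code{qnorm(1 - (1 - level)/2) * sd}.
#' @export
ciHalfWidth <- function(sd, level = 0.95) {
    if (level <= 0 || level >= 1) stop("'level' must lie in (0, 1)")
    stats::qnorm(1 - (1 - level) / 2) * sd
}
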