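#' Describe synthetic prediction tools
#'
#' Builds the \code{profiles} data.frame consumed by
#' \code{\link{scenarioConfig}}. Each profile describes one tool by the
#' marginal behaviour of its binary core call: \code{tpr} is the probability
#' that a mitochondrial protein receives a positive call, \code{fpr} the
#' same for a non-mitochondrial protein, \code{coverage} the probability the
#' tool returns any call at all (uncovered cells are missing), \code{group}
#' an optional correlation-group id shared by tools that rest on the same
#' underlying evidence, and \code{noiseSd} the standard deviation of
#' Gaussian jitter added to the core call (scores are clamped to
#' \code{[0, 1]}), which turns a hit/no-hit tool into a continuous scorer.
#'
#' Arguments are recycled to the length of \code{name}.
#'
#' @param name character, unique tool names.
#' @param tpr,fpr,coverage numerics in \code{[0, 1]}.
#' @param group character correlation-group ids, \code{NA} for none.
#' @param noiseSd numeric >= 0.
#' @param role free-text tag (e.g. \code{"strong"}, \code{"detrimental"});
#'   carried through for bookkeeping only.
#' @return A data.frame, one row per tool.
#' @export
predictorProfiles <- function(name, tpr, fpr, coverage = 1,
                              group = NA_character_, noiseSd = 0,
                              role = "custom") {
    n <- length(name)
    data.frame(name = as.character(name),
               tpr = rep_len(tpr, n), fpr = rep_len(fpr, n),
               coverage = rep_len(coverage, n),
               group = rep_len(as.character(group), n),
               noiseSd = rep_len(noiseSd, n),
               role = rep_len(role, n),
               stringsAsFactors = FALSE)
}

#' Construct a ScenarioConfig
#'
#' @param profiles data.frame from \code{\link{predictorProfiles}} (rows may
#'   be concatenated with \code{rbind}).
#' @param nPos,nNeg class sizes; defaults are the 467 mitochondrial / 6352
#'   non-mitochondrial composition of the study this generator emulates.
#' @param latentStrength probability in \code{[0, 1]} that tools sharing a
#'   correlation group use one shared draw for a given protein.
#' @param seed integer RNG seed.
#' @return A \linkS4class{ScenarioConfig}.
#' @export
scenarioConfig <- function(profiles, nPos = 467L, nNeg = 6352L,
                           latentStrength = 0.5, seed = 1L) {
    obj <- methods::new("ScenarioConfig", profiles = profiles,
                        nPos = as.integer(nPos), nNeg = as.integer(nNeg),
                        latentStrength = as.numeric(latentStrength),
                        seed = as.integer(seed))
    methods::validObject(obj)
    obj
}

setMethod("show", "ScenarioConfig", function(object) {
    cat(sprintf("ScenarioConfig: %d tools, %d positive / %d negative proteins, seed %d\n",
                nrow(object@profiles), object@nPos, object@nNeg, object@seed))
    print(object@profiles, row.names = FALSE)
    invisible(NULL)
})

#' Generate a synthetic labelled feature table
#'
#' Draws a \linkS4class{FeatureSet} from a \linkS4class{ScenarioConfig}.
#' For every protein and tool, independently: with probability
#' \code{1 - coverage} the cell is missing; otherwise a binary core call is
#' drawn, 1 with probability \code{tpr} for mitochondrial proteins and
#' \code{fpr} for the rest. Tools sharing a correlation group are coupled:
#' for each protein, with probability \code{latentStrength} all tools in the
#' group derive their call from one shared uniform draw (each tool keeps its
#' own threshold, so marginal rates are unchanged while calls become
#' positively correlated). The recorded score is
#' \code{clamp(call + N(0, noiseSd), 0, 1)}.
#'
#' Draws follow a fixed documented order (group latents first, then tools in
#' profile order), so the same configuration yields a byte-identical table.
#'
#' @param config a \linkS4class{ScenarioConfig}.
#' @param ... unused.
#' @return A \linkS4class{FeatureSet} with \code{nPos + nNeg} proteins
#'   (positives first).
#' @rdname generateDataset
#' @export
setMethod("generateDataset", "ScenarioConfig", function(config, ...) {
    pr <- config@profiles
    n <- config@nPos + config@nNeg
    label <- c(rep(1L, config@nPos), rep(0L, config@nNeg))
    ids <- sprintf("prot%05d", seq_len(n))
    groups <- unique(pr$group[!is.na(pr$group)])
    withSeed(config@seed, {
        useShared <- matrix(stats::runif(n * length(groups)) <
                            config@latentStrength, nrow = n)
        sharedU <- matrix(stats::runif(n * length(groups)), nrow = n)
        score <- matrix(NA_real_, nrow = nrow(pr), ncol = n,
                        dimnames = list(pr$name, ids))
        for (j in seq_len(nrow(pr))) {
            p <- ifelse(label == 1L, pr$tpr[j], pr$fpr[j])
            u <- stats::runif(n)
            if (!is.na(pr$group[j])) {
                g <- match(pr$group[j], groups)
                u <- ifelse(useShared[, g], sharedU[, g], u)
            }
            call <- as.numeric(u < p)
            v <- call
            if (pr$noiseSd[j] > 0)
                v <- pmin(pmax(call + stats::rnorm(n, 0, pr$noiseSd[j]), 0), 1)
            if (pr$coverage[j] < 1)
                v[stats::runif(n) >= pr$coverage[j]] <- NA_real_
            score[j, ] <- v
        }
        FeatureSet(score, label)
    })
})

#' Packaged paradox scenario
#'
#' An eleven-tool scenario whose structure mirrors the predictor roster of
#' the mitochondrial-localization study this package evaluates: three strong
#' complementary tools (two of which share a Pfam-domain evidence base and
#' are therefore correlated), four moderate tools, and four detrimental
#' tools — low-coverage, near-random callers standing in for yeast homology,
#' PGC-1alpha induction, \emph{Rickettsia prowazekii} orthology and
#' coexpression evidence — whose inclusion degrades the combined SVM's
#' sensitivity. The exact rates are fixed choices of this package,
#' documented in the vignette; \code{nPos}/\code{nNeg} allow scaled-down
#' instances that keep the ~1:13.6 class imbalance.
#'
#' @param seed integer seed stored in the configuration.
#' @param nPos,nNeg class sizes (defaults 467 / 6352).
#' @return A \linkS4class{ScenarioConfig} with 11 profiles, of which exactly
#'   4 carry \code{role == "detrimental"}.
#' @export
paradoxScenario <- function(seed = 1L, nPos = 467L, nNeg = 6352L) {
    profiles <- rbind(
        predictorProfiles("MITODOMAIN",     0.60, 0.010, 1.00, "pfam", 0.02, "strong"),
        predictorProfiles("TargetP",        0.55, 0.010, 1.00, NA,     0.05, "strong"),
        predictorProfiles("MITOPRED",       0.65, 0.010, 1.00, "pfam", 0.05, "strong"),
        predictorProfiles("CisMotif",       0.30, 0.050, 0.90, NA,     0.00, "moderate"),
        predictorProfiles("MsMsTissue",     0.30, 0.050, 1.00, NA,     0.00, "moderate"),
        predictorProfiles("MitoProtII",     0.30, 0.050, 1.00, NA,     0.05, "moderate"),
        predictorProfiles("SubLoc",         0.30, 0.050, 1.00, NA,     0.05, "moderate"),
        predictorProfiles("YeastHomology",  0.08, 0.080, 0.30, NA,     0.00, "detrimental"),
        predictorProfiles("Induction",      0.06, 0.060, 0.25, NA,     0.00, "detrimental"),
        predictorProfiles("RickettsiaOrth", 0.05, 0.050, 0.20, NA,     0.00, "detrimental"),
        predictorProfiles("Coexpression",   0.10, 0.100, 0.30, NA,     0.00, "detrimental"))
    scenarioConfig(profiles, nPos = nPos, nNeg = nNeg,
                   latentStrength = 0.4, seed = seed)
}
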