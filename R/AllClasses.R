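#' @import SummarizedExperiment
#' @import S4Vectors
NULL

## ---------------------------------------------------------------- census ----

#' AbundanceCensus: a proteome-by-domain abundance census
#'
#' Container for a genomic census of protein domain structure: non-negative
#' integer counts of each domain type (e.g. a SCOP fold superfamily such as
#' `"c.37.1"`) in each proteome. Extends
#' [SummarizedExperiment::SummarizedExperiment] with domains as rows
#' (features) and proteomes as columns (samples); the superkingdom of each
#' proteome, when known, lives in `colData(x)$superkingdom`. On disk the
#' census is a TSV with proteomes as rows (see [readCensusTable()]); the
#' constructor and accessors hide the transposition.
#'
#' @param counts integer matrix of abundances, domains x proteomes, with
#'   dimnames (domain ids as rownames, proteome ids as colnames).
#' @param superkingdoms optional named character vector mapping proteome id
#'   to one of `"Archaea"`, `"Bacteria"`, `"Eukarya"`.
#' @return An `AbundanceCensus` object.
#' @examples
#' cn <- matrix(c(0L, 3L, 12L, 1L), 2, 2,
#'              dimnames = list(c("c.37.1", "d.58.7"), c("A01", "B01")))
#' census <- AbundanceCensus(cn, c(A01 = "Archaea", B01 = "Bacteria"))
#' gmax(census)
#' @seealso [censusCounts()], [gmax()], [encodeCensus()]
#' @export
AbundanceCensus <- function(counts, superkingdoms = NULL) {
    if (!is.matrix(counts))
        counts <- as.matrix(counts)
    storage.mode(counts) <- "integer"
    cd <- S4Vectors::DataFrame(row.names = colnames(counts))
    if (!is.null(superkingdoms)) {
        if (is.data.frame(superkingdoms))
            superkingdoms <- setNames(as.character(superkingdoms[[2L]]),
                                      as.character(superkingdoms[[1L]]))
        missing <- setdiff(colnames(counts), names(superkingdoms))
        if (length(missing))
            stop("no superkingdom mapping for proteome(s): ",
                 paste(missing, collapse = ", "))
        cd$superkingdom <- unname(superkingdoms[colnames(counts)])
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), colData = cd)
    new("AbundanceCensus", se)
}

#' @rdname AbundanceCensus
#' @aliases AbundanceCensus-class
#' @export
setClass("AbundanceCensus", contains = "SummarizedExperiment")

setValidity("AbundanceCensus", function(object) {
    cn <- SummarizedExperiment::assay(object, "counts")
    if (anyNA(cn)) return("census contains NA counts")
    if (length(cn) && any(cn < 0)) return("census contains negative counts")
    if (is.null(rownames(object)) && nrow(object) > 0)
        return("domain ids (rownames) are required")
    if (is.null(colnames(object)) && ncol(object) > 0)
        return("proteome ids (colnames) are required")
    if (anyDuplicated(rownames(object))) return("duplicate domain ids")
    if (anyDuplicated(colnames(object))) return("duplicate proteome ids")
    TRUE
})

#' Accessors for AbundanceCensus objects
#'
#' `censusCounts()` returns the raw count matrix in either orientation;
#' `gmax()` the matrix-wide maximum abundance (the heat-map colour-scale
#' maximum, the paper-style `N`); `proteomeIds()` / `domainIds()` the taxon
#' and character labels; `superkingdoms()` the proteome to superkingdom map
#' (or `NULL` when unset).
#'
#' @param x an `AbundanceCensus`.
#' @param orientation `"proteomes"` for a proteome x domain matrix (the
#'   on-disk layout), `"domains"` for the internal domains x proteomes
#'   layout.
#' @return `censusCounts()`: an integer matrix; `gmax()`: a single integer;
#'   the id accessors: character vectors.
#' @name census-accessors
NULL

#' @rdname census-accessors
#' @export
censusCounts <- function(x, orientation = c("proteomes", "domains")) {
    orientation <- match.arg(orientation)
    cn <- SummarizedExperiment::assay(x, "counts")
    if (orientation == "proteomes") t(cn) else cn
}

#' @rdname census-accessors
#' @export
setGeneric("gmax", function(x) standardGeneric("gmax"))

#' @rdname census-accessors
#' @export
setMethod("gmax", "AbundanceCensus", function(x) {
    cn <- SummarizedExperiment::assay(x, "counts")
    if (!length(cn)) 0L else max(cn)
})

#' @rdname census-accessors
#' @export
proteomeIds <- function(x) colnames(x)

#' @rdname census-accessors
#' @export
domainIds <- function(x) rownames(x)

#' @rdname census-accessors
#' @export
superkingdoms <- function(x) {
    cd <- SummarizedExperiment::colData(x)
    if (!"superkingdom" %in% colnames(cd)) return(NULL)
    setNames(as.character(cd$superkingdom), rownames(cd))
}

setMethod("show", "AbundanceCensus", function(object) {
    cat(sprintf("AbundanceCensus: %d domains x %d proteomes, gmax = %d\n",
                nrow(object), ncol(object), gmax(object)))
    sk <- superkingdoms(object)
    if (!is.null(sk)) {
        tb <- table(sk)
        cat("  superkingdoms:",
            paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
    }
})

## ----------------------------------------------------------- coded matrix ----

#' CodedMatrix: an abundance census coded as ordered multistate characters
#'
#' Holds the character-state matrix produced by [encodeCensus()]: integer
#' states `0..23` written with the alphanumeric alphabet `0-9`, `A-N`.
#' Orientation `"ToL"` has proteomes as rows (taxa) and domains as columns
#' (characters); `"ToD"` is the transpose. `t()` flips the orientation.
#'
#' @slot states integer matrix of states in `0..23`, with dimnames.
#' @slot orientation `"ToL"` or `"ToD"`.
#' @slot scheme coding scheme used, `"log"` or `"linear"` (or `NA` when
#'   read from a character-matrix file).
#' @slot gmax matrix-wide maximum abundance of the source census (`NA` when
#'   unknown); needed to decode states back to abundances.
#' @export
setClass("CodedMatrix",
         representation(states = "matrix", orientation = "character",
                        scheme = "character", gmax = "numeric"))

setValidity("CodedMatrix", function(object) {
    st <- object@states
    if (!is.integer(st)) return("states must be an integer matrix")
    if (anyNA(st)) return("states contain NA")
    if (length(st) && (min(st) < 0L || max(st) > 23L))
        return("states must lie in 0..23")
    if (!object@orientation %in% c("ToL", "ToD"))
        return("orientation must be 'ToL' or 'ToD'")
    TRUE
})

#' Construct a CodedMatrix
#'
#' Usually produced by [encodeCensus()] or [readCharacterMatrix()]; the
#' constructor is exported for building small matrices directly in analyses
#' and tests.
#'
#' @param states integer matrix of states `0..23` with dimnames
#'   (rows = taxa).
#' @param orientation `"ToL"` (taxa are proteomes) or `"ToD"` (taxa are
#'   domains).
#' @param scheme,gmax coding provenance; see the class slots.
#' @return A [CodedMatrix-class] object.
#' @export
CodedMatrix <- function(states, orientation = c("ToL", "ToD"),
                        scheme = NA_character_, gmax = NA_real_) {
    orientation <- match.arg(orientation)
    storage.mode(states) <- "integer"
    new("CodedMatrix", states = states, orientation = orientation,
        scheme = scheme, gmax = as.numeric(gmax))
}

#' @describeIn CodedMatrix the raw integer state matrix (rows = taxa).
#' @param m a `CodedMatrix`.
#' @export
codedStates <- function(m) m@states

#' @describeIn CodedMatrix the orientation flag (`"ToL"` or `"ToD"`).
#' @export
orientation <- function(m) m@orientation

#' @describeIn CodedMatrix taxon labels (row names).
#' @export
taxonIds <- function(m) rownames(m@states)

#' @describeIn CodedMatrix character labels (column names).
#' @export
characterIds <- function(m) colnames(m@states)

setMethod("show", "CodedMatrix", function(object) {
    cat(sprintf(
        "CodedMatrix (%s): %d taxa x %d characters, scheme = %s, gmax = %s\n",
        object@orientation, nrow(object@states), ncol(object@states),
        object@scheme, format(object@gmax)))
})

## ------------------------------------------------------------- simulation ----

#' SimParams: parameters of the synthetic census generator
#'
#' See [simulateCensus()] for the generative model. Defaults describe a
#' small but structurally faithful census: three superkingdom clades of 5
#' proteomes each arising from a stem line, 50 domain types born
#' semi-punctuately along a 100-step timeline, per-copy Bernoulli
#' duplication, and complete-loss risk that decays geometrically with copy
#' number so that loss concentrates soon after a domain's origin.
#'
#' @param nProteomes integer(3): terminal proteomes per superkingdom, in the
#'   order Archaea, Bacteria, Eukarya.
#' @param nFsf total number of domain (fold-superfamily) types to be born.
#' @param tSteps length of the discrete timeline.
#' @param birthRate expected new domain types per step (intensity of the
#'   birth process; births are placed along the timeline with burst-prone
#'   weights, conditioned on `nFsf` total).
#' @param dupRate per-copy per-step duplication probability.
#' @param lossBase per-lineage per-step probability of complete loss for a
#'   domain with exactly one copy.
#' @param lossDecay multiplicative decay of the loss probability per
#'   additional copy: `P(loss | n copies) = lossBase * lossDecay^(n-1)`.
#' @param splitTimes integer(2), strictly increasing and `< tSteps`: the
#'   step at which the stem line spawns the Archaea lineage, then the step
#'   at which it splits into the Bacteria and Eukarya lineages.
#' @param seed random seed; identical `SimParams` give bit-identical output.
#' @return A `SimParams` object.
#' @export
SimParams <- function(nProteomes = c(5L, 5L, 5L), nFsf = 50L, tSteps = 100L,
                      birthRate = 0.5, dupRate = 0.1, lossBase = 0.02,
                      lossDecay = 0.3, splitTimes = c(24L, 26L), seed = 1L) {
    new("SimParams",
        nProteomes = vapply(nProteomes, .assertCount, 0L, field = "nProteomes"),
        nFsf = .assertCount(nFsf, "nFsf"),
        tSteps = .assertCount(tSteps, "tSteps"),
        birthRate = as.numeric(birthRate),
        dupRate = .assertRate(dupRate, "dupRate"),
        lossBase = .assertRate(lossBase, "lossBase"),
        lossDecay = .assertRate(lossDecay, "lossDecay"),
        splitTimes = as.integer(splitTimes),
        seed = .assertCount(seed, "seed"))
}

#' @rdname SimParams
#' @export
setClass("SimParams",
         representation(nProteomes = "integer", nFsf = "integer",
                        tSteps = "integer", birthRate = "numeric",
                        dupRate = "numeric", lossBase = "numeric",
                        lossDecay = "numeric", splitTimes = "integer",
                        seed = "integer"))

setValidity("SimParams", function(object) {
    if (length(object@nProteomes) != 3L || any(object@nProteomes < 1L))
        return("nProteomes must give >= 1 proteome for each of the 3 superkingdoms")
    if (object@birthRate < 0) return("birthRate must be >= 0")
    if (length(object@splitTimes) != 2L) return("splitTimes must have length 2")
    if (object@splitTimes[1L] >= object@splitTimes[2L])
        return("splitTimes must be strictly increasing")
    if (object@splitTimes[1L] < 1L || object@splitTimes[2L] >= object@tSteps)
        return("splitTimes must lie within 1..(tSteps-1)")
    TRUE
})

setMethod("show", "SimParams", function(object) {
    cat(sprintf(
        paste0("SimParams: %d+%d+%d proteomes (A/B/E), %d domain types, ",
               "%d steps\n  dup = %.3g, loss = %.3g x %.3g^(n-1), ",
               "splits at %d and %d, seed = %d\n"),
        object@nProteomes[1L], object@nProteomes[2L], object@nProteomes[3L],
        object@nFsf, object@tSteps, object@dupRate, object@lossBase,
        object@lossDecay, object@splitTimes[1L], object@splitTimes[2L],
        object@seed))
})

#' SyntheticTruth: ground truth recorded by the census generator
#'
#' @slot birthTime named integer, birth step of every domain that was born
#'   (including domains later lost everywhere and hence absent from the
#'   census).
#' @slot tree the true organismal lineage tree (`ape::phylo`, tip labels =
#'   proteome ids, branch lengths in timeline steps).
#' @slot lossEvents data.frame with columns `domain`, `lineage`, `step`:
#'   every complete-loss event.
#' @slot rootRepertoire character: domains present in the stem line at the
#'   moment the first lineage (Archaea) split away — the true urancestral
#'   repertoire.
#' @slot everPresent logical matrix (domains x superkingdoms): whether the
#'   domain was ever present on a lineage belonging to each superkingdom's
#'   clade (clade-ancestor segments included).
#' @slot params the `SimParams` used.
#' @export
setClass("SyntheticTruth",
         representation(birthTime = "integer", tree = "ANY",
                        lossEvents = "data.frame", rootRepertoire = "character",
                        everPresent = "matrix", params = "SimParams"))

setValidity("SyntheticTruth", function(object) {
    le <- object@lossEvents
    if (nrow(le)) {
        if (!all(c("domain", "lineage", "step") %in% colnames(le)))
            return("lossEvents needs columns domain, lineage, step")
        bt <- object@birthTime[le$domain]
        if (anyNA(bt)) return("loss event for a domain without a birth time")
        if (any(le$step < bt)) return("loss event predates the domain's birth")
    }
    TRUE
})

setMethod("show", "SyntheticTruth", function(object) {
    cat(sprintf(
        "SyntheticTruth: %d domains born, %d loss events, root repertoire %d domains\n",
        length(object@birthTime), nrow(object@lossEvents),
        length(object@rootRepertoire)))
})

#' @describeIn SyntheticTruth-class named integer vector of birth steps.
#' @param truth a `SyntheticTruth`.
#' @export
birthTimes <- function(truth) truth@birthTime

#' @describeIn SyntheticTruth-class the true organismal tree (`phylo`).
#' @export
trueTree <- function(truth) truth@tree

#' @describeIn SyntheticTruth-class data.frame of complete-loss events.
#' @export
lossEvents <- function(truth) truth@lossEvents

#' @describeIn SyntheticTruth-class the true urancestral domain repertoire.
#' @export
rootRepertoire <- function(truth) truth@rootRepertoire

## ---------------------------------------------------------------- search ----

#' SearchParams: settings of the parsimony-ratchet tree search
#'
#' @param ratchetIterations number of ratchet iterations per restart. Each
#'   iteration reweights a random fraction of characters, re-searches,
#'   restores unit weights and re-searches.
#' @param reweightFraction fraction of characters perturbed per iteration,
#'   in (0, 1).
#' @param reweightFactor multiplier applied to perturbed characters (> 1).
#' @param neighborhood branch-swap neighbourhood: `"NNI"`, `"SPR"` or
#'   `"NNI+SPR"` (NNI until a local optimum, then SPR scans).
#' @param restarts number of random-addition-sequence starting trees.
#' @param seed seed for the search RNG; identical seeds give identical
#'   results.
#' @param maxTrees cap on the number of distinct equally parsimonious
#'   topologies retained.
#' @return A `SearchParams` object.
#' @seealso [searchTrees()]
#' @export
SearchParams <- function(ratchetIterations = 50L, reweightFraction = 0.25,
                         reweightFactor = 2, neighborhood = c("NNI+SPR", "NNI", "SPR"),
                         restarts = 5L, seed = 1L, maxTrees = 100L) {
    neighborhood <- match.arg(neighborhood)
    new("SearchParams",
        ratchetIterations = .assertCount(ratchetIterations, "ratchetIterations"),
        reweightFraction = as.numeric(reweightFraction),
        reweightFactor = as.numeric(reweightFactor),
        neighborhood = neighborhood,
        restarts = .assertCount(restarts, "restarts"),
        seed = .assertCount(seed, "seed"),
        maxTrees = .assertCount(maxTrees, "maxTrees"))
}

#' @rdname SearchParams
#' @export
setClass("SearchParams",
         representation(ratchetIterations = "integer",
                        reweightFraction = "numeric",
                        reweightFactor = "numeric", neighborhood = "character",
                        restarts = "integer", seed = "integer",
                        maxTrees = "integer"))

setValidity("SearchParams", function(object) {
    if (object@reweightFraction <= 0 || object@reweightFraction >= 1)
        return("reweightFraction must lie in (0, 1)")
    if (object@reweightFactor <= 1) return("reweightFactor must exceed 1")
    if (object@restarts < 1L) return("restarts must be >= 1")
    if (object@maxTrees < 1L) return("maxTrees must be >= 1")
    TRUE
})

setMethod("show", "SearchParams", function(object) {
    cat(sprintf(
        paste0("SearchParams: %d ratchet iterations (%.0f%% of characters x %g), ",
               "%s swaps, %d restarts, seed %d\n"),
        object@ratchetIterations, 100 * object@reweightFraction,
        object@reweightFactor, object@neighborhood, object@restarts,
        object@seed))
})

#' HypotheticalAncestor: polarization-model ancestor used for rooting
#'
#' @slot states integer vector of character states `0..23`, one per
#'   character, named by character id.
#' @slot model `"max-state"`, `"zero-state"` or `"custom"`.
#' @seealso [polarizedAncestor()], [lundbergRoot()]
#' @export
setClass("HypotheticalAncestor",
         representation(states = "integer", model = "character"))

setValidity("HypotheticalAncestor", function(object) {
    if (anyNA(object@states)) return("ancestor states contain NA")
    if (length(object@states) &&
        (min(object@states) < 0L || max(object@states) > 23L))
        return("ancestor states must lie in 0..23")
    TRUE
})

setMethod("show", "HypotheticalAncestor", function(object) {
    cat(sprintf("HypotheticalAncestor (%s): %d characters\n",
                object@model, length(object@states)))
})

#' @describeIn HypotheticalAncestor-class the ancestor's state vector.
#' @param anc a `HypotheticalAncestor`.
#' @export
ancestorStates <- function(anc) anc@states

## ------------------------------------------------------------- chronology ----

#' ClockModel: a fitted linear molecular clock
#'
#' Ordinary least squares of calibration age (Gy before present) on node
#' distance nd; see [fitClock()].
#'
#' @slot slope Gy per unit nd (negative for a clock running forward in
#'   time).
#' @slot intercept age at nd = 0, in Gy.
#' @slot rSquared coefficient of determination.
#' @slot nPoints number of calibration points used.
#' @slot residualSd residual standard deviation in Gy (`NA` with two
#'   points).
#' @export
setClass("ClockModel",
         representation(slope = "numeric", intercept = "numeric",
                        rSquared = "numeric", nPoints = "integer",
                        residualSd = "numeric"))

setValidity("ClockModel", function(object) {
    if (object@nPoints < 2L) return("a clock needs at least 2 points")
    if (!is.na(object@rSquared) &&
        (object@rSquared < -1e-12 || object@rSquared > 1 + 1e-12))
        return("rSquared must lie in [0, 1]")
    TRUE
})

setMethod("show", "ClockModel", function(object) {
    cat(sprintf(
        "ClockModel: age = %.4g %+.4g * nd  (R^2 = %.4f, n = %d, sd = %.3g Gy)\n",
        object@intercept, object@slope, object@rSquared, object@nPoints,
        object@residualSd))
})

#' @describeIn ClockModel-class slope in Gy per nd unit.
#' @param model a `ClockModel`.
#' @export
clockSlope <- function(model) model@slope

#' @describeIn ClockModel-class intercept (age at nd = 0) in Gy.
#' @export
clockIntercept <- function(model) model@intercept

#' @describeIn ClockModel-class coefficient of determination.
#' @export
clockRSquared <- function(model) model@rSquared

#' @describeIn ClockModel-class number of calibration points.
#' @export
clockNPoints <- function(model) model@nPoints

#' @describeIn ClockModel-class residual standard deviation in Gy.
#' @export
clockResidualSd <- function(model) model@residualSd

#' Chronology: node distances and calibrated ages for the leaves of a tree
#'
#' @slot nd named numeric, node distance per leaf in `[0, 1]` (0 = most
#'   ancient).
#' @slot age named numeric, calibrated age per leaf in Gy before present
#'   (empty until a clock is applied).
#' @slot treeId identifier of the source tree.
#' @slot imbalance normalized Colless index of the source tree (`NA` when
#'   undefined).
#' @seealso [buildChronology()]
#' @export
setClass("Chronology",
         representation(nd = "numeric", age = "numeric", treeId = "character",
                        imbalance = "numeric"))

setValidity("Chronology", function(object) {
    if (length(object@nd) &&
        (min(object@nd) < -1e-12 || max(object@nd) > 1 + 1e-12))
        return("nd must lie in [0, 1]")
    if (length(object@age) && length(object@age) != length(object@nd))
        return("age and nd must cover the same leaves")
    TRUE
})

setMethod("show", "Chronology", function(object) {
    cat(sprintf("Chronology of %d leaves (tree %s, Colless = %s)\n",
                length(object@nd), object@treeId,
                format(object@imbalance, digits = 3)))
    if (length(object@age))
        cat(sprintf("  ages %.3g .. %.3g Gy\n",
                    min(object@age), max(object@age)))
})

#' @describeIn Chronology-class named nd values per leaf.
#' @param chron a `Chronology`.
#' @export
ndValues <- function(chron) chron@nd

#' @describeIn Chronology-class named calibrated ages per leaf (Gy).
#' @export
ageValues <- function(chron) chron@age

#' @describeIn Chronology-class normalized Colless imbalance of the source
#'   tree.
#' @export
chronImbalance <- function(chron) chron@imbalance

#' Coerce a Chronology to a data.frame
#'
#' @param x a [Chronology-class].
#' @param ... unused.
#' @return data.frame with columns `leaf`, `nd` and, when calibrated,
#'   `age_Gy`, sorted by increasing nd.
#' @export
#' @method as.data.frame Chronology
as.data.frame.Chronology <- function(x, ...) {
    df <- data.frame(leaf = names(x@nd), nd = unname(x@nd),
                     stringsAsFactors = FALSE)
    if (length(x@age)) df$age_Gy <- unname(x@age[df$leaf])
    df[order(df$nd, df$leaf), , drop = FALSE]
}
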