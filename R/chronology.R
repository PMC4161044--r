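# Node-distance chronologies, imbalance diagnostics, and the linear
# molecular clock.

.leafDepths <- function(tree) {
    # number of internal nodes on the root-to-leaf path, root included
    # (equivalently the edge count of the path)
    if (!inherits(tree, "phylo")) stop("expected an ape 'phylo' tree")
    if (!ape::is.rooted(tree))
        stop("tree is unrooted; root it first (see lundbergRoot)")
    tree <- ape::reorder.phylo(tree, "cladewise")
    ntip <- length(tree$tip.label)
    nNode <- ntip + tree$Nnode
    depth <- integer(nNode)
    for (i in seq_len(nrow(tree$edge)))
        depth[tree$edge[i, 2L]] <- depth[tree$edge[i, 1L]] + 1L
    setNames(depth[seq_len(ntip)], tree$tip.label)
}

#' Node distances (nd) of the leaves of a rooted tree
#'
#' For each leaf, counts the internal nodes on the root-to-leaf path (root
#' included) and rescales to `[0, 1]`: `nd = (d - 1) / (dmax - 1)`. On the
#' highly unbalanced, pectinate trees produced by semi-punctuated change,
#' nd is a proxy for relative age: 0 marks the earliest-diverging
#' (most ancient) leaf and 1 the most derived. For a two-leaf tree
#' (`dmax = 1`) all nd are 0.
#'
#' @param tree a rooted `ape::phylo`.
#' @return Named numeric vector of nd values in `[0, 1]`.
#' @examples
#' nodeDistances(ape::read.tree(text = "(((A,B),C),D);"))
#' @export
nodeDistances <- function(tree) {
    d <- .leafDepths(tree)
    dmax <- max(d)
    if (dmax <= 1L) return(setNames(rep(0, length(d)), names(d)))
    (d - 1) / (dmax - 1)
}

#' Normalized Colless imbalance of a rooted binary tree
#'
#' Sum over internal nodes of the absolute difference between the leaf
#' counts of the two daughter clades, normalized by its maximum
#' `(n - 1)(n - 2) / 2`: 1 for a caterpillar (fully pectinate) tree, 0 for
#' a fully balanced one. Node-distance chronologies are meaningful on
#' highly unbalanced trees; near-balanced trees (stochastic/null branching)
#' trigger a warning in [buildChronology()].
#'
#' @param tree a rooted, binary `ape::phylo` with at least 3 leaves.
#' @return Normalized Colless index in `[0, 1]`.
#' @export
treeImbalance <- function(tree) {
    if (!ape::is.rooted(tree)) stop("tree is unrooted; root it first")
    if (!ape::is.binary(tree)) stop("Colless imbalance needs a binary tree")
    n <- length(tree$tip.label)
    if (n < 3L) stop("Colless imbalance is undefined for fewer than 3 leaves")
    tree <- ape::reorder.phylo(tree, "postorder")
    nNode <- n + tree$Nnode
    size <- integer(nNode)
    size[seq_len(n)] <- 1L
    for (i in seq_len(nrow(tree$edge)))
        size[tree$edge[i, 1L]] <- size[tree$edge[i, 1L]] + size[tree$edge[i, 2L]]
    kidsOf <- split(tree$edge[, 2L], tree$edge[, 1L])
    colless <- sum(vapply(kidsOf, function(k) abs(diff(size[k])), 0))
    colless / ((n - 1) * (n - 2) / 2)
}

#' Fit a linear molecular clock to calibration points
#'
#' Ordinary least squares of geological age (Gy before present) on node
#' distance. Calibration rows may name a domain (resolved against
#' `chronNd`) or carry a literal nd value.
#'
#' @param cal calibration data.frame with columns `age_Gy` and `id` and/or
#'   `nd` (see [readCalibrationTable()]).
#' @param chronNd named numeric vector of nd values (e.g.
#'   [nodeDistances()] of the rooted ToD), used to resolve `id` rows.
#' @return A [ClockModel-class].
#' @examples
#' cal <- data.frame(id = NA, nd = c(0, 0.5, 1), age_Gy = c(3.8, 1.9, 0))
#' fitClock(cal)
#' @export
fitClock <- function(cal, chronNd = NULL) {
    if (is.null(cal$nd)) cal$nd <- NA_real_
    nd <- cal$nd
    needs <- is.na(nd)
    if (any(needs)) {
        if (is.null(chronNd))
            stop("calibration rows name domains but no chronology nd was given")
        nd[needs] <- chronNd[as.character(cal$id[needs])]
        bad <- is.na(nd) & needs
        if (any(bad))
            stop("calibration domain(s) absent from the chronology: ",
                 paste(unique(cal$id[bad]), collapse = ", "))
    }
    age <- cal$age_Gy
    keep <- !is.na(nd) & !is.na(age)
    nd <- nd[keep]; age <- age[keep]
    if (length(nd) < 2L)
        stop("clock calibration needs at least 2 points")
    if (isTRUE(all.equal(var(nd), 0)) || sd(nd) == 0)
        stop("calibration points have zero nd variance; cannot fit a clock")
    fit <- stats::lm(age ~ nd)
    res <- stats::residuals(fit)
    sst <- sum((age - mean(age))^2)
    ssr <- sum(res^2)
    r2 <- if (sst > 0) 1 - ssr / sst else 1
    rsd <- if (length(nd) > 2L) sqrt(ssr / (length(nd) - 2L)) else NA_real_
    new("ClockModel",
        slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
        rSquared = max(0, min(1, r2)), nPoints = length(nd),
        residualSd = rsd)
}

#' Build a calibrated chronology from a rooted tree and a clock
#'
#' Computes nd for every leaf and converts it to an age,
#' `age = intercept + slope * nd`, clamping negative extrapolations to 0 Gy
#' with a warning. A fitted clock must run backwards (negative slope: age
#' decreases toward the present); a positive slope is refused unless
#' `allowForward = TRUE`. When the source tree is well balanced
#' (normalized Colless below `imbalanceThreshold`) a warning flags that
#' nd-based chronologies assume pectinate, semi-punctuated trees.
#'
#' @param tree a rooted `ape::phylo` (typically from [lundbergRoot()]).
#' @param model a [ClockModel-class] from [fitClock()], or `NULL` for an
#'   uncalibrated (nd-only) chronology.
#' @param imbalanceThreshold warn when the tree's normalized Colless index
#'   falls below this value (default 0.3).
#' @param allowForward permit a non-negative slope.
#' @param treeId identifier stored with the chronology.
#' @return A [Chronology-class].
#' @export
buildChronology <- function(tree, model = NULL, imbalanceThreshold = 0.3,
                            allowForward = FALSE, treeId = "tree") {
    nd <- nodeDistances(tree)
    imb <- tryCatch(treeImbalance(tree), error = function(e) NA_real_)
    if (!is.na(imb) && imb < imbalanceThreshold)
        warning(sprintf(
            paste0("tree imbalance %.3f is below %.3f: the tree is nearly ",
                   "balanced and nd is a poor proxy for age"),
            imb, imbalanceThreshold))
    age <- numeric(0)
    if (!is.null(model)) {
        if (model@slope > 0 && !allowForward)
            stop("clock slope is positive (ages would increase toward the ",
                 "present); use allowForward = TRUE to override")
        age <- model@intercept + model@slope * nd
        if (any(age < 0)) {
            warning(sprintf("%d negative age(s) clamped to 0 Gy",
                            sum(age < 0)))
            age[age < 0] <- 0
        }
    }
    new("Chronology", nd = nd, age = age, treeId = treeId, imbalance = imb)
}

#' Write a chronology as TSV
#'
#' Columns `leaf`, `nd` and (when calibrated) `age_Gy`, sorted by nd.
#'
#' @param chron a [Chronology-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeChronology <- function(chron, path) {
    utils::write.table(as.data.frame(chron), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
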