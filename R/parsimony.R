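# Ordered (Wagner) multistate parsimony: lengths, heuristic ratchet search,
# polarization-model ancestors, Lundberg rooting.

.statesForTree <- function(m) {
    st <- codedStates(m)
    if (is.null(rownames(st))) stop("coded matrix has no taxon labels")
    st
}

#' Parsimony length of a single ordered character on a tree
#'
#' Minimum total state change, summed as `|i - j|` per branch, over all
#' assignments of internal states: characters transform along linearly
#' ordered, reversible pathways. Computed by the interval (Farris)
#' algorithm, which for ordered characters equals Sankoff dynamic
#' programming with cost matrix `|i - j|`.
#'
#' @param tree an `ape::phylo` tree, rooted or unrooted (the length does
#'   not depend on the root position), binary.
#' @param states named integer vector of leaf states in `0..23`; names must
#'   cover every tip label.
#' @return Integer: the minimal character length (steps).
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' characterLength(tr, c(A = 0, B = 2, C = 2, D = 4))  # 4
#' @export
characterLength <- function(tree, states) {
    if (anyNA(states)) stop("missing leaf state(s)")
    miss <- setdiff(tree$tip.label, names(states))
    if (length(miss))
        stop("no state for leaf (leaves): ", paste(miss, collapse = ", "))
    labels <- tree$tip.label
    stm <- matrix(as.integer(states[labels]), ncol = 1L,
                  dimnames = list(labels, NULL))
    rt <- .rtFromPhylo(tree, labels)
    as.integer(.rtLength(rt$kids, rt$root, rt$ntip, stm))
}

#' Weighted parsimony length of a tree on a coded matrix
#'
#' Sum of [characterLength()] over the characters of `m`, each multiplied
#' by its weight (all 1 by default, the equal weighting of the analysis;
#' the ratchet perturbs these internally).
#'
#' @param tree an `ape::phylo` whose tips are exactly the taxa (rows) of
#'   `m`.
#' @param m a [CodedMatrix-class].
#' @param weights numeric vector of per-character multipliers, recycled
#'   from 1.
#' @return Numeric tree length (integer-valued under integer weights).
#' @export
treeLength <- function(tree, m, weights = NULL) {
    st <- .statesForTree(m)
    rt <- .rtFromPhylo(tree, rownames(st))
    if (!is.null(weights) && length(weights) != ncol(st))
        stop("weights must have one entry per character")
    as.numeric(.rtLength(rt$kids, rt$root, rt$ntip, st, weights))
}

#' Heuristic maximum-parsimony tree search with the parsimony ratchet
#'
#' Searches unrooted binary topologies for the taxa of `m` under ordered
#' (Wagner) parsimony. Each restart builds a random-addition-sequence
#' starting tree and hill-climbs by steepest-descent branch swapping (NNI,
#' SPR or both). Ratchet iterations then perturb the landscape: a random
#' fraction of characters is up-weighted, the current tree is re-searched
#' under the perturbed weights, weights are restored and the search repeats;
#' the result is accepted when not worse than the incumbent. All distinct
#' topologies attaining the best length found are retained (up to
#' `maxTrees`), including equal-length NNI neighbours of the final trees.
#' Fixed `seed` gives identical results.
#'
#' @param m a [CodedMatrix-class] with at least 3 taxa.
#' @param params a [SearchParams()] object.
#' @return A list with components `trees` (a `multiPhylo` of unrooted best
#'   trees), `length` (best length found) and `log` (data.frame of the
#'   length trajectory: `restart`, `iteration`, `length`).
#' @examples
#' st <- matrix(c(0L,0L,1L,1L, 0L,1L,1L,0L), 4, 2,
#'              dimnames = list(c("A","B","C","D"), NULL))
#' fit <- searchTrees(CodedMatrix(st), SearchParams(ratchetIterations = 2L,
#'                                                  restarts = 1L))
#' fit$length
#' @export
searchTrees <- function(m, params = SearchParams()) {
    st <- .statesForTree(m)
    taxa <- rownames(st)
    n <- nrow(st)
    if (n < 3L) stop("tree search needs at least 3 taxa")
    nch <- ncol(st)
    if (nch < 1L) stop("coded matrix has no characters")
    .withSeed(params@seed, {
        state <- new.env(parent = emptyenv())
        state$bestLen <- Inf
        state$best <- list()
        state$keys <- character(0)
        note <- function(rt, len) {
            if (len < state$bestLen - 1e-9) {
                state$bestLen <- len
                state$best <- list(rt)
                state$keys <- .rtKey(rt)
            } else if (abs(len - state$bestLen) < 1e-9 &&
                       length(state$best) < params@maxTrees) {
                k <- .rtKey(rt)
                if (!k %in% state$keys) {
                    state$best[[length(state$best) + 1L]] <- rt
                    state$keys <- c(state$keys, k)
                }
            }
        }
        logRestart <- integer(0); logIter <- integer(0); logLen <- numeric(0)
        for (r in seq_len(params@restarts)) {
            ord <- sample.int(n)
            rt <- .rtStepwise(st, taxa, ord)
            cur <- .rtHillClimb(rt, st, NULL, params@neighborhood)
            note(cur$rt, cur$len)
            logRestart <- c(logRestart, r); logIter <- c(logIter, 0L)
            logLen <- c(logLen, cur$len)
            if (params@ratchetIterations > 0L && n > 3L) {
                for (it in seq_len(params@ratchetIterations)) {
                    w <- rep(1, nch)
                    nPerturb <- max(1L, .roundHalfUp(params@reweightFraction * nch))
                    idx <- sample.int(nch, min(nPerturb, nch))
                    w[idx] <- w[idx] * params@reweightFactor
                    a <- .rtHillClimb(cur$rt, st, w, params@neighborhood)
                    b <- .rtHillClimb(a$rt, st, NULL, params@neighborhood)
                    if (b$len <= cur$len + 1e-9) cur <- b
                    note(b$rt, b$len)
                    logRestart <- c(logRestart, r); logIter <- c(logIter, it)
                    logLen <- c(logLen, b$len)
                }
            }
        }
        # plateau scan: equal-length NNI neighbours of the retained optima
        for (rt in state$best) {
            if (length(state$best) >= params@maxTrees) break
            for (k in .rtNNI(rt)) {
                len <- .rtLength(k$kids, k$root, rt$ntip, st)
                if (abs(len - state$bestLen) < 1e-9)
                    note(list(kids = k$kids, root = k$root, ntip = rt$ntip,
                              labels = rt$labels), len)
                if (length(state$best) >= params@maxTrees) break
            }
        }
        trees <- lapply(state$best, function(rt) ape::unroot(.rtToPhylo(rt)))
        class(trees) <- "multiPhylo"
        list(trees = trees, length = as.numeric(state$bestLen),
             log = data.frame(restart = logRestart, iteration = logIter,
                              length = logLen))
    })
}

#' Polarization-model hypothetical ancestor
#'
#' Builds the hypothetical ancestor whose attachment roots the tree. Under
#' the `"max-state"` model the ancestor carries, per character, the maximum
#' observed state: the polarization assumption that the most abundant and
#' most widely distributed domains are ancestral, so character change is
#' read as decay from high abundance. The `"zero-state"` alternative (all
#' states 0) polarizes change as gain from absence.
#'
#' @param m a [CodedMatrix-class].
#' @param model `"max-state"` (default) or `"zero-state"`.
#' @return A [HypotheticalAncestor-class].
#' @seealso [lundbergRoot()]
#' @export
polarizedAncestor <- function(m, model = c("max-state", "zero-state")) {
    model <- match.arg(model)
    st <- .statesForTree(m)
    if (!nrow(st)) stop("empty coded matrix")
    states <- if (model == "max-state") apply(st, 2L, max) else
        integer(ncol(st))
    new("HypotheticalAncestor",
        states = setNames(as.integer(states), colnames(st)), model = model)
}

#' Root an unrooted tree by the Lundberg method
#'
#' Attaches the hypothetical ancestor as an extra leaf on every edge of the
#' optimal unrooted tree in turn, scores each attachment by the increase in
#' total parsimony length, and roots the tree on an edge of minimum added
#' length (first such edge under a deterministic edge enumeration; all
#' tying edges are reported). The returned tree is rooted at the attachment
#' point (a degree-2 root) with the ancestor itself removed.
#'
#' @param tree an unrooted `ape::phylo` over the taxa of `m`.
#' @param anc a [HypotheticalAncestor-class] with one state per character
#'   of `m`.
#' @param m the [CodedMatrix-class] the tree was inferred from.
#' @return A rooted `phylo` with attributes `addedLength` (minimum added
#'   parsimony length) and `tieEdges` (data.frame describing every edge
#'   attaining it by the smaller of the two tip sets it separates).
#' @export
lundbergRoot <- function(tree, anc, m) {
    if (is.null(tree) || length(tree$tip.label) < 2L)
        stop("cannot root an empty tree")
    st <- .statesForTree(m)
    if (length(anc@states) != ncol(st))
        stop("ancestor has ", length(anc@states), " states but the matrix has ",
             ncol(st), " characters")
    rt <- .rtFromPhylo(tree, rownames(st))
    n <- rt$ntip
    # augmented numbering: tips keep ids 1..n, ancestor becomes tip n+1,
    # internal ids shift by one, the attachment node takes the last id
    shift <- function(id) ifelse(id > n, id + 1L, id)
    nAll2 <- 2L * (n + 1L) - 1L
    kidsA0 <- matrix(0L, nAll2, 2L)
    for (v in which(rt$kids[, 1L] > 0L))
        kidsA0[shift(v), ] <- shift(rt$kids[v, ])
    rootA <- shift(rt$root)
    q <- nAll2
    statesA <- rbind(st, matrix(anc@states, nrow = 1L))
    baseLen <- .rtLength(rt$kids, rt$root, n, st)
    ys <- .rtEdgeTargets(rt$kids, rt$root, n)
    pA <- integer(nAll2)
    act <- which(kidsA0[, 1L] > 0L)
    pA[kidsA0[act, 1L]] <- act
    pA[kidsA0[act, 2L]] <- act
    added <- vapply(ys, function(y) {
        y2 <- shift(y)
        x2 <- pA[y2]
        k2 <- kidsA0
        k2[x2, which(k2[x2, ] == y2)] <- q
        k2[q, ] <- c(y2, n + 1L)
        .rtLength(k2, rootA, n + 1L, statesA) - baseLen
    }, 0)
    best <- min(added)
    ties <- ys[added <= best + 1e-9]
    tipSet <- function(y) {
        tips <- integer(0)
        stk <- y
        while (length(stk)) {
            v <- stk[1L]; stk <- stk[-1L]
            if (v <= n) tips <- c(tips, v) else stk <- c(stk, rt$kids[v, ])
        }
        if (length(tips) > n / 2) tips <- setdiff(seq_len(n), tips)
        paste(sort(rt$labels[tips]), collapse = ",")
    }
    rooted <- .rtToPhylo(.rtRerootAtEdge(rt, ties[1L]))
    attr(rooted, "addedLength") <- best
    attr(rooted, "tieEdges") <- data.frame(
        side = vapply(ties, tipSet, ""), addedLength = added[added <= best + 1e-9])
    rooted
}
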