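# Internal light-weight rooted-binary tree representation used by the
# parsimony engine. Unrooted n-taxon topologies are carried as rooted binary
# trees whose (degree-2) root sits on one of the unrooted edges; Wagner
# parsimony length is invariant to where that root sits, so all search moves
# operate on child arrays and never renumber nodes.
#
# rt: list(kids  = integer matrix (2*ntip-1 x 2); row v = children of node v,
#                  0 for tips,
#          root  = id of the root node,
#          ntip  = number of tips; node ids 1..ntip are tips and index the
#                  rows of the state matrix,
#          labels= tip labels, labels[i] is the label of tip id i)

.rtParents <- function(rt) {
    p <- integer(nrow(rt$kids))
    act <- which(rt$kids[, 1L] > 0L)
    p[rt$kids[act, 1L]] <- act
    p[rt$kids[act, 2L]] <- act
    p
}

# ape phylo -> rt; tip ids follow `labels` so a fixed state matrix can be
# shared across many trees on the same taxa.
.rtFromPhylo <- function(phy, labels = NULL) {
    if (!inherits(phy, "phylo")) stop("expected an ape 'phylo' tree")
    if (is.null(labels)) labels <- phy$tip.label
    if (!ape::is.rooted(phy))
        phy <- ape::root(phy, outgroup = phy$tip.label[1L],
                         resolve.root = TRUE)
    if (!ape::is.binary(phy)) stop("tree must be binary")
    ntip <- length(phy$tip.label)
    if (length(labels) != ntip || !setequal(phy$tip.label, labels)) {
        extra <- setdiff(phy$tip.label, labels)
        miss <- setdiff(labels, phy$tip.label)
        stop("tree tips do not match the matrix taxa; ",
             if (length(miss)) paste0("missing from tree: ",
                                      paste(miss, collapse = ", "), "; ") else "",
             if (length(extra)) paste0("extra in tree: ",
                                       paste(extra, collapse = ", ")) else "")
    }
    E <- phy$edge
    nNode <- ntip + phy$Nnode
    map <- integer(nNode)
    map[seq_len(ntip)] <- match(phy$tip.label, labels)
    map[(ntip + 1L):nNode] <- (ntip + 1L):nNode
    kids <- matrix(0L, nNode, 2L)
    for (i in seq_len(nrow(E))) {
        p <- map[E[i, 1L]]
        ch <- map[E[i, 2L]]
        slot <- if (kids[p, 1L] == 0L) 1L
                else if (kids[p, 2L] == 0L) 2L
                else stop("tree must be binary")
        kids[p, slot] <- ch
    }
    rootApe <- setdiff(E[, 1L], E[, 2L])[1L]
    list(kids = kids, root = map[rootApe], ntip = ntip, labels = labels)
}

# rt -> ape phylo, edges in cladewise order, internals renumbered ntip+1, ...
.rtToPhylo <- function(rt) {
    kids <- rt$kids
    ntip <- rt$ntip
    env <- new.env()
    env$nextI <- ntip + 1L
    env$ep <- integer(0)
    env$ec <- integer(0)
    id2new <- integer(nrow(kids))
    id2new[seq_len(ntip)] <- seq_len(ntip)
    id2new[rt$root] <- ntip + 1L
    rec <- function(v) {
        for (ch in kids[v, ]) {
            if (ch == 0L) next
            if (ch > ntip) {
                env$nextI <- env$nextI + 1L
                id2new[ch] <<- env$nextI
            }
            env$ep <- c(env$ep, id2new[v])
            env$ec <- c(env$ec, id2new[ch])
            if (ch > ntip) rec(ch)
        }
    }
    rec(rt$root)
    phy <- list(edge = cbind(env$ep, env$ec), tip.label = rt$labels,
                Nnode = env$nextI - ntip)
    dimnames(phy$edge) <- NULL
    class(phy) <- "phylo"
    attr(phy, "order") <- "cladewise"
    phy
}

# weighted Wagner length of a kids/root configuration
.rtLength <- function(kids, root, ntip, states, weights = NULL) {
    cost <- .wagnerDownPass(kids, root, ntip, states)$cost
    if (is.null(weights)) sum(cost) else sum(weights * cost)
}

# One representative node y per unrooted edge (the edge (parent(y), y));
# the root's second child is skipped because both root edges are halves of
# the same unrooted edge.
.rtEdgeTargets <- function(kids, root, ntip) {
    ys <- integer(0)
    stk <- kids[root, kids[root, ] > 0L]
    while (length(stk)) {
        v <- stk[1L]
        stk <- stk[-1L]
        ys <- c(ys, v)
        if (v > ntip) stk <- c(stk, kids[v, ])
    }
    ys[ys != kids[root, 2L]]
}

# All NNI rearrangements of the unrooted topology. Standard case: for every
# internal edge (u, v) away from the root, swap v's children with v's
# sibling. When the root sits on an internal edge, the two rearrangements of
# that edge are generated by swapping across the root.
.rtNNI <- function(rt) {
    kids <- rt$kids
    ntip <- rt$ntip
    root <- rt$root
    p <- .rtParents(rt)
    res <- vector("list", 0L)
    for (v in seq_len(nrow(kids))) {
        if (v <= ntip || kids[v, 1L] == 0L) next
        u <- p[v]
        if (v == root || u == root) next
        A <- if (kids[u, 1L] == v) kids[u, 2L] else kids[u, 1L]
        for (j in 1:2) {
            k2 <- kids
            k2[u, which(k2[u, ] == A)] <- k2[v, j]
            k2[v, j] <- A
            res[[length(res) + 1L]] <- list(kids = k2, root = root)
        }
    }
    c1 <- kids[root, 1L]
    c2 <- kids[root, 2L]
    if (c1 > ntip && c2 > ntip) {     # root on an internal edge
        for (j in 1:2) {
            k2 <- kids
            A <- k2[c1, 2L]
            k2[c1, 2L] <- k2[c2, j]
            k2[c2, j] <- A
            res[[length(res) + 1L]] <- list(kids = k2, root = root)
        }
    }
    res
}

# All subtree-prune-regraft rearrangements of the unrooted topology:
# detach the subtree below s, then reattach it on every edge of the
# remainder (skipping the edge it came from and duplicate root edges).
.rtSPR <- function(rt) {
    kids <- rt$kids
    ntip <- rt$ntip
    root <- rt$root
    p <- .rtParents(rt)
    res <- vector("list", 0L)
    emit <- function(kidsP, rootP, s, pp, skip) {
        # enumerate regraft targets on the pruned tree and rebuild with the
        # spare internal node pp holding (target, s)
        ys <- .rtEdgeTargets(kidsP, rootP, ntip)
        for (y in ys) {
            if (y %in% skip) next
            x <- which(kidsP[, 1L] == y | kidsP[, 2L] == y)[1L]
            k2 <- kidsP
            k2[x, which(k2[x, ] == y)] <- pp
            k2[pp, ] <- c(y, s)
            res[[length(res) + 1L]] <<- list(kids = k2, root = rootP)
        }
    }
    for (s in seq_len(nrow(kids))) {
        if (s == root) next
        pp <- p[s]
        if (pp == 0L) next
        b <- if (kids[pp, 1L] == s) kids[pp, 2L] else kids[pp, 1L]
        if (pp != root) {
            g <- p[pp]
            kidsP <- kids
            kidsP[g, which(kidsP[g, ] == pp)] <- b
            kidsP[pp, ] <- 0L
            # skip b (recreates the original position); .rtEdgeTargets
            # already drops the duplicate second root edge
            emit(kidsP, root, s, pp, skip = b)
        } else if (b > ntip) {
            # s hangs off the root: the sibling b becomes the new root
            kidsP <- kids
            kidsP[pp, ] <- 0L
            emit(kidsP, b, s, pp, skip = kidsP[b, ])
        }
    }
    res
}

# splits-based canonical key of the unrooted topology (root-position
# independent), for duplicate detection among equally parsimonious trees
.rtKey <- function(rt) {
    kids <- rt$kids
    ntip <- rt$ntip
    post <- integer(0)
    stk <- rt$root
    while (length(stk)) {
        v <- stk[length(stk)]
        stk <- stk[-length(stk)]
        post <- c(post, v)
        if (v > ntip) stk <- c(stk, kids[v, ])
    }
    post <- rev(post)
    below <- vector("list", nrow(kids))
    splits <- character(0)
    for (v in post) {
        if (v <= ntip) {
            below[[v]] <- v
        } else {
            below[[v]] <- sort(c(below[[kids[v, 1L]]], below[[kids[v, 2L]]]))
            if (v != rt$root) {
                side <- below[[v]]
                if (1L %in% side) side <- setdiff(seq_len(ntip), side)
                # trivial splits (single tips, full set) are shared by every
                # topology and would make keys order-dependent
                if (length(side) >= 2L && length(side) <= ntip - 2L)
                    splits <- c(splits, paste(side, collapse = ","))
            }
        }
    }
    paste(sort(unique(splits)), collapse = ";")
}

# greedy random-addition-sequence starting tree (Wagner stepwise addition)
.rtStepwise <- function(states, labels, ord, weights = NULL) {
    ntip <- length(labels)
    stopifnot(ntip >= 3L)
    nAll <- 2L * ntip - 1L
    kids <- matrix(0L, nAll, 2L)
    root <- ntip + 1L
    kids[root, ] <- c(ord[1L], ntip + 2L)
    kids[ntip + 2L, ] <- c(ord[2L], ord[3L])
    nextInt <- ntip + 2L
    if (ntip > 3L) {
        for (i in 4L:ntip) {
            tip <- ord[i]
            nextInt <- nextInt + 1L
            q <- nextInt
            ys <- .rtEdgeTargets(kids, root, ntip)
            bestLen <- Inf
            bestKids <- NULL
            for (y in ys) {
                x <- which(kids[, 1L] == y | kids[, 2L] == y)[1L]
                k2 <- kids
                k2[x, which(k2[x, ] == y)] <- q
                k2[q, ] <- c(y, tip)
                len <- .rtLength(k2, root, ntip, states, weights)
                if (len < bestLen - 1e-9) {
                    bestLen <- len
                    bestKids <- k2
                }
            }
            kids <- bestKids
        }
    }
    list(kids = kids, root = root, ntip = ntip, labels = labels)
}

# steepest-descent branch swapping to a local optimum
.rtHillClimb <- function(rt, states, weights, neighborhood = "NNI+SPR") {
    useNNI <- neighborhood %in% c("NNI", "NNI+SPR")
    useSPR <- neighborhood %in% c("SPR", "NNI+SPR")
    len <- .rtLength(rt$kids, rt$root, rt$ntip, states, weights)
    repeat {
        improved <- FALSE
        if (useNNI) {
            repeat {
                cand <- .rtNNI(rt)
                if (!length(cand)) break
                lens <- vapply(cand, function(k)
                    .rtLength(k$kids, k$root, rt$ntip, states, weights), 0)
                j <- which.min(lens)
                if (lens[j] < len - 1e-9) {
                    rt$kids <- cand[[j]]$kids
                    rt$root <- cand[[j]]$root
                    len <- lens[j]
                    improved <- TRUE
                } else break
            }
        }
        if (useSPR) {
            cand <- .rtSPR(rt)
            if (length(cand)) {
                lens <- vapply(cand, function(k)
                    .rtLength(k$kids, k$root, rt$ntip, states, weights), 0)
                j <- which.min(lens)
                if (lens[j] < len - 1e-9) {
                    rt$kids <- cand[[j]]$kids
                    rt$root <- cand[[j]]$root
                    len <- lens[j]
                    improved <- TRUE
                }
            }
        }
        if (!improved) break
    }
    list(rt = rt, len = len)
}

# reroot the unrooted topology carried by rt so that the (new, degree-2)
# root sits on the edge (parent(y), y); the old root node id is reused
.rtRerootAtEdge <- function(rt, y) {
    kids <- rt$kids
    root <- rt$root
    p <- .rtParents(rt)
    if (y == root) stop("cannot reroot at the root node itself")
    nAll <- nrow(kids)
    adj <- vector("list", nAll)
    addE <- function(a, b) {
        adj[[a]] <<- c(adj[[a]], b)
        adj[[b]] <<- c(adj[[b]], a)
    }
    for (v in seq_len(nAll)) {
        if (v == root || kids[v, 1L] == 0L) next
        for (ch in kids[v, ]) addE(v, ch)
    }
    rc <- kids[root, ]
    addE(rc[1L], rc[2L])                 # collapse the old root
    x <- p[y]
    if (x == root) x <- if (rc[1L] == y) rc[2L] else rc[1L]
    adj[[x]] <- adj[[x]][adj[[x]] != y]  # sever the target edge
    adj[[y]] <- adj[[y]][adj[[y]] != x]
    adj[[root]] <- c(x, y)
    adj[[x]] <- c(adj[[x]], root)
    adj[[y]] <- c(adj[[y]], root)
    kids2 <- matrix(0L, nAll, 2L)
    stk <- list(c(root, 0L))
    while (length(stk)) {
        vp <- stk[[length(stk)]]
        stk[[length(stk)]] <- NULL
        v <- vp[1L]
        nb <- adj[[v]][adj[[v]] != vp[2L]]
        if (v > rt$ntip && v != root || v == root) {
            if (length(nb) != 2L && v == root)
                stop("internal error: malformed reroot")
        }
        if (v <= rt$ntip) next
        kids2[v, seq_along(nb)] <- nb
        for (w in nb) stk[[length(stk) + 1L]] <- c(w, v)
    }
    list(kids = kids2, root = root, ntip = rt$ntip, labels = rt$labels)
}
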