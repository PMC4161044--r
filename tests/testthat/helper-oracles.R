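# Independent oracles: deliberately different algorithms and code paths from
# the package implementation (Sankoff state-vector dynamic programming and
# explicit enumeration, against the package's interval down-pass).

# Sankoff DP over explicit state vectors with cost |i - j|
oracleSankoff <- function(tree, states, nStates = 24L) {
    if (!ape::is.rooted(tree))
        tree <- ape::root(tree, outgroup = tree$tip.label[1L],
                          resolve.root = TRUE)
    tree <- ape::reorder.phylo(tree, "postorder")
    ntip <- length(tree$tip.label)
    C <- matrix(1e9, ntip + tree$Nnode, nStates)
    for (i in seq_len(ntip)) C[i, states[tree$tip.label[i]] + 1L] <- 0
    kids <- split(tree$edge[, 2L], tree$edge[, 1L])
    for (p in unique(tree$edge[, 1L])) {
        tot <- rep(0, nStates)
        for (k in kids[[as.character(p)]]) {
            tot <- tot + vapply(seq_len(nStates), function(s)
                min(C[k, ] + abs(seq_len(nStates) - s)), 0)
        }
        C[p, ] <- tot
    }
    root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
    list(cost = min(C[root, ]),
         rootSet = which(C[root, ] == min(C[root, ])) - 1L)
}

oracleTreeLength <- function(tree, stm, weights = NULL, nStates = 24L) {
    costs <- vapply(seq_len(ncol(stm)), function(j)
        oracleSankoff(tree, stm[, j], nStates)$cost, 0)
    if (is.null(weights)) sum(costs) else sum(weights * costs)
}

# full enumeration of internal-state assignments (tiny instances only)
oracleBruteChar <- function(tree, states, maxState = 4L) {
    if (!ape::is.rooted(tree))
        tree <- ape::root(tree, outgroup = tree$tip.label[1L],
                          resolve.root = TRUE)
    ntip <- length(tree$tip.label)
    nInt <- tree$Nnode
    grid <- as.matrix(expand.grid(rep(list(0:maxState), nInt)))
    full <- c(states[tree$tip.label], rep(NA, nInt))
    best <- Inf
    for (r in seq_len(nrow(grid))) {
        full[(ntip + 1L):(ntip + nInt)] <- grid[r, ]
        len <- sum(abs(full[tree$edge[, 1L]] - full[tree$edge[, 2L]]))
        if (len < best) best <- len
    }
    best
}

# root-to-tip internal-node counts by climbing parent pointers tip by tip
oracleDepths <- function(tree) {
    parent <- setNames(tree$edge[, 1L], tree$edge[, 2L])
    vapply(seq_along(tree$tip.label), function(i) {
        d <- 0L
        v <- i
        while (as.character(v) %in% names(parent)) {
            v <- parent[[as.character(v)]]
            d <- d + 1L
        }
        d
    }, 0L) |> setNames(tree$tip.label)
}

# Colless sum by recursive subtree-size counting
oracleColless <- function(tree) {
    ntip <- length(tree$tip.label)
    kids <- split(tree$edge[, 2L], tree$edge[, 1L])
    sizeOf <- function(v) {
        if (v <= ntip) return(1L)
        sum(vapply(kids[[as.character(v)]], sizeOf, 0L))
    }
    root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
    tot <- 0L
    for (p in unique(tree$edge[, 1L])) {
        k <- kids[[as.character(p)]]
        tot <- tot + abs(sizeOf(k[1L]) - sizeOf(k[2L]))
    }
    tot / ((ntip - 1) * (ntip - 2) / 2)
}

# a coded matrix whose characters are split-compatible with one topology
# (zero homoplasy): its length on the generating tree equals the sum of the
# per-character step sizes, and that tree is the unique global optimum
zeroHomoplasyMatrix <- function(seed, ntaxa = 6L) {
    set.seed(seed)
    labs <- paste0("t", seq_len(ntaxa))
    tre <- ape::unroot(ape::rtree(ntaxa, tip.label = labs))
    rt <- ape::root(tre, outgroup = labs[1L], resolve.root = TRUE)
    pp <- ape::prop.part(rt)
    plabs <- attr(pp, "labels")
    chars <- list()
    minLen <- 0L
    for (cl in pp) {
        if (length(cl) < 2L || length(cl) > ntaxa - 2L) next
        step <- sample(1:3, 1L)
        chars[[length(chars) + 1L]] <- step * as.integer(plabs %in% plabs[cl])
        minLen <- minLen + step
    }
    # plus a constant and an autapomorphic character (neither moves the optimum)
    chars[[length(chars) + 1L]] <- rep(2L, ntaxa)
    aut <- integer(ntaxa); aut[sample.int(ntaxa, 1L)] <- 1L
    chars[[length(chars) + 1L]] <- aut
    minLen <- minLen + 1L
    stm <- do.call(cbind, chars)
    rownames(stm) <- plabs
    list(m = CodedMatrix(stm[labs, , drop = FALSE]), tree = tre,
         minLength = minLen)
}

# small random census for property tests
randomCensus <- function(seed, nProt = 6L, nDom = 8L) {
    set.seed(seed)
    cn <- matrix(rpois(nProt * nDom, 3) *
                     rbinom(nProt * nDom, 1L, 0.7), nDom, nProt)
    while (any(rowSums(cn) == 0))
        cn[rowSums(cn) == 0, ] <- rpois(sum(rowSums(cn) == 0) * nProt, 2) + 1L
    dimnames(cn) <- list(sprintf("f%02d", seq_len(nDom)),
                         c(sprintf("A%02d", 1:2), sprintf("B%02d", 1:2),
                           sprintf("E%02d", 1:2))[seq_len(nProt)])
    sk <- setNames(rep(c("Archaea", "Bacteria", "Eukarya"), each = 2)[
        seq_len(nProt)], colnames(cn))
    AbundanceCensus(cn, sk)
}
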