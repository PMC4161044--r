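test_that("ordered character length follows the |i-j| transformation cost", {
    tr2 <- ape::read.tree(text = "(A,B);")
    expect_identical(characterLength(tr2, c(A = 0L, B = 4L)), 4L)
    tr4 <- ape::read.tree(text = "((A,B),(C,D));")
    expect_identical(characterLength(tr4, c(A = 0L, B = 2L, C = 2L, D = 4L)),
                     4L)
    expect_identical(characterLength(tr4, c(A = 7L, B = 7L, C = 7L, D = 7L)),
                     0L)
    expect_error(characterLength(tr4, c(A = 0L, B = 1L, C = 2L)), "D")
})

test_that("character and tree lengths equal independent Sankoff DP", {
    set.seed(42)
    for (i in 1:40) {
        n <- sample(4:6, 1L)
        tre <- ape::rtree(n, tip.label = LETTERS[seq_len(n)])
        stm <- matrix(sample(0:4, 4L * n, replace = TRUE), n, 4L,
                      dimnames = list(LETTERS[seq_len(n)], NULL))
        m <- CodedMatrix(stm)
        expect_identical(treeLength(tre, m), oracleTreeLength(tre, stm, nStates = 6L))
        expect_identical(characterLength(tre, stm[, 1L]),
                         as.integer(oracleSankoff(tre, stm[, 1L], 6L)$cost))
    }
    # and equals full enumeration on a handful of tiny instances
    for (i in 1:6) {
        tre <- ape::rtree(5, tip.label = LETTERS[1:5])
        st <- setNames(sample(0:3, 5, replace = TRUE), LETTERS[1:5])
        expect_identical(characterLength(tre, st),
                         as.integer(oracleBruteChar(tre, st, 3L)))
    }
})

test_that("tree length is additive over characters and linear in weights", {
    tr4 <- ape::read.tree(text = "((A,B),(C,D));")
    stm <- matrix(c(0L, 2L, 2L, 4L, 1L, 1L, 3L, 3L), 4, 2,
                  dimnames = list(LETTERS[1:4], c("f1", "f2")))
    m <- CodedMatrix(stm)
    c1 <- characterLength(tr4, stm[, 1L])
    c2 <- characterLength(tr4, stm[, 2L])
    expect_identical(treeLength(tr4, m), as.numeric(c1 + c2))
    expect_identical(treeLength(tr4, m, weights = c(2, 1)),
                     as.numeric(2 * c1 + c2))
    bad <- tr4
    bad$tip.label <- c("A", "B", "C", "X")
    expect_error(treeLength(bad, m), "X")
    expect_error(treeLength(bad, m), "D")
})

test_that("three taxa give the unique topology at its exact length", {
    stm <- matrix(c(0L, 1L, 3L), 3, 1, dimnames = list(c("A", "B", "C"), NULL))
    fit <- searchTrees(CodedMatrix(stm), SearchParams(seed = 1L))
    expect_length(fit$trees, 1L)
    expect_identical(fit$length, 3)
    expect_identical(sort(fit$trees[[1L]]$tip.label), c("A", "B", "C"))
})

test_that("ratchet search recovers zero-homoplasy topologies deterministically", {
    ok <- 0L
    for (seed in 1:6) {
        zh <- zeroHomoplasyMatrix(seed)
        fit <- searchTrees(zh$m, SearchParams(ratchetIterations = 3L,
                                              restarts = 1L, seed = seed))
        expect_identical(fit$length, as.numeric(zh$minLength))
        if (phangorn::RF.dist(fit$trees[[1L]], zh$tree) == 0) ok <- ok + 1L
    }
    expect_identical(ok, 6L)                       # unique optimum recovered
    zh <- zeroHomoplasyMatrix(99)
    p <- SearchParams(ratchetIterations = 4L, restarts = 2L, seed = 7L)
    f1 <- searchTrees(zh$m, p)
    f2 <- searchTrees(zh$m, p)
    expect_identical(lapply(f1$trees, ape::write.tree),
                     lapply(f2$trees, ape::write.tree))
    expect_identical(f1$log, f2$log)
})

test_that("ratchet never ends worse than the plain hill-climb", {
    for (seed in c(2, 5)) {
        sim <- simulateCensus(SimParams(nFsf = 25L, seed = seed))
        m <- t(encodeCensus(sim$census))
        plain <- searchTrees(m, SearchParams(ratchetIterations = 0L,
                                             restarts = 1L, seed = 3L,
                                             neighborhood = "NNI"))
        ratch <- searchTrees(m, SearchParams(ratchetIterations = 4L,
                                             restarts = 1L, seed = 3L,
                                             neighborhood = "NNI"))
        expect_lte(ratch$length, plain$length)
        expect_true(all(ratch$log$length >= ratch$length))
    }
})

test_that("polarization ancestors take column maxima or zeros", {
    stm <- matrix(c(0L, 23L, 5L, 2L, 1L, 4L), 3, 2,
                  dimnames = list(c("x", "y", "z"), c("f1", "f2")))
    m <- CodedMatrix(stm)
    anc <- polarizedAncestor(m, "max-state")
    expect_identical(unname(ancestorStates(anc)), c(23L, 4L))
    expect_true(all(ancestorStates(anc) >=
                        apply(codedStates(m), 2L, max)))
    expect_identical(unname(ancestorStates(polarizedAncestor(m, "zero-state"))),
                     c(0L, 0L))
})

test_that("Lundberg rooting matches a brute-force edge scan", {
    set.seed(7)
    for (i in 1:10) {
        n <- sample(5:6, 1L)
        labs <- LETTERS[seq_len(n)]
        tre <- ape::unroot(ape::rtree(n, tip.label = labs))
        stm <- matrix(sample(0:6, 3L * n, replace = TRUE), n, 3L,
                      dimnames = list(labs, NULL))
        m <- CodedMatrix(stm)
        anc <- polarizedAncestor(m, "max-state")
        rooted <- lundbergRoot(tre, anc, m)
        # oracle: attach the ancestor on every edge with phytools::bind.tip
        # and score with the Sankoff DP
        base <- oracleTreeLength(tre, stm, nStates = 24L)
        tre2 <- tre
        tre2$edge.length <- rep(1, nrow(tre2$edge))
        added <- vapply(seq_len(nrow(tre2$edge)), function(e) {
            aug <- phytools::bind.tip(tre2, "ANC", edge.length = 1,
                                      where = tre2$edge[e, 2L], position = 0.5)
            stmA <- rbind(stm, matrix(ancestorStates(anc), 1L,
                                      dimnames = list("ANC", NULL)))
            oracleTreeLength(aug, stmA, nStates = 24L) - base
        }, 0)
        expect_identical(attr(rooted, "addedLength"), min(added))
        # the tie table reports exactly the argmin edges
        expect_identical(nrow(attr(rooted, "tieEdges")), sum(added == min(added)))
    }
})

test_that("an ancestor equal to a leaf attaches beside it at zero cost", {
    set.seed(11)
    for (i in 1:8) {
        n <- 6L
        labs <- LETTERS[seq_len(n)]
        tre <- ape::unroot(ape::rtree(n, tip.label = labs))
        stm <- matrix(sample(0:9, 4L * n, replace = TRUE), n, 4L,
                      dimnames = list(labs, NULL))
        m <- CodedMatrix(stm)
        leaf <- sample(labs, 1L)
        anc <- new("HypotheticalAncestor", states = stm[leaf, ],
                   model = "custom")
        rooted <- lundbergRoot(tre, anc, m)
        expect_identical(attr(rooted, "addedLength"), 0)
        expect_true(leaf %in% unlist(strsplit(
            attr(rooted, "tieEdges")$side, ",")))
        expect_identical(treeLength(rooted, m), treeLength(tre, m))
    }
})

test_that("a taxon holding every column maximum hosts the max-state root", {
    labs <- c("old", "v", "w", "x", "y")
    stm <- rbind(old = c(20L, 18L, 23L),
                 v = c(3L, 5L, 2L), w = c(2L, 4L, 1L),
                 x = c(1L, 1L, 0L), y = c(0L, 2L, 0L))
    colnames(stm) <- paste0("p", 1:3)
    m <- CodedMatrix(stm)
    tre <- ape::unroot(ape::read.tree(text = "((old,v),(w,(x,y)));"))
    rooted <- lundbergRoot(tre, polarizedAncestor(m, "max-state"), m)
    kidsOfRoot <- rooted$edge[rooted$edge[, 1L] ==
                                  length(labs) + 1L, 2L]
    expect_true(match("old", rooted$tip.label) %in% kidsOfRoot)
})
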