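test_that("Venn groups are the occupied superkingdom sets", {
    cn <- rbind(onlyA = c(2L, 0L, 0L), ubiq = c(5L, 1L, 9L),
                be = c(0L, 3L, 4L))
    colnames(cn) <- c("A01", "B01", "E01")
    census <- AbundanceCensus(cn, c(A01 = "Archaea", B01 = "Bacteria",
                                    E01 = "Eukarya"))
    g <- vennAssign(census)
    expect_identical(g, c(onlyA = "A", ubiq = "ABE", be = "BE"))

    noMap <- AbundanceCensus(cn)
    expect_error(vennAssign(noMap), "map")
    expect_error(vennAssign(census, c(A01 = "Archaea", B01 = "Bacteria")),
                 "E01")
    zero <- rbind(cn, gone = c(0L, 0L, 0L))
    expect_error(vennAssign(AbundanceCensus(zero, superkingdoms(census))),
                 "gone")
})

test_that("Venn groups match brute-force recomputation and partition domains", {
    for (seed in 1:6) {
        census <- randomCensus(seed)
        g <- vennAssign(census)
        cn <- censusCounts(census, "domains")
        sk <- superkingdoms(census)
        for (f in rownames(cn)) {
            expected <- paste(c(
                if (any(cn[f, sk[colnames(cn)] == "Archaea"] > 0)) "A",
                if (any(cn[f, sk[colnames(cn)] == "Bacteria"] > 0)) "B",
                if (any(cn[f, sk[colnames(cn)] == "Eukarya"] > 0)) "E"),
                collapse = "")
            expect_identical(unname(g[f]), expected)
        }
        expect_identical(sort(names(g)), sort(domainIds(census)))
        expect_identical(sum(table(g)), length(domainIds(census)))
    }
})

test_that("group emergence is the oldest member age; empty groups are absent", {
    groups <- c(f1 = "B", f2 = "B", f3 = "ABE")
    ages <- c(f1 = 2.1, f2 = 1.0, f3 = 3.6)
    emt <- groupEmergenceTimes(groups, ages)
    expect_equal(emt[["B"]], 2.1)
    expect_equal(emt[["ABE"]], 3.6)
    expect_false("E" %in% names(emt))
    expect_error(groupEmergenceTimes(c(f9 = "A"), ages), "f9")
})

test_that("whole-superkingdom losses need absence, dual presence and age priority", {
    cn <- rbind(lostInA = c(0L, 0L, 7L, 9L),      # old, gone from Archaea
                youngB = c(0L, 0L, 3L, 0L),       # B-specific
                onlyA = c(3L, 1L, 0L, 0L),        # defines the Archaea onset
                ubiq = c(4L, 2L, 8L, 5L),
                beYoung = c(0L, 0L, 2L, 1L))      # BE but younger than A onset
    colnames(cn) <- c("A01", "A02", "B01", "E01")
    sk <- c(A01 = "Archaea", A02 = "Archaea", B01 = "Bacteria",
            E01 = "Eukarya")
    census <- AbundanceCensus(cn, sk)
    ages <- c(lostInA = 3.2, youngB = 2.0, onlyA = 2.5, ubiq = 3.7,
              beYoung = 1.5)
    ev <- detectSuperkingdomLosses(census, chron = ages)
    expect_identical(ev$domain, "lostInA")
    expect_identical(ev$superkingdom, "Archaea")
    expect_true(ev$firstLoss)
    # nothing is ever flagged in a superkingdom where it occurs
    for (seed in 1:4) {
        census2 <- randomCensus(seed + 30)
        ages2 <- setNames(runif(length(domainIds(census2)), 0, 3.8),
                          domainIds(census2))
        ev2 <- detectSuperkingdomLosses(census2, chron = ages2)
        if (nrow(ev2)) {
            sk2 <- superkingdoms(census2)
            cn2 <- censusCounts(census2, "domains")
            for (r in seq_len(nrow(ev2)))
                expect_identical(sum(cn2[ev2$domain[r],
                                         sk2 == ev2$superkingdom[r]]), 0L)
        }
    }
})

test_that("ladderize is deterministic, idempotent and size-ordered", {
    set.seed(12)
    tre <- ape::rtree(12)
    l1 <- ladderizeTree(tre)
    l2 <- ladderizeTree(l1)
    expect_identical(ape::write.tree(l1), ape::write.tree(l2))
    # bigger subtree first at every node
    kids <- split(l1$edge[, 2L], l1$edge[, 1L])
    sizes <- vapply(seq_len(12 + l1$Nnode), function(v)
        if (v <= 12) 1L else length(ape::extract.clade(l1, v)$tip.label), 0L)
    for (p in names(kids))
        expect_true(all(diff(sizes[kids[[p]]]) <= 0))
})

test_that("heat-map ordering follows the ladderized ToL and ascending nd", {
    census <- randomCensus(3)
    tol <- ape::rtree(6, tip.label = proteomeIds(census))
    nd <- setNames(seq(0, 1, length.out = length(domainIds(census))),
                   sample(domainIds(census)))
    oh <- orderHeatmap(census, tol, nd)
    expect_identical(sort(oh$rowOrder), sort(proteomeIds(census)))
    expect_identical(oh$rowOrder, rownames(oh$counts))
    expect_true(all(diff(oh$nd) >= 0))
    expect_identical(oh$colOrder, names(sort(nd)))
    expect_identical(names(oh$vennGroups), oh$colOrder)
    # already-sorted input is a fixed point
    sortedCensus <- AbundanceCensus(
        t(oh$counts), superkingdoms(census)[oh$rowOrder])
    oh2 <- orderHeatmap(sortedCensus, ladderizeTree(tol), nd)
    expect_identical(oh2$counts, oh$counts)
    expect_error(orderHeatmap(census, tol, nd[-1L]), "nd")
    badTol <- tol
    badTol$tip.label[1L] <- "zzz"
    expect_error(orderHeatmap(census, badTol, nd), "differ")
})

test_that("caterpillar ToL rows come out in node-distance order", {
    tol <- ape::read.tree(text = "((((p4,p5),p3),p2),p1);")
    census <- randomCensus(9, nProt = 5L)
    cn <- censusCounts(census, "domains")
    colnames(cn) <- paste0("p", 1:5)
    census2 <- AbundanceCensus(cn)
    nd <- setNames(seq(0, 1, length.out = nrow(cn)), rownames(cn))
    oh <- orderHeatmap(census2, tol, nd, skMap = NULL)
    ndP <- nodeDistances(tol)[oh$rowOrder]
    expect_true(all(diff(ndP) <= 0) || all(diff(ndP) >= 0))
})
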