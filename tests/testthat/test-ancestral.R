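test_that("root state intervals contain exactly the minimum-cost states", {
    labs <- c("A", "B", "C", "D")
    stm <- matrix(c(0L, 2L, 2L, 4L), 4, 1, dimnames = list(labs, "f1"))
    tr <- ape::read.tree(text = "((A,B),(C,D));")   # rooted on central edge
    iv <- rootStateIntervals(tr, CodedMatrix(stm))
    expect_identical(c(iv$lower, iv$upper, iv$cost), c(2L, 2L, 4L))

    tr2 <- ape::read.tree(text = "(A,B);")
    iv2 <- rootStateIntervals(tr2, CodedMatrix(
        matrix(c(0L, 4L), 2, 1, dimnames = list(c("A", "B"), "f1"))))
    expect_identical(c(iv2$lower, iv2$upper, iv2$cost), c(0L, 4L, 4L))

    const <- CodedMatrix(matrix(7L, 4, 1, dimnames = list(labs, "f1")))
    iv3 <- rootStateIntervals(tr, const)
    expect_identical(c(iv3$lower, iv3$upper, iv3$cost), c(7L, 7L, 0L))

    expect_error(rootStateIntervals(tr, t(const)), "ToL")
    expect_error(rootStateIntervals(ape::unroot(ape::rtree(4, tip.label = labs)),
                                    const), "root")
})

test_that("intervals equal brute-force root-state scans on small instances", {
    set.seed(23)
    for (i in 1:30) {
        n <- sample(4:6, 1L)
        labs <- LETTERS[seq_len(n)]
        tre <- ape::rtree(n, tip.label = labs)
        stm <- matrix(sample(0:4, 3L * n, replace = TRUE), n, 3L,
                      dimnames = list(labs, paste0("f", 1:3)))
        iv <- rootStateIntervals(tre, CodedMatrix(stm))
        for (j in 1:3) {
            orc <- oracleSankoff(tre, stm[, j], 6L)
            expect_identical(iv$lower[j], min(orc$rootSet))
            expect_identical(iv$upper[j], max(orc$rootSet))
            expect_identical(iv$cost[j], as.integer(orc$cost))
            # every state inside the interval attains the minimum: the
            # ordered-character optimum set is contiguous
            expect_identical(sort(orc$rootSet),
                             seq.int(iv$lower[j], iv$upper[j]))
        }
    }
})

test_that("a constant character survives any caterpillar topology", {
    for (txt in c("(((A,B),C),D);", "(((D,C),B),A);", "((A,D),(B,C));")) {
        tre <- ape::read.tree(text = txt)
        iv <- rootStateIntervals(tre, CodedMatrix(
            matrix(5L, 4, 1, dimnames = list(c("A", "B", "C", "D"), "f1"))))
        expect_identical(c(iv$lower, iv$upper), c(5L, 5L))
    }
})

test_that("the urancestral repertoire shrinks monotonically with stringency", {
    labs <- paste0("p", 1:6)
    set.seed(4)
    stm <- matrix(sample(0:23, 6 * 10, replace = TRUE), 6, 10,
                  dimnames = list(labs, paste0("f", 1:10)))
    m <- CodedMatrix(stm, scheme = "log", gmax = 15112)
    tre <- ape::rtree(6, tip.label = labs)
    iv <- rootStateIntervals(tre, m)
    urn <- urancestralRepertoire(iv)
    expect_identical(urn$threshold, 1:23)
    expect_true(all(diff(urn$fsfCount) <= 0))
    expect_true(all(diff(urn$domainCount) <= 0))
    pres <- attr(urn, "presence")
    expect_identical(dim(pres), c(10L, 23L))
    expect_identical(unname(colSums(pres)), as.double(urn$fsfCount))
})

test_that("repertoire presence and decoding honour the interval midpoints", {
    iv <- data.frame(character = c("gone", "top"), lower = c(0L, 23L),
                     upper = c(0L, 23L), cost = c(0L, 0L))
    attr(iv, "gmax") <- 15112
    attr(iv, "scheme") <- "log"
    urn <- urancestralRepertoire(iv, thresholds = c(1L, 5L))
    pres <- attr(urn, "presence")
    expect_false(any(pres["gone", ]))        # interval {0}: absent at any tau
    expect_true(all(pres["top", ]))
    expect_identical(urn$domainCount, c(15112, 15112))  # top state decodes to gmax
    expect_error(urancestralRepertoire(iv[0, , drop = FALSE]), "intervals")
})
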