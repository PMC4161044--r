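test_that("node distances count internal nodes from the root, rescaled to [0,1]", {
    cat4 <- ape::read.tree(text = "(((A,B),C),D);")
    nd <- nodeDistances(cat4)
    expect_equal(nd[c("D", "C", "A", "B")],
                 c(D = 0, C = 0.5, A = 1, B = 1))
    bal <- ape::read.tree(text = "((A,B),(C,D));")
    expect_true(length(unique(nodeDistances(bal))) == 1L)
    expect_equal(unname(nodeDistances(ape::read.tree(text = "(A,B);"))),
                 c(0, 0))
    expect_error(nodeDistances(ape::unroot(ape::rtree(5))), "root")
})

test_that("node distances match an independent path-counting oracle", {
    set.seed(31)
    for (i in 1:10) {
        tre <- ape::rtree(20)
        d <- oracleDepths(tre)
        expect_equal(nodeDistances(tre),
                     (d - 1) / (max(d) - 1))
    }
})

test_that("normalized Colless is 1 on caterpillars, 0 on balanced trees", {
    cater8 <- ape::read.tree(
        text = "(((((((A,B),C),D),E),F),G),H);")
    expect_equal(treeImbalance(cater8), 1)
    bal8 <- ape::read.tree(
        text = "(((A,B),(C,D)),((E,F),(G,H)));")
    expect_equal(treeImbalance(bal8), 0)
    mid <- ape::read.tree(text = "((((A,B),C),D),(E,F));")
    expect_equal(treeImbalance(mid), 5 / 10)   # hand-computed Colless sum / 10
    expect_error(treeImbalance(ape::read.tree(text = "(A,B);")), "3 leaves")
    set.seed(5)
    for (i in 1:8) {
        tre <- ape::rtree(12)
        expect_equal(treeImbalance(tre), oracleColless(tre))
    }
})

test_that("the clock is exact on collinear calibrations", {
    cal <- data.frame(id = NA_character_, nd = c(0, 0.5, 1),
                      age_Gy = c(3.8, 1.9, 0))
    clk <- fitClock(cal)
    expect_equal(clockSlope(clk), -3.8, tolerance = 1e-12)
    expect_equal(clockIntercept(clk), 3.8, tolerance = 1e-12)
    expect_equal(clockRSquared(clk), 1)
    two <- fitClock(data.frame(id = NA, nd = c(0.2, 0.9),
                               age_Gy = c(3.0, 0.5)))
    expect_equal(clockRSquared(two), 1)
    expect_identical(clockNPoints(two), 2L)
    expect_error(fitClock(data.frame(id = NA, nd = 0.5, age_Gy = 1)),
                 "at least 2")
    expect_error(fitClock(data.frame(id = NA, nd = c(0.5, 0.5),
                                     age_Gy = c(1, 2))), "variance")
})

test_that("domain-keyed calibrations resolve against a chronology's nd", {
    nd <- c(f1 = 0, f2 = 0.5, f3 = 1)
    cal <- data.frame(id = c("f1", "f2", "f3"), nd = NA_real_,
                      age_Gy = c(3.8, 1.9, 0))
    clk <- fitClock(cal, nd)
    expect_equal(clockSlope(clk), -3.8, tolerance = 1e-12)
    cal$id[1L] <- "missing"
    expect_error(fitClock(cal, nd), "missing")
})

test_that("noiseless synthetic calibrations recover the generating clock", {
    sim <- simulateCensus(SimParams(seed = 17L))
    cal <- simulateCalibrations(sim$truth, clock = c(3.8, 3.8),
                                nPoints = 20L, noiseSd = 0, seed = 2L)
    trueNd <- birthTimes(sim$truth) / sim$truth@params@tSteps
    clk <- fitClock(cal, trueNd)
    expect_equal(clockSlope(clk), -3.8, tolerance = 1e-9)
    expect_equal(clockIntercept(clk), 3.8, tolerance = 1e-9)
})

test_that("chronologies apply the clock, clamp at the present and warn on balance", {
    cat4 <- ape::read.tree(text = "(((A,B),C),D);")
    clk <- new("ClockModel", slope = -3.8, intercept = 3.8, rSquared = 1,
               nPoints = 3L, residualSd = 0)
    chron <- buildChronology(cat4, clk, treeId = "toy")
    expect_equal(unname(ageValues(chron)[c("D", "C", "A")]),
                 c(3.8, 1.9, 0))
    expect_equal(chronImbalance(chron), 1)
    # negative extrapolation clamps with a warning
    clk2 <- new("ClockModel", slope = -3.8, intercept = 3.0, rSquared = 1,
                nPoints = 3L, residualSd = 0)
    expect_warning(ch2 <- buildChronology(cat4, clk2), "clamped")
    expect_equal(min(ageValues(ch2)), 0)
    # forward-running clocks are refused unless explicitly allowed
    fwd <- new("ClockModel", slope = 1.0, intercept = 0.2, rSquared = 1,
               nPoints = 3L, residualSd = 0)
    expect_error(buildChronology(cat4, fwd), "positive")
    expect_s4_class(buildChronology(cat4, fwd, allowForward = TRUE),
                    "Chronology")
    # well-balanced trees are flagged as unfit for nd chronologies
    bal8 <- ape::read.tree(text = "(((A,B),(C,D)),((E,F),(G,H)));")
    expect_warning(buildChronology(bal8, clk), "balanced")
    # age ranking is the reverse of nd ranking under a negative slope
    set.seed(8)
    tre <- ape::rtree(15)
    ch <- suppressWarnings(buildChronology(tre, clk))
    expect_equal(rank(ndValues(ch)), rank(-ageValues(ch)))
})

test_that("chronology TSV export is sorted by nd with ages attached", {
    cat4 <- ape::read.tree(text = "(((A,B),C),D);")
    clk <- new("ClockModel", slope = -3.8, intercept = 3.8, rSquared = 1,
               nPoints = 3L, residualSd = 0)
    chron <- buildChronology(cat4, clk)
    f <- withr::local_tempfile()
    writeChronology(chron, f)
    df <- utils::read.table(f, header = TRUE, sep = "\t")
    expect_identical(names(df), c("leaf", "nd", "age_Gy"))
    expect_identical(df$leaf[1L], "D")
    expect_true(all(diff(df$nd) >= 0))
})
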