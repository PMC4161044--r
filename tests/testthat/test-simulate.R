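test_that("parameter validation names the offending field", {
    expect_error(SimParams(dupRate = 1.5), "dupRate")
    expect_error(SimParams(lossBase = -0.1), "lossBase")
    expect_error(SimParams(splitTimes = c(40L, 30L)), "increasing")
    expect_error(SimParams(splitTimes = c(40L, 120L), tSteps = 100L),
                 "splitTimes")
    expect_error(SimParams(nProteomes = c(5L, 5L)), "nProteomes|superkingdom")
})

test_that("an empty domain universe yields an empty census and truth", {
    sim <- simulateCensus(SimParams(nFsf = 0L, seed = 1L))
    expect_identical(nrow(sim$census), 0L)
    expect_identical(ncol(sim$census), 15L)
    expect_length(birthTimes(sim$truth), 0L)
    expect_identical(nrow(lossEvents(sim$truth)), 0L)
})

test_that("identical parameters and seed give bit-identical censuses", {
    a <- simulateCensus(SimParams(seed = 5L))
    b <- simulateCensus(SimParams(seed = 5L))
    expect_identical(censusCounts(a$census), censusCounts(b$census))
    expect_identical(birthTimes(a$truth), birthTimes(b$truth))
    expect_identical(ape::write.tree(trueTree(a$truth)),
                     ape::write.tree(trueTree(b$truth)))
    d <- simulateCensus(SimParams(seed = 6L))
    expect_false(identical(censusCounts(a$census), censusCounts(d$census)))
})

test_that("the census respects its structural contracts", {
    for (seed in 1:5) {
        sim <- simulateCensus(SimParams(seed = seed))
        cn <- censusCounts(sim$census, "proteomes")
        expect_true(all(cn >= 0L))
        expect_identical(nrow(cn), 15L)
        sk <- superkingdoms(sim$census)
        expect_identical(as.vector(table(sk)[c("Archaea", "Bacteria",
                                               "Eukarya")]),
                         c(5L, 5L, 5L))
        expect_true(all(colSums(cn) > 0L))   # no all-zero census column
        # every census domain has a birth time; losses postdate births
        expect_true(all(colnames(cn) %in% names(birthTimes(sim$truth))))
        le <- lossEvents(sim$truth)
        if (nrow(le))
            expect_true(all(le$step >= birthTimes(sim$truth)[le$domain]))
        # the true tree covers exactly the proteomes
        expect_setequal(trueTree(sim$truth)$tip.label, rownames(cn))
        expect_true(all(rootRepertoire(sim$truth) %in%
                            names(birthTimes(sim$truth))))
    }
})

test_that("early-born domains are more widespread and abundant than late ones", {
    reps <- 40L
    early <- late <- matrix(NA_real_, reps, 2L)
    for (s in seq_len(reps)) {
        sim <- simulateCensus(SimParams(seed = 1000L + s))
        bt <- sort(birthTimes(sim$truth))
        cn <- censusCounts(sim$census, "domains")
        grab <- function(ids) {
            ids <- intersect(ids, rownames(cn))
            if (!length(ids)) return(c(NA, NA))
            c(mean(cn[ids, , drop = FALSE] > 0),
              mean(cn[ids, , drop = FALSE]))
        }
        early[s, ] <- grab(names(bt)[1:10])
        late[s, ] <- grab(names(bt)[41:50])
    }
    expect_gt(mean(early[, 1L], na.rm = TRUE), mean(late[, 1L], na.rm = TRUE))
    expect_gt(mean(early[, 2L], na.rm = TRUE), mean(late[, 2L], na.rm = TRUE))
    # occupancy gap is large, not marginal
    expect_gt(mean(early[, 1L], na.rm = TRUE), 0.7)
    expect_lt(mean(late[, 1L], na.rm = TRUE), 0.4)
})

test_that("complete losses concentrate soon after a domain's origin", {
    delays <- unlist(lapply(1:10, function(s) {
        sim <- simulateCensus(SimParams(seed = 2000L + s))
        le <- lossEvents(sim$truth)
        le$step - birthTimes(sim$truth)[le$domain]
    }))
    expect_gt(length(delays), 20L)
    expect_lt(median(delays), 100 / 4)
})

test_that("domains shared by all three clades outnumber clade-unique ones", {
    counts <- t(vapply(1:10, function(s) {
        g <- vennAssign(simulateCensus(SimParams(seed = 3000L + s))$census)
        c(abe = sum(g == "ABE"),
          maxUnique = max(sum(g == "A"), sum(g == "B"), sum(g == "E")))
    }, c(abe = 0, maxUnique = 0)))
    expect_gt(mean(counts[, "abe"]), mean(counts[, "maxUnique"]))
    expect_gte(mean(counts[, "abe"] > counts[, "maxUnique"]), 0.8)
})

test_that("synthetic calibrations map birth steps onto the clock line", {
    params <- SimParams(tSteps = 100L)
    truth <- new("SyntheticTruth",
                 birthTime = c(f0 = 0L, fT = 100L, fm = 50L),
                 tree = ape::read.tree(text = "(A,B);"),
                 lossEvents = data.frame(domain = character(0),
                                         lineage = integer(0),
                                         step = integer(0)),
                 rootRepertoire = character(0),
                 everPresent = matrix(FALSE, 0, 3),
                 params = params)
    cal <- simulateCalibrations(truth, clock = c(3.8, 3.8), nPoints = 3L,
                                noiseSd = 0, seed = 1L)
    ages <- setNames(cal$age_Gy, cal$id)
    expect_equal(ages[["f0"]], 3.8)
    expect_equal(ages[["fT"]], 0)
    expect_equal(ages[["fm"]], 1.9)
    expect_error(simulateCalibrations(truth, nPoints = 10L), "exceeds")
    expect_error(simulateCalibrations(truth, nPoints = 1L), ">= 2")
})

test_that("calibration noise is unbiased about the true ages", {
    sim <- simulateCensus(SimParams(seed = 77L))
    Tn <- sim$truth@params@tSteps
    bias <- vapply(1:100, function(s) {
        cal <- simulateCalibrations(sim$truth, clock = c(3.8, 3.8),
                                    nPoints = 20L, noiseSd = 0.2, seed = s)
        true <- 3.8 - 3.8 * birthTimes(sim$truth)[cal$id] / Tn
        mean(cal$age_Gy - true)
    }, 0)
    expect_lt(abs(mean(bias)), 0.05)
})
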