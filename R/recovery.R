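# Simulation study: how well does the inference chain recover the
# generator's ground truth?

#' Score truth recovery of the full inference chain on one synthetic census
#'
#' Simulates a census, runs the analysis (coding, ToD and ToL searches,
#' Lundberg rooting under the max-state polarization, nd chronology, clock
#' calibration, urancestral reconstruction, loss detection) and scores it
#' against the recorded truth:
#'
#' * `ndSpearman`: Spearman correlation between true domain birth steps
#'   and inferred ToD nd (positive when early-born domains get small nd);
#' * `ageSpearman`: Spearman correlation between birth steps and
#'   calibrated ages (expected negative);
#' * `lossTP` / `lossFlagged`: whole-superkingdom loss events flagged, and
#'   how many are genuine (the domain was truly present in that clade's
#'   history);
#' * `urnRecall`: fraction of the true urancestral repertoire recovered at
#'   the loosest presence threshold;
#' * clock fit statistics and the ToD imbalance.
#'
#' @param simParams a [SimParams()] object (its seed drives everything).
#' @param searchParams a [SearchParams()] template; its seed is re-derived
#'   from `simParams@seed`.
#' @param calNPoints,calNoiseSd calibration points drawn from the truth and
#'   their age noise (Gy).
#' @param clock numeric(2) `(originGy, spanGy)` of the true clock.
#' @return A list of scores (see above).
#' @export
assessRecovery <- function(simParams = SimParams(),
                           searchParams = SearchParams(
                               ratchetIterations = 5L, restarts = 1L,
                               neighborhood = "NNI+SPR"),
                           calNPoints = 10L, calNoiseSd = 0.1,
                           clock = c(3.8, 3.8)) {
    sim <- simulateCensus(simParams)
    census <- sim$census
    truth <- sim$truth
    if (length(domainIds(census)) < 4L)
        stop("census too small to assess recovery")

    tolM <- encodeCensus(census, "log")
    todM <- t(tolM)

    reseed <- function(off) {
        p <- searchParams
        p@seed <- simParams@seed + off
        p
    }
    todFit <- searchTrees(todM, reseed(101L))
    todRooted <- lundbergRoot(todFit$trees[[1L]],
                              polarizedAncestor(todM, "max-state"), todM)
    nd <- nodeDistances(todRooted)

    bt <- birthTimes(truth)[names(nd)]
    ndSpearman <- suppressWarnings(cor(bt, nd, method = "spearman"))

    cal <- simulateCalibrations(truth, clock = clock,
                                nPoints = min(calNPoints, length(nd)),
                                noiseSd = calNoiseSd,
                                seed = simParams@seed + 7L,
                                domains = names(nd))
    clk <- fitClock(cal, nd)
    chron <- suppressWarnings(buildChronology(todRooted, clk, allowForward = TRUE, treeId = "ToD"))
    age <- ageValues(chron)
    ageSpearman <- suppressWarnings(
        cor(bt, age[names(nd)], method = "spearman"))

    ## losses: flagged events vs. the truth's clade-presence records
    lossDf <- detectSuperkingdomLosses(census, chron = chron)
    lossTP <- 0L
    if (nrow(lossDf)) {
        ep <- truth@everPresent
        lossTP <- sum(ep[cbind(lossDf$domain, lossDf$superkingdom)])
    }

    ## urancestor: recall of the stem repertoire at the loosest threshold
    tolFit <- searchTrees(tolM, reseed(202L))
    tolRooted <- lundbergRoot(tolFit$trees[[1L]],
                              polarizedAncestor(tolM, "max-state"), tolM)
    iv <- rootStateIntervals(tolRooted, tolM)
    urn <- urancestralRepertoire(iv, thresholds = 1L)
    inferredRoot <- rownames(attr(urn, "presence"))[attr(urn, "presence")[, 1L]]
    trueRoot <- intersect(rootRepertoire(truth), domainIds(census))
    urnRecall <- if (length(trueRoot))
        length(intersect(inferredRoot, trueRoot)) / length(trueRoot) else
        NA_real_

    list(ndSpearman = ndSpearman, ageSpearman = ageSpearman,
         lossFlagged = nrow(lossDf), lossTP = lossTP,
         urnRecall = urnRecall,
         clockSlope = clockSlope(clk), clockIntercept = clockIntercept(clk),
         clockR2 = clockRSquared(clk),
         todImbalance = chronImbalance(chron),
         todLength = todFit$length,
         nDomains = length(domainIds(census)),
         gmax = gmax(census))
}
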