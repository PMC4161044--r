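# Synthetic domain-abundance censuses with recorded ground truth.

.skNames <- c("Archaea", "Bacteria", "Eukarya")

# SCOP-flavoured synthetic fold-superfamily ids, e.g. "c.37.1"
.fsfIds <- function(n) {
    if (n == 0L) return(character(0))
    cls <- sample(letters[1:7], n, replace = TRUE)
    idx <- stats::ave(seq_len(n), cls, FUN = seq_along)
    sprintf("%s.%d.1", cls, idx)
}

#' Simulate a domain-abundance census with ground truth
#'
#' Generates a proteome x domain count matrix with the statistical
#' structure the timetree analysis assumes, together with the truth needed
#' to score any downstream inference. The model, on a discrete timeline of
#' `tSteps` steps:
#'
#' * **Lineages.** A single stem line spawns the Archaea ancestor at
#'   `splitTimes[1]` and then splits into the Bacteria and Eukarya
#'   ancestors at `splitTimes[2]`. Within each superkingdom clade, random
#'   coalescent-style bifurcations (uniformly chosen lineages at uniformly
#'   drawn times) produce the requested number of terminal proteomes.
#' * **Births.** `nFsf` domain types arise at steps drawn with
#'   gamma-distributed per-step weights, so discovery of new structures is
#'   semi-punctuated (burst-prone) rather than uniform. Each new domain
#'   starts as a single copy in one uniformly chosen extant lineage:
#'   domains born before the first split seed every superkingdom, later
#'   ones only their clade of origin — the nested Venn structure.
#' * **Duplication.** Each copy duplicates per step with probability
#'   `dupRate` (per-copy Bernoulli, geometric-like growth), so early-born
#'   domains reach abundances orders of magnitude above late ones.
#' * **Loss.** A lineage loses a domain completely with per-step
#'   probability `lossBase * lossDecay^(copies - 1)`: complete loss is
#'   concentrated soon after a domain's origin, while abundant domains are
#'   effectively immortal.
#'
#' Domains lost everywhere before the present are dropped from the census
#' but remain in the truth records. Identical `params` (including the
#' seed) give bit-identical output.
#'
#' @param params a [SimParams()] object.
#' @return A list with components `census` (an [AbundanceCensus-class]
#'   with superkingdom annotations) and `truth` (a
#'   [SyntheticTruth-class]).
#' @examples
#' sim <- simulateCensus(SimParams(nFsf = 20L, seed = 42L))
#' sim$census
#' @export
simulateCensus <- function(params = SimParams()) {
    stopifnot(is(params, "SimParams"))
    validObject(params)
    .withSeed(params@seed, .simulateCensusImpl(params))
}

.simulateCensusImpl <- function(params) {
    nF <- params@nFsf
    Tn <- params@tSteps
    s1 <- params@splitTimes[1L]
    s2 <- params@splitTimes[2L]
    nP <- params@nProteomes            # A, B, E

    # semi-punctuated birth schedule: burst-prone gamma step weights with a
    # declining trend, so the universal core is discovered early and new
    # structures keep appearing (more slowly) later
    stepW <- (rgamma(Tn, shape = 0.6, rate = 1) + 1e-9) *
        exp(-3 * seq_len(Tn) / Tn)
    birthStep <- if (nF > 0L)
        sort(sample.int(Tn, nF, replace = TRUE, prob = stepW)) else integer(0)
    ids <- .fsfIds(nF)
    names(birthStep) <- ids

    # within-clade bifurcation schedules
    splitSchedule <- function(origin, k) {
        if (k <= 1L) return(integer(0))
        pool <- seq.int(origin + 1L, Tn)
        if (length(pool) < k - 1L)
            stop("tSteps too short for the requested proteome count")
        sort(sample(pool, k - 1L))
    }
    cladeSplits <- list(A = splitSchedule(s1, nP[1L]),
                        B = splitSchedule(s2, nP[2L]),
                        E = splitSchedule(s2, nP[3L]))

    # lineage state
    counts <- matrix(0L, nrow = 1L, ncol = nF)   # rows = lineages
    tag <- ""                                     # per lineage
    alive <- TRUE
    splitRec <- data.frame(lineage = integer(0), child = integer(0),
                           step = integer(0))
    lossRec <- list()
    everPresent <- matrix(FALSE, nF, 3L,
                          dimnames = list(ids, .skNames))
    rootRep <- character(0)

    newLineage <- function(from, t, newTag) {
        counts <<- rbind(counts, counts[from, , drop = FALSE])
        tag <<- c(tag, newTag)
        alive <<- c(alive, TRUE)
        id <- nrow(counts)
        splitRec <<- rbind(splitRec,
                           data.frame(lineage = from, child = id, step = t))
        id
    }

    for (t in seq_len(Tn)) {
        ## lineage events
        if (t == s1) {
            rootRep <- ids[counts[1L, ] > 0L]
            newLineage(1L, t, "A")
            tag[1L] <- "BE"
        }
        if (t == s2) {
            newLineage(1L, t, "E")
            tag[1L] <- "B"
        }
        for (cl in c("A", "B", "E")) {
            for (dummy in which(cladeSplits[[cl]] == t)) {
                cand <- which(alive & tag == cl)
                from <- cand[sample.int(length(cand), 1L)]
                newLineage(from, t, cl)
            }
        }
        ## births
        for (f in which(birthStep == t)) {
            cand <- which(alive)
            l <- cand[sample.int(length(cand), 1L)]
            counts[l, f] <- 1L
        }
        ## duplication (per-copy Bernoulli)
        for (l in which(alive)) {
            pos <- which(counts[l, ] > 0L)
            if (length(pos))
                counts[l, pos] <- counts[l, pos] +
                    rbinom(length(pos), counts[l, pos], params@dupRate)
        }
        ## presence bookkeeping (before losses apply this step)
        for (l in which(alive)) {
            if (tag[l] == "") next
            sk <- match(strsplit(tag[l], "")[[1L]], c("A", "B", "E"))
            here <- counts[l, ] > 0L
            everPresent[here, sk] <- TRUE
        }
        ## complete loss, hazard decaying with copy number
        for (l in which(alive)) {
            pos <- which(counts[l, ] > 0L)
            if (!length(pos)) next
            p <- params@lossBase * params@lossDecay^(counts[l, pos] - 1L)
            hit <- pos[runif(length(pos)) < p]
            if (length(hit)) {
                counts[l, hit] <- 0L
                lossRec[[length(lossRec) + 1L]] <-
                    data.frame(domain = ids[hit], lineage = l, step = t)
            }
        }
    }

    ## name terminal proteomes per superkingdom
    tipName <- character(nrow(counts))
    for (cl in c("A", "B", "E")) {
        idx <- which(tag == cl)
        tipName[idx] <- sprintf("%s%02d", cl, seq_along(idx))
    }
    skMap <- setNames(.skNames[match(tag, c("A", "B", "E"))], tipName)

    ## true organismal tree, branch lengths in timeline steps
    nwk <- function(l, from) {
        sp <- splitRec[splitRec$lineage == l & splitRec$step > from, ,
                       drop = FALSE]
        if (!nrow(sp))
            return(sprintf("%s:%d", tipName[l], Tn - from))
        s <- sp[which.min(sp$step), ]
        sprintf("(%s,%s):%d", nwk(l, s$step), nwk(s$child, s$step),
                s$step - from)
    }
    tree <- ape::read.tree(text = paste0(nwk(1L, 0L), ";"))

    ## census: drop domains extinct everywhere, keep them in the truth
    cn <- counts
    dimnames(cn) <- list(tipName, ids)
    keep <- colSums(cn) > 0L
    census <- AbundanceCensus(t(cn[, keep, drop = FALSE]),
                              superkingdoms = skMap)
    losses <- if (length(lossRec)) do.call(rbind, lossRec) else
        data.frame(domain = character(0), lineage = integer(0),
                   step = integer(0))
    truth <- new("SyntheticTruth", birthTime = birthStep, tree = tree,
                 lossEvents = losses, rootRepertoire = rootRep,
                 everPresent = everPresent, params = params)
    list(census = census, truth = truth)
}

#' Simulate clock calibration points from synthetic truth
#'
#' Maps true birth steps onto geological ages with a linear clock,
#' `age = originGy - spanGy * birthStep / tSteps`, optionally adding
#' Gaussian noise, and returns them as a calibration table keyed by domain
#' id. With `noiseSd = 0` the points lie exactly on the clock line.
#'
#' @param truth a [SyntheticTruth-class].
#' @param clock numeric(2): `(originGy, spanGy)`; the default `(3.8, 3.8)`
#'   spans the full history of a 3.8-Gy clock.
#' @param nPoints number of calibration points (>= 2).
#' @param noiseSd Gaussian age noise in Gy.
#' @param seed seed for point selection and noise.
#' @param domains candidate domain ids to draw from (default: every born
#'   domain; pass the census domains to guarantee resolvability against an
#'   inferred chronology).
#' @return Calibration data.frame with columns `id`, `nd`, `age_Gy`,
#'   `label` (see [readCalibrationTable()]).
#' @export
simulateCalibrations <- function(truth, clock = c(3.8, 3.8), nPoints = 10L,
                                 noiseSd = 0, seed = 1L,
                                 domains = names(birthTimes(truth))) {
    if (nPoints < 2L) stop("nPoints must be >= 2")
    if (clock[2L] <= 0) stop("clock span must be > 0")
    bt <- birthTimes(truth)[domains]
    if (anyNA(bt)) stop("unknown domain id(s) among candidates")
    if (nPoints > length(bt))
        stop("nPoints exceeds the ", length(bt), " available domains")
    Tn <- truth@params@tSteps
    .withSeed(seed, {
        pick <- sample(names(bt), nPoints)
        age <- clock[1L] - clock[2L] * bt[pick] / Tn
        if (noiseSd > 0) age <- age + rnorm(nPoints, 0, noiseSd)
        data.frame(id = pick, nd = NA_real_,
                   age_Gy = pmax(0, unname(age)), label = "synthetic",
                   stringsAsFactors = FALSE)
    })
}
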