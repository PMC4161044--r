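# Venn distribution groups, emergence times, whole-superkingdom losses and
# the ladderized heat-map ordering.

.SUPERKINGDOMS <- c(Archaea = "A", Bacteria = "B", Eukarya = "E")

.skLetters <- function(skMap) {
    sk <- as.character(skMap)
    letter <- .SUPERKINGDOMS[sk]
    unknown <- is.na(letter) & !sk %in% c("A", "B", "E")
    letter[unknown] <- NA_character_
    letter[sk %in% c("A", "B", "E")] <- sk[sk %in% c("A", "B", "E")]
    if (anyNA(letter))
        stop("unknown superkingdom label(s): ",
             paste(unique(sk[is.na(letter)]), collapse = ", "))
    setNames(letter, names(skMap))
}

#' Assign domains to superkingdom Venn distribution groups
#'
#' A domain's group is the set of superkingdoms in which it occurs
#' (count > 0 in at least one member proteome): unique groups `A`, `B`,
#' `E`; shared groups `AB`, `AE`, `BE`; and the ubiquitous group `ABE`.
#' Domains occurring nowhere are invalid input and rejected.
#'
#' @param census an [AbundanceCensus-class].
#' @param skMap named character vector proteome -> superkingdom
#'   (`"Archaea"`/`"Bacteria"`/`"Eukarya"` or the letters `A`/`B`/`E`);
#'   defaults to the map stored in the census.
#' @param minOccupancy optional occupancy fraction: a superkingdom counts
#'   as occupied only when the domain is present in more than this fraction
#'   of its member proteomes (default 0, i.e. one proteome suffices).
#' @return Named character vector domain -> group.
#' @export
vennAssign <- function(census, skMap = superkingdoms(census),
                       minOccupancy = 0) {
    if (is.null(skMap))
        stop("no proteome-to-superkingdom map available")
    letter <- .skLetters(skMap)
    prot <- proteomeIds(census)
    unmapped <- setdiff(prot, names(letter))
    if (length(unmapped))
        stop("proteome(s) without a superkingdom: ",
             paste(unmapped, collapse = ", "))
    letter <- letter[prot]
    if (!all(c("A", "B", "E") %in% letter))
        stop("every superkingdom needs at least one proteome; present: ",
             paste(sort(unique(letter)), collapse = ", "))
    cn <- censusCounts(census, "domains")       # domains x proteomes
    occ <- vapply(c("A", "B", "E"), function(l) {
        memb <- letter == l
        rowSums(cn[, memb, drop = FALSE] > 0) / sum(memb)
    }, numeric(nrow(cn)))
    present <- occ > minOccupancy
    nowhere <- rownames(cn)[rowSums(present) == 0L]
    if (length(nowhere))
        stop("domain(s) absent from every superkingdom: ",
             paste(head(nowhere, 5L), collapse = ", "),
             if (length(nowhere) > 5L) ", ..." else "")
    groups <- apply(present, 1L, function(p)
        paste(c("A", "B", "E")[p], collapse = ""))
    setNames(groups, rownames(cn))
}

#' Emergence time of each Venn distribution group
#'
#' The oldest (maximum) calibrated age among the member domains of each
#' group; groups with no members are reported absent (dropped), not as
#' zero.
#'
#' @param groups named character vector domain -> group, from
#'   [vennAssign()].
#' @param chron a [Chronology-class] of the domains (a calibrated ToD
#'   chronology), or a named numeric vector of ages.
#' @return Named numeric vector group -> oldest age (Gy), covering only
#'   non-empty groups.
#' @export
groupEmergenceTimes <- function(groups, chron) {
    age <- if (is(chron, "Chronology")) ageValues(chron) else chron
    miss <- setdiff(names(groups), names(age))
    if (length(miss))
        stop("no age for domain(s): ", paste(head(miss, 5L), collapse = ", "))
    vapply(split(age[names(groups)], groups), max, 0)
}

#' Detect whole-superkingdom domain losses
#'
#' Flags domains with zero occurrence across every proteome of one
#' superkingdom while present in both others — the census signature of a
#' complete loss (or never-gain) in that clade. Because complete loss is
#' most likely soon after a domain's origin, candidates are additionally
#' required to predate the superkingdom's own diversification: their age
#' must exceed the oldest clade-specific (unique-group) domain of that
#' superkingdom, when one exists. Events are sorted by age, oldest first,
#' and the oldest event per superkingdom is labelled the first loss.
#'
#' @param census an [AbundanceCensus-class].
#' @param skMap proteome -> superkingdom map (defaults to the census map).
#' @param chron a [Chronology-class] (calibrated ToD) or named age vector
#'   covering every census domain.
#' @return data.frame with columns `domain`, `superkingdom`, `age_Gy`,
#'   `presentIn`, `firstLoss`; zero rows when nothing is flagged.
#' @export
detectSuperkingdomLosses <- function(census, skMap = superkingdoms(census),
                                     chron) {
    age <- if (is(chron, "Chronology")) ageValues(chron) else chron
    miss <- setdiff(domainIds(census), names(age))
    if (length(miss))
        stop("chronology lacks age(s) for: ",
             paste(head(miss, 5L), collapse = ", "))
    groups <- vennAssign(census, skMap)
    onset <- c(A = NA_real_, B = NA_real_, E = NA_real_)
    for (l in c("A", "B", "E")) {
        own <- names(groups)[groups == l]
        if (length(own)) onset[l] <- max(age[own])
    }
    full <- c(A = "Archaea", B = "Bacteria", E = "Eukarya")
    rows <- list()
    for (l in c("A", "B", "E")) {
        others <- setdiff(c("A", "B", "E"), l)
        cand <- names(groups)[groups == paste(others, collapse = "")]
        if (!length(cand)) next
        keep <- if (is.na(onset[l])) rep(TRUE, length(cand)) else
            age[cand] > onset[l]
        cand <- cand[keep]
        if (!length(cand)) next
        rows[[l]] <- data.frame(domain = cand, superkingdom = full[[l]],
                                age_Gy = unname(age[cand]),
                                presentIn = paste(full[others], collapse = "+"),
                                stringsAsFactors = FALSE)
    }
    out <- if (length(rows)) do.call(rbind, rows) else
        data.frame(domain = character(0), superkingdom = character(0),
                   age_Gy = numeric(0), presentIn = character(0))
    rownames(out) <- NULL
    out <- out[order(-out$age_Gy, out$domain), , drop = FALSE]
    out$firstLoss <- !duplicated(out$superkingdom)
    rownames(out) <- NULL
    out
}

#' Deterministically ladderize a rooted tree
#'
#' Reorders the children of every node by decreasing subtree size, breaking
#' ties by the smallest tip label; deterministic and idempotent. Fixes the
#' heat-map row order.
#'
#' @param tree a rooted `ape::phylo`.
#' @return The reordered `phylo`.
#' @export
ladderizeTree <- function(tree) {
    if (!ape::is.rooted(tree)) stop("ladderize needs a rooted tree")
    tree <- ape::reorder.phylo(tree, "postorder")
    ntip <- length(tree$tip.label)
    nNode <- ntip + tree$Nnode
    size <- integer(nNode)
    size[seq_len(ntip)] <- 1L
    minLab <- character(nNode)
    minLab[seq_len(ntip)] <- tree$tip.label
    kidsOf <- vector("list", nNode)
    for (i in seq_len(nrow(tree$edge))) {
        p <- tree$edge[i, 1L]; ch <- tree$edge[i, 2L]
        kidsOf[[p]] <- c(kidsOf[[p]], ch)
    }
    po <- unique(tree$edge[, 1L])    # postorder parents
    for (p in po) {
        k <- kidsOf[[p]]
        size[p] <- sum(size[k])
        minLab[p] <- min(minLab[k])
    }
    elOf <- if (!is.null(tree$edge.length))
        setNames(tree$edge.length, tree$edge[, 2L]) else NULL
    root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
    ep <- integer(0); ec <- integer(0); el <- numeric(0)
    rec <- function(v) {
        k <- kidsOf[[v]]
        k <- k[order(-size[k], minLab[k])]
        for (ch in k) {
            ep <<- c(ep, v); ec <<- c(ec, ch)
            if (!is.null(elOf)) el <<- c(el, elOf[[as.character(ch)]])
            if (ch > ntip) rec(ch)
        }
    }
    rec(root)
    out <- tree
    out$edge <- cbind(ep, ec)
    dimnames(out$edge) <- NULL
    if (!is.null(elOf)) out$edge.length <- el
    attr(out, "order") <- "cladewise"
    out
}

.tipOrder <- function(tree) {
    tree <- ape::reorder.phylo(tree, "cladewise")
    e2 <- tree$edge[, 2L]
    tree$tip.label[e2[e2 <= length(tree$tip.label)]]
}

#' Order the census heat map by the ToL and the ToD chronology
#'
#' Rows (proteomes) follow the leaf order of the ladderized rooted ToL;
#' columns (domains) are sorted by ascending nd from the ToD chronology
#' (oldest first), ties broken by domain id. The result bundles the
#' reordered count matrix with the row/column permutations, the nd track
#' and the Venn-group track per column.
#'
#' @param census an [AbundanceCensus-class].
#' @param tol rooted ToL (`phylo`, leaves = proteomes of the census).
#' @param todChron a [Chronology-class] (or named nd vector) covering every
#'   census domain.
#' @param skMap proteome -> superkingdom map for the Venn track; defaults
#'   to the census map, `NULL` to skip the track.
#' @return A list with components `counts` (reordered proteome x domain
#'   matrix), `rowOrder`, `colOrder`, `nd`, and `vennGroups` (or `NULL`).
#' @seealso [plotCensusHeatmap()]
#' @export
orderHeatmap <- function(census, tol, todChron,
                         skMap = superkingdoms(census)) {
    nd <- if (is(todChron, "Chronology")) ndValues(todChron) else todChron
    missD <- setdiff(domainIds(census), names(nd))
    if (length(missD))
        stop("chronology lacks nd for domain(s): ",
             paste(head(missD, 5L), collapse = ", "))
    missP <- c(setdiff(proteomeIds(census), tol$tip.label),
               setdiff(tol$tip.label, proteomeIds(census)))
    if (length(missP))
        stop("ToL leaves and census proteomes differ: ",
             paste(head(missP, 5L), collapse = ", "))
    rowOrder <- .tipOrder(ladderizeTree(tol))
    nd <- nd[domainIds(census)]
    colOrder <- domainIds(census)[order(nd, domainIds(census))]
    counts <- censusCounts(census, "proteomes")[rowOrder, colOrder,
                                                drop = FALSE]
    venn <- if (!is.null(skMap))
        vennAssign(census, skMap)[colOrder] else NULL
    list(counts = counts, rowOrder = rowOrder, colOrder = colOrder,
         nd = unname(nd[colOrder]), vennGroups = venn)
}

#' Raster rendering of an ordered census heat map
#'
#' Draws the coded abundances with the conventional palette: gray for
#' absence (state 0) and a red-to-blue ramp for increasing abundance
#' states 1..23.
#'
#' @param oh list from [orderHeatmap()].
#' @param scheme coding scheme used to bin abundances for display.
#' @param ... further arguments passed to [graphics::image()].
#' @return Invisibly, the state matrix drawn.
#' @export
plotCensusHeatmap <- function(oh, scheme = "log", ...) {
    g <- oh$counts
    N <- max(g)
    G <- if (N >= 1 && scheme == "log")
        .roundHalfUp(23 * log(g + 1) / log(N + 1)) else if (N >= 1)
        .roundHalfUp(23 * g / N) else g * 0
    G[g > 0 & G == 0] <- 1
    pal <- c("gray85", grDevices::colorRampPalette(c("red3", "blue3"))(23))
    graphics::image(x = seq_len(ncol(G)), y = seq_len(nrow(G)), z = t(G),
                    zlim = c(0, 23), col = pal, xlab = "domains (by nd)",
                    ylab = "proteomes (ladderized ToL)", axes = FALSE, ...)
    graphics::box()
    invisible(G)
}
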