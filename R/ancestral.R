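# Urancestral (root) proteome reconstruction on the rooted ToL.

#' Minimum-cost root state intervals per character
#'
#' Runs the ordered-character Sankoff/Farris down-pass on the rooted ToL
#' and returns, for every character (domain), the interval of root states
#' that attain the minimum tree length. For linearly ordered characters the
#' optimal root set is always a contiguous interval `[lower, upper]`.
#'
#' @param tree a rooted binary `ape::phylo` over the proteomes.
#' @param m a [CodedMatrix-class] in `"ToL"` orientation (characters are
#'   domains).
#' @return data.frame with columns `character`, `lower`, `upper`, `cost`
#'   (one row per character), carrying the coding provenance of `m` as
#'   attributes `gmax` and `scheme`.
#' @examples
#' st <- matrix(c(0L, 2L, 2L, 4L), 4, 1,
#'              dimnames = list(c("A", "B", "C", "D"), "c.37.1"))
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' tr <- ape::root(tr, outgroup = "A", resolve.root = TRUE)
#' rootStateIntervals(tr, CodedMatrix(st))
#' @export
rootStateIntervals <- function(tree, m) {
    if (orientation(m) != "ToL")
        stop("root-state reconstruction expects a ToL-oriented matrix ",
             "(taxa = proteomes, characters = domains); got ", orientation(m))
    if (!ape::is.rooted(tree))
        stop("tree is unrooted; root it first (see lundbergRoot)")
    st <- codedStates(m)
    if (is.null(colnames(st)))
        colnames(st) <- sprintf("char%03d", seq_len(ncol(st)))
    rt <- .rtFromPhylo(tree, rownames(st))
    dp <- .wagnerDownPass(rt$kids, rt$root, rt$ntip, st)
    out <- data.frame(character = colnames(st), lower = dp$lower,
                      upper = dp$upper, cost = dp$cost,
                      stringsAsFactors = FALSE)
    attr(out, "gmax") <- m@gmax
    attr(out, "scheme") <- m@scheme
    out
}

#' Urancestral repertoire under a stringency sweep
#'
#' Converts per-character root state intervals into the inferred repertoire
#' of the urancestor. A domain is deemed present at stringency `tau` when
#' the midpoint of its root interval (rounded down) reaches
#' `max(1, tau)`; sweeping `tau` yields a (conservative .. liberal) range
#' of repertoire sizes, the package's reading of iterative reconstruction
#' at multiple stringencies. `fsfCount` is the number of domains present;
#' `domainCount` decodes each present domain's midpoint state back to an
#' abundance (geometric bin midpoint under the log scheme, see
#' [decodeStates()]) and totals them.
#'
#' @param intervals data.frame from [rootStateIntervals()].
#' @param gmax,scheme coding provenance used to decode states; default to
#'   the attributes carried by `intervals`.
#' @param thresholds integer state cutoffs to sweep (default `1:23`).
#' @return data.frame with one row per threshold (`threshold`, `fsfCount`,
#'   `domainCount`), with the per-domain presence matrix (domains x
#'   thresholds) as attribute `presence`.
#' @export
urancestralRepertoire <- function(intervals, gmax = attr(intervals, "gmax"),
                                  scheme = attr(intervals, "scheme"),
                                  thresholds = 1:23) {
    if (is.null(intervals) || !nrow(intervals))
        stop("no root state intervals given")
    if (any(thresholds < 0 | thresholds > 23))
        stop("thresholds must lie in 0..23")
    if (is.null(scheme) || is.na(scheme)) scheme <- "log"
    mid <- floor((intervals$lower + intervals$upper) / 2)
    presence <- vapply(thresholds, function(tau) mid >= max(1, tau),
                       logical(nrow(intervals)))
    presence <- matrix(presence, nrow = nrow(intervals),
                       dimnames = list(intervals$character,
                                       as.character(thresholds)))
    decoded <- if (!is.null(gmax) && !is.na(gmax))
        decodeStates(mid, gmax = gmax, scheme = scheme) else rep(NA_real_,
                                                                 length(mid))
    out <- data.frame(
        threshold = thresholds,
        fsfCount = colSums(presence),
        domainCount = vapply(seq_along(thresholds), function(j)
            sum(decoded[presence[, j]]), 0),
        row.names = NULL)
    attr(out, "presence") <- presence
    out
}
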