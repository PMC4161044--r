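#' The 24-symbol ordered character alphabet
#'
#' Character states run 0..23 and are written with the alphanumeric scheme
#' `0`--`9` then `A`--`N`, in increasing order of abundance.
#'
#' @return Character vector of the 24 symbols, in state order.
#' @export
codingAlphabet <- function() c(as.character(0:9), LETTERS[1:14])

#' Convert between integer states and alphabet symbols
#'
#' A bijection between states `0..23` and the symbols `0-9`, `A-N`:
#' `0 <-> "0"`, `9 <-> "9"`, `10 <-> "A"`, `23 <-> "N"`.
#'
#' @param state integer vector of states in `0..23`.
#' @param symbol character vector of single symbols from the alphabet.
#' @return `stateToSymbol()`: character vector; `symbolToState()`: integer
#'   vector.
#' @examples
#' stateToSymbol(c(0, 9, 10, 23))   # "0" "9" "A" "N"
#' symbolToState(c("B", "N"))       # 11 23
#' @export
stateToSymbol <- function(state) {
    state <- as.integer(state)
    if (anyNA(state) || any(state < 0L | state > 23L))
        stop("states must lie in 0..23")
    codingAlphabet()[state + 1L]
}

#' @rdname stateToSymbol
#' @export
symbolToState <- function(symbol) {
    idx <- match(as.character(symbol), codingAlphabet())
    if (anyNA(idx))
        stop("symbol(s) outside the 0-9,A-N alphabet: ",
             paste(unique(symbol[is.na(idx)]), collapse = ", "))
    idx - 1L
}

#' Code an abundance census into ordered multistate characters
#'
#' Rescales abundances to the 24 states `0..23`. Under the default `"log"`
#' scheme `G = round(23 * ln(g + 1) / ln(gmax + 1))`; under `"linear"`,
#' `G = round(23 * g / gmax)`. Rounding is half away from zero. An abundance
#' of 0 always maps to state 0 (the gray cells of the heat map), and a
#' nonzero abundance never maps to state 0: under the linear scheme small
#' counts that would round down are clamped to state 1 so that
#' presence/absence survives the coding. `gmax` is the matrix-wide maximum,
#' mirroring the single colour scale of the heat map.
#'
#' The logarithmic default reflects that genomic domain abundances span
#' several orders of magnitude (census maxima above 10^4); linear rescaling
#' would collapse almost every cell onto the lowest states.
#'
#' @param census an [AbundanceCensus-class].
#' @param scheme `"log"` (default) or `"linear"`.
#' @param orientation orientation of the result; `"ToL"` (rows = proteomes)
#'   by default.
#' @return A [CodedMatrix-class].
#' @examples
#' cn <- matrix(c(0L, 100L, 15112L, 7L), 2, 2,
#'              dimnames = list(c("c.37.1", "d.58.7"), c("A01", "B01")))
#' m <- encodeCensus(AbundanceCensus(cn))
#' codedStates(m)
#' @export
encodeCensus <- function(census, scheme = c("log", "linear"),
                         orientation = "ToL") {
    scheme <- match.arg(scheme)
    g <- censusCounts(census, "proteomes")   # proteomes x domains
    if (any(g < 0)) stop("census contains negative counts")
    N <- gmax(census)
    if (N < 1L) {
        G <- g * 0L
    } else if (scheme == "log") {
        G <- .roundHalfUp(23 * log(g + 1) / log(N + 1))
    } else {
        G <- .roundHalfUp(23 * g / N)
    }
    G[g > 0 & G == 0] <- 1L      # presence must stay visible
    storage.mode(G) <- "integer"
    m <- CodedMatrix(G, orientation = "ToL", scheme = scheme, gmax = N)
    if (orientation == "ToD") t(m) else m
}

#' Decode character states back to representative abundances
#'
#' The coding is many-to-one, so exact inversion is impossible; each state
#' is decoded to the geometric midpoint of its abundance bin under the log
#' scheme (`(gmax+1)^(s/23) - 1`), or the linear midpoint (`s * gmax / 23`)
#' under the linear scheme, rounded half-up to an integer count. State 0
#' decodes to 0 and the top state 23 decodes to `gmax` exactly.
#'
#' @param states integer vector/matrix of states `0..23`.
#' @param gmax matrix-wide maximum abundance of the source census.
#' @param scheme `"log"` or `"linear"`.
#' @return Numeric abundances with the shape of `states`.
#' @export
decodeStates <- function(states, gmax, scheme = c("log", "linear")) {
    scheme <- match.arg(scheme)
    if (is.na(gmax)) stop("gmax is required to decode states")
    g <- if (scheme == "log") (gmax + 1)^(states / 23) - 1
         else states * gmax / 23
    out <- .roundHalfUp(g)
    out[states == 0] <- 0
    out[states > 0 & out == 0] <- 1
    out
}

#' @describeIn CodedMatrix transpose: swaps taxa and characters and flips
#'   the orientation flag between `"ToL"` and `"ToD"`. Transposing twice is
#'   the identity.
#' @param x a `CodedMatrix`.
#' @export
setMethod("t", "CodedMatrix", function(x) {
    new("CodedMatrix", states = t(x@states),
        orientation = if (x@orientation == "ToL") "ToD" else "ToL",
        scheme = x@scheme, gmax = x@gmax)
})
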