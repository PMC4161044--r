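# shared internal helpers

# Half-away-from-zero rounding. base::round() rounds half to even, which is
# platform-stable but surprises when coding abundances; the coding contract
# fixes half-up so encodings are identical everywhere.
.roundHalfUp <- function(x) floor(x + 0.5)

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
.withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

.assertCount <- function(x, field) {
    if (length(x) != 1L || is.na(x) || x < 0 || x != as.integer(x))
        stop(sprintf("'%s' must be a single non-negative integer", field),
             call. = FALSE)
    as.integer(x)
}

.assertRate <- function(x, field) {
    if (length(x) != 1L || is.na(x) || x < 0 || x > 1)
        stop(sprintf("'%s' must be a probability in [0, 1]", field),
             call. = FALSE)
    as.numeric(x)
}
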