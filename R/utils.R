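## Internal helpers: scoped RNG and argument checks.

# Run `expr` under a fixed seed without disturbing the caller's RNG state.
# Used by every stochastic generator so that a single master seed plus a
# component index fully determines output, independent of call order.
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
    force(expr)
}

# Deterministic substream seed for component k of a master seed.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
subSeed <- function(seed, k) {
    as.integer((as.numeric(seed) + 7919 * as.numeric(k)) %% 2147483647)
}

stopIfNot <- function(cond, msg, class = "bmq_error") {
    if (!isTRUE(cond)) {
        stop(structure(class = c(class, "error", "condition"),
                       list(message = msg, call = sys.call(-1))))
    }
    invisible(TRUE)
}

configError <- function(msg) {
    stop(structure(class = c("bmq_config_error", "bmq_error", "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
}

ioError <- function(msg) {
    stop(structure(class = c("bmq_io_error", "bmq_error", "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
}

alignmentError <- function(msg) {
    stop(structure(class = c("bmq_alignment_error", "bmq_error", "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
}

lookupError <- function(msg) {
    stop(structure(class = c("bmq_lookup_error", "bmq_error", "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
}

# HU are treated as integers downstream; round half away from zero.
roundHalfAwayFromZero <- function(x) {
    sign(x) * floor(abs(x) + 0.5)
}
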