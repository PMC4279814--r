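# Internal helpers shared across modules.

# Overlap extent between interval hulls [s1, e1] and [s2, e2], measured as
# min(end) - max(start): positive when the hulls properly overlap, 0 when
# they touch end-to-end, negative when separated. Event geometry and the
# reported donor-side overlap both use this convention.
.hullOverlap <- function(s1, e1, s2, e2) {
    pmin(e1, e2) - pmax(s1, s2)
}

# Gap between two interval hulls (0 when they overlap or touch).
.hullGap <- function(s1, e1, s2, e2) {
    pmax(0, pmax(s1, s2) - pmin(e1, e2))
}

# Unscaled median / median-absolute-deviation pair.
.medianMAD <- function(x) {
    m <- stats::median(x)
    list(M = m, MAD = stats::median(abs(x - m)))
}

# Run `expr` under a fixed RNG seed without clobbering the caller's stream.
.withSeed <- function(seed, expr) {
    if (is.null(seed))
        return(expr)
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has)
        old <- get(".Random.seed", envir = globalenv())
    set.seed(seed)
    on.exit({
        if (has)
            assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    expr
}

# Stable small integer sub-seed derived from a base seed, < 2^31.
.subSeed <- function(seed, k) {
    (as.numeric(seed) * 1009 + k * 9176) %% 2147483647
}

# Strand couple as a single key string, e.g. "-/+".
.orientKey <- function(a, b) paste(a, b, sep = "/")

# Named chromosome lengths of a DNAStringSet.
.chromLens <- function(genome) {
    stats::setNames(as.integer(Biostrings::width(genome)), names(genome))
}

.checkColumns <- function(df, need, what = "mapping table") {
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop(sprintf("%s lacks required column(s): %s", what,
                     paste(miss, collapse = ", ")), call. = FALSE)
    invisible(TRUE)
}
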