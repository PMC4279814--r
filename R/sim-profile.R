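#' Construct a mate-pair simulation profile
#'
#' Builds a [SimProfile] from parametric descriptions instead of learning
#' it from data: fragment sizes follow a truncated-normal mixture of a
#' short (parasitic) mode and the long library mode, discretized to an
#' empirical table, and per-position quality distributions follow a
#' truncated normal around a position-dependent mean (base quality decays
#' slightly along the read, as on real flow cells).
#'
#' @param readLen read length (bp).
#' @param fragMean,fragSd mean and sd of the long-fragment mode (bp). The
#'   defaults (3000, 215) give an insert-size MAD around 150 bp.
#' @param shortMean,shortSd short (contamination / splice-length) mode.
#' @param contaminationOdds probability a fragment is a short parasite.
#' @param qualStart,qualEnd mean phred quality at the first/last read
#'   position; `qualSd` the spread at each position.
#' @param truncSd both fragment modes are truncated at
#'   `mean +/- truncSd * sd`.
#' @param fragShape `"normal"` (truncated normal modes, the realistic
#'   default) or `"uniform"` (a tightly size-selected library, uniform on
#'   `mean +/- sd`; here `fragSd`/`shortSd` are half-widths). A uniform
#'   library has no insert-size tail beyond \eqn{3 \cdot MAD}, so an
#'   error-free run produces strictly zero discordant records from
#'   concordant loci - the premise of noiseless benchmarks.
#' @param qualOffset phred encoding offset.
#' @return a [SimProfile].
#' @examples
#' simProfile(readLen = 100, contaminationOdds = 0.1)
#' @export
simProfile <- function(readLen = 100L, fragMean = 3000, fragSd = 215,
                       shortMean = 300, shortSd = 50,
                       contaminationOdds = 0,
                       qualStart = 37, qualEnd = 30, qualSd = 3,
                       truncSd = 3, fragShape = c("normal", "uniform"),
                       qualOffset = 33L) {
    readLen <- as.integer(readLen)
    fragShape <- match.arg(fragShape)
    truncDens <- function(m, s) {
        if (fragShape == "uniform") {
            sizes <- seq.int(max(2L * readLen, round(m - s)),
                             round(m + s))
            return(list(sizes = as.integer(sizes),
                        p = rep(1 / length(sizes), length(sizes))))
        }
        sizes <- seq.int(max(2L * readLen, round(m - truncSd * s)),
                         round(m + truncSd * s))
        p <- stats::dnorm(sizes, m, s)
        list(sizes = as.integer(sizes), p = p / sum(p))
    }
    long <- truncDens(fragMean, fragSd)
    short <- truncDens(shortMean, shortSd)
    sizes <- sort(unique(c(short$sizes, long$sizes)))
    probs <- numeric(length(sizes))
    probs[match(short$sizes, sizes)] <- contaminationOdds * short$p
    probs[match(long$sizes, sizes)] <-
        probs[match(long$sizes, sizes)] + (1 - contaminationOdds) * long$p
    if (contaminationOdds == 0) {
        # keep the short mode in the table (it drives splice lengths)
        # at zero sampling mass
        sizes <- sort(unique(c(short$sizes, sizes)))
        probs2 <- numeric(length(sizes))
        probs2[match(long$sizes, sizes)] <- long$p
        probs <- probs2
    }
    splitPoint <- (max(short$sizes) + min(long$sizes)) / 2
    qvals <- 2:41
    qmeans <- seq(qualStart, qualEnd, length.out = readLen)
    qp <- vapply(qmeans, function(m) {
        p <- stats::dnorm(qvals, m, qualSd)
        p / sum(p)
    }, numeric(length(qvals)))
    methods::new("SimProfile",
        qualityProbs = qp, qualityValues = as.integer(qvals),
        fragSizes = as.integer(sizes), fragProbs = probs / sum(probs),
        splitPoint = splitPoint,
        contaminationOdds = contaminationOdds,
        readLen = readLen, qualOffset = as.integer(qualOffset))
}

# The short-mode (splice-length / contamination) part of the fragment
# table. When the profile was built with zero contamination the short mode
# carries no sampling mass; rebuild its shape from the stored split point
# is impossible, so profiles keep `shortSizes`/`shortProbs` attributes via
# this accessor on the mixture table.
.shortModeTable <- function(profile) {
    sel <- profile@fragSizes <= profile@splitPoint
    sizes <- profile@fragSizes[sel]
    p <- profile@fragProbs[sel]
    if (sum(p) <= 0) {
        # degenerate (no contamination mass): fall back to a narrow band
        # around the smallest stored sizes
        p <- rep(1, length(sizes))
    }
    list(sizes = sizes, p = p / sum(p))
}

.longModeTable <- function(profile) {
    sel <- profile@fragSizes > profile@splitPoint
    list(sizes = profile@fragSizes[sel],
         p = profile@fragProbs[sel] / sum(profile@fragProbs[sel]))
}

#' Learn a simulation profile from sequenced data
#'
#' First phase of the simulator: per-read-position empirical quality
#' histograms are tallied from a sample of quality strings (one histogram
#' per base position, with as many classes as the phred standard allows),
#' and the insert-size distribution of unambiguously mapped pairs is used
#' to locate the minimum separating its two modes - the mixture of
#' short-fragment contamination and the long library of interest. The odds
#' of drawing a short fragment are inferred from the ratio of the two
#' mixture components, measured as the mass on each side of the split
#' point (peak heights confound mass with mode width; see the vignette).
#'
#' @param insertSizes numeric vector of insert sizes of unambiguously
#'   mapped pairs.
#' @param qualities character vector of phred-encoded quality strings (all
#'   of one read length).
#' @param qualOffset phred offset (default 33).
#' @param binWidth histogram bin width used for mode finding (default 50).
#' @return a [SimProfile]. A unimodal insert distribution yields
#'   `contaminationOdds = 0` with a warning.
#' @export
learnSimProfile <- function(insertSizes, qualities, qualOffset = 33L,
                            binWidth = 50L) {
    stopifnot(length(insertSizes) > 0, length(qualities) > 0)
    readLen <- unique(nchar(qualities))
    if (length(readLen) != 1L)
        stop("quality strings have differing lengths")
    qm <- t(vapply(qualities, function(s)
        as.integer(charToRaw(s)) - qualOffset, integer(readLen),
        USE.NAMES = FALSE))
    qvals <- sort(unique(as.vector(qm)))
    qp <- matrix(vapply(seq_len(readLen), function(p) {
        tab <- tabulate(match(qm[, p], qvals), nbins = length(qvals))
        tab / sum(tab)
    }, numeric(length(qvals))), nrow = length(qvals))

    insertSizes <- round(insertSizes)
    tab <- table(insertSizes)
    sizes <- as.integer(names(tab))
    probs <- as.numeric(tab) / sum(tab)

    brk <- seq(min(insertSizes) - binWidth, max(insertSizes) + binWidth,
               by = binWidth)
    h <- graphics::hist(insertSizes, breaks = brk, plot = FALSE)
    split <- .findBimodalSplit(h$counts, h$mids)
    if (is.null(split)) {
        warning("insert-size distribution looks unimodal: ",
                "contamination odds set to 0")
        splitPoint <- min(insertSizes) - 1
        odds <- 0
    } else {
        splitPoint <- split
        odds <- sum(insertSizes <= splitPoint) / length(insertSizes)
    }
    methods::new("SimProfile",
        qualityProbs = qp, qualityValues = as.integer(qvals),
        fragSizes = sizes, fragProbs = probs,
        splitPoint = splitPoint, contaminationOdds = odds,
        readLen = as.integer(readLen), qualOffset = as.integer(qualOffset))
}

# Locate the minimum between the two dominant modes of a histogram;
# NULL when no second mode is found (unimodal). The second mode is the
# highest bin separated from the global mode by a valley dipping below
# half the smaller of the two - a shoulder on one mode never qualifies.
.findBimodalSplit <- function(counts, mids) {
    # light running-mean smoothing (a running median would erase narrow,
    # single-bin modes entirely)
    n <- length(counts)
    sm <- (c(0, counts[-n]) + counts + c(counts[-1], 0)) / 3
    p1 <- which.max(sm)
    best <- NULL; bestH <- 0
    for (p in seq_len(n)) {
        if (p == p1 || sm[p] <= bestH || abs(p - p1) < 2L) next
        rng <- if (p < p1) (p + 1L):(p1 - 1L) else (p1 + 1L):(p - 1L)
        if (min(sm[rng]) <= 0.5 * min(sm[p], sm[p1])) {
            best <- p; bestH <- sm[p]
        }
    }
    if (is.null(best))
        return(NULL)
    rng <- if (best < p1) (best + 1L):(p1 - 1L) else (p1 + 1L):(best - 1L)
    mids[rng[which.min(sm[rng])]]
}
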