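#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Insert-size statistics of a sequencing library
#'
#' Robust summary of the insert-size distribution of a paired library:
#' the median \eqn{M}, the unscaled median absolute deviation \eqn{MAD}
#' (no 1.4826 consistency factor), and the derived concordance limits
#' \eqn{d_{inf} = M - 3 \cdot MAD} and \eqn{d_{sup} = M + 3 \cdot MAD}.
#' A pair mapping on one chromosome, in the library's proper orientation,
#' with insert size strictly inside \eqn{(d_{inf}, d_{sup})} is concordant;
#' everything else carries a discordance signature.
#'
#' @slot median median insert size \eqn{M} (bp).
#' @slot mad unscaled median absolute deviation of the insert size (bp).
#' @slot dInf lower concordance limit \eqn{M - 3 \cdot MAD} (bp).
#' @slot dSup upper concordance limit \eqn{M + 3 \cdot MAD} (bp).
#' @slot properOrient length-2 character, expected orientation couple of a
#'   concordant pair after relabelling mates so that the first has the
#'   smaller coordinate. `c("-", "+")` for a circularization (mate-pair)
#'   library, `c("+", "-")` for a standard short-fragment FR library.
#' @slot degenerate logical; `TRUE` when `mad == 0`, in which case every
#'   non-median insert is discordant and the limits are uninformative.
#' @slot n number of insert sizes the estimate was computed from.
#'
#' @seealso [estimateLibraryStats()], [classifyPairs()]
#' @export
setClass("LibraryStats",
    representation(
        median = "numeric",
        mad = "numeric",
        dInf = "numeric",
        dSup = "numeric",
        properOrient = "character",
        degenerate = "logical",
        n = "integer"
    ),
    prototype(
        properOrient = c("-", "+"),
        degenerate = FALSE,
        n = 0L
    )
)

setValidity("LibraryStats", function(object) {
    msg <- character()
    if (length(object@median) != 1L || length(object@mad) != 1L)
        msg <- c(msg, "'median' and 'mad' must be single values")
    if (object@mad < 0)
        msg <- c(msg, "'mad' must be non-negative")
    if (!isTRUE(all.equal(object@dInf, object@median - 3 * object@mad)))
        msg <- c(msg, "'dInf' must equal median - 3*mad")
    if (!isTRUE(all.equal(object@dSup, object@median + 3 * object@mad)))
        msg <- c(msg, "'dSup' must equal median + 3*mad")
    if (length(object@properOrient) != 2L ||
        !all(object@properOrient %in% c("+", "-")))
        msg <- c(msg, "'properOrient' must be two strands")
    if (length(msg)) msg else TRUE
})

#' Discordant read-pair mapping records
#'
#' Container for the discordance-extraction stage output: one row per
#' retained pair mapping of a discordant fragment, with both mate
#' coordinates (relabelled so mate A precedes mate B), the insert size
#' where defined, and the discordance signature. A fragment contributes
#' rows only when none of its mate-mapping combinations is concordant,
#' in which case every combination is recorded as if it were a unique
#' mapping from a separate pair.
#'
#' @slot records a [S4Vectors::DataFrame] with columns `pairId`, `chromA`,
#'   `posA`, `orientA`, `chromB`, `posB`, `orientB`, `insert`, `signature`,
#'   `nmA`, `nmB`, `width`.
#' @slot stats the [LibraryStats] used for classification.
#' @slot counters named integer vector of bookkeeping counts (fragments
#'   seen, concordant fragments dropped, orphan reads skipped, records
#'   masked by the coverage filter, combination-capped fragments).
#'
#' @seealso [extractDiscordantPairs()]
#' @export
setClass("DiscordantPairs",
    representation(
        records = "DataFrame",
        stats = "LibraryStats",
        counters = "integer"
    )
)

setValidity("DiscordantPairs", function(object) {
    need <- c("pairId", "chromA", "posA", "orientA",
              "chromB", "posB", "orientB", "insert", "signature")
    miss <- setdiff(need, colnames(object@records))
    if (length(miss))
        return(paste("missing record columns:", paste(miss, collapse = ", ")))
    TRUE
})

#' Transposition event calls
#'
#' One row per (acceptor, donor candidate) couple. Lines that refer to
#' different donor candidates of the same insertion share an `acceptorId`.
#' Coordinates are 1-based inclusive.
#'
#' @slot calls a [S4Vectors::DataFrame] with columns `acceptorId`,
#'   `eventType` (`insertion_sense`, `insertion_antisense`,
#'   `insertion_interchrom`, `deletion`), `acceptorChrom`, `acceptorStart`,
#'   `acceptorEnd`, `acceptorSize`, `donorChrom`, `donorStart`, `donorEnd`,
#'   `donorSize`, `overlap` (donor-side cluster overlap, bp), `support`
#'   (distinct supporting fragments), `inverted`, `companionDel` (advisory:
#'   a further deletion-signature cluster at the donor, the cut-and-paste
#'   footprint). Annotation and scoring may append `donorAnnotation`,
#'   `acceptorAnnotation`, `donorScore`, `ambiguousDonor`.
#' @slot params list of run metadata (grid, thresholds, seed point,
#'   removed lines, stage counters).
#'
#' @seealso [callEvents()], [runGrid()], [mergeGridResults()]
#' @export
setClass("TranspositionCalls",
    representation(calls = "DataFrame", params = "list"),
    prototype(params = list())
)

#' Mate-pair simulation profile
#'
#' Learned (or declared) model of a long-fragment circularization library:
#' per-read-position empirical quality distributions, the empirical
#' fragment-size distribution (a mixture of the short parasitic mode and
#' the long library mode), the split point at the minimum separating the
#' two modes, and the odds that a random fragment is a short contaminant.
#'
#' @slot qualityProbs numeric matrix, rows = quality values (phred),
#'   columns = read positions; each column sums to 1.
#' @slot qualityValues integer vector of the phred values indexing the rows.
#' @slot fragSizes integer vector of fragment sizes with non-zero mass.
#' @slot fragProbs numeric vector, same length, summing to 1.
#' @slot splitPoint fragment size at the minimum separating the two modes;
#'   sizes `<= splitPoint` belong to the short mode. Splice lengths during
#'   circularization are drawn from the short mode.
#' @slot contaminationOdds probability that a drawn fragment is a short
#'   parasitic fragment.
#' @slot readLen read length (bp).
#' @slot qualOffset phred encoding offset (33 or 64).
#'
#' @seealso [simProfile()], [learnSimProfile()], [simulateMatePairs()]
#' @export
setClass("SimProfile",
    representation(
        qualityProbs = "matrix",
        qualityValues = "integer",
        fragSizes = "integer",
        fragProbs = "numeric",
        splitPoint = "numeric",
        contaminationOdds = "numeric",
        readLen = "integer",
        qualOffset = "integer"
    ),
    prototype(qualOffset = 33L)
)

setValidity("SimProfile", function(object) {
    msg <- character()
    if (ncol(object@qualityProbs) != object@readLen)
        msg <- c(msg, "qualityProbs must have one column per read position")
    if (nrow(object@qualityProbs) != length(object@qualityValues))
        msg <- c(msg, "qualityProbs rows must match qualityValues")
    if (any(abs(colSums(object@qualityProbs) - 1) > 1e-6))
        msg <- c(msg, "each qualityProbs column must sum to 1")
    if (length(object@fragSizes) != length(object@fragProbs))
        msg <- c(msg, "fragSizes and fragProbs lengths differ")
    if (abs(sum(object@fragProbs) - 1) > 1e-6)
        msg <- c(msg, "fragProbs must sum to 1")
    if (object@contaminationOdds < 0 || object@contaminationOdds > 1)
        msg <- c(msg, "contaminationOdds must be in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Synthetic reference genome with annotated TE copies
#'
#' @slot genome a [Biostrings::DNAStringSet], one entry per chromosome.
#' @slot annotation a [GenomicRanges::GRanges] of TE copies with metadata
#'   columns `Name` (unique copy name) and `family`.
#'
#' @seealso [simulateTEGenome()]
#' @export
setClass("TEGenome",
    representation(genome = "DNAStringSet", annotation = "GRanges")
)

#' Truth table of injected transposition events
#'
#' Result of injecting planned copy-and-paste events into a reference:
#' the modified genome that was "sequenced", the per-event truth record
#' and the coordinate map linking modified to original coordinates.
#'
#' @slot events a [S4Vectors::DataFrame]; one row per injected event with
#'   columns `eventClass`, `donorChrom`, `donorStart`, `donorEnd`,
#'   `acceptorChrom`, `acceptorPos`, `inverted`, `tsdLen`, plus the
#'   modified-frame block coordinates `blockStart`, `blockEnd`.
#' @slot modifiedGenome the tampered [Biostrings::DNAStringSet].
#' @slot original the untouched reference.
#'
#' @seealso [injectTranspositions()], [evaluateCalls()]
#' @export
setClass("TranspositionTruth",
    representation(
        events = "DataFrame",
        modifiedGenome = "DNAStringSet",
        original = "DNAStringSet"
    )
)

setValidity("TranspositionTruth", function(object) {
    ev <- object@events
    added <- sum(ev$donorEnd - ev$donorStart + 1L + ev$tsdLen)
    if (sum(lengths(object@modifiedGenome)) !=
        sum(lengths(object@original)) + added)
        return("modified genome length must equal original + sum(donor span + tsd)")
    TRUE
})
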