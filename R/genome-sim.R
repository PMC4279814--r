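#' Simulate a reference genome carrying annotated TE families
#'
#' Builds a random multi-chromosome genome and plants copies of synthetic
#' TE families in it. Family members are derived from one consensus per
#' family with a per-copy number of substitutions, so families contain
#' near-identical members - the situation that makes donor attribution
#' hard. The default layout emulates a compact plant-like genome: two 1 Mb
#' chromosomes; family `TEA` with three 3 kb copies, two of them byte
#' identical and one differing by 5 substitutions; two shorter families
#' `TEB` and `TEC` whose first copies sit adjacent (separated by a 100 bp
#' spacer), the way real composite elements juxtapose members of
#' *different* families.
#'
#' @param chromLengths named integer vector of chromosome lengths.
#' @param families list describing each family:
#'   `list(length =, copies =, subs =)` where `subs` gives per-copy
#'   substitution counts relative to the family consensus.
#' @param tandemPair character(2): one copy of each named family is
#'   placed adjacently (spacer `tandemGap`), providing a contiguous
#'   multi-TE block for composite events. `NULL` disables.
#' @param tandemGap spacer between the tandem copies (bp).
#' @param minSeparation minimum distance between planted copies and from
#'   chromosome ends (bp).
#' @param seed RNG seed.
#' @return a [TEGenome]: the genome plus a TE annotation with `Name` and
#'   `family` columns.
#' @export
simulateTEGenome <- function(
        chromLengths = c(chr1 = 1e6, chr2 = 1e6),
        families = list(
            TEA = list(length = 3000L, copies = 3L, subs = c(0L, 0L, 5L)),
            TEB = list(length = 1500L, copies = 3L, subs = c(0L, 3L, 4L)),
            TEC = list(length = 1200L, copies = 2L, subs = c(0L, 3L))),
        tandemPair = c("TEB", "TEC"), tandemGap = 100L,
        minSeparation = 20000L, seed = 1L) {
    .withSeed(seed, {
        chroms <- lapply(chromLengths, .randomDNA)
        names(chroms) <- names(chromLengths)
        consensi <- lapply(families, function(spec) .randomDNA(spec$length))
        anno <- list()
        reserved <- lapply(chromLengths, function(len) IRanges::IRanges())
        chromCycle <- rep(names(chromLengths), length.out = 50L)
        ci <- 0L
        put <- function(chr, at, fam, copyIdx) {
            spec <- families[[fam]]
            copy <- .mutateDNA(consensi[[fam]], spec$subs[copyIdx])
            chroms[[chr]] <<- Biostrings::replaceAt(chroms[[chr]],
                IRanges::IRanges(at, width = spec$length), copy)
            anno[[length(anno) + 1L]] <<- data.frame(
                chrom = chr, start = at, end = at + spec$length - 1L,
                Name = sprintf("%s_%d", fam, copyIdx), family = fam)
        }
        done <- stats::setNames(rep(0L, length(families)), names(families))
        if (!is.null(tandemPair)) {
            f1 <- tandemPair[1]; f2 <- tandemPair[2]
            span <- families[[f1]]$length + tandemGap +
                families[[f2]]$length
            ci <- ci + 1L
            chr <- chromCycle[ci]
            pos <- .placeInterval(chromLengths[[chr]], span,
                                  reserved[[chr]], minSeparation)
            reserved[[chr]] <- c(reserved[[chr]],
                                 IRanges::IRanges(pos, width = span))
            put(chr, pos, f1, 1L)
            put(chr, pos + families[[f1]]$length + tandemGap, f2, 1L)
            done[f1] <- 1L; done[f2] <- 1L
        }
        for (fam in names(families)) {
            spec <- families[[fam]]
            for (k in seq_len(spec$copies)) {
                if (k <= done[fam]) next
                ci <- ci + 1L
                chr <- chromCycle[ci]
                pos <- .placeInterval(chromLengths[[chr]], spec$length,
                                      reserved[[chr]], minSeparation)
                reserved[[chr]] <- c(reserved[[chr]],
                    IRanges::IRanges(pos, width = spec$length))
                put(chr, pos, fam, k)
            }
        }
        annoDf <- do.call(rbind, anno)
        gr <- GenomicRanges::GRanges(annoDf$chrom,
            IRanges::IRanges(annoDf$start, annoDf$end),
            Name = annoDf$Name, family = annoDf$family,
            seqlengths = chromLengths)
        gr <- GenomicRanges::sort(gr)
        methods::new("TEGenome",
            genome = Biostrings::DNAStringSet(chroms),
            annotation = gr)
    })
}

.randomDNA <- function(len) {
    Biostrings::DNAString(paste(
        sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""))
}

# Substitute `n` distinct positions with a different base each.
.mutateDNA <- function(x, n) {
    if (n == 0L)
        return(x)
    at <- sort(sample.int(length(x), n))
    old <- strsplit(as.character(Biostrings::extractAt(
        x, IRanges::IRanges(at, at))), "")
    repl <- vapply(unlist(old), function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    Biostrings::replaceAt(x, IRanges::IRanges(at, at),
                          Biostrings::DNAStringSet(repl))
}

# Draw a start position for an interval of width `span` keeping
# `minSeparation` away from reserved intervals and chromosome ends.
.placeInterval <- function(chromLen, span, reserved, minSeparation,
                           maxTries = 1000L) {
    for (t in seq_len(maxTries)) {
        pos <- sample.int(chromLen - span - 2L * minSeparation, 1L) +
            minSeparation
        cand <- IRanges::IRanges(pos - minSeparation,
                                 pos + span + minSeparation)
        if (!length(reserved) ||
            !any(IRanges::overlapsAny(cand, reserved)))
            return(pos)
    }
    stop("could not place an interval of width ", span,
         "; reduce copy count or separation")
}

#' Plan a set of transposition events
#'
#' Draws donors from the annotated TE copies and acceptor positions from
#' unique sequence, producing one truth record per planned event. The four
#' event classes mirror the ways real elements mobilize:
#' \describe{
#'   \item{normal}{the exact span of one annotated copy;}
#'   \item{composite}{a block spanning \eqn{\ge 2} contiguous annotated
#'     copies (adjacent within `contigGap`);}
#'   \item{long}{one copy plus a uniform 100-600 bp flank on each side
#'     (mis-annotated or extended elements);}
#'   \item{short}{a uniform 30-70% interior sub-span of one copy
#'     (truncated mobilization).}
#' }
#' Donor spans are capped at `maxSpan` so that every event stays below the
#' \eqn{2L} detectability bound of the library; acceptors avoid annotated
#' TEs, chromosome ends and one another, so each injected breakpoint has
#' unique flanking sequence.
#'
#' @param teGenome a [TEGenome].
#' @param counts named integer vector of events per class.
#' @param L mean fragment length of the intended library (bp).
#' @param tsdLen target-site-duplication length (bp, default 5).
#' @param invertedProb probability an event inserts in reverse complement.
#' @param maxSpan donor-span cap (default `2 * L - 1000`).
#' @param contigGap maximum gap defining "contiguous" TEs (default 300).
#' @param minSeparation minimum distance between acceptors and from any
#'   annotated TE (default `2 * L`).
#' @param seed RNG seed.
#' @return data.frame of planned events (`eventClass`, donor and acceptor
#'   coordinates, `inverted`, `tsdLen`).
#' @export
planTranspositions <- function(teGenome,
        counts = c(normal = 5L, composite = 5L, long = 5L, short = 5L),
        L = 3000, tsdLen = 5L, invertedProb = 0.3,
        maxSpan = 2 * L - 1000, contigGap = 300L,
        minSeparation = 2 * L, seed = 1L) {
    anno <- teAnnotation(teGenome)
    lens <- .chromLens(refGenome(teGenome))
    .withSeed(seed, {
        runs <- .contiguousRuns(anno, contigGap)
        plans <- list()
        for (cls in names(counts)) {
            for (k in seq_len(counts[[cls]])) {
                donor <- .drawDonor(cls, anno, runs, maxSpan)
                plans[[length(plans) + 1L]] <- donor
                plans[[length(plans)]]$eventClass <- cls
            }
        }
        plan <- do.call(rbind, plans)
        plan$inverted <- stats::runif(nrow(plan)) < invertedProb
        plan$tsdLen <- as.integer(tsdLen)
        # acceptors in unique sequence, mutually separated
        keepOut <- GenomicRanges::resize(anno,
            GenomicRanges::width(anno) + 2L * minSeparation, fix = "center")
        accChrom <- character(nrow(plan))
        accPos <- integer(nrow(plan))
        for (i in seq_len(nrow(plan))) {
            repeat {
                chr <- sample(names(lens), 1L)
                pos <- sample.int(lens[[chr]] - 4L * minSeparation, 1L) +
                    2L * minSeparation
                cand <- GenomicRanges::GRanges(chr,
                    IRanges::IRanges(pos - minSeparation,
                                     pos + minSeparation))
                prior <- accChrom == chr & accPos > 0L
                if (!IRanges::overlapsAny(cand, keepOut) &&
                    (!any(prior) ||
                     min(abs(accPos[prior] - pos)) > 2L * minSeparation))
                    break
            }
            accChrom[i] <- chr
            accPos[i] <- pos
        }
        plan$acceptorChrom <- accChrom
        plan$acceptorPos <- accPos
        rownames(plan) <- NULL
        plan
    })
}

# Runs of annotation copies lying within `contigGap` of each other.
.contiguousRuns <- function(anno, contigGap) {
    red <- GenomicRanges::reduce(anno, min.gapwidth = contigGap + 1L,
                                 with.revmap = TRUE)
    red[lengths(red$revmap) >= 2L]
}

# lower detectability bound applied to "short" donor sub-spans (bp)
.minShortSpan <- 600L

.drawDonor <- function(cls, anno, runs, maxSpan) {
    pickCopy <- function(maxLen = Inf, minLen = 0L) {
        ok <- which(GenomicRanges::width(anno) <= maxLen &
                    GenomicRanges::width(anno) >= minLen)
        if (!length(ok))
            stop("no annotated copy fits the requested span range")
        anno[sample(rep(ok, 2L), 1L)]
    }
    if (cls == "normal") {
        a <- pickCopy(maxSpan)
        data.frame(donorChrom = as.character(GenomicRanges::seqnames(a)),
                   donorStart = GenomicRanges::start(a),
                   donorEnd = GenomicRanges::end(a))
    } else if (cls == "composite") {
        ok <- which(GenomicRanges::width(runs) <= maxSpan)
        if (!length(ok))
            stop("no contiguous TE run fits under the donor-span cap")
        r <- runs[sample(rep(ok, 2L), 1L)]
        data.frame(donorChrom = as.character(GenomicRanges::seqnames(r)),
                   donorStart = GenomicRanges::start(r),
                   donorEnd = GenomicRanges::end(r))
    } else if (cls == "long") {
        a <- pickCopy(maxSpan - 200L)
        room <- maxSpan - GenomicRanges::width(a)
        fl <- sample(100:600, 2L, replace = TRUE)
        while (sum(fl) > room)
            fl <- sample(100:600, 2L, replace = TRUE)
        data.frame(donorChrom = as.character(GenomicRanges::seqnames(a)),
                   donorStart = GenomicRanges::start(a) - fl[1],
                   donorEnd = GenomicRanges::end(a) + fl[2])
    } else if (cls == "short") {
        # sub-spans below ~minShortSpan are outside the method's
        # detectability envelope: the acceptor-side clusters of a donor of
        # length T stop ~(F_min - T) short of the junction on each side,
        # so the breakpoint gap exceeds the insert-size dispersion for
        # very small T (see vignette)
        a <- pickCopy(minLen = .minShortSpan + 100L)
        w <- GenomicRanges::width(a)
        frac <- stats::runif(1, 0.3, 0.7)
        sub <- min(w - 2L, max(.minShortSpan, round(w * frac)))
        off <- sample.int(w - sub - 1L, 1L)
        data.frame(donorChrom = as.character(GenomicRanges::seqnames(a)),
                   donorStart = GenomicRanges::start(a) + off,
                   donorEnd = GenomicRanges::start(a) + off + sub - 1L)
    } else {
        stop("unknown event class: ", cls)
    }
}

#' Inject planned transposition events into the reference
#'
#' Copy-and-paste injection: for each planned event the donor span is
#' copied (reverse-complemented when `inverted`), prefixed with a
#' duplicate of the `tsdLen` bases immediately following the acceptor
#' position, and inserted after that position, so the new copy sits
#' between two direct repeats of the target site - the canonical
#' target-site duplication left by a real transposition. All donors are
#' read from the *original* sequence, so earlier insertions never corrupt
#' later donors.
#'
#' @param teGenome a [TEGenome].
#' @param plan planned events from [planTranspositions()], or a list
#'   `(counts, seed, ...)` forwarded to the planner.
#' @return a [TranspositionTruth] holding the modified genome and the
#'   truth table with both original-frame (`acceptorPos`) and
#'   modified-frame (`blockStart`, `blockEnd`, spanning duplicate TSD plus
#'   element) coordinates. In explicit-plan mode an acceptor falling
#'   inside another planned insertion is an error.
#' @export
injectTranspositions <- function(teGenome, plan) {
    if (!is.data.frame(plan))
        plan <- do.call(planTranspositions, c(list(teGenome), plan))
    genome <- refGenome(teGenome)
    need <- c("donorChrom", "donorStart", "donorEnd", "acceptorChrom",
              "acceptorPos", "inverted", "tsdLen")
    .checkColumns(plan, need, "event plan")
    if (is.null(plan$eventClass))
        plan$eventClass <- "normal"
    plan <- plan[order(match(plan$acceptorChrom, names(genome)),
                       plan$acceptorPos), , drop = FALSE]
    plan$blockStart <- NA_integer_
    plan$blockEnd <- NA_integer_
    modified <- genome
    for (chr in unique(plan$acceptorChrom)) {
        rows <- which(plan$acceptorChrom == chr)
        pos <- plan$acceptorPos[rows]
        if (anyDuplicated(pos))
            stop("two events share acceptor position on ", chr)
        blocks <- lapply(rows, function(i) {
            donor <- Biostrings::subseq(genome[[plan$donorChrom[i]]],
                                        plan$donorStart[i], plan$donorEnd[i])
            if (plan$inverted[i])
                donor <- Biostrings::reverseComplement(donor)
            tsd <- Biostrings::subseq(genome[[chr]],
                plan$acceptorPos[i] + 1L,
                plan$acceptorPos[i] + plan$tsdLen[i])
            ds <- Biostrings::DNAStringSet(list(tsd, donor))
            Biostrings::DNAString(unlist(ds))
        })
        blockLens <- vapply(blocks, length, integer(1))
        modified[[chr]] <- Biostrings::replaceAt(genome[[chr]],
            IRanges::IRanges(start = pos + 1L, width = 0L),
            Biostrings::DNAStringSet(blocks))
        shift <- cumsum(c(0L, blockLens[-length(blockLens)]))
        plan$blockStart[rows] <- pos + shift + 1L
        plan$blockEnd[rows] <- pos + shift + blockLens
    }
    methods::new("TranspositionTruth",
        events = S4Vectors::DataFrame(plan),
        modifiedGenome = modified,
        original = genome)
}
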