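#' Filter alignments on the edit distance of each read's best mapping
#'
#' Drops a read entirely when its best mapping carries more than
#' `maxMismatch` mismatches, and removes the individual mappings above the
#' threshold from the reads that are retained. Run before any discordance
#' analysis: a breakpoint signal supported only by poorly matching mappings
#' is overwhelmingly a mapping artefact.
#'
#' @param maps mapping table: one row per mapping with columns `pairId`,
#'   `mate` (1 or 2), `chrom`, `pos` (1-based leftmost), `strand`, `nm`
#'   (edit distance) and `width` (aligned read length). See
#'   [readPairAlignments()] and [placeReads()].
#' @param maxMismatch maximum tolerated edit distance (default 1).
#' @param missingNM policy for mappings with `NA` edit distance: `"drop"`
#'   (default; treated as failing the filter, with a warning) or `"keep"`.
#' @return the filtered mapping table.
#' @examples
#' maps <- data.frame(pairId = 1L, mate = c(1L, 2L, 2L), chrom = "chr1",
#'                    pos = c(100L, 5000L, 9000L), strand = c("-", "+", "+"),
#'                    nm = c(0L, 1L, 3L), width = 100L)
#' filterMappings(maps)  # the nm = 3 mapping is removed
#' @export
filterMappings <- function(maps, maxMismatch = 1L,
                           missingNM = c("drop", "keep")) {
    missingNM <- match.arg(missingNM)
    .checkColumns(maps, c("pairId", "mate", "chrom", "pos", "strand", "nm"))
    stopifnot(maxMismatch >= 0)
    if (!nrow(maps))
        return(maps)
    nm <- maps$nm
    if (anyNA(nm)) {
        if (missingNM == "drop") {
            warning(sum(is.na(nm)),
                    " mapping(s) without an edit distance treated as",
                    " failing the mismatch filter")
            nm[is.na(nm)] <- maxMismatch + 1L
        } else {
            nm[is.na(nm)] <- 0L
        }
    }
    dt <- data.table::data.table(
        readKey = paste(maps$pairId, maps$mate, sep = "\r"), nm = nm)
    best <- dt[, list(best = min(nm)), by = "readKey"]
    badRead <- best$readKey[best$best > maxMismatch]
    keep <- !(dt$readKey %in% badRead) & nm <= maxMismatch
    maps[keep, , drop = FALSE]
}

#' Estimate robust insert-size statistics of a paired library
#'
#' Computes the median insert size \eqn{M}, the unscaled median absolute
#' deviation \eqn{MAD}, and the concordance limits
#' \eqn{d_{inf} = M - 3 \cdot MAD}, \eqn{d_{sup} = M + 3 \cdot MAD} from a
#' sample of pair mappings. When a mapping table is supplied, the sample is
#' restricted to fragments where both mates map uniquely on the same
#' chromosome in the library's proper orientation, taking the first
#' `sampleSize` such inserts in file order.
#'
#' @param x either a numeric vector of insert sizes, or a mapping table
#'   (see [filterMappings()]).
#' @param sampleSize maximum number of inserts used (default `1e6`).
#' @param properOrient expected orientation couple of a concordant pair
#'   after the mates are relabelled by coordinate; `c("-", "+")` for a
#'   mate-pair (circularization) library, `c("+", "-")` for paired-end FR.
#' @return a [LibraryStats] object. When all inserts are identical the
#'   `degenerate` flag is set (with a warning): `MAD = 0` collapses the
#'   concordance window to a point and every other insert becomes
#'   discordant.
#' @examples
#' estimateLibraryStats(c(4800, 4900, 5000, 5100, 5300))
#' @export
estimateLibraryStats <- function(x, sampleSize = 1e6,
                                 properOrient = c("-", "+")) {
    if (is.data.frame(x) || methods::is(x, "DataFrame")) {
        inserts <- .properInserts(x, properOrient)
    } else {
        inserts <- as.numeric(x)
    }
    inserts <- inserts[!is.na(inserts)]
    if (length(inserts) > sampleSize)
        inserts <- inserts[seq_len(sampleSize)]
    if (length(inserts) < 2L)
        stop("need at least 2 insert sizes to estimate library statistics")
    mm <- .medianMAD(inserts)
    degenerate <- mm$MAD == 0
    if (degenerate)
        warning("insert-size MAD is 0: concordance window is degenerate,",
                " all non-median inserts will be classified discordant")
    methods::new("LibraryStats",
        median = mm$M, mad = mm$MAD,
        dInf = mm$M - 3 * mm$MAD, dSup = mm$M + 3 * mm$MAD,
        properOrient = properOrient, degenerate = degenerate,
        n = length(inserts))
}

# Inserts of uniquely-mapped, same-chromosome, proper-orientation pairs.
.properInserts <- function(maps, properOrient) {
    .checkColumns(maps, c("pairId", "mate", "chrom", "pos", "strand"))
    dt <- data.table::as.data.table(maps[, c("pairId", "mate", "chrom",
                                             "pos", "strand")])
    nmap <- dt[, list(n = .N), by = c("pairId", "mate")]
    multi <- unique(nmap$pairId[nmap$n > 1L])
    dt <- dt[!dt$pairId %in% multi]
    counts <- dt[, list(n = .N), by = "pairId"]
    dt <- dt[dt$pairId %in% counts$pairId[counts$n == 2L]]
    if (!nrow(dt))
        return(numeric())
    data.table::setorderv(dt, c("pairId", "pos"))
    a <- dt[seq(1L, nrow(dt), by = 2L)]
    b <- dt[seq(2L, nrow(dt), by = 2L)]
    ok <- a$chrom == b$chrom & a$strand == properOrient[1] &
        b$strand == properOrient[2]
    (b$pos - a$pos)[ok]
}

#' Classify pair mappings into discordance signatures
#'
#' Applies the signature rules to relabelled pair mappings (mate A precedes
#' mate B in genome order). With proper orientation couple
#' \eqn{(o_A, o_B)} and insert \eqn{d = l_B - l_A}:
#' \itemize{
#'   \item `Concordant`: same chromosome, proper orientation, and
#'     \eqn{d_{inf} < d < d_{sup}};
#'   \item `Del`: proper orientation but \eqn{d \ge d_{sup}} (too far
#'     apart, as over a deleted segment);
#'   \item `Ins`: proper orientation but \eqn{d \le d_{inf}};
#'   \item `Dup`: same chromosome, orientation couple reversed;
#'   \item `Inv`: same chromosome, both mates on the same strand;
#'   \item `Trans`: mates on different chromosomes.
#' }
#' The classification is total and exclusive; insert sizes exactly at a
#' limit count as discordant because concordance requires the strict
#' inequalities.
#'
#' @param pairs data.frame of relabelled pair mappings with columns
#'   `chromA`, `posA`, `orientA`, `chromB`, `posB`, `orientB`.
#' @param stats a [LibraryStats] object.
#' @return character vector of classes, one per row.
#' @examples
#' st <- estimateLibraryStats(c(4800, 4900, 5000, 5100, 5300))
#' classifyPairs(data.frame(chromA = "chr1", posA = 100, orientA = "-",
#'                          chromB = "chr1", posB = 20100, orientB = "+"),
#'               st)  # "Del"
#' @export
classifyPairs <- function(pairs, stats) {
    .checkColumns(pairs, c("chromA", "posA", "orientA",
                           "chromB", "posB", "orientB"), "pair table")
    po <- stats@properOrient
    sameChrom <- pairs$chromA == pairs$chromB
    proper <- pairs$orientA == po[1] & pairs$orientB == po[2]
    reversed <- pairs$orientA == po[2] & pairs$orientB == po[1]
    equalStrand <- pairs$orientA == pairs$orientB
    d <- pairs$posB - pairs$posA

    out <- character(nrow(pairs))
    out[!sameChrom] <- "Trans"
    out[sameChrom & equalStrand] <- "Inv"
    out[sameChrom & reversed] <- "Dup"
    out[sameChrom & proper & d >= stats@dSup] <- "Del"
    out[sameChrom & proper & d <= stats@dInf] <- "Ins"
    out[sameChrom & proper & d > stats@dInf & d < stats@dSup] <- "Concordant"
    out
}

# Relabel mate-1/mate-2 mapping couples so A precedes B in genome order.
# `chromIdx` orders chromosomes (reference sequence order).
.relabelPairs <- function(df, chromIdx) {
    ia <- chromIdx[df$chrom1]
    ib <- chromIdx[df$chrom2]
    swap <- ib < ia | (ib == ia & df$pos2 < df$pos1)
    out <- data.frame(
        pairId = df$pairId,
        chromA = ifelse(swap, df$chrom2, df$chrom1),
        posA = ifelse(swap, df$pos2, df$pos1),
        orientA = ifelse(swap, df$strand2, df$strand1),
        nmA = ifelse(swap, df$nm2, df$nm1),
        chromB = ifelse(swap, df$chrom1, df$chrom2),
        posB = ifelse(swap, df$pos1, df$pos2),
        orientB = ifelse(swap, df$strand1, df$strand2),
        nmB = ifelse(swap, df$nm1, df$nm2),
        width = df$width,
        stringsAsFactors = FALSE
    )
    out$insert <- ifelse(out$chromA == out$chromB, out$posB - out$posA,
                         NA_real_)
    out
}

# Enumerate all mate-mapping combinations of every fragment, relabelled.
# Duplicated mappings (same chrom/pos/strand within one mate) are collapsed
# first; fragments whose combination count would exceed `maxCombos` are
# truncated (primary mappings first) and counted.
.pairCombos <- function(maps, chromLevels, maxCombos = 10000L) {
    dt <- data.table::as.data.table(maps)
    if (!"width" %in% names(dt)) dt$width <- NA_integer_
    dt <- unique(dt, by = c("pairId", "mate", "chrom", "pos", "strand"))
    n <- dt[, list(n = .N), by = c("pairId", "mate")]
    wide <- data.table::dcast(n, pairId ~ mate, value.var = "n", fill = 0L)
    if (!"1" %in% names(wide)) wide$`1` <- 0L
    if (!"2" %in% names(wide)) wide$`2` <- 0L
    orphans <- wide$pairId[wide$`1` == 0L | wide$`2` == 0L]
    paired <- wide[!wide$pairId %in% orphans]

    capped <- paired$pairId[paired$`1` * paired$`2` > maxCombos]

    m1 <- dt[dt$mate == 1L & dt$pairId %in% paired$pairId]
    m2 <- dt[dt$mate == 2L & dt$pairId %in% paired$pairId]

    uniqIds <- paired$pairId[paired$`1` == 1L & paired$`2` == 1L]
    combos <- NULL
    if (length(uniqIds)) {
        a <- m1[m1$pairId %in% uniqIds]
        b <- m2[m2$pairId %in% uniqIds]
        data.table::setkeyv(a, "pairId"); data.table::setkeyv(b, "pairId")
        combos <- data.frame(pairId = a$pairId,
                             chrom1 = a$chrom, pos1 = a$pos,
                             strand1 = a$strand, nm1 = a$nm,
                             chrom2 = b$chrom, pos2 = b$pos,
                             strand2 = b$strand, nm2 = b$nm,
                             width = a$width, stringsAsFactors = FALSE)
    }
    multiIds <- setdiff(paired$pairId, uniqIds)
    if (length(multiIds)) {
        a <- m1[m1$pairId %in% multiIds,
                c("pairId", "chrom", "pos", "strand", "nm", "width")]
        b <- m2[m2$pairId %in% multiIds,
                c("pairId", "chrom", "pos", "strand", "nm")]
        data.table::setnames(a, c("pairId", "chrom1", "pos1", "strand1",
                                  "nm1", "width"))
        data.table::setnames(b, c("pairId", "chrom2", "pos2", "strand2",
                                  "nm2"))
        cj <- merge(a, b, by = "pairId", allow.cartesian = TRUE)
        keepRow <- cj[, seq_len(.N) <= maxCombos, by = "pairId"]$V1
        cj <- cj[keepRow]
        combos <- rbind(combos,
                        as.data.frame(cj[, c("pairId", "chrom1", "pos1",
                                             "strand1", "nm1", "chrom2",
                                             "pos2", "strand2", "nm2",
                                             "width")]))
    }
    chromIdx <- stats::setNames(seq_along(chromLevels), chromLevels)
    list(
        combos = if (is.null(combos) || !nrow(combos)) NULL
                 else .relabelPairs(combos, chromIdx),
        orphans = length(orphans),
        capped = length(capped)
    )
}

#' Extract discordant pair-mapping records from filtered alignments
#'
#' Enumerates every combination of mate mappings for each fragment and
#' classifies each combination. A fragment is discordant only when *none*
#' of its combinations is concordant; in that case all combinations are
#' emitted as individual records, each carrying its own signature, as if
#' they were unique mappings from separate pairs. Records whose two mates
#' both fall inside a high-coverage mask interval are discarded. Orphan
#' reads (mate never mapped) are skipped and counted.
#'
#' @param maps filtered mapping table (see [filterMappings()]).
#' @param stats a [LibraryStats] object.
#' @param mask optional high-coverage mask, a
#'   [GenomicRanges::GRanges] as returned by [buildCoverageMask()].
#' @param chromLevels chromosome ordering used to relabel mates; defaults
#'   to the order of first appearance in `maps`.
#' @param maxCombos cap on mapping combinations per fragment (default
#'   10000, mirroring the aligner's reporting cap).
#' @return a [DiscordantPairs] object.
#' @export
extractDiscordantPairs <- function(maps, stats, mask = NULL,
                                   chromLevels = NULL, maxCombos = 10000L) {
    .checkColumns(maps, c("pairId", "mate", "chrom", "pos", "strand", "nm"))
    if (is.null(chromLevels))
        chromLevels <- unique(maps$chrom)
    pc <- .pairCombos(maps, chromLevels, maxCombos)
    counters <- c(fragments = length(unique(maps$pairId)),
                  orphans = as.integer(pc$orphans),
                  capped = as.integer(pc$capped),
                  concordantFragments = 0L, masked = 0L)
    empty <- S4Vectors::DataFrame(
        pairId = character(), chromA = character(), posA = integer(),
        orientA = character(), chromB = character(), posB = integer(),
        orientB = character(), insert = numeric(), signature = character(),
        nmA = integer(), nmB = integer(), width = integer())
    if (is.null(pc$combos))
        return(methods::new("DiscordantPairs", records = empty,
                            stats = stats, counters = counters))
    combos <- pc$combos
    combos$signature <- classifyPairs(combos, stats)
    concordantIds <- unique(combos$pairId[combos$signature == "Concordant"])
    counters["concordantFragments"] <- length(concordantIds)
    rec <- combos[!combos$pairId %in% concordantIds, , drop = FALSE]
    if (!is.null(mask) && length(mask) && nrow(rec)) {
        inMask <- function(chrom, pos) {
            gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
            IRanges::overlapsAny(gr, mask)
        }
        both <- inMask(rec$chromA, rec$posA) & inMask(rec$chromB, rec$posB)
        counters["masked"] <- sum(both)
        rec <- rec[!both, , drop = FALSE]
    }
    rec <- rec[order(match(rec$chromA, chromLevels), rec$posA,
                     match(rec$chromB, chromLevels), rec$posB), ,
               drop = FALSE]
    cols <- c("pairId", "chromA", "posA", "orientA", "chromB", "posB",
              "orientB", "insert", "signature", "nmA", "nmB", "width")
    methods::new("DiscordantPairs",
                 records = S4Vectors::DataFrame(rec[, cols]),
                 stats = stats, counters = counters)
}

#' Mask of anomalously deep genomic regions
#'
#' Computes per-position read depth from primary mappings and returns the
#' maximal intervals whose depth exceeds
#' \eqn{c_{sup} = \mathrm{median} + 3 \cdot MAD} (unscaled MAD over all
#' genome positions). Regions above an absolute floor only are maskable:
#' the pathological regions this mask targets (centromeric and rDNA repeat
#' arrays) sit at depths orders of magnitude above the genome median, so a
#' floor (default 1000x) keeps ordinary fluctuations unmasked. Pairs whose
#' two mates both fall inside the mask are discarded from the discordant
#' set (see [extractDiscordantPairs()]).
#'
#' @param maps mapping table; only rows with `primary = TRUE` are used when
#'   that column is present.
#' @param chromLengths named integer vector of chromosome lengths; defaults
#'   to the rightmost mapped base per chromosome.
#' @param nMAD multiplier on the depth MAD (default 3).
#' @param floorDepth absolute minimum depth for a position to be maskable;
#'   set to 0 to threshold on `cSup` alone.
#' @return a [GenomicRanges::GRanges] of masked intervals; `metadata()`
#'   holds `cSup`, `cInf` (computed and reported, unused downstream) and
#'   the depth median/MAD. Zero-coverage input gives an empty mask with a
#'   warning.
#' @export
buildCoverageMask <- function(maps, chromLengths = NULL, nMAD = 3,
                              floorDepth = 1000) {
    .checkColumns(maps, c("chrom", "pos", "width"))
    use <- if ("primary" %in% colnames(maps)) maps[maps$primary, ] else maps
    if (!nrow(use) || all(is.na(use$width))) {
        warning("no usable mappings: returning an empty coverage mask")
        return(GenomicRanges::GRanges())
    }
    if (is.null(chromLengths)) {
        ends <- tapply(use$pos + use$width - 1L, use$chrom, max)
        chromLengths <- stats::setNames(as.integer(ends), names(ends))
    }
    gr <- GenomicRanges::GRanges(
        use$chrom,
        IRanges::IRanges(use$pos, width = use$width),
        seqlengths = chromLengths)
    gr <- GenomicRanges::trim(gr)
    cov <- GenomicRanges::coverage(gr)
    allDepth <- unlist(lapply(cov, S4Vectors::runValue), use.names = FALSE)
    allLen <- unlist(lapply(cov, S4Vectors::runLength), use.names = FALSE)
    med <- .weightedMedian(allDepth, allLen)
    madv <- .weightedMedian(abs(allDepth - med), allLen)
    cSup <- med + nMAD * madv
    cInf <- med - nMAD * madv
    thresh <- max(cSup, floorDepth)
    sl <- IRanges::slice(cov, lower = thresh + 1e-9, rangesOnly = TRUE)
    mask <- GenomicRanges::GRanges(sl)
    S4Vectors::metadata(mask) <- list(cSup = cSup, cInf = cInf,
                                      depthMedian = med, depthMAD = madv,
                                      floorDepth = floorDepth)
    mask
}

# Median of values repeated with integer weights, without expansion.
.weightedMedian <- function(v, w) {
    o <- order(v)
    v <- v[o]; w <- as.numeric(w[o])
    cw <- cumsum(w)
    tot <- cw[length(cw)]
    i <- which(cw >= tot / 2)[1]
    if (abs(cw[i] - tot / 2) < 1e-9 && i < length(v))
        (v[i] + v[i + 1]) / 2
    else
        v[i]
}
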