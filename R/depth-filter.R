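#' Per-window read depth with GC correction
#'
#' Read depth is averaged over consecutive non-overlapping windows
#' (default 100 bp) and corrected for GC-content bias by median-ratio
#' normalization: windows are binned by GC percentage (1% bins) and each
#' window's depth is scaled by the ratio of the global median depth to its
#' GC bin's median depth. Bins holding fewer than `minBinWindows` windows
#' fall back to the global median (scale factor 1). On a GC-uniform genome
#' the correction is the identity.
#'
#' @param maps mapping table (primary mappings used when flagged).
#' @param genome reference [Biostrings::DNAStringSet] (for window GC and
#'   chromosome lengths).
#' @param window window width in bp (default 100).
#' @param minBinWindows minimum windows per GC bin (default 20).
#' @return data.frame of windows: `chrom`, `start`, `end`, `gc`,
#'   `rawDepth`, `depth` (corrected). Chromosomes shorter than one window
#'   are skipped with a warning.
#' @export
computeDepthWindows <- function(maps, genome, window = 100L,
                                minBinWindows = 20L) {
    .checkColumns(maps, c("chrom", "pos", "width"))
    use <- if ("primary" %in% colnames(maps)) maps[maps$primary, ] else maps
    lens <- .chromLens(genome)
    short <- lens < window
    if (any(short)) {
        warning("skipping chromosome(s) shorter than one window: ",
                paste(names(lens)[short], collapse = ", "))
        lens <- lens[!short]
    }
    if (!length(lens))
        stop("no chromosome is at least one window long")
    gr <- GenomicRanges::GRanges(use$chrom,
        IRanges::IRanges(use$pos, width = use$width))
    gr <- gr[as.character(GenomicRanges::seqnames(gr)) %in% names(lens)]
    GenomeInfoDb::seqlevels(gr) <- names(lens)
    GenomeInfoDb::seqlengths(gr) <- unname(lens)
    cov <- GenomicRanges::coverage(GenomicRanges::trim(gr))
    out <- lapply(names(lens), function(chr) {
        n <- lens[[chr]] %/% window
        starts <- seq(1L, by = window, length.out = n)
        v <- IRanges::Views(cov[[chr]],
                            IRanges::IRanges(starts, width = window))
        gcv <- Biostrings::letterFrequency(
            Biostrings::Views(genome[[chr]],
                              IRanges::IRanges(starts, width = window)),
            "GC", as.prob = TRUE)[, 1]
        data.frame(chrom = chr, start = starts,
                   end = starts + window - 1L,
                   gc = gcv, rawDepth = IRanges::viewMeans(v))
    })
    win <- do.call(rbind, out)
    bin <- round(win$gc * 100)
    globalMed <- stats::median(win$rawDepth)
    binMed <- tapply(win$rawDepth, bin, stats::median)
    binN <- tapply(win$rawDepth, bin, length)
    factor <- globalMed / binMed
    factor[binN < minBinWindows | binMed == 0] <- 1
    win$depth <- as.numeric(win$rawDepth * factor[as.character(bin)])
    win
}

#' Segment anomalously deep regions
#'
#' Windows whose corrected depth is more than `nMAD` (unscaled) MADs above
#' the median depth are outliers; consecutive outlier windows, tolerating
#' single-window interruptions (`gapWindows = 1`), are merged into
#' segments. These segments capture centromeric/rDNA repeat arrays where
#' insertion breakpoints cannot be mapped with confidence.
#'
#' @param windows window table from [computeDepthWindows()] (or a mapping
#'   table plus `genome`, in which case windows are computed first).
#' @param genome reference genome, required when `windows` is a mapping
#'   table.
#' @param nMAD outlier threshold multiplier (default 3); the rule is
#'   one-sided high, since only excessive coverage creates spurious
#'   acceptor clusters.
#' @param gapWindows tolerated interior gap in windows (default 1).
#' @param window window width (only used when windows are computed here).
#' @return a [GenomicRanges::GRanges] of segments (lengths in `width`).
#' @export
computeDepthSegments <- function(windows, genome = NULL, nMAD = 3,
                                 gapWindows = 1L, window = 100L) {
    if (!all(c("depth", "start", "end") %in% colnames(windows))) {
        stopifnot(!is.null(genome))
        windows <- computeDepthWindows(windows, genome, window = window)
    }
    w <- windows$end[1] - windows$start[1] + 1L
    med <- stats::median(windows$depth)
    madv <- stats::median(abs(windows$depth - med))
    hot <- windows$depth > med + nMAD * madv
    if (!any(hot))
        return(GenomicRanges::GRanges())
    gr <- GenomicRanges::GRanges(windows$chrom[hot],
        IRanges::IRanges(windows$start[hot], windows$end[hot]))
    GenomicRanges::reduce(gr, min.gapwidth = gapWindows * w + 1L)
}

#' Exclude acceptor sites in ambiguous high-depth regions
#'
#' Removes event lines whose acceptor interval overlaps a high-depth
#' segment longer than `minLen` (default 500 bp). Isolated short segments
#' (single outlier windows) do not trigger exclusion. Removals are logged
#' in `params$depthFiltered` together with the offending segment.
#'
#' @param x a [TranspositionCalls] object.
#' @param segments segment [GenomicRanges::GRanges] from
#'   [computeDepthSegments()].
#' @param minLen minimum segment length (bp) for exclusion; only segments
#'   strictly longer are applied.
#' @return the filtered [TranspositionCalls]; adding segments can only
#'   remove further events, never re-admit one.
#' @export
filterAcceptorSites <- function(x, segments, minLen = 500L) {
    stopifnot(methods::is(x, "TranspositionCalls"))
    df <- as.data.frame(calls(x))
    if (!nrow(df) || !length(segments))
        return(x)
    segments <- segments[GenomicRanges::width(segments) > minLen]
    if (!length(segments))
        return(x)
    acc <- GenomicRanges::GRanges(df$acceptorChrom,
        IRanges::IRanges(df$acceptorStart,
                         pmax(df$acceptorStart, df$acceptorEnd)))
    hits <- GenomicRanges::findOverlaps(acc, segments)
    drop <- unique(S4Vectors::queryHits(hits))
    if (!length(drop))
        return(x)
    removed <- df[drop, , drop = FALSE]
    removed$segment <- as.character(
        segments[S4Vectors::subjectHits(hits)[
            match(drop, S4Vectors::queryHits(hits))]])
    params <- x@params
    params$depthFiltered <- removed
    methods::initialize(x,
        calls = S4Vectors::DataFrame(df[-drop, , drop = FALSE]),
        params = params)
}
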