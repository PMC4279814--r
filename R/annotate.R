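#' Read a TE annotation file
#'
#' Thin wrapper over [rtracklayer::import()] for GFF3/BED annotation that
#' normalizes the feature-name column to `Name` (falling back to `ID`,
#' `name`, or the range names). Malformed input is handled by the
#' underlying parser.
#'
#' @param path path to a GFF3 or BED file.
#' @return a [GenomicRanges::GRanges] with a `Name` metadata column.
#' @export
readTEAnnotation <- function(path) {
    gr <- rtracklayer::import(path)
    nm <- S4Vectors::mcols(gr)
    name <- if ("Name" %in% colnames(nm)) nm$Name
        else if ("name" %in% colnames(nm)) nm$name
        else if ("ID" %in% colnames(nm)) nm$ID
        else names(gr)
    if (is.null(name))
        name <- sprintf("feature_%06d", seq_along(gr))
    name[is.na(name)] <- sprintf("feature_%06d", which(is.na(name)))
    S4Vectors::mcols(gr)$Name <- as.character(name)
    gr
}

#' Annotate event calls with overlapping features
#'
#' Adds, for each line, the names of every annotation feature overlapping
#' (by at least 1 bp) its donor interval and its acceptor interval, in
#' genomic-position order, comma-joined. Lines with no overlapping feature
#' get the star placeholder `"*"` so the column stays parseable.
#'
#' @param x a [TranspositionCalls] object.
#' @param annotation a [GenomicRanges::GRanges] with a `Name` column
#'   (see [readTEAnnotation()]), or a path to a GFF3/BED file.
#' @return `x` with `donorAnnotation` and `acceptorAnnotation` columns.
#' @export
annotateEvents <- function(x, annotation) {
    stopifnot(methods::is(x, "TranspositionCalls"))
    if (is.character(annotation))
        annotation <- readTEAnnotation(annotation)
    if (is.null(annotation$Name))
        annotation$Name <- sprintf("feature_%06d", seq_along(annotation))
    df <- as.data.frame(calls(x))
    featNames <- function(chrom, start, end) {
        if (!nrow(df)) return(character())
        ok <- !is.na(chrom)
        res <- rep("*", length(chrom))
        if (any(ok)) {
            gr <- GenomicRanges::GRanges(chrom[ok],
                IRanges::IRanges(start[ok], pmax(start[ok], end[ok])))
            hits <- GenomicRanges::findOverlaps(gr, annotation)
            if (length(hits)) {
                sh <- S4Vectors::subjectHits(hits)
                qh <- S4Vectors::queryHits(hits)
                ord <- order(qh, GenomicRanges::start(annotation)[sh])
                lab <- tapply(annotation$Name[sh[ord]], qh[ord],
                              paste, collapse = ",")
                res[ok][as.integer(names(lab))] <- unname(lab)
            }
        }
        res
    }
    df$donorAnnotation <- featNames(df$donorChrom, df$donorStart,
                                    df$donorEnd)
    df$acceptorAnnotation <- featNames(df$acceptorChrom, df$acceptorStart,
                                       df$acceptorEnd)
    methods::initialize(x, calls = S4Vectors::DataFrame(df))
}

#' Score candidate donors by discriminating-read counts
#'
#' When an insertion has several candidate donors (near-identical copies of
#' one TE family), reads anchored at the acceptor whose mates cover a
#' polymorphism specific to one copy map strictly better there than on any
#' other candidate. Counting those reads per candidate yields a specificity
#' score: the true donor accumulates discriminating reads while copies
#' identical to it score uniformly low.
#'
#' For every read with one mate mapping inside the acceptor interval
#' (extended by \eqn{d_{sup}} on each side) and the other mate mapping to
#' at least one candidate donor interval, the per-candidate best edit
#' distance is compared: if one candidate beats every other by at least
#' `minScoreDelta` the read increments that candidate's score, otherwise
#' the read is discarded as non-discriminating. A read mapping to only one
#' candidate counts for it.
#'
#' @param x a [TranspositionCalls] object.
#' @param maps the mapping table the discordant records were extracted
#'   from (all mappings retained, with `nm`).
#' @param stats a [LibraryStats] (for the anchoring pad).
#' @param minScoreDelta required edit-distance margin (default 1: a single
#'   discriminating substitution changes the edit distance by exactly 1).
#' @return `x` with integer `donorScore` (NA for single-candidate
#'   insertions and deletions, rendered as `"*"` in text output) and
#'   logical `ambiguousDonor` (single candidate, or no discriminating read
#'   for any candidate). A warning is emitted for groups with no anchored
#'   reads.
#' @export
scoreDonors <- function(x, maps, stats, minScoreDelta = 1L) {
    stopifnot(methods::is(x, "TranspositionCalls"))
    .checkColumns(maps, c("pairId", "mate", "chrom", "pos", "nm", "width"))
    df <- as.data.frame(calls(x))
    df$donorScore <- NA_integer_
    df$ambiguousDonor <- NA
    pad <- stats@dSup
    ins <- df$eventType != "deletion"
    groups <- split(which(ins), df$acceptorId[ins])
    dtm <- data.table::as.data.table(
        maps[, c("pairId", "mate", "chrom", "pos", "nm", "width")])
    dtm$end <- dtm$pos + dtm$width - 1L
    for (rows in groups) {
        if (length(rows) < 2L) {
            df$ambiguousDonor[rows] <- TRUE
            next
        }
        accChrom <- df$acceptorChrom[rows[1]]
        lo <- min(df$acceptorStart[rows]) - pad
        hi <- max(df$acceptorEnd[rows]) + pad
        anch <- dtm[dtm$chrom == accChrom & dtm$pos <= hi & dtm$end >= lo]
        if (!nrow(anch)) {
            warning("no acceptor-anchored reads for group ",
                    df$acceptorId[rows[1]], ": all donor scores 0")
            df$donorScore[rows] <- 0L
            df$ambiguousDonor[rows] <- TRUE
            next
        }
        scores <- integer(length(rows))
        anchKey <- unique(data.frame(pairId = anch$pairId, mate = anch$mate))
        sub <- dtm[dtm$pairId %in% unique(anchKey$pairId)]
        subByRead <- split(sub, paste(sub$pairId, sub$mate, sep = "\r"))
        for (g in seq_len(nrow(anchKey))) {
            pid <- anchKey$pairId[g]
            otherMate <- 3L - anchKey$mate[g]
            mm <- subByRead[[paste(pid, otherMate, sep = "\r")]]
            if (is.null(mm) || !nrow(mm)) next
            best <- rep(Inf, length(rows))
            for (d in seq_along(rows)) {
                r <- rows[d]
                sel <- mm$chrom == df$donorChrom[r] &
                    mm$pos <= df$donorEnd[r] & mm$end >= df$donorStart[r]
                if (any(sel))
                    best[d] <- min(mm$nm[sel])
            }
            if (all(is.infinite(best))) next
            o <- order(best)
            if (best[o[2]] - best[o[1]] >= minScoreDelta)
                scores[o[1]] <- scores[o[1]] + 1L
        }
        df$donorScore[rows] <- scores
        df$ambiguousDonor[rows] <- all(scores == 0L)
    }
    methods::initialize(x, calls = S4Vectors::DataFrame(df))
}
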