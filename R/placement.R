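#' Place simulated reads on the original reference
#'
#' Exact-placement fixture writer: converts reads simulated from a
#' tampered genome (see [injectTranspositions()] and
#' [simulateMatePairs()]) into the alignment records a strict aligner
#' would report against the *original* reference, without running an
#' aligner. Placement follows the injection map:
#' \itemize{
#'   \item reads fully inside untouched sequence lift by the cumulative
#'     insertion offset;
#'   \item reads fully inside an inserted element map to the donor span
#'     (mirrored and strand-flipped for inverted insertions);
#'   \item reads straddling an insertion boundary (or the duplicated
#'     target site) and junction-chimeric reads are unmapped - exactly
#'     what a \eqn{\le}1-mismatch filter leaves of reads crossing novel
#'     junctions - so their mates become orphans;
#'   \item a read whose placed interval falls fully inside an annotated TE
#'     copy additionally receives one candidate mapping at the same offset
#'     in every other family member long enough to host it, with the edit
#'     distance computed by direct comparison of the read sequence against
#'     the reference window.
#' }
#'
#' @param sim result of [simulateMatePairs()] run on
#'   `modifiedGenome(truth)`.
#' @param truth the [TranspositionTruth] describing the injections.
#' @param teGenome the [TEGenome] the truth was built from; its annotation
#'   drives homologous multi-mapping. `NULL` disables multi-mappings.
#' @return mapping table (`pairId`, `mate`, `chrom`, `pos`, `strand`,
#'   `nm`, `width`, `primary`) ready for [filterMappings()]; attribute
#'   `counters` reports dropped junction/chimeric reads.
#' @export
placeReads <- function(sim, truth, teGenome = NULL) {
    reads <- sim$reads
    rl <- sim$readLen
    ev <- as.data.frame(truthEvents(truth))
    nErr <- if (is.null(sim$errors)) integer(nrow(reads))
            else lengths(sim$errors$pos)

    chimeric <- reads$overhang > 0L
    counters <- c(chimericDropped = sum(chimeric), junctionDropped = 0L)
    keep <- which(!chimeric)

    mapped <- data.frame(
        row = keep, chrom = NA_character_, pos = NA_integer_,
        strand = NA_character_, stringsAsFactors = FALSE)
    rstart <- reads$start[keep]; rend <- reads$end[keep]
    rchrom <- reads$chrom[keep]; rstrand <- reads$strand[keep]

    for (chr in unique(rchrom)) {
        sel <- which(rchrom == chr)
        blocks <- ev[ev$acceptorChrom == chr, , drop = FALSE]
        blocks <- blocks[order(blocks$blockStart), , drop = FALSE]
        if (!nrow(blocks)) {
            mapped$chrom[sel] <- chr
            mapped$pos[sel] <- rstart[sel]
            mapped$strand[sel] <- rstrand[sel]
            next
        }
        bs <- blocks$blockStart; be <- blocks$blockEnd
        blockLen <- be - bs + 1L
        shift <- cumsum(blockLen)
        j <- findInterval(rstart[sel], bs)
        startsInBlock <- j >= 1L & rstart[sel] <= be[pmax(j, 1L)]
        # flank reads: start after block j (or before any block), and the
        # read must end before the next block starts
        nextStart <- ifelse(j + 1L <= length(bs), bs[pmin(j + 1L,
            length(bs))], Inf)
        inFlank <- !startsInBlock & rend[sel] < nextStart
        fl <- sel[inFlank]
        if (length(fl)) {
            sh <- c(0L, shift)[j[inFlank] + 1L]
            mapped$chrom[fl] <- chr
            mapped$pos[fl] <- rstart[fl] - sh
            mapped$strand[fl] <- rstrand[fl]
        }
        # TE-part reads: fully inside block j beyond the duplicated TSD
        inTE <- startsInBlock &
            rstart[sel] >= bs[pmax(j, 1L)] + blocks$tsdLen[pmax(j, 1L)] &
            rend[sel] <= be[pmax(j, 1L)]
        te <- sel[inTE]
        if (length(te)) {
            jj <- j[inTE]
            off <- rstart[te] - (bs[jj] + blocks$tsdLen[jj])
            inv <- blocks$inverted[jj]
            dChrom <- blocks$donorChrom[jj]
            dStart <- blocks$donorStart[jj]
            dEnd <- blocks$donorEnd[jj]
            pos <- ifelse(inv, dEnd - (off + rl - 1L), dStart + off)
            strand <- ifelse(inv,
                             ifelse(rstrand[te] == "+", "-", "+"),
                             rstrand[te])
            mapped$chrom[te] <- dChrom
            mapped$pos[te] <- as.integer(pos)
            mapped$strand[te] <- strand
        }
    }
    lost <- is.na(mapped$chrom)
    counters["junctionDropped"] <- sum(lost)
    mapped <- mapped[!lost, , drop = FALSE]

    out <- data.frame(
        pairId = reads$pairId[mapped$row],
        mate = reads$mate[mapped$row],
        chrom = mapped$chrom, pos = mapped$pos, strand = mapped$strand,
        nm = as.integer(nErr[mapped$row]), width = rl, primary = TRUE,
        stringsAsFactors = FALSE)

    if (!is.null(teGenome)) {
        alt <- .homologMappings(out, mapped$row, sim, truth, teGenome)
        if (!is.null(alt))
            out <- rbind(out, alt)
    }
    out <- out[order(out$pairId, out$mate, !out$primary), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "counters") <- counters
    out
}

# Candidate mappings at homologous family copies, with exact edit
# distances from sequence comparison.
.homologMappings <- function(primary, readRows, sim, truth, teGenome) {
    anno <- teAnnotation(teGenome)
    original <- truth@original
    rl <- sim$readLen
    gr <- GenomicRanges::GRanges(primary$chrom,
        IRanges::IRanges(primary$pos, width = primary$width))
    hits <- GenomicRanges::findOverlaps(gr, anno, type = "within")
    if (!length(hits))
        return(NULL)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    fam <- anno$family
    annoStart <- GenomicRanges::start(anno)
    annoWidth <- GenomicRanges::width(anno)
    annoChrom <- as.character(GenomicRanges::seqnames(anno))

    # expand: one row per (read-with-hit, other family member)
    famIdx <- split(seq_along(anno), fam)
    cand <- list()
    for (k in seq_along(qh)) {
        f <- sh[k]
        others <- setdiff(famIdx[[fam[f]]], f)
        if (!length(others)) next
        relOff <- primary$pos[qh[k]] - annoStart[f]
        fit <- others[annoWidth[others] >= relOff + rl]
        if (!length(fit)) next
        cand[[length(cand) + 1L]] <- data.frame(
            q = qh[k], g = fit, pos = annoStart[fit] + relOff)
    }
    if (!length(cand))
        return(NULL)
    cand <- do.call(rbind, cand)

    # reference-forward read sequences for the reads needing comparison
    needQ <- sort(unique(cand$q))
    readFwd <- .referenceForwardSeqs(primary[needQ, , drop = FALSE],
                                     readRows[needQ], sim, truth)
    names(readFwd) <- as.character(needQ)

    nm <- integer(nrow(cand))
    for (chr in unique(annoChrom[cand$g])) {
        sel <- which(annoChrom[cand$g] == chr)
        win <- Biostrings::extractAt(original[[chr]],
            IRanges::IRanges(cand$pos[sel], width = rl))
        wmat <- as.matrix(win)
        rmat <- as.matrix(readFwd[as.character(cand$q[sel])])
        nm[sel] <- rowSums(wmat != rmat)
    }
    data.frame(
        pairId = primary$pairId[cand$q],
        mate = primary$mate[cand$q],
        chrom = annoChrom[cand$g],
        pos = as.integer(cand$pos),
        strand = primary$strand[cand$q],
        nm = nm, width = rl, primary = FALSE,
        stringsAsFactors = FALSE)
}

# Sequenced bases of each read, oriented to the forward strand of its
# placed reference location (so it can be compared against reference
# windows directly).
.referenceForwardSeqs <- function(primary, readRows, sim, truth) {
    reads <- sim$reads[readRows, , drop = FALSE]
    mod <- modifiedGenome(truth)
    n <- nrow(reads)
    out <- character(n)
    for (chr in unique(reads$chrom)) {
        sel <- which(reads$chrom == chr)
        win <- Biostrings::extractAt(mod[[chr]],
            IRanges::IRanges(reads$start[sel], reads$end[sel]))
        out[sel] <- as.character(win)
    }
    seqs <- Biostrings::DNAStringSet(out)
    # apply sequencing errors in sequencing orientation
    if (!is.null(sim$errors)) {
        sense <- reads$strand == "+"
        seqs[!sense] <- Biostrings::reverseComplement(seqs[!sense])
        seqs <- .applyErrors(seqs,
                             sim$errors$pos[readRows],
                             sim$errors$shift[readRows])
        # back to modified-genome forward orientation
        seqs[!sense] <- Biostrings::reverseComplement(seqs[!sense])
    }
    # orient to the placed reference forward strand: flipped only when the
    # placed strand differs from the modified-genome strand (inverted
    # insertions)
    flip <- primary$strand != reads$strand
    if (any(flip))
        seqs[flip] <- Biostrings::reverseComplement(seqs[flip])
    seqs
}
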