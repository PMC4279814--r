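#' Simulate a long-fragment mate-pair sequencing run
#'
#' Mirrors the physical protocol of a circularization (mate-pair) library.
#' Per fragment: a size is sampled from the profile's empirical fragment
#' distribution and a location uniformly on the genome; the fragment is
#' circularized; a splice length is drawn from the short-fragment mode and
#' a splice start uniformly around the circularization point; both ends of
#' the spliced subfragment are "sequenced" inward. A read whose splice
#' window extends over the circularization point becomes a junction
#' chimera (its two parts come from opposite fragment ends). At the
#' profile's contamination odds, a short parasitic fragment is produced
#' instead and sequenced as an ordinary forward-reverse pair. Per-base
#' qualities are sampled from the positional histograms and substitution
#' errors injected with the probability the quality encodes.
#'
#' After coordinate-sorting mates, clean main-library pairs map in the
#' `(-, +)` orientation with insert \eqn{d = F - \ell + r} (fragment F,
#' splice \eqn{\ell}, read length r); contaminant pairs map `(+, -)` at
#' short insert - the two artefact classes real mate-pair data shows.
#'
#' @param genome a [Biostrings::DNAStringSet] to sequence.
#' @param profile a [SimProfile].
#' @param coverage mean read-depth fold (reads x length / genome length).
#' @param seed RNG seed; identical inputs and seed give identical output.
#' @param chimeras when `FALSE` the splice start is confined so no read
#'   crosses the junction (useful for noise-free benchmarks).
#' @param contamination when `FALSE` contamination odds are forced to 0.
#' @param errors simulate sequencing errors (and per-base qualities).
#' @param keepQualities retain the sampled quality matrix (needed for
#'   FASTQ output with realistic qualities and for profile round-trips).
#' @return a list of class data: `pairs` (per-fragment table: `pairId`,
#'   `chrom`, `fragStart`, `fragSize`, `spliceLen`, `spliceU`,
#'   `contaminant`), `reads` (per-read table: `pairId`, `mate`, `chrom`,
#'   `start`, `end`, `strand`, `overhang` - bases of the read that belong
#'   to the opposite fragment end, 0 for a clean read), `errors`
#'   (list-columns `pos` and `shift` per read, when simulated),
#'   `qualities` (integer matrix, reads x positions, when kept),
#'   `readLen`, `profile`.
#' @export
simulateMatePairs <- function(genome, profile, coverage, seed = 1L,
                              chimeras = TRUE, contamination = TRUE,
                              errors = TRUE, keepQualities = errors) {
    stopifnot(coverage > 0)
    rl <- profile@readLen
    lens <- .chromLens(genome)
    nPairs <- max(1L, round(sum(lens) * coverage / (2 * rl)))
    .withSeed(seed, {
        odds <- if (contamination) profile@contaminationOdds else 0
        contaminant <- stats::runif(nPairs) < odds
        shortTab <- .shortModeTable(profile)
        longTab <- .longModeTable(profile)
        F <- integer(nPairs)
        nShort <- sum(contaminant)
        if (nShort)
            F[contaminant] <- sample(shortTab$sizes, nShort, replace = TRUE,
                                     prob = shortTab$p)
        F[!contaminant] <- sample(longTab$sizes, nPairs - nShort,
                                  replace = TRUE, prob = longTab$p)
        chromIdx <- sample.int(length(lens), nPairs, replace = TRUE,
                               prob = lens / sum(lens))
        # resample fragments that do not fit their chromosome
        for (tries in 1:5) {
            bad <- F > lens[chromIdx]
            if (!any(bad)) break
            chromIdx[bad] <- sample.int(length(lens), sum(bad),
                                        replace = TRUE,
                                        prob = lens / sum(lens))
        }
        if (any(F > lens[chromIdx]))
            stop("fragment larger than every chromosome")
        s <- floor(stats::runif(nPairs) * (lens[chromIdx] - F + 1)) + 1L

        ell <- sample(shortTab$sizes, nPairs, replace = TRUE,
                      prob = shortTab$p)
        if (!chimeras) {
            ell <- pmax(ell, 2L * rl)
            u <- rl + floor(stats::runif(nPairs) * (ell - 2L * rl + 1L))
        } else {
            u <- floor(stats::runif(nPairs) * (ell + 1L))
        }
        # contaminant pairs are plain FR fragments; splice fields unused
        u[contaminant] <- NA_integer_
        ell[contaminant] <- NA_integer_

        pairs <- data.frame(
            pairId = seq_len(nPairs), chrom = names(lens)[chromIdx],
            fragStart = as.integer(s), fragSize = F,
            spliceLen = ell, spliceU = u, contaminant = contaminant,
            stringsAsFactors = FALSE)
        reads <- .pairReads(pairs, rl)

        errPos <- NULL; errShift <- NULL; qmat <- NULL
        if (errors || keepQualities) {
            nReads <- nrow(reads)
            qmat <- matrix(0L, nReads, rl)
            qv <- profile@qualityValues
            for (p in seq_len(rl))
                qmat[, p] <- qv[sample.int(length(qv), nReads,
                                           replace = TRUE,
                                           prob = profile@qualityProbs[, p])]
            if (errors) {
                perr <- 10^(-qmat / 10)
                isErr <- matrix(stats::runif(length(perr)) < perr,
                                nrow(perr), ncol(perr))
                errPos <- apply(isErr, 1L, which, simplify = FALSE)
                nErr <- lengths(errPos)
                shifts <- sample.int(3L, sum(nErr), replace = TRUE)
                errShift <- split(shifts, rep.int(seq_along(nErr), nErr))
                tmp <- vector("list", length(errPos))
                tmp[as.integer(names(errShift))] <- errShift
                tmp[vapply(tmp, is.null, logical(1))] <- list(integer())
                errShift <- tmp
            }
            if (!keepQualities)
                qmat <- NULL
        }
        structure(list(pairs = pairs, reads = reads,
                       errors = if (!is.null(errPos))
                           list(pos = errPos, shift = errShift),
                       qualities = qmat, readLen = rl, profile = profile),
                  class = "MatePairSim")
    })
}

# Per-read coordinates from the per-fragment table. Mate 1 is the
# tail-side read (forward), mate 2 the head-side read (reverse) for main
# fragments; contaminants are plain FR pairs. `overhang` counts the bases
# of a junction-chimeric read that belong to the opposite fragment end;
# the stored start/end describe the read's major (anchoring) part.
.pairReads <- function(pairs, rl) {
    n <- nrow(pairs)
    mk <- function(mate, start, end, strand, overhang) {
        data.frame(pairId = pairs$pairId, mate = mate,
                   chrom = pairs$chrom,
                   start = as.integer(start), end = as.integer(end),
                   strand = strand, overhang = as.integer(overhang),
                   stringsAsFactors = FALSE)
    }
    s <- pairs$fragStart; F <- pairs$fragSize
    ell <- pairs$spliceLen; u <- pairs$spliceU
    cont <- pairs$contaminant
    # mate 1
    st1 <- en1 <- integer(n); ov1 <- integer(n)
    main <- !cont
    tailLen <- ifelse(is.na(u), NA_integer_, u)
    # clean when u == 0 (read entirely in head) or u >= rl (entirely tail)
    clean1 <- main & (tailLen == 0L | tailLen >= rl)
    st1[main] <- ifelse(tailLen[main] == 0L, s[main],
                        s[main] + F[main] - tailLen[main])
    en1[main] <- st1[main] + rl - 1L
    chim1 <- main & !clean1
    ov1[chim1] <- rl - tailLen[chim1]     # head-part bases
    # chimeric mate 1 anchors on its longer part
    swap1 <- chim1 & (ov1 > rl - ov1)
    st1[swap1] <- s[swap1]
    en1[swap1] <- s[swap1] + ov1[swap1] - 1L
    ov1[swap1] <- rl - ov1[swap1]
    en1[chim1 & !swap1] <- s[chim1 & !swap1] + F[chim1 & !swap1] - 1L
    st1[chim1 & !swap1] <- en1[chim1 & !swap1] -
        (rl - ov1[chim1 & !swap1]) + 1L
    st1[cont] <- s[cont]; en1[cont] <- s[cont] + rl - 1L
    m1 <- mk(1L, st1, en1, "+", ov1)
    # mate 2
    st2 <- en2 <- integer(n); ov2 <- integer(n)
    headLen <- ifelse(is.na(u), NA_integer_, ell - u)
    clean2 <- main & (headLen == 0L | headLen >= rl)
    st2[main] <- ifelse(headLen[main] == 0L,
                        s[main] + F[main] - rl,
                        s[main] + headLen[main] - rl)
    en2[main] <- st2[main] + rl - 1L
    chim2 <- main & !clean2
    ov2[chim2] <- rl - headLen[chim2]     # tail-part bases
    swap2 <- chim2 & (ov2 > rl - ov2)
    en2[swap2] <- s[swap2] + F[swap2] - 1L
    st2[swap2] <- en2[swap2] - ov2[swap2] + 1L
    ov2[swap2] <- rl - ov2[swap2]
    st2[chim2 & !swap2] <- s[chim2 & !swap2]
    en2[chim2 & !swap2] <- s[chim2 & !swap2] +
        (rl - ov2[chim2 & !swap2]) - 1L
    st2[cont] <- s[cont] + F[cont] - rl; en2[cont] <- s[cont] + F[cont] - 1L
    m2 <- mk(2L, st2, en2, "-", ov2)
    out <- rbind(m1, m2)
    out[order(out$pairId, out$mate), , drop = FALSE]
}

#' Materialize simulated read sequences
#'
#' Rebuilds each read's base sequence from the genome: clean reads are
#' plain (possibly reverse-complemented) substrings; junction chimeras are
#' the concatenation of their two fragment-end parts; substitution errors
#' recorded by the simulator are applied by shifting the true base within
#' the alphabet, so a stored error never silently restores the original
#' base.
#'
#' @param sim result of [simulateMatePairs()].
#' @param genome the same genome the simulation used.
#' @return a [Biostrings::DNAStringSet], one entry per row of
#'   `sim$reads`, 5'->3' as sequenced.
#' @export
simReadSequences <- function(sim, genome) {
    reads <- sim$reads
    pairs <- sim$pairs
    rl <- sim$readLen
    seqs <- .spliceSequences(reads, pairs, genome, rl)
    if (!is.null(sim$errors)) {
        seqs <- .applyErrors(seqs, sim$errors$pos, sim$errors$shift)
    }
    seqs
}

# Sequences as sequenced (before errors): build per read from fragment
# geometry, including junction chimeras.
.spliceSequences <- function(reads, pairs, genome, rl) {
    idx <- match(reads$pairId, pairs$pairId)
    s <- pairs$fragStart[idx]; F <- pairs$fragSize[idx]
    u <- pairs$spliceU[idx]; ell <- pairs$spliceLen[idx]
    cont <- pairs$contaminant[idx]
    chrom <- reads$chrom
    n <- nrow(reads)
    # part1/part2 genomic windows in sequencing order (5'->3' of the read)
    p1s <- p1e <- p2s <- p2e <- integer(n)
    revc <- reads$strand == "-"
    for (i in seq_len(n)) {
        if (cont[i]) {
            if (reads$mate[i] == 1L) { p1s[i] <- s[i]; p1e[i] <- s[i] + rl - 1L }
            else { p1s[i] <- s[i] + F[i] - rl; p1e[i] <- s[i] + F[i] - 1L }
            next
        }
        if (reads$mate[i] == 1L) {
            tl <- u[i]
            if (tl == 0L) { p1s[i] <- s[i]; p1e[i] <- s[i] + rl - 1L }
            else if (tl >= rl) {
                p1s[i] <- s[i] + F[i] - tl; p1e[i] <- p1s[i] + rl - 1L
            } else {
                p1s[i] <- s[i] + F[i] - tl; p1e[i] <- s[i] + F[i] - 1L
                p2s[i] <- s[i]; p2e[i] <- s[i] + (rl - tl) - 1L
            }
        } else {
            hl <- ell[i] - u[i]
            if (hl == 0L) { p1s[i] <- s[i] + F[i] - rl; p1e[i] <- s[i] + F[i] - 1L }
            else if (hl >= rl) {
                p1s[i] <- s[i] + hl - rl; p1e[i] <- s[i] + hl - 1L
            } else {
                p1s[i] <- s[i] + F[i] - (rl - hl); p1e[i] <- s[i] + F[i] - 1L
                p2s[i] <- s[i]; p2e[i] <- s[i] + hl - 1L
            }
        }
    }
    out <- vector("list", n)
    for (chr in unique(chrom)) {
        sel <- which(chrom == chr)
        part1 <- Biostrings::extractAt(genome[[chr]],
            IRanges::IRanges(p1s[sel], p1e[sel]))
        hasP2 <- p2e[sel] > 0L
        seqs <- as.character(part1)
        if (any(hasP2)) {
            part2 <- Biostrings::extractAt(genome[[chr]],
                IRanges::IRanges(p2s[sel][hasP2], p2e[sel][hasP2]))
            seqs[hasP2] <- paste0(seqs[hasP2], as.character(part2))
        }
        out[sel] <- seqs
    }
    res <- Biostrings::DNAStringSet(unlist(out))
    res[revc] <- Biostrings::reverseComplement(res[revc])
    res
}

.applyErrors <- function(seqs, posList, shiftList) {
    bases <- c("A", "C", "G", "T")
    chars <- NULL
    any <- which(lengths(posList) > 0L)
    if (!length(any))
        return(seqs)
    str <- as.character(seqs)
    for (i in any) {
        v <- strsplit(str[i], "")[[1]]
        p <- posList[[i]]
        sh <- shiftList[[i]]
        bi <- match(v[p], bases)
        ok <- !is.na(bi)
        v[p[ok]] <- bases[((bi[ok] - 1L + sh[ok]) %% 4L) + 1L]
        str[i] <- paste(v, collapse = "")
    }
    Biostrings::DNAStringSet(str)
}

#' Write simulated reads as a FASTQ pair
#'
#' @param sim result of [simulateMatePairs()].
#' @param genome the genome the simulation used.
#' @param prefix output prefix; files `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq` are written with mate-consistent names.
#' @return invisibly, the two file paths.
#' @export
writeSimFastq <- function(sim, genome, prefix) {
    seqs <- simReadSequences(sim, genome)
    rl <- sim$readLen
    if (!is.null(sim$qualities)) {
        qual <- apply(sim$qualities + sim$profile@qualOffset, 1L,
                      function(q) rawToChar(as.raw(q)))
    } else {
        qual <- rep(strrep(rawToChar(as.raw(40L + sim$profile@qualOffset)),
                           rl), nrow(sim$reads))
    }
    names(seqs) <- sprintf("frag%08d/%d", sim$reads$pairId, sim$reads$mate)
    paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
    for (m in 1:2) {
        sel <- sim$reads$mate == m
        q <- Biostrings::PhredQuality(qual[sel])
        x <- Biostrings::QualityScaledDNAStringSet(seqs[sel], q)
        Biostrings::writeQualityScaledXStringSet(x, paths[m])
    }
    invisible(paths)
}
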