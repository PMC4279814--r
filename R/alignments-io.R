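#' Read paired alignments into a mapping table
#'
#' Loads a coordinate-sorted BAM into the flat mapping table the rest of
#' the pipeline consumes: one row per mapping, with multiple mappings
#' recovered both from secondary alignment records (flag 0x100) and from
#' alternative-hit `XA` tags (`chr,±pos,CIGAR,NM;...`). Duplicated
#' mappings of one read (same chromosome, position and strand) are
#' collapsed. Unmapped records are dropped.
#'
#' @param file path to a BAM file (a `.sam` file is converted on the fly
#'   via [Rsamtools::asBam()]).
#' @param what extra BAM fields to keep (qualities can be requested for
#'   profile learning with `what = "qual"`).
#' @return mapping table: `pairId`, `mate`, `chrom`, `pos`, `strand`,
#'   `nm` (NA when no `NM` tag), `width`, `primary` plus requested extras.
#' @export
readPairAlignments <- function(file, what = character()) {
    if (grepl("\\.sam$", file)) {
        file <- Rsamtools::asBam(file,
            destination = sub("\\.sam$", "", file),
            overwrite = TRUE, indexDestination = FALSE)
    }
    param <- Rsamtools::ScanBamParam(
        what = c("qname", "flag", "rname", "strand", "pos", "qwidth", what),
        tag = c("NM", "XA"))
    res <- Rsamtools::scanBam(file, param = param)[[1]]
    ok <- !is.na(res$pos)
    flag <- res$flag[ok]
    mate <- ifelse(bitwAnd(flag, 128L) > 0L, 2L, 1L)
    base <- data.frame(
        pairId = res$qname[ok],
        mate = mate,
        chrom = as.character(res$rname[ok]),
        pos = res$pos[ok],
        strand = as.character(res$strand[ok]),
        nm = if (is.null(res$tag$NM)) NA_integer_
             else as.integer(res$tag$NM[ok]),
        width = res$qwidth[ok],
        primary = bitwAnd(flag, 256L) == 0L,
        stringsAsFactors = FALSE)
    for (w in what)
        base[[w]] <- as.character(res[[w]][ok])
    xa <- if (is.null(res$tag$XA)) rep(NA_character_, sum(ok))
          else res$tag$XA[ok]
    alt <- .parseXA(base, xa)
    out <- rbind(base, alt)
    out <- out[!duplicated(out[, c("pairId", "mate", "chrom", "pos",
                                   "strand")]), , drop = FALSE]
    rownames(out) <- NULL
    out
}

# Expand `XA:Z:` alternative-hit strings into extra mapping rows.
.parseXA <- function(base, xa) {
    has <- which(!is.na(xa) & nzchar(xa))
    if (!length(has))
        return(NULL)
    pieces <- strsplit(xa[has], ";", fixed = TRUE)
    nHit <- lengths(pieces)
    src <- rep(has, nHit)
    fields <- strsplit(unlist(pieces), ",", fixed = TRUE)
    okf <- lengths(fields) == 4L
    fields <- fields[okf]; src <- src[okf]
    chrom <- vapply(fields, `[[`, character(1), 1L)
    posStr <- vapply(fields, `[[`, character(1), 2L)
    nm <- as.integer(vapply(fields, `[[`, character(1), 4L))
    out <- base[src, , drop = FALSE]
    out$chrom <- chrom
    out$strand <- substr(posStr, 1L, 1L)
    out$pos <- as.integer(substring(posStr, 2L))
    out$nm <- nm
    out$primary <- FALSE
    out
}

#' Write a mapping table as a SAM file
#'
#' Emits minimal, valid SAM (header from chromosome lengths; sequences and
#' qualities written as `*`) so placed alignments can round-trip through
#' standard tools and [readPairAlignments()]. Secondary mappings get flag
#' 0x100; mate fields are filled from each read's primary mapping.
#'
#' @param maps mapping table (see [placeReads()]).
#' @param chromLengths named vector of reference lengths for the header.
#' @param path output path (`.sam`).
#' @param sortBy `"coordinate"` (default) or `"none"`.
#' @return invisibly, `path`.
#' @export
writeSamFile <- function(maps, chromLengths, path, sortBy = "coordinate") {
    .checkColumns(maps, c("pairId", "mate", "chrom", "pos", "strand", "nm"))
    if (!"primary" %in% colnames(maps))
        maps$primary <- !duplicated(paste(maps$pairId, maps$mate))
    if (!"width" %in% colnames(maps))
        maps$width <- 100L
    prim <- maps[maps$primary, , drop = FALSE]
    key <- paste(prim$pairId, prim$mate)
    mateKey <- paste(maps$pairId, 3L - maps$mate)
    mi <- match(mateKey, key)
    flag <- 1L +                                   # paired
        ifelse(maps$strand == "-", 16L, 0L) +
        ifelse(!is.na(mi) & prim$strand[mi] == "-", 32L, 0L) +
        ifelse(maps$mate == 1L, 64L, 128L) +
        ifelse(maps$primary, 0L, 256L) +
        ifelse(is.na(mi), 8L, 0L)                  # mate unmapped
    rnext <- ifelse(is.na(mi), "*",
                    ifelse(prim$chrom[mi] == maps$chrom, "=",
                           prim$chrom[mi]))
    pnext <- ifelse(is.na(mi), 0L, prim$pos[mi])
    cigar <- paste0(maps$width, "M")
    lines <- paste(maps$pairId, flag, maps$chrom, maps$pos,
                   ifelse(maps$primary, 60L, 0L), cigar, rnext, pnext, 0L,
                   "*", "*", paste0("NM:i:", maps$nm), sep = "\t")
    if (sortBy == "coordinate") {
        o <- order(match(maps$chrom, names(chromLengths)), maps$pos)
        lines <- lines[o]
    }
    hdr <- c(sprintf("@HD\tVN:1.6\tSO:%s", sortBy),
             sprintf("@SQ\tSN:%s\tLN:%d", names(chromLengths),
                     as.integer(chromLengths)))
    writeLines(c(hdr, lines), path)
    invisible(path)
}
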