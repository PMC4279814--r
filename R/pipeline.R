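.defaultConfig <- function() {
    list(
        bam = NA_character_,          # input coordinate-sorted BAM
        reference = NA_character_,    # reference FASTA (names/lengths)
        annotation = NA_character_,   # optional TE annotation (GFF3/BED)
        outPrefix = NA_character_,    # output prefix; NA = no files
        orient = "mp",                # library preset: mp | pe
        maxMismatch = 1,              # best-mapping edit-distance filter
        sampleSize = 1e6,             # inserts used for library stats
        minSupport = 10,              # cluster support threshold
        acceptorMaxGap = NA_real_,    # NA = d_sup
        mergeGap = NA_real_,          # NA = current Y
        maskFloorDepth = 1000,        # coverage-mask maskable floor
        minSegLen = 500,              # depth-filter segment length
        minScoreDelta = 1,            # donor-score edit-distance margin
        tol = 300,                    # evaluation tolerance
        gridX = "50:1000:50",         # X grid as from:to:step
        gridY = "100:5000:100",       # Y grid as from:to:step
        score = TRUE,                 # run donor scoring
        depthFilter = TRUE,           # run acceptor-site depth filter
        seed = 1
    )
}

#' Load and validate a pipeline configuration
#'
#' Reads a flat `key = value` configuration file (lines starting with `#`
#' are comments) and applies command-line style overrides, which take
#' precedence over file values. Unknown keys and non-numeric thresholds
#' are hard errors naming the key. The effective configuration is echoed
#' by [runPipeline()]'s report.
#'
#' @param path optional path to the configuration file.
#' @param overrides named list of overriding values.
#' @return validated configuration list.
#' @examples
#' cfg <- loadConfig(overrides = list(minSupport = 5))
#' cfg$minSupport
#' @export
loadConfig <- function(path = NULL, overrides = list()) {
    cfg <- .defaultConfig()
    fileVals <- list()
    if (!is.null(path)) {
        lines <- readLines(path, warn = FALSE)
        lines <- trimws(sub("#.*$", "", lines))
        lines <- lines[nzchar(lines)]
        kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
        bad <- lengths(kv) != 3L
        if (any(bad))
            stop("malformed configuration line: ", lines[bad][1])
        fileVals <- stats::setNames(
            lapply(kv, function(m) trimws(m[3])),
            vapply(kv, function(m) trimws(m[2]), character(1)))
    }
    for (vals in list(fileVals, overrides)) {
        for (key in names(vals)) {
            if (!key %in% names(cfg))
                stop("unknown configuration key: ", key)
            cfg[[key]] <- .coerceLike(cfg[[key]], vals[[key]], key)
        }
    }
    numericKeys <- c("maxMismatch", "sampleSize", "minSupport",
                     "maskFloorDepth", "minSegLen", "minScoreDelta", "tol")
    for (key in numericKeys) {
        v <- cfg[[key]]
        if (!is.numeric(v) || is.na(v) || v < 0)
            stop("configuration value must be a non-negative number: ", key)
    }
    for (key in c("acceptorMaxGap", "mergeGap")) {
        v <- cfg[[key]]
        if (!is.na(v) && (!is.numeric(v) || v < 0))
            stop("configuration value must be a non-negative number: ", key)
    }
    if (!cfg$orient %in% c("mp", "pe"))
        stop("configuration key 'orient' must be \"mp\" or \"pe\"")
    cfg$grid <- gridSpec(.parseGridSpec(cfg$gridX),
                         .parseGridSpec(cfg$gridY))
    cfg
}

.coerceLike <- function(template, value, key) {
    if (is.numeric(template)) {
        out <- suppressWarnings(as.numeric(value))
        if (is.na(out) && !is.na(value))
            stop("configuration value for '", key, "' is not numeric: ",
                 value)
        out
    } else if (is.logical(template)) {
        out <- as.logical(value)
        if (is.na(out))
            stop("configuration value for '", key,
                 "' is not TRUE/FALSE: ", value)
        out
    } else {
        as.character(value)
    }
}

.parseGridSpec <- function(spec) {
    if (is.numeric(spec))
        return(spec)
    parts <- as.numeric(strsplit(spec, ":", fixed = TRUE)[[1]])
    if (length(parts) == 1L)
        return(parts)
    if (length(parts) != 3L || anyNA(parts))
        stop("grid specification must be from:to:step, got: ", spec)
    seq(parts[1], parts[2], by = parts[3])
}

#' Run the full detection pipeline
#'
#' Chains the stages end to end: mapping filter, insert-size statistics,
#' coverage mask, discordant-pair extraction, grid clustering and calling,
#' grid pooling, depth-based acceptor filtering, and (optionally)
#' annotation and donor scoring. Identical configuration and inputs give
#' identical outputs.
#'
#' @param config configuration from [loadConfig()].
#' @param alignments optional in-memory mapping table (see
#'   [readPairAlignments()], [placeReads()]); when `NULL` the BAM named in
#'   the configuration is read.
#' @param genome optional [Biostrings::DNAStringSet] reference (read from
#'   `config$reference` otherwise); required for the depth filter.
#' @param annotation optional annotation [GenomicRanges::GRanges].
#' @return list: `calls` (a [TranspositionCalls]), `stats`, `mask`,
#'   `segments`, and `report` (stage counters, library statistics, grid
#'   size, exclusion counts). With no usable input, a zero-event result is
#'   returned gracefully.
#' @export
runPipeline <- function(config = loadConfig(), alignments = NULL,
                        genome = NULL, annotation = NULL) {
    report <- list(config = config[setdiff(names(config), "grid")])
    if (is.null(alignments)) {
        if (is.na(config$bam))
            stop("no alignments supplied and no 'bam' configured")
        alignments <- readPairAlignments(config$bam)
    }
    if (is.null(genome) && !is.na(config$reference))
        genome <- Biostrings::readDNAStringSet(config$reference)
    if (!is.null(genome))
        names(genome) <- sub("\\s.*$", "", names(genome))
    if (is.null(annotation) && !is.na(config$annotation))
        annotation <- readTEAnnotation(config$annotation)

    emptyResult <- function(reason) {
        report$note <- reason
        cls <- methods::new("TranspositionCalls",
            calls = S4Vectors::DataFrame(.emptyCalls()),
            params = list())
        list(calls = cls, stats = NULL, mask = NULL, segments = NULL,
             report = report)
    }
    if (!nrow(alignments))
        return(emptyResult("no mapped reads in input"))

    properOrient <- if (config$orient == "mp") c("-", "+") else c("+", "-")
    filtered <- filterMappings(alignments, config$maxMismatch)
    report$mappings <- c(input = nrow(alignments),
                         afterMismatchFilter = nrow(filtered))
    if (!nrow(filtered))
        return(emptyResult("no mappings pass the mismatch filter"))

    stats <- estimateLibraryStats(filtered, config$sampleSize,
                                  properOrient)
    report$libraryStats <- c(M = stats@median, MAD = stats@mad,
                             dInf = stats@dInf, dSup = stats@dSup)

    chromLengths <- if (!is.null(genome))
        .chromLens(genome) else NULL
    mask <- buildCoverageMask(filtered, chromLengths,
                              floorDepth = config$maskFloorDepth)
    report$maskedRegions <- length(mask)

    disc <- extractDiscordantPairs(filtered, stats, mask,
        chromLevels = if (!is.null(chromLengths)) names(chromLengths)
                      else unique(filtered$chrom))
    report$discordant <- disc@counters
    report$discordantRecords <- nrow(records(disc))

    acceptorMaxGap <- if (is.na(config$acceptorMaxGap)) NULL
                      else config$acceptorMaxGap
    mergeGap <- if (is.na(config$mergeGap)) NULL else config$mergeGap
    perPoint <- runGrid(disc, config$grid,
                        minSupport = config$minSupport,
                        acceptorMaxGap = acceptorMaxGap,
                        mergeGap = mergeGap)
    report$clusteringAttempts <- length(perPoint)
    pooled <- mergeGridResults(perPoint)
    report$pooledLines <- nrow(calls(pooled))

    segments <- NULL
    if (config$depthFilter && !is.null(genome)) {
        segments <- computeDepthSegments(filtered, genome)
        pooled <- filterAcceptorSites(pooled, segments, config$minSegLen)
        report$depthSegments <- length(segments)
        report$depthExcludedLines <-
            report$pooledLines - nrow(calls(pooled))
    }
    if (!is.null(annotation))
        pooled <- annotateEvents(pooled, annotation)
    if (config$score)
        pooled <- scoreDonors(pooled, filtered, stats,
                              config$minScoreDelta)
    report$finalLines <- nrow(calls(pooled))
    report$finalAcceptorSites <- length(unique(
        calls(pooled)$acceptorId[calls(pooled)$eventType != "deletion"]))

    if (!is.na(config$outPrefix)) {
        writeEventTable(pooled,
                        paste0(config$outPrefix, ".events.tsv"))
        writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = 6,
                                    pretty = TRUE, force = TRUE),
                   paste0(config$outPrefix, ".report.json"))
        if (!is.null(segments) && length(segments)) {
            seg <- as.data.frame(segments)
            utils::write.table(
                data.frame(seg$seqnames, seg$start - 1L, seg$end),
                paste0(config$outPrefix, ".excluded.bed"),
                sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
        }
    }
    list(calls = pooled, stats = stats, mask = mask, segments = segments,
         report = report)
}

#' Write calls as a tab-separated event table
#'
#' One line per acceptor/donor couple, 1-based inclusive coordinates,
#' missing values (single-candidate donor scores, absent annotation)
#' rendered as the star placeholder.
#'
#' @param x a [TranspositionCalls] object.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeEventTable <- function(x, path) {
    df <- as.data.frame(calls(x))
    for (col in colnames(df)) {
        v <- df[[col]]
        if (is.numeric(v)) v <- as.character(v)
        if (is.logical(v)) v <- as.character(as.integer(v))
        v[is.na(v)] <- "*"
        df[[col]] <- v
    }
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
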