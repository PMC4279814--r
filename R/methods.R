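#' @rdname DiscordantPairs-class
#' @aliases records,DiscordantPairs-method
#' @export
setMethod("records", "DiscordantPairs", function(x) x@records)

#' @rdname DiscordantPairs-class
#' @export
setMethod("libStats", "DiscordantPairs", function(x) x@stats)

#' @rdname LibraryStats-class
#' @export
setMethod("libStats", "LibraryStats", function(x) x)

#' @rdname TranspositionCalls-class
#' @export
setMethod("calls", "TranspositionCalls", function(x) x@calls)

#' @rdname TEGenome-class
#' @export
setMethod("refGenome", "TEGenome", function(x) x@genome)

#' @rdname TEGenome-class
#' @export
setMethod("teAnnotation", "TEGenome", function(x) x@annotation)

#' @rdname TranspositionTruth-class
#' @export
setMethod("truthEvents", "TranspositionTruth", function(x) x@events)

#' @rdname TranspositionTruth-class
#' @export
setMethod("modifiedGenome", "TranspositionTruth", function(x) x@modifiedGenome)

setMethod("length", "DiscordantPairs", function(x) nrow(x@records))
setMethod("length", "TranspositionCalls", function(x) nrow(x@calls))

setMethod("show", "LibraryStats", function(object) {
    cat("LibraryStats\n")
    cat(sprintf("  median insert (M):  %.0f bp\n", object@median))
    cat(sprintf("  MAD (unscaled):     %.0f bp\n", object@mad))
    cat(sprintf("  concordance limits: (%.0f, %.0f)\n",
                object@dInf, object@dSup))
    cat(sprintf("  proper orientation: (%s, %s)\n",
                object@properOrient[1], object@properOrient[2]))
    cat(sprintf("  estimated from:     %d inserts%s\n", object@n,
                if (object@degenerate) "  [degenerate: MAD = 0]" else ""))
})

setMethod("show", "DiscordantPairs", function(object) {
    cat(sprintf("DiscordantPairs: %d pair-mapping records, %d fragments\n",
                nrow(object@records),
                length(unique(object@records$pairId))))
    if (nrow(object@records)) {
        tab <- table(object@records$signature)
        cat("  signatures:",
            paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
    }
    if (length(object@counters))
        cat("  counters:",
            paste(sprintf("%s=%d", names(object@counters), object@counters),
                  collapse = " "), "\n")
})

setMethod("show", "TranspositionCalls", function(object) {
    cc <- object@calls
    cat(sprintf("TranspositionCalls: %d lines", nrow(cc)))
    if (nrow(cc)) {
        ins <- cc$eventType != "deletion"
        cat(sprintf(", %d acceptor sites (%d insertion, %d deletion lines)",
                    length(unique(cc$acceptorId[ins])),
                    sum(ins), sum(!ins)))
    }
    cat("\n")
    if (!is.null(object@params$grid))
        cat(sprintf("  pooled over %d (X, Y) grid points\n",
                    nrow(object@params$grid)))
})

setMethod("show", "SimProfile", function(object) {
    cat("SimProfile\n")
    cat(sprintf("  read length:        %d bp (phred+%d)\n",
                object@readLen, object@qualOffset))
    cat(sprintf("  fragment sizes:     %d-%d bp, split point %.0f\n",
                min(object@fragSizes), max(object@fragSizes),
                object@splitPoint))
    cat(sprintf("  contamination odds: %.3f\n", object@contaminationOdds))
})

setMethod("show", "TEGenome", function(object) {
    cat(sprintf("TEGenome: %d chromosomes (%s bp), %d annotated TE copies in %d families\n",
                length(object@genome),
                format(sum(lengths(object@genome)), big.mark = ","),
                length(object@annotation),
                length(unique(object@annotation$family))))
})

setMethod("show", "TranspositionTruth", function(object) {
    tab <- table(object@events$eventClass)
    cat(sprintf("TranspositionTruth: %d injected events (%s)\n",
                nrow(object@events),
                paste(sprintf("%s=%d", names(tab), tab), collapse = " ")))
})

#' @export
#' @method as.data.frame TranspositionCalls
as.data.frame.TranspositionCalls <- function(x, ...)
    as.data.frame(x@calls, ...)
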