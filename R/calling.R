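#' Assemble signature clusters into transposition and deletion calls
#'
#' Implements the cluster-overlap calling heuristic. When the library
#' fragment is long relative to the mobilized sequence, the two clusters
#' anchored on the transposon (donor) side partly overlap over the middle
#' of the element, while on the insertion (acceptor) side the corresponding
#' cluster ends are close but do *not* overlap, because reads spanning the
#' exact insertion point are left unmapped. Concretely:
#' \itemize{
#'   \item sense intra-chromosomal insertion: a deletion-signature cluster
#'     and a duplication-signature cluster whose donor-side hulls overlap
#'     by at least 1 bp while their acceptor-side hulls are disjoint and
#'     separated by at most `acceptorMaxGap`;
#'   \item antisense insertion: two inversion-signature clusters of
#'     opposite orientation with the same geometry (`inverted = TRUE`);
#'   \item inter-chromosomal insertion: two translocation-signature
#'     clusters with different orientation couples overlapping at the
#'     donor; couples \{(-,+),(+,-)\} give a sense event,
#'     \{(-,-),(+,+)\} an inverted one;
#'   \item deletion: a deletion-signature cluster overlapping no
#'     duplication cluster, whose inner gap (the implied deleted length)
#'     exceeds \eqn{d_{inf}}.
#' }
#' Because each cluster hull is at most \eqn{d_{sup}} wide (see
#' [filterClusters()]) and the donor-side hulls must intersect, the donor
#' interval of any call is bounded by \eqn{2M + 6 \cdot MAD}; see
#' [maxDetectableLength()].
#'
#' @param clusters cluster table from [clusterDiscordantPairs()].
#' @param stats a [LibraryStats] object.
#' @param acceptorMaxGap maximum separation of the acceptor-side hulls
#'   (default \eqn{2 d_{sup} = 2M + 6 MAD}). For an element of length
#'   \eqn{T} the flank-anchored clusters stop roughly \eqn{F - T} short
#'   of the insertion point on each side (fragment length \eqn{F}), so
#'   the unmapped breakpoint gap can approach two fragment lengths for
#'   short elements; bounding it by \eqn{2 d_{sup}} keeps those callable
#'   while still rejecting unrelated cluster couples.
#' @return a [TranspositionCalls] object. Insertion lines that share an
#'   acceptor interval (candidate donors of one insertion) share an
#'   `acceptorId`. The `companionDel` column flags a further
#'   deletion-signature cluster at the donor, the expected footprint of a
#'   cut-and-paste event. Clusters that pair with nothing are returned in
#'   `params$unpaired` for manual inspection.
#' @export
callEvents <- function(clusters, stats, acceptorMaxGap = NULL) {
    if (is.null(acceptorMaxGap))
        acceptorMaxGap <- 2 * stats@dSup
    out <- list()
    usedDel <- logical(nrow(clusters))
    paired <- logical(nrow(clusters))
    if (nrow(clusters)) {
        bySame <- clusters$chromA == clusters$chromB
        idx <- seq_len(nrow(clusters))
        # intra-chromosomal: Del x Dup (sense), Inv x Inv opposite (antisense)
        for (chr in unique(clusters$chromA[bySame])) {
            sel <- bySame & clusters$chromA == chr
            del <- idx[sel & clusters$signature == "Del"]
            dup <- idx[sel & clusters$signature == "Dup"]
            for (i in del) for (j in dup) {
                ev <- .clusterPairGeometry(clusters, i, j, acceptorMaxGap)
                if (is.null(ev)) next
                usedDel[i] <- TRUE; paired[c(i, j)] <- TRUE
                out[[length(out) + 1L]] <- .eventRow(
                    "insertion_sense", chr, ev, chr, FALSE,
                    .pairSupport(clusters, i, j))
            }
            invm <- idx[sel & clusters$signature == "Inv" &
                        clusters$orientA == "-"]
            invp <- idx[sel & clusters$signature == "Inv" &
                        clusters$orientA == "+"]
            for (i in invm) for (j in invp) {
                ev <- .clusterPairGeometry(clusters, i, j, acceptorMaxGap)
                if (is.null(ev)) next
                paired[c(i, j)] <- TRUE
                out[[length(out) + 1L]] <- .eventRow(
                    "insertion_antisense", chr, ev, chr, TRUE,
                    .pairSupport(clusters, i, j))
            }
        }
        # inter-chromosomal: Trans x Trans, different orientation couples
        trans <- idx[!bySame & clusters$signature == "Trans"]
        if (length(trans) > 1L) {
            pairKey <- paste(clusters$chromA[trans], clusters$chromB[trans])
            for (key in unique(pairKey)) {
                tt <- trans[pairKey == key]
                if (length(tt) < 2L) next
                for (a in seq_len(length(tt) - 1L)) for (b in (a + 1L):length(tt)) {
                    i <- tt[a]; j <- tt[b]
                    oi <- c(clusters$orientA[i], clusters$orientB[i])
                    oj <- c(clusters$orientA[j], clusters$orientB[j])
                    if (identical(oi, oj)) next
                    eqI <- oi[1] == oi[2]; eqJ <- oj[1] == oj[2]
                    if (eqI != eqJ) next   # incompatible couples
                    ev <- .clusterPairGeometry(clusters, i, j, acceptorMaxGap)
                    if (is.null(ev)) next
                    paired[c(i, j)] <- TRUE
                    donorChrom <- if (ev$donorSide == "A")
                        clusters$chromA[i] else clusters$chromB[i]
                    accChrom <- if (ev$donorSide == "A")
                        clusters$chromB[i] else clusters$chromA[i]
                    out[[length(out) + 1L]] <- .eventRow(
                        "insertion_interchrom", accChrom, ev, donorChrom,
                        eqI, .pairSupport(clusters, i, j))
                }
            }
        }
        # deletions: unpaired Del clusters with no overlapping Dup cluster
        del <- idx[bySame & clusters$signature == "Del" & !usedDel]
        for (i in del) {
            chr <- clusters$chromA[i]
            dup <- idx[bySame & clusters$chromA == chr &
                       clusters$signature == "Dup"]
            ovl <- any(vapply(dup, function(j) {
                .hullOverlap(clusters$startA[i], clusters$endA[i],
                             clusters$startA[j], clusters$endA[j]) >= 1 ||
                .hullOverlap(clusters$startB[i], clusters$endB[i],
                             clusters$startB[j], clusters$endB[j]) >= 1
            }, logical(1)))
            innerGap <- clusters$startB[i] - clusters$endA[i]
            if (!ovl && innerGap > stats@dInf) {
                paired[i] <- TRUE
                out[[length(out) + 1L]] <- data.frame(
                    eventType = "deletion", acceptorChrom = chr,
                    acceptorStart = clusters$endA[i],
                    acceptorEnd = clusters$startB[i],
                    donorChrom = NA_character_, donorStart = NA_real_,
                    donorEnd = NA_real_, overlap = NA_real_,
                    support = clusters$support[i], inverted = FALSE,
                    stringsAsFactors = FALSE)
            }
        }
    }
    df <- if (length(out)) do.call(rbind, out) else .emptyCalls()
    df$acceptorSize <- df$acceptorEnd - df$acceptorStart
    df$donorSize <- df$donorEnd - df$donorStart
    df <- .flagCompanionDel(df, clusters)
    df <- .assignAcceptorIds(df)
    cols <- c("acceptorId", "eventType", "acceptorChrom", "acceptorStart",
              "acceptorEnd", "acceptorSize", "donorChrom", "donorStart",
              "donorEnd", "donorSize", "overlap", "support", "inverted",
              "companionDel")
    methods::new("TranspositionCalls",
        calls = S4Vectors::DataFrame(df[, cols]),
        params = list(acceptorMaxGap = acceptorMaxGap,
                      unpaired = clusters[!paired, , drop = FALSE]))
}

.emptyCalls <- function() {
    data.frame(eventType = character(), acceptorChrom = character(),
               acceptorStart = numeric(), acceptorEnd = numeric(),
               donorChrom = character(), donorStart = numeric(),
               donorEnd = numeric(), overlap = numeric(),
               support = integer(), inverted = logical(),
               stringsAsFactors = FALSE)
}

# Two-sided geometry test for a candidate cluster couple: one axis must
# overlap (the donor side), the other must be disjoint with a bounded gap
# (the acceptor side, the unsequenced breakpoint). Returns NULL or the
# donor/acceptor intervals.
.clusterPairGeometry <- function(cl, i, j, maxGap) {
    ovA <- .hullOverlap(cl$startA[i], cl$endA[i], cl$startA[j], cl$endA[j])
    ovB <- .hullOverlap(cl$startB[i], cl$endB[i], cl$startB[j], cl$endB[j])
    gapA <- .hullGap(cl$startA[i], cl$endA[i], cl$startA[j], cl$endA[j])
    gapB <- .hullGap(cl$startB[i], cl$endB[i], cl$startB[j], cl$endB[j])
    if (ovB >= 1 && ovA < 1 && gapA <= maxGap) {
        donor <- c(min(cl$startB[i], cl$startB[j]),
                   max(cl$endB[i], cl$endB[j]))
        acc <- sort(c(min(cl$endA[i], cl$endA[j]),
                      max(cl$startA[i], cl$startA[j])))
        list(donor = donor, acceptor = acc, overlap = ovB, donorSide = "B")
    } else if (ovA >= 1 && ovB < 1 && gapB <= maxGap) {
        donor <- c(min(cl$startA[i], cl$startA[j]),
                   max(cl$endA[i], cl$endA[j]))
        acc <- sort(c(min(cl$endB[i], cl$endB[j]),
                      max(cl$startB[i], cl$startB[j])))
        list(donor = donor, acceptor = acc, overlap = ovA, donorSide = "A")
    } else {
        NULL
    }
}

.pairSupport <- function(cl, i, j) {
    length(unique(c(cl$memberIds[[i]], cl$memberIds[[j]])))
}

.eventRow <- function(type, accChrom, ev, donorChrom, inverted, support) {
    data.frame(eventType = type, acceptorChrom = accChrom,
               acceptorStart = ev$acceptor[1], acceptorEnd = ev$acceptor[2],
               donorChrom = donorChrom, donorStart = ev$donor[1],
               donorEnd = ev$donor[2], overlap = ev$overlap,
               support = support, inverted = inverted,
               stringsAsFactors = FALSE)
}

# Advisory flag: an unrelated Del cluster whose implied deleted interval
# overlaps the donor marks possible cut-and-paste transposition.
.flagCompanionDel <- function(df, clusters) {
    df$companionDel <- logical(nrow(df))
    ins <- which(df$eventType != "deletion")
    if (!length(ins) || !nrow(clusters))
        return(df)
    del <- which(clusters$signature == "Del" &
                 clusters$chromA == clusters$chromB)
    for (k in ins) {
        if (!length(del)) break
        hit <- vapply(del, function(i) {
            clusters$chromA[i] == df$donorChrom[k] &&
            .hullOverlap(clusters$endA[i], clusters$startB[i],
                         df$donorStart[k], df$donorEnd[k]) >= 1
        }, logical(1))
        df$companionDel[k] <- any(hit)
    }
    df
}

# Insertion lines whose acceptor intervals overlap describe candidate
# donors of the same insertion and share an acceptor id; ids are assigned
# in (chrom, start) order for deterministic output.
.assignAcceptorIds <- function(df) {
    df$acceptorId <- rep(NA_character_, nrow(df))
    if (!nrow(df))
        return(df)
    o <- order(df$acceptorChrom, df$acceptorStart, df$acceptorEnd,
               df$eventType, df$donorChrom, df$donorStart)
    df <- df[o, , drop = FALSE]
    ins <- df$eventType != "deletion"
    for (part in list(which(ins), which(!ins))) {
        if (!length(part)) next
        gid <- 0L; lastChrom <- ""; lastEnd <- -Inf
        ids <- integer(length(part))
        for (k in seq_along(part)) {
            r <- part[k]
            if (df$acceptorChrom[r] != lastChrom ||
                df$acceptorStart[r] > lastEnd) {
                gid <- gid + 1L
                lastChrom <- df$acceptorChrom[r]
                lastEnd <- df$acceptorEnd[r]
            } else {
                lastEnd <- max(lastEnd, df$acceptorEnd[r])
            }
            ids[k] <- gid
        }
        prefix <- if (df$eventType[part[1]] == "deletion") "D" else "A"
        df$acceptorId[part] <- sprintf("%s%04d", prefix, ids)
    }
    rownames(df) <- NULL
    df
}

#' Detectability bounds of the method
#'
#' The donor sequence is reconstituted from the overlap of the two
#' breakpoint-anchored clusters, so an element is only fully spanned when
#' it is shorter than twice the mean fragment length \eqn{L}; the
#' cluster-size filter likewise bounds callable translocations at
#' \eqn{2M + 6 \cdot MAD}.
#'
#' @param L mean sequenced-fragment length (bp).
#' @param M,MAD median and median absolute deviation of the insert size.
#' @return named numeric: `teBound` (\eqn{2L}) and `translocationBound`
#'   (\eqn{2M + 6 \cdot MAD}).
#' @examples
#' maxDetectableLength(5000, 4900, 100)
#' @export
maxDetectableLength <- function(L, M, MAD) {
    stopifnot(L > 0, M > 0, MAD >= 0)
    c(teBound = 2 * L, translocationBound = 2 * M + 6 * MAD)
}

#' Default clustering-threshold grid
#'
#' The two linking thresholds are the method's main free parameters; to
#' maximize sensitivity the clustering is re-run over a regular grid of
#' increasing `X` (step 50, 50-1000) and `Y` (step 100, 100-5000) - 1000
#' clustering attempts - and the per-point results pooled.
#'
#' @param xValues,yValues strictly increasing threshold sequences.
#' @return list with `x`, `y` and the full `grid` (a data.frame of all
#'   couples in (X, Y) lexicographic order).
#' @export
gridSpec <- function(xValues = seq(50, 1000, by = 50),
                     yValues = seq(100, 5000, by = 100)) {
    stopifnot(all(diff(xValues) > 0), all(diff(yValues) > 0),
              all(xValues > 0), all(yValues > 0))
    list(x = xValues, y = yValues,
         grid = expand.grid(Y = yValues, X = xValues)[, c("X", "Y")])
}

#' Run clustering and calling over a threshold grid
#'
#' One complete cluster + call pass per grid point. Points are independent;
#' results are keyed by `"X=..,Y=.."` and are identical to sequential
#' execution by construction.
#'
#' @param x a [DiscordantPairs] object.
#' @param grid a grid from [gridSpec()].
#' @param minSupport,acceptorMaxGap,mergeGap forwarded to
#'   [clusterDiscordantPairs()] and [callEvents()].
#' @return named list; each element holds `X`, `Y`, `calls` (a
#'   [TranspositionCalls]) and `nClusters`. Per-point failures are
#'   propagated with the offending `(X, Y)` named.
#' @export
runGrid <- function(x, grid = gridSpec(), minSupport = 10L,
                    acceptorMaxGap = NULL, mergeGap = NULL) {
    stopifnot(nrow(grid$grid) > 0L)
    stats <- libStats(x)
    res <- vector("list", nrow(grid$grid))
    names(res) <- sprintf("X=%d,Y=%d", grid$grid$X, grid$grid$Y)
    for (k in seq_len(nrow(grid$grid))) {
        X <- grid$grid$X[k]; Y <- grid$grid$Y[k]
        res[[k]] <- tryCatch({
            cl <- clusterDiscordantPairs(x, X, Y, mergeGap = mergeGap,
                                         minSupport = minSupport)
            list(X = X, Y = Y,
                 calls = callEvents(cl, stats, acceptorMaxGap),
                 nClusters = nrow(cl))
        }, error = function(e) {
            stop(sprintf("grid point (X=%d, Y=%d) failed: %s",
                         X, Y, conditionMessage(e)), call. = FALSE)
        })
    }
    res
}

#' Pool event calls across the threshold grid
#'
#' Builds a registry seeded from the grid point with the largest number of
#' insertions (distinct acceptor sites; ties broken by total support, then
#' by (X, Y) order). Every other point is then traversed in (X, Y) order:
#' a line overlapping a registry line on *both* donor and acceptor
#' intervals is the same event, and the instance supported by the most
#' reads is kept; a line overlapping no registry line on either side is a
#' new event and is appended; a line overlapping on exactly one side is
#' ambiguous and dropped. Deletion lines are pooled against deletion lines
#' on the acceptor interval alone.
#'
#' @param perPoint result list from [runGrid()].
#' @return a pooled [TranspositionCalls]; `params$seedPoint` names the
#'   seeding grid point.
#' @export
mergeGridResults <- function(perPoint) {
    stopifnot(length(perPoint) > 0L)
    tabs <- lapply(perPoint, function(p) as.data.frame(calls(p$calls)))
    nIns <- vapply(tabs, function(t)
        length(unique(t$acceptorId[t$eventType != "deletion"])), integer(1))
    supTot <- vapply(tabs, function(t) sum(t$support), numeric(1))
    XY <- data.frame(X = vapply(perPoint, `[[`, numeric(1), "X"),
                     Y = vapply(perPoint, `[[`, numeric(1), "Y"))
    o <- order(-nIns, -supTot, XY$X, XY$Y)
    seed <- o[1]
    registry <- tabs[[seed]]
    others <- setdiff(order(XY$X, XY$Y), seed)
    for (k in others) {
        tab <- tabs[[k]]
        if (!nrow(tab)) next
        for (r in seq_len(nrow(tab))) {
            line <- tab[r, , drop = FALSE]
            if (!nrow(registry)) {
                registry <- line
                next
            }
            accOv <- registry$acceptorChrom == line$acceptorChrom &
                .hullOverlap(registry$acceptorStart, registry$acceptorEnd,
                             line$acceptorStart, line$acceptorEnd) >= 0
            if (line$eventType == "deletion") {
                same <- accOv & registry$eventType == "deletion"
                if (any(same)) {
                    b <- which(same)[which.max(registry$support[same])]
                    if (line$support > registry$support[b])
                        registry[b, ] <- line
                } else if (!any(accOv)) {
                    registry <- rbind(registry, line)
                }
                next
            }
            donOv <- !is.na(registry$donorChrom) &
                registry$donorChrom == line$donorChrom &
                .hullOverlap(registry$donorStart, registry$donorEnd,
                             line$donorStart, line$donorEnd) >= 0
            both <- accOv & donOv
            if (any(both)) {
                b <- which(both)[which.max(registry$support[both])]
                if (line$support > registry$support[b]) {
                    keepId <- registry$acceptorId[b]
                    registry[b, ] <- line
                    registry$acceptorId[b] <- keepId
                }
            } else if (!any(accOv) && !any(donOv)) {
                registry <- rbind(registry, line)
            }
        }
    }
    registry <- .assignAcceptorIds(registry)
    methods::new("TranspositionCalls",
        calls = S4Vectors::DataFrame(registry),
        params = list(grid = XY,
                      seedPoint = c(X = XY$X[seed], Y = XY$Y[seed]),
                      nGridPoints = nrow(XY)))
}
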