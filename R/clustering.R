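#' Partition discordant records for independent clustering
#'
#' Discordant pair mappings are clustered independently per signature kind,
#' orientation couple and (ordered) chromosome pair: two records can only
#' ever support the same breakpoint side if they agree on all three. With
#' `k` chromosomes and four orientation couples this yields at most
#' \eqn{4 \times \binom{k+1}{2}} partitions per insert regime, and each
#' partition can be processed independently (and concurrently), so run time
#' scales with per-chromosome-pair, not whole-genome, read counts.
#'
#' @param x a [DiscordantPairs] object or its `records` table.
#' @return named list of partitions; each element is a data.frame of
#'   cluster points with columns `la` (sorted-mate coordinate), `lb`
#'   (unsorted-mate coordinate), `pairId`, plus the shared `signature`,
#'   `chromA`, `chromB`, `orientA`, `orientB`.
#' @export
partitionPoints <- function(x) {
    rec <- if (methods::is(x, "DiscordantPairs")) as.data.frame(records(x))
           else as.data.frame(x)
    if (!nrow(rec))
        return(list())
    key <- paste(rec$signature, rec$chromA, rec$chromB,
                 rec$orientA, rec$orientB, sep = "|")
    parts <- split(rec, key)
    lapply(parts, function(p) {
        data.frame(la = p$posA, lb = p$posB, pairId = p$pairId,
                   signature = p$signature[1],
                   chromA = p$chromA[1], chromB = p$chromB[1],
                   orientA = p$orientA[1], orientB = p$orientB[1],
                   stringsAsFactors = FALSE)
    })
}

# Disjoint-set forest with path halving, held in a closure environment.
.newUnionFind <- function(n) {
    parent <- seq_len(n)
    find <- function(i) {
        while (parent[i] != i) {
            parent[i] <<- parent[parent[i]]
            i <- parent[i]
        }
        i
    }
    union <- function(i, j) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <<- rj
        invisible(NULL)
    }
    components <- function() vapply(seq_len(n), find, integer(1))
    list(find = find, union = union, components = components)
}

#' Seeded single-linkage clustering in mate-position space
#'
#' Each discordant pair mapping is a point \eqn{(l_a, l_b)}. Two points are
#' linked when \eqn{|\Delta l_a| \le X} *and* \eqn{|\Delta l_b| \le Y};
#' clusters are the connected components of the resulting graph. The
#' sorted-mate threshold `X` is governed by coverage fluctuation and is
#' intentionally smaller than the unsorted-mate threshold `Y`, which must
#' absorb the insert-size dispersion. The implementation scans points in
#' `la` order, linking each point against the still-active window
#' (`la` within `X`), which reproduces the exact transitive closure because
#' every graph edge satisfies the window condition.
#'
#' @param points data.frame with columns `la`, `lb`, `pairId` (a partition
#'   from [partitionPoints()]; extra columns are carried through).
#' @param X,Y linking thresholds (bp), both `> 0`.
#' @return data.frame of clusters: hull intervals `startA`, `endA`
#'   (over `la`), `startB`, `endB` (over `lb`), `support` (distinct
#'   fragments), `nRecords`, and a `members` list-column of row indices
#'   into `points` (with the member `pairId`s as `memberIds`).
#' @examples
#' pts <- data.frame(la = c(1000, 1050, 1120), lb = c(9000, 9200, 9600),
#'                   pairId = as.character(1:3))
#' singleLinkageCluster(pts, X = 100, Y = 500)  # one cluster of 3
#' @export
singleLinkageCluster <- function(points, X, Y) {
    stopifnot(X > 0, Y > 0)
    if (!nrow(points))
        return(.emptyClusters())
    o <- order(points$la, points$lb)
    la <- points$la[o]
    lb <- points$lb[o]
    n <- length(la)
    uf <- .newUnionFind(n)
    lo <- 1L
    for (i in seq_len(n)) {
        while (la[i] - la[lo] > X) lo <- lo + 1L
        if (lo < i) {
            js <- lo:(i - 1L)
            js <- js[abs(lb[js] - lb[i]) <= Y]
            for (j in js)
                uf$union(i, j)
        }
    }
    .summarizeClusters(points, o, uf$components())
}

.emptyClusters <- function() {
    df <- data.frame(startA = integer(), endA = integer(),
                     startB = integer(), endB = integer(),
                     support = integer(), nRecords = integer())
    df$members <- list()
    df$memberIds <- list()
    df
}

.summarizeClusters <- function(points, o, comp) {
    idx <- split(o, comp)
    clusters <- lapply(idx, function(ii) {
        data.frame(
            startA = min(points$la[ii]), endA = max(points$la[ii]),
            startB = min(points$lb[ii]), endB = max(points$lb[ii]),
            support = length(unique(points$pairId[ii])),
            nRecords = length(ii))
    })
    out <- do.call(rbind, clusters)
    out$members <- unname(idx)
    out$memberIds <- lapply(unname(idx), function(ii)
        unique(points$pairId[ii]))
    extra <- setdiff(colnames(points), c("la", "lb", "pairId"))
    for (cn in extra)
        out[[cn]] <- points[[cn]][1]
    rownames(out) <- NULL
    out[order(out$startA, out$startB), , drop = FALSE]
}

#' Merge nearby clusters with identical signatures
#'
#' Local drops in coverage can interrupt the linking process and split the
#' evidence for one breakpoint into several same-signature clusters. Two
#' clusters are merged (transitively) when the gaps between their interval
#' hulls are at most `gap` on *both* axes; member sets concatenate and the
#' hulls take the union. The operation is idempotent. Only clusters sharing
#' signature, chromosome pair and orientation couple are ever considered.
#'
#' @param clusters cluster table from [singleLinkageCluster()].
#' @param gap proximity threshold (bp). The pipeline default is the current
#'   `Y`: the same insert-size dispersion that motivates `Y` governs how
#'   far a coverage drop can split a cluster.
#' @return merged cluster table.
#' @export
mergeClusters <- function(clusters, gap) {
    n <- nrow(clusters)
    if (n <= 1L)
        return(clusters)
    sig <- if (!is.null(clusters$signature))
        paste(clusters$signature, clusters$chromA, clusters$chromB,
              clusters$orientA, clusters$orientB)
    else rep("", n)
    uf <- .newUnionFind(n)
    o <- order(sig, clusters$startA)
    sA <- clusters$startA[o]; eA <- clusters$endA[o]
    sB <- clusters$startB[o]; eB <- clusters$endB[o]
    sigO <- sig[o]
    # scan in startA order; a link requires startA[i] - endA[j] <= gap, so
    # once the running max of endA over all earlier clusters falls more
    # than `gap` behind startA[i] no earlier cluster can link to i
    cmax <- eA
    for (i in 2:n) {
        if (sigO[i] == sigO[i - 1L])
            cmax[i] <- max(cmax[i - 1L], eA[i])
        j <- i - 1L
        while (j >= 1L && sigO[j] == sigO[i] && sA[i] - cmax[j] <= gap) {
            gA <- .hullGap(sA[i], eA[i], sA[j], eA[j])
            gB <- .hullGap(sB[i], eB[i], sB[j], eB[j])
            if (gA <= gap && gB <= gap)
                uf$union(o[i], o[j])
            j <- j - 1L
        }
    }
    groups <- split(seq_len(n), uf$components())
    merged <- lapply(groups, function(ii) {
        row <- clusters[ii[1], , drop = FALSE]
        row$startA <- min(clusters$startA[ii])
        row$endA <- max(clusters$endA[ii])
        row$startB <- min(clusters$startB[ii])
        row$endB <- max(clusters$endB[ii])
        row$members[[1]] <- unlist(clusters$members[ii], use.names = FALSE)
        row$memberIds[[1]] <- unique(unlist(clusters$memberIds[ii],
                                            use.names = FALSE))
        row$support <- length(row$memberIds[[1]])
        row$nRecords <- sum(clusters$nRecords[ii])
        row
    })
    out <- do.call(rbind, merged)
    rownames(out) <- NULL
    out[order(out$startA, out$startB), , drop = FALSE]
}

#' Filter clusters on hull size and support
#'
#' Reads around a single breakpoint can only be dispersed by as much as the
#' insert-size distribution allows, so any cluster whose hull extent
#' exceeds \eqn{d_{sup}} on either axis is rejected. Clusters supported by
#' fewer than `minSupport` distinct fragments are rejected as likely
#' mapping noise.
#'
#' @param clusters cluster table.
#' @param stats a [LibraryStats] object.
#' @param minSupport minimum distinct supporting fragments (default 10,
#'   appropriate for long-fragment libraries; use ~3 for short-fragment
#'   paired-end data).
#' @return filtered cluster table.
#' @export
filterClusters <- function(clusters, stats, minSupport = 10L) {
    if (!nrow(clusters))
        return(clusters)
    spanA <- clusters$endA - clusters$startA
    spanB <- clusters$endB - clusters$startB
    keep <- spanA <= stats@dSup & spanB <= stats@dSup &
        clusters$support >= minSupport
    clusters[keep, , drop = FALSE]
}

#' One full clustering pass over all partitions
#'
#' Partition, single-linkage cluster, merge and filter for one `(X, Y)`
#' setting. Deletion- and insertion-signature points, which share the
#' proper orientation couple, are clustered separately because they carry
#' different signatures.
#'
#' @inheritParams partitionPoints
#' @inheritParams singleLinkageCluster
#' @param mergeGap proximity threshold for cluster merging; `NULL` (the
#'   default) uses `Y`.
#' @param stats a [LibraryStats]; defaults to the one carried by `x`.
#' @param minSupport see [filterClusters()].
#' @return a single cluster table (rows from all partitions), sorted by
#'   chromosome pair and `startA` for deterministic output.
#' @export
clusterDiscordantPairs <- function(x, X, Y, mergeGap = NULL,
                                   stats = NULL, minSupport = 10L) {
    if (is.null(stats)) {
        stopifnot(methods::is(x, "DiscordantPairs"))
        stats <- libStats(x)
    }
    if (is.null(mergeGap))
        mergeGap <- Y
    parts <- partitionPoints(x)
    res <- lapply(parts, function(p) {
        cl <- singleLinkageCluster(p, X, Y)
        cl <- mergeClusters(cl, mergeGap)
        filterClusters(cl, stats, minSupport)
    })
    res <- res[vapply(res, nrow, integer(1)) > 0L]
    if (!length(res)) {
        out <- .emptyClusters()
        out$signature <- character()
        out$chromA <- character(); out$chromB <- character()
        out$orientA <- character(); out$orientB <- character()
        return(out)
    }
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out[order(out$chromA, out$chromB, out$startA, out$signature), ,
        drop = FALSE]
}
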