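#' Evaluate event calls against an injection truth table
#'
#' Scores predictions at the acceptor-site level (lines sharing an
#' `acceptorId` are candidate donors of one predicted insertion):
#' \describe{
#'   \item{found}{an injected event whose true insertion point lies
#'     within `tol` bp of some predicted acceptor interval;}
#'   \item{found with donor}{additionally, one such line's donor interval
#'     overlaps the true donor span;}
#'   \item{true positive prediction}{a predicted acceptor site matching
#'     some injected event on both criteria;}
#' }
#' `PPV` is true positives over all predicted acceptor sites, and
#' `sensitivity` is found-with-donor over injected events (both as
#' percentages). The report is invariant to the ordering of events and to
#' duplicated donor lines under one `acceptorId`.
#'
#' @param x a [TranspositionCalls] object (insertion lines are used).
#' @param truth a [TranspositionTruth] (or its events table).
#' @param tol acceptor-match tolerance in bp (default 300).
#' @return list: per-truth-event table (`found`, `foundWithDonor`),
#'   counts, `ppv`, `sensitivity` (percent; `ppv` is `NA` when nothing
#'   was predicted).
#' @export
evaluateCalls <- function(x, truth, tol = 300) {
    ev <- if (methods::is(truth, "TranspositionTruth"))
        as.data.frame(truthEvents(truth)) else as.data.frame(truth)
    if (!nrow(ev))
        stop("empty truth table")
    df <- as.data.frame(calls(x))
    df <- df[df$eventType != "deletion", , drop = FALSE]

    found <- logical(nrow(ev))
    foundDonor <- logical(nrow(ev))
    minDist <- rep(Inf, nrow(ev))
    predTrue <- setNames(logical(length(unique(df$acceptorId))),
                         unique(df$acceptorId))
    if (nrow(df)) {
        for (i in seq_len(nrow(ev))) {
            accDist <- ifelse(df$acceptorChrom == ev$acceptorChrom[i],
                pmax(0, pmax(df$acceptorStart - ev$acceptorPos[i],
                             ev$acceptorPos[i] - df$acceptorEnd)),
                Inf)
            minDist[i] <- min(accDist)
            nearAcc <- accDist <= tol
            if (!any(nearAcc)) next
            found[i] <- TRUE
            donorOv <- nearAcc & !is.na(df$donorChrom) &
                df$donorChrom == ev$donorChrom[i] &
                .hullOverlap(df$donorStart, df$donorEnd,
                             ev$donorStart[i], ev$donorEnd[i]) >= 0
            if (any(donorOv)) {
                foundDonor[i] <- TRUE
                predTrue[unique(df$acceptorId[donorOv])] <- TRUE
            }
        }
    }
    nPred <- length(predTrue)
    tp <- sum(predTrue)
    list(
        perEvent = data.frame(ev, found = found,
                              foundWithDonor = foundDonor,
                              minAcceptorDist = minDist),
        nTruth = nrow(ev),
        nPredicted = nPred,
        found = sum(found),
        foundWithDonor = sum(foundDonor),
        truePositives = tp,
        falsePositives = nPred - tp,
        ppv = if (nPred) 100 * tp / nPred else NA_real_,
        sensitivity = 100 * sum(foundDonor) / nrow(ev))
}
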