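st <- mkStats(5000, 100)

# hand-built cluster rows (as produced by clusterDiscordantPairs)
mkCluster <- function(sig, oA, oB, startA, endA, startB, endB,
                      chromA = "chr1", chromB = "chr1",
                      ids = sprintf("p%03d", seq_len(12))) {
    df <- data.frame(startA = startA, endA = endA, startB = startB,
                     endB = endB, support = length(ids),
                     nRecords = length(ids), stringsAsFactors = FALSE)
    df$members <- list(seq_along(ids))
    df$memberIds <- list(ids)
    df$signature <- sig
    df$chromA <- chromA; df$chromB <- chromB
    df$orientA <- oA; df$orientB <- oB
    df
}

test_that("a Del/Dup couple with donor-side overlap calls a sense insertion", {
    cl <- rbind(
        mkCluster("Del", "-", "+", 5000, 5400, 20000, 24000,
                  ids = sprintf("a%d", 1:12)),
        mkCluster("Dup", "+", "-", 5450, 5800, 22000, 26000,
                  ids = sprintf("b%d", 1:12)))
    ev <- as.data.frame(calls(callEvents(cl, st)))
    expect_equal(nrow(ev), 1L)
    expect_equal(ev$eventType, "insertion_sense")
    expect_equal(c(ev$donorStart, ev$donorEnd), c(20000, 26000))
    expect_equal(ev$overlap, 2000)
    expect_equal(c(ev$acceptorStart, ev$acceptorEnd), c(5400, 5450))
    expect_equal(ev$support, 24L)
    expect_false(ev$inverted)
})

test_that("no insertion is called from a single cluster or without donor overlap", {
    # lone Dup cluster: nothing
    lone <- mkCluster("Dup", "+", "-", 5450, 5800, 22000, 26000)
    expect_equal(nrow(calls(callEvents(lone, st))), 0L)
    # donor sides disjoint: nothing
    cl <- rbind(
        mkCluster("Del", "-", "+", 5000, 5400, 20000, 21000),
        mkCluster("Dup", "+", "-", 5450, 5800, 25000, 26000))
    ev <- as.data.frame(calls(callEvents(cl, st)))
    expect_false(any(ev$eventType == "insertion_sense"))
    # acceptor sides overlapping: nothing
    cl2 <- rbind(
        mkCluster("Del", "-", "+", 5000, 5600, 20000, 24000),
        mkCluster("Dup", "+", "-", 5450, 5800, 22000, 26000))
    expect_equal(sum(as.data.frame(calls(callEvents(cl2, st)))$eventType ==
                     "insertion_sense"), 0L)
})

test_that("opposite-orientation inversion clusters call an antisense insertion", {
    cl <- rbind(
        mkCluster("Inv", "-", "-", 5000, 5400, 20000, 24000,
                  ids = sprintf("a%d", 1:12)),
        mkCluster("Inv", "+", "+", 5450, 5800, 22500, 26000,
                  ids = sprintf("b%d", 1:12)))
    ev <- as.data.frame(calls(callEvents(cl, st)))
    expect_equal(ev$eventType, "insertion_antisense")
    expect_true(ev$inverted)
    expect_equal(ev$overlap, 1500)
})

test_that("same-orientation inversion clusters never pair", {
    cl <- rbind(
        mkCluster("Inv", "-", "-", 5000, 5400, 20000, 24000,
                  ids = sprintf("a%d", 1:12)),
        mkCluster("Inv", "-", "-", 5450, 5800, 22500, 26000,
                  ids = sprintf("b%d", 1:12)))
    expect_equal(nrow(calls(callEvents(cl, st))), 0L)
})

test_that("translocation clusters of different orientation call interchromosomal insertions", {
    cl <- rbind(
        mkCluster("Trans", "-", "+", 5000, 5400, 20000, 24000,
                  chromB = "chr2", ids = sprintf("a%d", 1:12)),
        mkCluster("Trans", "+", "-", 5450, 5800, 22000, 26000,
                  chromB = "chr2", ids = sprintf("b%d", 1:12)))
    ev <- as.data.frame(calls(callEvents(cl, st)))
    expect_equal(ev$eventType, "insertion_interchrom")
    expect_equal(ev$acceptorChrom, "chr1")
    expect_equal(ev$donorChrom, "chr2")
    expect_false(ev$inverted)

    # equal-strand couples mark an inverted interchromosomal event
    cl2 <- rbind(
        mkCluster("Trans", "-", "-", 5000, 5400, 20000, 24000,
                  chromB = "chr2", ids = sprintf("a%d", 1:12)),
        mkCluster("Trans", "+", "+", 5450, 5800, 22000, 26000,
                  chromB = "chr2", ids = sprintf("b%d", 1:12)))
    ev2 <- as.data.frame(calls(callEvents(cl2, st)))
    expect_equal(ev2$eventType, "insertion_interchrom")
    expect_true(ev2$inverted)

    # incompatible couples (one equal-strand, one not) never pair
    cl3 <- rbind(
        mkCluster("Trans", "-", "+", 5000, 5400, 20000, 24000,
                  chromB = "chr2", ids = sprintf("a%d", 1:12)),
        mkCluster("Trans", "+", "+", 5450, 5800, 22000, 26000,
                  chromB = "chr2", ids = sprintf("b%d", 1:12)))
    expect_equal(nrow(calls(callEvents(cl3, st))), 0L)
})

test_that("a lone Del cluster with a large inner gap supports a deletion", {
    # inner gap = 13000 - 5400 > dInf = 4700
    del <- mkCluster("Del", "-", "+", 5000, 5400, 13000, 13400)
    ev <- as.data.frame(calls(callEvents(del, st)))
    expect_equal(ev$eventType, "deletion")
    expect_equal(c(ev$acceptorStart, ev$acceptorEnd), c(5400, 13000))
    # small inner gap (< dInf): no deletion call
    near <- mkCluster("Del", "-", "+", 5000, 5400, 8000, 8400)
    expect_equal(nrow(calls(callEvents(near, st))), 0L)
})

test_that("a Del cluster consumed by an insertion never doubles as a deletion", {
    cl <- rbind(
        mkCluster("Del", "-", "+", 5000, 5400, 20000, 24000,
                  ids = sprintf("a%d", 1:12)),
        mkCluster("Dup", "+", "-", 5450, 5800, 22000, 26000,
                  ids = sprintf("b%d", 1:12)))
    ev <- as.data.frame(calls(callEvents(cl, st)))
    expect_equal(ev$eventType, "insertion_sense")
    expect_false("deletion" %in% ev$eventType)
})

test_that("detectability bounds follow the fragment and insert statistics", {
    expect_equal(unname(maxDetectableLength(5000, 4900, 100)),
                 c(10000, 10400))
    expect_equal(unname(maxDetectableLength(150, 140, 10)["teBound"]), 300)
})

test_that("the default grid enumerates 1000 clustering attempts", {
    g <- gridSpec()
    expect_equal(nrow(g$grid), 1000L)
    expect_equal(length(g$x), 20L)
    expect_equal(length(g$y), 50L)
    expect_equal(nrow(gridSpec(100, 500)$grid), 1L)
    expect_equal(nrow(gridSpec(c(50, 100), c(400, 800))$grid), 4L)
    expect_error(gridSpec(c(100, 50), 500))
})

test_that("grid pooling keeps the best-supported instance of a recurring event", {
    line <- function(id, accStart, accEnd, donStart, donEnd, support,
                     type = "insertion_sense") {
        data.frame(acceptorId = id, eventType = type,
                   acceptorChrom = "chr1", acceptorStart = accStart,
                   acceptorEnd = accEnd, acceptorSize = accEnd - accStart,
                   donorChrom = "chr1", donorStart = donStart,
                   donorEnd = donEnd, donorSize = donEnd - donStart,
                   overlap = 100, support = support, inverted = FALSE,
                   companionDel = FALSE, stringsAsFactors = FALSE)
    }
    p1 <- list(X = 50, Y = 400, calls = mkCalls(rbind(
        line("A0001", 5400, 5450, 20000, 26000, 12),
        line("A0002", 90000, 90100, 120000, 125000, 30))))
    p2 <- list(X = 100, Y = 800, calls = mkCalls(rbind(
        line("A0001", 5380, 5470, 20100, 25900, 15),
        line("A0002", 300000, 300100, 320000, 325000, 8))))
    pooled <- as.data.frame(calls(mergeGridResults(list(p1, p2))))
    # same event at two points -> kept once with max support
    same <- pooled[pooled$acceptorStart < 6000, ]
    expect_equal(nrow(same), 1L)
    expect_equal(same$support, 15)
    # non-overlapping event unique to the weaker point is appended
    expect_true(any(pooled$acceptorStart == 300000))
    # registry seeds from the point with most insertions: both had 2;
    # tie broken by total support -> p1 (42 > 23)
    expect_equal(nrow(pooled), 3L)

    # single contributing point: output equals that point
    solo <- mergeGridResults(list(p1, list(X = 1, Y = 1,
                                           calls = mkCalls(line(
        "A0001", 5400, 5450, 20000, 26000, 12)[0, ]))))
    expect_equal(nrow(calls(solo)), 2L)
})

test_that("pooled output is at least as large as the best single grid point", {
    fx <- smallEndToEnd()
    pp <- runGrid(fx$disc, gridSpec(c(50, 100), c(400, 800)))
    pooled <- mergeGridResults(pp)
    best <- max(vapply(pp, function(p)
        length(unique(calls(p$calls)$acceptorId)), integer(1)))
    expect_true(length(unique(calls(pooled)$acceptorId)) >= best)
    # support of every pooled line is the max over matching per-point lines
    df <- as.data.frame(calls(pooled))
    allLines <- do.call(rbind, lapply(pp, function(p)
        as.data.frame(calls(p$calls))))
    for (r in seq_len(nrow(df))) {
        cand <- allLines$donorChrom == df$donorChrom[r] &
            allLines$acceptorChrom == df$acceptorChrom[r] &
            pmin(allLines$donorEnd, df$donorEnd[r]) -
                pmax(allLines$donorStart, df$donorStart[r]) >= 0 &
            pmin(allLines$acceptorEnd, df$acceptorEnd[r]) -
                pmax(allLines$acceptorStart, df$acceptorStart[r]) >= 0
        expect_true(df$support[r] >= max(allLines$support[cand]))
    }
})
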