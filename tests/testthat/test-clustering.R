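st <- mkStats(5000, 100)

mkPoints <- function(la, lb, sig = "Del") {
    data.frame(la = la, lb = lb, pairId = as.character(seq_along(la)),
               signature = sig, chromA = "chr1", chromB = "chr1",
               orientA = "-", orientB = "+", stringsAsFactors = FALSE)
}

test_that("chain linking groups points transitively; broken links split", {
    one <- singleLinkageCluster(
        mkPoints(c(1000, 1050, 1120), c(9000, 9200, 9600)), 100, 500)
    expect_equal(nrow(one), 1L)
    expect_equal(one$support, 3L)
    expect_equal(c(one$startA, one$endA, one$startB, one$endB),
                 c(1000, 1120, 9000, 9600))

    two <- singleLinkageCluster(
        mkPoints(c(1000, 1050), c(9000, 9600)), 100, 500)
    expect_equal(nrow(two), 2L)
    expect_equal(two$support, c(1L, 1L))

    single <- singleLinkageCluster(mkPoints(2000, 8000), 100, 500)
    expect_equal(nrow(single), 1L)
    expect_equal(single$support, 1L)
})

test_that("the seeded scan equals brute-force transitive closure", {
    set.seed(31)
    for (rep in 1:8) {
        n <- 300
        pts <- mkPoints(sample.int(20000, n, replace = TRUE),
                        sample.int(40000, n, replace = TRUE))
        X <- sample(c(30, 100, 400, 1500), 1)
        Y <- sample(c(60, 300, 800, 3000), 1)
        cl <- singleLinkageCluster(pts, X, Y)
        oracle <- bruteSingleLinkage(pts, X, Y)
        expect_identical(clustersToPartition(cl),
                         canonicalPartition(oracle))
        expect_equal(sum(lengths(cl$members)), n)
    }
})

test_that("clustering is invariant to permutation of equal-la points", {
    pts <- mkPoints(c(100, 100, 100, 300), c(500, 900, 700, 600))
    a <- singleLinkageCluster(pts, 250, 150)
    b <- singleLinkageCluster(pts[c(3, 1, 4, 2), ], 250, 150)
    expect_equal(nrow(a), nrow(b))
    expect_identical(
        lapply(a$memberIds, function(x) sort(pts$pairId[as.integer(x)])),
        lapply(b$memberIds, function(x) sort(pts$pairId[as.integer(x)])))
})

test_that("enlarging X or Y never increases the number of clusters", {
    set.seed(77)
    pts <- mkPoints(sample.int(50000, 400, replace = TRUE),
                    sample.int(50000, 400, replace = TRUE))
    nX <- vapply(c(50, 100, 200, 400, 800),
                 function(X) nrow(singleLinkageCluster(pts, X, 300)),
                 integer(1))
    nY <- vapply(c(50, 100, 200, 400, 800),
                 function(Y) nrow(singleLinkageCluster(pts, 200, Y)),
                 integer(1))
    expect_true(all(diff(nX) <= 0))
    expect_true(all(diff(nY) <= 0))
})

test_that("nearby same-signature clusters merge; different signatures never do", {
    pts <- mkPoints(c(1000, 1100, 1300, 1400), c(9000, 9100, 9400, 9500))
    cl <- singleLinkageCluster(pts, 150, 200)
    expect_equal(nrow(cl), 2L)
    # interval_a gap 200, interval_b gap 300 -> merged at gap 500
    merged <- mergeClusters(cl, gap = 500)
    expect_equal(nrow(merged), 1L)
    expect_equal(merged$support, 4L)
    expect_equal(merged$nRecords, 4L)
    # idempotence
    expect_equal(mergeClusters(merged, gap = 500)$support, 4L)
    # not merged at a tighter threshold
    expect_equal(nrow(mergeClusters(cl, gap = 100)), 2L)

    # adjacent Del and Dup clusters are never merged
    dupPts <- mkPoints(c(1150, 1250), c(9150, 9250), sig = "Dup")
    dupPts$pairId <- c("d1", "d2")
    dupPts$orientA <- "+"; dupPts$orientB <- "-"
    dup <- singleLinkageCluster(dupPts, 150, 200)
    expect_equal(nrow(mergeClusters(rbind(cl, dup), gap = 500)), 2L)
})

test_that("merging conserves members and never decreases support", {
    set.seed(5)
    pts <- mkPoints(sort(sample.int(30000, 150)),
                    sample.int(30000, 150, replace = TRUE))
    cl <- singleLinkageCluster(pts, 60, 120)
    merged <- mergeClusters(cl, gap = 400)
    expect_equal(sum(merged$nRecords), sum(cl$nRecords))
    expect_equal(sort(unlist(merged$members)), sort(unlist(cl$members)))
    expect_true(min(merged$support) >= min(cl$support))
})

test_that("size and support filters reject oversized and weak clusters", {
    big <- singleLinkageCluster(
        mkPoints(seq(1000, 7000, by = 50), seq(9000, 15000, by = 50)),
        100, 200)
    expect_equal(nrow(big), 1L)
    expect_equal(nrow(filterClusters(big, st, minSupport = 1)), 0L)

    ok <- singleLinkageCluster(
        mkPoints(seq(1000, 2000, by = 50), seq(9000, 10000, by = 50)),
        100, 200)
    expect_equal(nrow(filterClusters(ok, st, minSupport = 10)), 1L)
    expect_equal(nrow(filterClusters(ok, st, minSupport = 50)), 0L)
})

test_that("records partition by signature, chromosome pair and orientation", {
    maps <- rbind(
        mkMap("a", 1, "chr1", 1000, "-"), mkMap("a", 2, "chr1", 30000, "+"),
        mkMap("b", 1, "chr1", 1100, "-"), mkMap("b", 2, "chr1", 30100, "+"),
        mkMap("c", 1, "chr1", 1000, "+"), mkMap("c", 2, "chr1", 30000, "-"),
        mkMap("d", 1, "chr1", 1000, "-"), mkMap("d", 2, "chr2", 5000, "+"))
    disc <- extractDiscordantPairs(maps, st,
                                   chromLevels = c("chr1", "chr2"))
    parts <- partitionPoints(disc)
    expect_length(parts, 3L)
    expect_setequal(
        vapply(parts, function(p) p$signature[1], character(1)),
        c("Del", "Dup", "Trans"))
    # same-signature same-locus records share one partition
    del <- parts[[which(vapply(parts, function(p) p$signature[1],
                               character(1)) == "Del")]]
    expect_equal(nrow(del), 2L)
    # partition count bound: <= 4 orientation couples per chromosome pair
    key <- vapply(parts, function(p)
        paste(p$chromA[1], p$chromB[1]), character(1))
    expect_true(all(table(key) <= 4L))
})
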