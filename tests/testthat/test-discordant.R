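st <- mkStats(5000, 100)

test_that("mismatch filter drops reads by best mapping and prunes bad mappings", {
    maps <- rbind(
        mkMap("a", 1, "chr1", 100, "-", nm = 0),          # kept
        mkMap("b", 1, "chr1", 200, "-", nm = 2),          # read dropped
        mkMap("c", 1, "chr1", 300, "-", nm = 1),          # kept
        mkMap("c", 1, "chr2", 900, "-", nm = 3,
              primary = FALSE))                           # mapping pruned
    out <- filterMappings(maps, maxMismatch = 1)
    expect_identical(out$pairId, c("a", "c"))
    expect_equal(out$nm, c(0, 1))
})

test_that("mappings without an edit distance follow the configured policy", {
    maps <- rbind(mkMap("a", 1, "chr1", 100, "-", nm = NA),
                  mkMap("b", 1, "chr1", 200, "-", nm = 0))
    expect_warning(out <- filterMappings(maps), "without an edit distance")
    expect_identical(out$pairId, "b")
    expect_identical(filterMappings(maps, missingNM = "keep")$pairId,
                     c("a", "b"))
})

test_that("a fragment with any concordant combination yields no records", {
    maps <- rbind(
        mkMap("f", 1, "chr1", 1000, "-"),
        mkMap("f", 1, "chr1", 50000, "-", primary = FALSE),
        mkMap("f", 2, "chr1", 6000, "+"))
    # combination (1000, 6000) is concordant -> the fragment is dropped
    # even though (50000, 6000) would look like a Del pair
    disc <- extractDiscordantPairs(maps, st)
    expect_equal(nrow(records(disc)), 0L)
    expect_equal(unname(disc@counters["concordantFragments"]), 1L)
})

test_that("all combinations of a fully discordant fragment are recorded", {
    maps <- rbind(
        mkMap("f", 1, "chr1", 1000, "-"),
        mkMap("f", 2, "chr1", 30000, "+"),
        mkMap("f", 2, "chr2", 500, "+", primary = FALSE))
    disc <- extractDiscordantPairs(maps, st,
                                   chromLevels = c("chr1", "chr2"))
    rec <- as.data.frame(records(disc))
    expect_equal(nrow(rec), 2L)
    expect_setequal(rec$signature, c("Del", "Trans"))
})

test_that("orphan reads are skipped and counted", {
    maps <- rbind(
        mkMap("lone", 1, "chr1", 1000, "-"),
        mkMap("f", 1, "chr1", 1000, "-"),
        mkMap("f", 2, "chr1", 30000, "+"))
    disc <- extractDiscordantPairs(maps, st)
    expect_equal(unname(disc@counters["orphans"]), 1L)
    expect_identical(unique(as.data.frame(records(disc))$pairId), "f")
})

test_that("records with both mates inside the coverage mask are discarded", {
    mask <- GenomicRanges::GRanges("chr1",
                                   IRanges::IRanges(900, 40000))
    maps <- rbind(
        mkMap("in", 1, "chr1", 1000, "-"),
        mkMap("in", 2, "chr1", 30000, "+"),
        mkMap("half", 1, "chr1", 1000, "-"),
        mkMap("half", 2, "chr1", 60000, "+"))
    disc <- extractDiscordantPairs(maps, st, mask = mask)
    rec <- as.data.frame(records(disc))
    expect_identical(rec$pairId, "half")
    expect_equal(unname(disc@counters["masked"]), 1L)
})

test_that("duplicate mappings collapse before combination enumeration", {
    maps <- rbind(
        mkMap("f", 1, "chr1", 1000, "-"),
        mkMap("f", 1, "chr1", 1000, "-", primary = FALSE),
        mkMap("f", 2, "chr1", 30000, "+"))
    disc <- extractDiscordantPairs(maps, st)
    expect_equal(nrow(records(disc)), 1L)
})

test_that("mates are relabelled so A precedes B in genome order", {
    maps <- rbind(
        mkMap("f", 1, "chr1", 30000, "+"),
        mkMap("f", 2, "chr1", 1000, "-"))
    rec <- as.data.frame(records(extractDiscordantPairs(maps, st)))
    expect_equal(rec$posA, 1000)
    expect_equal(rec$orientA, "-")
    expect_equal(rec$insert, 29000)
    expect_equal(rec$signature, "Del")
})

test_that("no concordant fragment of an error-free proper library leaks through", {
    set.seed(9)
    n <- 300
    posA <- sample.int(1e6, n)
    d <- round(rnorm(n, 5000, 60))
    maps <- rbind(
        mkMap(seq_len(n), 1, "chr1", posA, "-"),
        mkMap(seq_len(n), 2, "chr1", posA + d, "+"))
    stats <- estimateLibraryStats(maps)
    disc <- extractDiscordantPairs(maps, stats)
    # every insert stays within the +/- 3 MAD window by construction
    keep <- abs(d - stats@median) < 3 * stats@mad
    expect_equal(nrow(records(disc)), sum(!keep))
})

test_that("coverage mask thresholds depth at median + 3 MAD with a maskable floor", {
    # uniform depth: no excursion, empty mask
    maps <- mkMap(seq_len(50), 1, "chr1", seq(1, 4901, by = 100), "+")
    expect_length(buildCoverageMask(maps, floorDepth = 0), 0L)

    # one single-base spike above cSup -> 1-bp interval (floor disabled)
    spike <- rbind(maps,
                   mkMap(100 + seq_len(30), 1, "chr1", 2000, "+",
                         width = 1L))
    m <- buildCoverageMask(spike, floorDepth = 0)
    expect_equal(as.character(GenomicRanges::seqnames(m)), "chr1")
    expect_equal(GenomicRanges::start(m), 2000)
    expect_equal(GenomicRanges::width(m), 1L)

    # the 1000x floor keeps moderate excursions unmasked
    expect_length(buildCoverageMask(spike, floorDepth = 1000), 0L)

    # raising the threshold never grows the mask
    m5 <- buildCoverageMask(spike, nMAD = 5, floorDepth = 0)
    expect_true(all(IRanges::overlapsAny(m5, m)))
    expect_true(sum(GenomicRanges::width(m5)) <=
                sum(GenomicRanges::width(m)))
})

test_that("zero-coverage input gives an empty mask with a warning", {
    empty <- data.frame(pairId = character(), mate = integer(),
                        chrom = character(), pos = integer(),
                        strand = character(), nm = integer(),
                        width = integer(), primary = logical())
    expect_warning(m <- buildCoverageMask(empty), "empty coverage mask")
    expect_length(m, 0L)
})
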