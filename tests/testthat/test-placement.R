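.chromLensTest <- function(g)
    stats::setNames(as.integer(Biostrings::width(g)), names(g))

test_that("placed reads reproduce the reference sequence at their position", {
    fx <- smallEndToEnd()
    maps <- fx$maps
    prim <- maps[maps$primary, ]
    set.seed(12)
    idx <- sample(nrow(prim), 40)
    seqsMod <- simReadSequences(fx$sim, modifiedGenome(fx$truth))
    readKey <- paste(fx$sim$reads$pairId, fx$sim$reads$mate)
    for (i in idx) {
        ref <- Biostrings::subseq(
            refGenome(fx$tg)[[prim$chrom[i]]],
            prim$pos[i], prim$pos[i] + prim$width[i] - 1L)
        k <- match(paste(prim$pairId[i], prim$mate[i]), readKey)
        readSeq <- seqsMod[[k]]
        if (prim$strand[i] == "-")
            readSeq <- Biostrings::reverseComplement(readSeq)
        expect_equal(as.character(readSeq), as.character(ref))
    }
})

test_that("homologous candidate mappings carry exact edit distances", {
    fx <- smallEndToEnd()
    maps <- fx$maps
    alt <- maps[!maps$primary, ]
    expect_gt(nrow(alt), 100)
    seqsMod <- simReadSequences(fx$sim, modifiedGenome(fx$truth))
    readKey <- paste(fx$sim$reads$pairId, fx$sim$reads$mate)
    set.seed(3)
    idx <- sample(nrow(alt), 30)
    for (i in idx) {
        k <- match(paste(alt$pairId[i], alt$mate[i]), readKey)
        readSeq <- seqsMod[[k]]
        # orient the read to the forward strand of the candidate location
        if (fx$sim$reads$strand[k] != alt$strand[i])
            readSeq <- Biostrings::reverseComplement(readSeq)
        if (alt$strand[i] == "-")
            readSeq <- Biostrings::reverseComplement(readSeq)
        win <- Biostrings::subseq(refGenome(fx$tg)[[alt$chrom[i]]],
                                  alt$pos[i],
                                  alt$pos[i] + alt$width[i] - 1L)
        expect_equal(alt$nm[i],
                     sum(as.matrix(Biostrings::DNAStringSet(win)) !=
                         as.matrix(Biostrings::DNAStringSet(readSeq))))
    }
})

test_that("junction-straddling reads are unmapped, their mates orphaned", {
    fx <- smallEndToEnd()
    counters <- attr(fx$maps, "counters")
    expect_gt(counters["junctionDropped"], 0)
    # no placed read interval crosses an insertion block boundary
    ev <- as.data.frame(truthEvents(fx$truth))
    placedKeys <- paste(fx$maps$pairId, fx$maps$mate)
    reads <- fx$sim$reads
    for (i in seq_len(nrow(ev))) {
        cross <- reads$chrom == ev$acceptorChrom[i] &
            reads$start < ev$blockStart[i] + ev$tsdLen[i] &
            reads$end >= ev$blockStart[i]
        expect_false(any(paste(reads$pairId[cross], reads$mate[cross])
                         %in% placedKeys))
    }
})

test_that("inverted insertions place element reads on the opposite strand", {
    tg <- simulateTEGenome(chromLengths = c(chr1 = 2e5, chr2 = 2e5),
                           minSeparation = 8000L, seed = 5)
    plan <- planTranspositions(tg, counts = c(normal = 1L), L = 3000,
                               minSeparation = 5000, seed = 2)
    plan$inverted <- TRUE
    truth <- injectTranspositions(tg, plan)
    sim <- simulateMatePairs(modifiedGenome(truth), simProfile(),
                             coverage = 5, seed = 4, chimeras = FALSE,
                             contamination = FALSE, errors = FALSE)
    maps <- placeReads(sim, truth, tg)
    ev <- as.data.frame(truthEvents(truth))
    inBlock <- fxIn <- sim$reads$chrom == ev$acceptorChrom &
        sim$reads$start >= ev$blockStart + ev$tsdLen &
        sim$reads$end <= ev$blockEnd
    keys <- paste(sim$reads$pairId, sim$reads$mate)[inBlock]
    placed <- maps[maps$primary &
                   paste(maps$pairId, maps$mate) %in% keys, ]
    expect_gt(nrow(placed), 10)
    origStrand <- sim$reads$strand[inBlock][
        match(paste(placed$pairId, placed$mate), keys)]
    expect_true(all(placed$strand != origStrand))
    expect_true(all(placed$chrom == ev$donorChrom))
    expect_true(all(placed$pos >= ev$donorStart &
                    placed$pos + placed$width - 1L <= ev$donorEnd))
})

test_that("placed alignments survive a SAM/BAM round trip", {
    fx <- smallEndToEnd()
    sub <- fx$maps[fx$maps$pairId %in%
                   unique(fx$maps$pairId)[1:200], ]
    sam <- tempfile(fileext = ".sam")
    writeSamFile(sub, .chromLensTest(refGenome(fx$tg)), sam)
    back <- readPairAlignments(sam)
    expect_equal(nrow(back), nrow(sub))
    a <- sub[order(as.character(sub$pairId), sub$mate, sub$chrom,
                   sub$pos), ]
    b <- back[order(as.character(back$pairId), back$mate, back$chrom,
                    back$pos), ]
    expect_equal(a$pos, b$pos)
    expect_equal(a$strand, b$strand)
    expect_equal(as.integer(a$nm), b$nm)
})

test_that("alternative-hit tags expand into extra mapping rows", {
    sam <- tempfile(fileext = ".sam")
    writeLines(c(
        "@HD\tVN:1.6\tSO:coordinate",
        "@SQ\tSN:chr1\tLN:100000",
        "@SQ\tSN:chr2\tLN:100000",
        paste("r1", 65, "chr1", 1000, 60, "100M", "=", 5000, 0, "*", "*",
              "NM:i:0", "XA:Z:chr2,+2000,100M,1;chr2,-3000,100M,2;",
              sep = "\t"),
        paste("r1", 129, "chr1", 5000, 60, "100M", "=", 1000, 0, "*", "*",
              "NM:i:1", sep = "\t")), sam)
    maps <- readPairAlignments(sam)
    expect_equal(nrow(maps), 4L)
    xa <- maps[!maps$primary, ]
    expect_equal(xa$chrom, c("chr2", "chr2"))
    expect_equal(xa$pos, c(2000L, 3000L))
    expect_equal(xa$strand, c("+", "-"))
    expect_equal(xa$nm, c(1L, 2L))
    expect_equal(xa$mate, c(1L, 1L))
})
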