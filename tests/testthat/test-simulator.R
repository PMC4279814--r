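set.seed(1)
uniformGenome <- Biostrings::DNAStringSet(c(chr1 = paste(
    sample(c("A", "C", "G", "T"), 60000, replace = TRUE), collapse = "")))

test_that("profile construction yields a valid bimodal mixture", {
    prof <- simProfile(contaminationOdds = 0.15)
    expect_true(validObject(prof))
    expect_true(prof@splitPoint > 450 && prof@splitPoint < 2400)
    shortMass <- sum(prof@fragProbs[prof@fragSizes <= prof@splitPoint])
    expect_equal(shortMass, 0.15, tolerance = 1e-6)
})

test_that("profile learning recovers split point and contamination odds", {
    prof <- simProfile(contaminationOdds = 0.15)
    set.seed(3)
    sizes <- sample(prof@fragSizes, 20000, replace = TRUE,
                    prob = prof@fragProbs)
    quals <- replicate(200, rawToChar(as.raw(
        33L + sample(30:40, 100, replace = TRUE))))
    learned <- learnSimProfile(sizes, quals)
    expect_true(learned@splitPoint > 450 &&
                learned@splitPoint < min(sizes[sizes > 1000]))
    expect_equal(learned@contaminationOdds, 0.15, tolerance = 0.03)
    # per-position histograms are built from exactly the sample given
    expect_equal(colSums(learned@qualityProbs), rep(1, 100))
})

test_that("a unimodal insert distribution yields zero contamination odds", {
    set.seed(4)
    sizes <- round(rnorm(5000, 3000, 200))
    quals <- replicate(50, strrep("I", 100))
    expect_warning(learned <- learnSimProfile(sizes, quals), "unimodal")
    expect_equal(learned@contaminationOdds, 0)
})

test_that("uniform base quality gives point-mass positional histograms", {
    quals <- replicate(80, strrep("?", 50))   # Q30 throughout
    learned <- learnSimProfile(c(rep(300, 50), rep(3000, 200)), quals)
    expect_equal(learned@qualityValues, 30L)
    expect_true(all(learned@qualityProbs == 1))
})

test_that("clean mate pairs map concordantly at the expected insert size", {
    prof <- simProfile(readLen = 100L, fragMean = 3000, fragSd = 215)
    sim <- simulateMatePairs(uniformGenome, prof, coverage = 4, seed = 8,
                             chimeras = FALSE, contamination = FALSE,
                             errors = FALSE)
    expect_true(all(sim$reads$overhang == 0L))
    r1 <- sim$reads[sim$reads$mate == 1L, ]
    r2 <- sim$reads[sim$reads$mate == 2L, ]
    # left mate is reverse, right mate forward: (-, +) after sorting
    expect_true(all(r2$start < r1$start))
    d <- r1$start - r2$start
    expect_equal(d, sim$pairs$fragSize - sim$pairs$spliceLen + 100L)
    st <- estimateLibraryStats(d)
    # median insert = fragment - splice + read length = 3000 - 300 + 100
    expect_equal(st@median, 2800, tolerance = 0.02)
    expect_true(st@mad > 100 && st@mad < 200)
})

test_that("simulated reads are exact genome substrings when error-free", {
    prof <- simProfile(readLen = 100L)
    sim <- simulateMatePairs(uniformGenome, prof, coverage = 1, seed = 2,
                             chimeras = FALSE, contamination = FALSE,
                             errors = FALSE)
    seqs <- simReadSequences(sim, uniformGenome)
    idx <- sample(length(seqs), 25)
    for (i in idx) {
        ref <- Biostrings::subseq(uniformGenome[[sim$reads$chrom[i]]],
                                  sim$reads$start[i], sim$reads$end[i])
        if (sim$reads$strand[i] == "-")
            ref <- Biostrings::reverseComplement(ref)
        expect_equal(as.character(seqs[[i]]), as.character(ref))
    }
})

test_that("error injection follows the phred probability of the drawn quality", {
    # all bases at Q20 -> 1% substitution rate
    prof <- simProfile(readLen = 100L, qualStart = 20, qualEnd = 20,
                       qualSd = 1e-6)
    sim <- simulateMatePairs(uniformGenome, prof, coverage = 4, seed = 5,
                             chimeras = FALSE, contamination = FALSE,
                             errors = TRUE)
    seqs <- simReadSequences(sim, uniformGenome)
    n <- 400
    mism <- 0L
    for (i in seq_len(n)) {
        ref <- Biostrings::subseq(uniformGenome[[sim$reads$chrom[i]]],
                                  sim$reads$start[i], sim$reads$end[i])
        if (sim$reads$strand[i] == "-")
            ref <- Biostrings::reverseComplement(ref)
        mism <- mism + sum(as.matrix(Biostrings::DNAStringSet(ref)) !=
                           as.matrix(seqs[i]))
    }
    nBases <- n * 100
    # binomial band around 1%
    p <- mism / nBases
    expect_true(abs(p - 0.01) < 4 * sqrt(0.01 * 0.99 / nBases))
})

test_that("junction chimeras join the two fragment ends", {
    prof <- simProfile(readLen = 100L)
    sim <- simulateMatePairs(uniformGenome, prof, coverage = 4, seed = 13,
                             chimeras = TRUE, contamination = FALSE,
                             errors = FALSE)
    chim <- which(sim$reads$overhang > 0L)
    expect_true(length(chim) > 50)
    seqs <- simReadSequences(sim, uniformGenome)
    for (i in chim[1:10]) {
        p <- sim$pairs[sim$pairs$pairId == sim$reads$pairId[i], ]
        frag <- Biostrings::subseq(uniformGenome[[p$chrom]], p$fragStart,
                                   p$fragStart + p$fragSize - 1L)
        # reconstruct the spliced subfragment around the junction
        u <- p$spliceU; ell <- p$spliceLen
        circ <- Biostrings::xscat(
            Biostrings::subseq(frag, p$fragSize - u + 1L, p$fragSize),
            Biostrings::subseq(frag, 1L, ell - u))
        readSeq <- if (sim$reads$mate[i] == 1L)
            Biostrings::subseq(circ, 1L, 100L)
        else
            Biostrings::reverseComplement(
                Biostrings::subseq(circ, ell - 99L, ell))
        expect_equal(as.character(seqs[[i]]), as.character(readSeq))
    }
})

test_that("contaminant pairs are short forward-reverse fragments", {
    prof <- simProfile(readLen = 100L, contaminationOdds = 0.5)
    sim <- simulateMatePairs(uniformGenome, prof, coverage = 2, seed = 21,
                             chimeras = FALSE, contamination = TRUE,
                             errors = FALSE)
    cont <- sim$pairs$contaminant
    expect_gt(mean(cont), 0.4)
    r1 <- sim$reads[sim$reads$mate == 1L, ]
    r2 <- sim$reads[sim$reads$mate == 2L, ]
    # contaminants: mate 1 forward at the left end -> (+, -) couple
    expect_true(all(r1$start[cont] <= r2$start[cont]))
    expect_true(all(sim$pairs$fragSize[cont] <= prof@splitPoint))
})

test_that("identical inputs and seed give byte-identical FASTQ", {
    prof <- simProfile(readLen = 60L, contaminationOdds = 0.1)
    run <- function() {
        sim <- simulateMatePairs(uniformGenome, prof, coverage = 0.5,
                                 seed = 33, chimeras = TRUE,
                                 contamination = TRUE, errors = TRUE)
        pre <- tempfile()
        writeSimFastq(sim, uniformGenome, pre)
        lapply(paste0(pre, c("_1.fastq", "_2.fastq")), readLines)
    }
    expect_identical(run(), run())
})

test_that("evaluation handles empty truth and empty predictions", {
    fx <- smallEndToEnd()
    expect_error(evaluateCalls(mkCalls(data.frame()), data.frame()),
                 "empty truth")
    empty <- mkCalls(data.frame(acceptorId = character(),
                                eventType = character(),
                                acceptorChrom = character(),
                                acceptorStart = numeric(),
                                acceptorEnd = numeric(),
                                donorChrom = character(),
                                donorStart = numeric(),
                                donorEnd = numeric(),
                                support = integer()))
    res <- evaluateCalls(empty, truthEvents(fx$truth))
    expect_equal(res$sensitivity, 0)
    expect_true(is.na(res$ppv))
})

test_that("evaluation is invariant to line order and duplicated donor lines", {
    fx <- smallEndToEnd()
    pp <- runGrid(fx$disc, gridSpec(c(50, 100), c(400, 800)))
    pooled <- mergeGridResults(pp)
    res1 <- evaluateCalls(pooled, fx$truth)
    df <- as.data.frame(calls(pooled))
    shuffled <- mkCalls(rbind(df[nrow(df):1, ], df[1, ]))
    res2 <- evaluateCalls(shuffled, fx$truth)
    expect_equal(res2$sensitivity, res1$sensitivity)
    expect_equal(res2$ppv, res1$ppv)
    expect_equal(res2$foundWithDonor, res1$foundWithDonor)
})
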