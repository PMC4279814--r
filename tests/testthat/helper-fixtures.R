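# Shared test fixtures and independent oracles.

# Quick builder for mapping-table rows.
mkMap <- function(pairId, mate, chrom, pos, strand, nm = 0L, width = 100L,
                  primary = TRUE) {
    data.frame(pairId = as.character(pairId), mate = mate, chrom = chrom,
               pos = pos, strand = strand, nm = nm, width = width,
               primary = primary, stringsAsFactors = FALSE)
}

# LibraryStats with given median and (unscaled) MAD.
mkStats <- function(M, MAD, properOrient = c("-", "+")) {
    methods::new("LibraryStats", median = M, mad = MAD,
                 dInf = M - 3 * MAD, dSup = M + 3 * MAD,
                 properOrient = properOrient, degenerate = MAD == 0,
                 n = 2L)
}

# Brute-force single linkage: pairwise edge enumeration + graph
# components (independent of the package's seeded scan).
bruteSingleLinkage <- function(points, X, Y) {
    n <- nrow(points)
    if (n == 0) return(integer())
    adj <- abs(outer(points$la, points$la, "-")) <= X &
        abs(outer(points$lb, points$lb, "-")) <= Y
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    igraph::components(g)$membership
}

# Canonical form of a clustering for comparison: sorted list of sorted
# member index sets.
canonicalPartition <- function(membership) {
    unname(lapply(
        sort(vapply(split(seq_along(membership), membership),
                    paste, character(1), collapse = ","), method = "radix"),
        identity))
}

clustersToPartition <- function(clusters) {
    canonicalPartition(
        rep(seq_len(nrow(clusters)), lengths(clusters$members))[
            order(unlist(clusters$members))])
}

# One cached small end-to-end run shared by the pipeline tests.
.fixtureCache <- new.env(parent = emptyenv())

smallEndToEnd <- function() {
    if (!is.null(.fixtureCache$small))
        return(.fixtureCache$small)
    tg <- simulateTEGenome(chromLengths = c(chr1 = 3e5, chr2 = 3e5),
                           seed = 7)
    plan <- planTranspositions(
        tg, counts = c(normal = 1L, composite = 1L, long = 1L, short = 1L),
        L = 3000, seed = 3)
    truth <- injectTranspositions(tg, plan)
    # tightly size-selected library: the whole insert distribution sits
    # inside the concordance window, as a noiseless benchmark assumes
    prof <- simProfile(fragShape = "uniform", fragSd = 300, shortSd = 50)
    sim <- simulateMatePairs(modifiedGenome(truth), prof, coverage = 15,
                             seed = 11, chimeras = FALSE,
                             contamination = FALSE, errors = FALSE)
    maps <- placeReads(sim, truth, tg)
    flt <- filterMappings(maps)
    st <- estimateLibraryStats(flt)
    disc <- extractDiscordantPairs(flt, st,
                                   chromLevels = names(refGenome(tg)))
    .fixtureCache$small <- list(tg = tg, truth = truth, sim = sim,
                                maps = maps, flt = flt, st = st,
                                disc = disc)
    .fixtureCache$small
}

# Full-scale noiseless benchmark: 2 x 1 Mb genome, 20 injected events
# (5 per class), error-free tightly size-selected mate pairs at 20x,
# exact-placement alignments, full pipeline. Cached per session.
fullEndToEnd <- function() {
    if (!is.null(.fixtureCache$full))
        return(.fixtureCache$full)
    tg <- simulateTEGenome(seed = 101)
    plan <- planTranspositions(tg, L = 3000, seed = 7)
    truth <- injectTranspositions(tg, plan)
    prof <- simProfile(fragShape = "uniform", fragSd = 300, shortSd = 50)
    sim <- simulateMatePairs(modifiedGenome(truth), prof, coverage = 20,
                             seed = 23, chimeras = FALSE,
                             contamination = FALSE, errors = FALSE)
    maps <- placeReads(sim, truth, tg)
    cfg <- loadConfig(overrides = list(gridX = "50:100:50",
                                       gridY = "400:800:400"))
    res <- runPipeline(cfg, alignments = maps, genome = refGenome(tg),
                       annotation = teAnnotation(tg))
    .fixtureCache$full <- list(tg = tg, truth = truth, maps = maps,
                               res = res,
                               eval = evaluateCalls(res$calls, truth))
    .fixtureCache$full
}

# One donor-scoring replicate: a two-copy family (optionally identical
# copies), one injected event, acceptor-anchored scoring only.
donorScoringReplicate <- function(seed, identical = FALSE) {
    tg <- simulateTEGenome(
        chromLengths = c(chr1 = 1.2e5),
        families = list(TED = list(length = 2000L, copies = 2L,
                                   subs = c(0L, if (identical) 0L else 3L))),
        tandemPair = NULL, minSeparation = 8000L, seed = seed)
    plan <- planTranspositions(tg, counts = c(normal = 1L), L = 3000,
                               minSeparation = 5000,
                               invertedProb = 0, seed = seed + 1)
    truth <- injectTranspositions(tg, plan)
    prof <- simProfile(fragShape = "uniform", fragSd = 300, shortSd = 50)
    sim <- simulateMatePairs(modifiedGenome(truth), prof, coverage = 15,
                             seed = seed + 2, chimeras = FALSE,
                             contamination = FALSE, errors = FALSE)
    maps <- filterMappings(placeReads(sim, truth, tg))
    st <- estimateLibraryStats(maps)
    anno <- teAnnotation(tg)
    ev <- as.data.frame(truthEvents(truth))
    line <- function(i) data.frame(
        acceptorId = "A0001", eventType = "insertion_sense",
        acceptorChrom = ev$acceptorChrom, acceptorStart = ev$acceptorPos - 100,
        acceptorEnd = ev$acceptorPos + 100, acceptorSize = 200,
        donorChrom = as.character(GenomicRanges::seqnames(anno)[i]),
        donorStart = GenomicRanges::start(anno)[i],
        donorEnd = GenomicRanges::end(anno)[i],
        donorSize = GenomicRanges::width(anno)[i], overlap = 1000,
        support = 50L, inverted = FALSE, companionDel = FALSE,
        stringsAsFactors = FALSE)
    x <- mkCalls(rbind(line(1), line(2)))
    out <- as.data.frame(calls(scoreDonors(x, maps, st)))
    trueDonor <- which(GenomicRanges::start(anno) == ev$donorStart &
                       GenomicRanges::end(anno) == ev$donorEnd)
    list(scores = out$donorScore, trueDonor = trueDonor,
         ambiguous = out$ambiguousDonor)
}

# Minimal TranspositionCalls from a plain line table.
mkCalls <- function(df, params = list()) {
    methods::new("TranspositionCalls",
                 calls = S4Vectors::DataFrame(df), params = params)
}
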