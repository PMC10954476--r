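# A DyadCalls-like object built directly from counts, for downstream ops.
fakeCalls <- function(chrom, watsonC, counts, minCoverage = 1L) {
    gr <- GRanges(chrom, IRanges(watsonC, watsonC + 1L),
                  kind = "CpG", rWatson = "A", rCrick = "A")
    mcols(gr) <- cbind(mcols(gr), DataFrame(counts))
    mcols(gr)$strandOnlyW <- 0L
    mcols(gr)$strandOnlyC <- 0L
    mcols(gr)$excluded <- rowSums(as.matrix(counts)) < minCoverage
    new("DyadCalls", gr)
}

test_that("region clusters map the predominant status motif-strand-relative", {
    counts <- DataFrame(unme = c(0L, 0L, 5L, 0L),
                        hemiW = c(5L, 5L, 0L, 0L),
                        hemiC = c(0L, 0L, 0L, 0L),
                        me = c(0L, 0L, 0L, 5L))
    # '+' regions look up start + offset; '-' regions look up end - offset
    calls <- fakeCalls("chr1", c(105L, 213L, 305L, 413L), counts)
    regions <- GRanges("chr1", IRanges(c(100L, 200L, 300L, 400L),
                                       c(118L, 218L, 318L, 418L)),
                       strand = c("+", "-", "+", "-"))
    cl <- assignRegionCluster(regions, calls, offset = 5L)
    # hemiW is motif-strand hemi on '+' (cluster 2), opposite on '-' (3)
    expect_equal(cl$cluster, c(2L, 3L, 1L, 4L))
    expect_equal(cl$reason, rep("ok", 4L))
    # a region with no dyad at the designated offset is excluded
    empty <- GRanges("chr1", IRanges(600L, 618L), strand = "+")
    cl2 <- assignRegionCluster(empty, calls, offset = 5L)
    expect_true(is.na(cl2$cluster))
    expect_equal(cl2$reason, "no_dyad")
    # sub-threshold counts exclude the region
    weak <- fakeCalls("chr1", 105L, DataFrame(unme = 0L, hemiW = 2L,
                                              hemiC = 0L, me = 0L))
    cl3 <- assignRegionCluster(regions[1], weak, offset = 5L)
    expect_equal(cl3$reason, "excluded")
})

test_that("unoriented regions are rejected", {
    calls <- fakeCalls("chr1", 105L, DataFrame(unme = 0L, hemiW = 5L,
                                               hemiC = 0L, me = 0L))
    r <- GRanges("chr1", IRanges(100L, 118L))
    expect_error(assignRegionCluster(r, calls, offset = 5L), "orientation")
})

test_that("oriented profiles place hemi levels at signed offsets", {
    counts <- DataFrame(unme = 0L, hemiW = 10L, hemiC = 0L, me = 0L)
    calls <- fakeCalls("chr1", 510L, counts)
    plus <- GRanges("chr1", IRanges(491L, 509L), strand = "+")  # center 500
    prof <- orientedHemiProfile(calls, plus, flank = 20L)
    expect_equal(prof$offset, 10L)
    expect_equal(prof$same, 1)
    expect_equal(prof$oppo, 0)
    # flipping the orientation mirrors the offset and swaps the strands
    minus <- plus
    strand(minus) <- "-"
    profM <- orientedHemiProfile(calls, minus, flank = 20L)
    expect_equal(profM$offset, -10L)
    expect_equal(profM$same, 0)
    expect_equal(profM$oppo, 1)
    # no dyads in the flank
    off <- GRanges("chr1", IRanges(2000L, 2018L), strand = "+")
    expect_equal(nrow(orientedHemiProfile(calls, off, flank = 20L)), 0L)
})

test_that("profile mirror symmetry holds on a multi-region simulation", {
    g <- makeGenome(1L, 30000L, gc = 0.5, seed = 119L)
    mm <- makeMethylome(g, methylomeDesign(), seed = 120L)
    frags <- simulateLibrary(g, mm$methylome, unitDigestion(),
                             LibraryParams(nMolecules = 10L), seed = 121L)
    calls <- countDyadStatuses(frags, scanDyads(g, "CpG"))
    centers <- seq(2000L, 28000L, by = 2000L)
    plus <- GRanges("chr1", IRanges(centers - 9L, centers + 9L),
                    strand = "+")
    minus <- plus
    strand(minus) <- "-"
    pP <- orientedHemiProfile(calls, plus, flank = 150L)
    pM <- orientedHemiProfile(calls, minus, flank = 150L)
    m <- match(-pP$offset, pM$offset)
    expect_false(anyNA(m))
    expect_equal(pP$same, pM$oppo[m])
    expect_equal(pP$oppo, pM$same[m])
})

test_that("region signal is the window mean of the track", {
    track <- list(chr1 = rep(2, 1000))
    regions <- GRanges("chr1", IRanges(c(101L, 301L), c(119L, 319L)))
    expect_equal(signalOverRegions(track, regions, 50L), c(2, 2))
    # impulse of 10 inside a 101 bp window
    imp <- list(chr1 = c(rep(0, 499), 10, rep(0, 500)))
    r <- GRanges("chr1", IRanges(461L, 479L))    # center 470
    expect_equal(signalOverRegions(imp, r, 50L), 10 / 101)
    expect_equal(signalOverRegions(track, GRanges(), 50L), numeric())
    expect_error(signalOverRegions(track, GRanges("chr1", IRanges(5, 9)),
                                   50L), "outside")
})

test_that("binomial bias test uses the coverage filter and exact tail", {
    counts <- data.frame(snp = c("a", "b", "c"),
                         chrom = "chr1", pos = c(100L, 200L, 300L),
                         maternal = c(12L, 6L, 5L),
                         paternal = c(0L, 6L, 5L))
    res <- binomialBiasTest(counts)
    # 12:0 two-sided exact p = 2 * (1/2)^12
    expect_equal(res$p[1], 2 * 0.5^12)
    expect_equal(res$p[2], 1)          # perfect balance
    expect_false(res$tested[3])        # coverage 10 is not > 10
    expect_true(is.na(res$p[3]))
    expect_false(res$bias[3])
})

test_that("balanced alleles stay below the FDR budget, imprinted are found", {
    bal <- makeAlleleModel(1000L, imprintFraction = 0, coverage = 20L,
                           seed = 41L)
    resB <- binomialBiasTest(bal)
    expect_lte(mean(resB$bias), 0.05)
    imp <- makeAlleleModel(1000L, imprintFraction = 1, coverage = 30L,
                           seed = 42L)
    resI <- binomialBiasTest(imp)
    expect_gte(mean(resI$bias), 0.90)
    # degenerate threshold flags every tested SNP
    resAll <- binomialBiasTest(imp, alpha = 1)
    expect_true(all(resAll$bias[resAll$tested]))
})

test_that("regions are flagged iff they contain a bias-SNP", {
    calls <- data.frame(snp = c("a", "b"), chrom = "chr1",
                        pos = c(150L, 450L),
                        maternal = c(20L, 10L), paternal = c(0L, 10L))
    res <- binomialBiasTest(calls)
    regions <- GRanges("chr1", IRanges(c(100L, 400L, 700L),
                                       c(200L, 500L, 800L)))
    out <- flagAlleleSpecificRegions(regions, res)
    expect_equal(mcols(out)$alleleSpecific, c(TRUE, FALSE, FALSE))
})
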