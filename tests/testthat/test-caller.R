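# The construct dyad (Watson C 0-based 72) has cut offsets L = 57, R = 89:
# the doubly-cut product is 0-based [57, 89) = 1-based [58, 89].

test_that("deduplication keeps one record per position+UMI", {
    f <- constructFragments(c(58L, 58L), c(89L, 89L), umi = c("AA", "AA"))
    expect_length(dedupFragments(f), 1L)
    f2 <- constructFragments(c(58L, 58L), c(89L, 89L), umi = c("AA", "AT"))
    expect_length(dedupFragments(f2), 2L)
    expect_length(dedupFragments(constructFragments(integer(), integer())),
                  0L)
})

test_that("fragment-vs-dyad classification follows the cut-edge rule", {
    dy <- scanDyads(plantConstruct(), "CpG")
    frags <- constructFragments(
        starts1 = c(58L, 1L, 58L, 1L, 61L, 58L, 60L),
        ends1 =   c(89L, 89L, 146L, 146L, 89L, 80L, 80L))
    expect_equal(classifyFragmentVsDyad(frags, dy),
                 c("me", "hemiW", "hemiC", "unme",
                   "strandOnlyW", "strandOnlyC", "no_call"))
    # a non-resolvable dyad must be filtered before classification
    dyBad <- scanDyads(dna(c(chr = "AACGTG")), "CpG")
    expect_error(classifyFragmentVsDyad(frags[1], dyBad), "resolvable")
})

test_that("status counting tallies all overlapping pairs and filters coverage", {
    dy <- scanDyads(plantConstruct(), "CpG")
    frags <- constructFragments(
        starts1 = c(rep(58L, 3L), 1L, 1L, 58L),
        ends1 =   c(rep(89L, 3L), 89L, 146L, 146L))
    calls <- countDyadStatuses(frags, dy)
    cnt <- dyadCounts(calls)
    expect_equal(unname(cnt[1L, ]), c(1L, 1L, 1L, 3L))   # unme hemiW hemiC me
    expect_equal(dyadCoverage(calls), 6L)
    expect_false(isExcluded(calls))
    # exactly 4 classified fragments: below the "more than four reads" bar
    calls4 <- countDyadStatuses(frags[1:4], dy)
    expect_equal(dyadCoverage(calls4), 4L)
    expect_true(isExcluded(calls4))
    # no overlap at all
    far <- constructFragments(1L, 40L)
    calls0 <- countDyadStatuses(far, dy)
    expect_equal(dyadCoverage(calls0), 0L)
    expect_true(isExcluded(calls0))
})

test_that("strand-only evidence never enters dyad coverage", {
    dy <- scanDyads(plantConstruct(), "CpG")
    frags <- constructFragments(
        starts1 = c(rep(58L, 5L), 61L, 58L),
        ends1 =   c(rep(89L, 5L), 89L, 80L))
    calls <- countDyadStatuses(frags, dy)
    expect_equal(dyadCoverage(calls), 5L)
    expect_equal(mcols(calls)$strandOnlyW, 1L)
    expect_equal(mcols(calls)$strandOnlyC, 1L)
    lv <- dyadLevels(calls)
    expect_equal(lv$fracMe, 1)
})

test_that("classification is invariant under fragment input order", {
    g <- makeGenome(1L, 30000L, gc = 0.5, seed = 108L)
    mm <- makeMethylome(g, methylomeDesign(), seed = 109L)
    frags <- simulateLibrary(g, mm$methylome, unitDigestion(),
                             LibraryParams(nMolecules = 10L), seed = 110L)
    dy <- scanDyads(g, "CpG")
    c1 <- countDyadStatuses(frags, dy)
    c2 <- countDyadStatuses(rev(frags), dy)
    expect_equal(as.data.frame(c1), as.data.frame(c2))
})

test_that("the caller recovers designed statuses exactly at unit efficiency", {
    g <- makeGenome(1L, 30000L, gc = 0.5, seed = 111L)
    mm <- makeMethylome(g, methylomeDesign(), seed = 112L)
    frags <- simulateLibrary(g, mm$methylome, unitDigestion(),
                             LibraryParams(nMolecules = 20L), seed = 113L)
    calls <- countDyadStatuses(frags, scanDyads(g, "CpG"))
    m <- match(paste(seqnames(mm$truth), start(mm$truth)),
               paste(seqnames(calls), start(calls)))
    expect_false(anyNA(m))
    covered <- !isExcluded(calls)[m]
    pred <- aggregatePredominant(dyadCounts(calls)[m, ], 1L)
    expect_true(any(covered))
    expect_equal(pred[covered], mcols(mm$truth)$status[covered])
    # fractions over the four statuses sum to 1
    lv <- dyadLevels(calls[!isExcluded(calls)])
    expect_equal(lv$fracUnme + lv$fracHemiW + lv$fracHemiC + lv$fracMe,
                 rep(1, nrow(lv)))
})

test_that("cytosine-level calls count edge matches against spanning reads", {
    g <- plantConstruct()
    sites <- scanCNNRSites(g)
    # Watson site (1-based 73, breakpoint 89) and Crick site (74, bp 57)
    frags <- constructFragments(
        starts1 = c(1L, 1L, 90L), ends1 = c(89L, 146L, 146L))
    lv <- callCytosineLevels(frags, sites, CallerConfig(minDyadCoverage = 1L))
    w <- as.data.frame(lv)[as.data.frame(lv)$strand == "+", ]
    expect_equal(w$meth, 1L)     # the fragment ending at the cut
    expect_equal(w$unmeth, 1L)   # the full-length spanning fragment
    expect_equal(w$level, 0.5)
    cr <- as.data.frame(lv)[as.data.frame(lv)$strand == "-", ]
    expect_equal(cr$meth, 0L)
    expect_equal(cr$unmeth, 2L)  # both fragments span offset 57 uncut
    expect_equal(cr$level, 0)
})

test_that("cytosine levels estimate the cutting efficiency", {
    # always-methylated CGNA-type Watson site cut at 80% efficiency
    g <- plantConstruct()
    m <- uniformDyadMethylome(g, "hemiW")     # Watson strand only
    frags <- simulateLibrary(g, m, DigestionParams(),
                             LibraryParams(nMolecules = 10000L),
                             seed = 114L)
    lv <- callCytosineLevels(frags, scanCNNRSites(g),
                             CallerConfig(dedup = FALSE))
    w <- as.data.frame(lv)[as.data.frame(lv)$strand == "+", ]
    se <- sqrt(0.8 * 0.2 / 10000)
    expect_lt(abs(w$level - 0.80), 3 * se)
})

test_that("dyad level computation needs positive coverage", {
    dy <- scanDyads(plantConstruct(), "CpG")
    calls <- countDyadStatuses(constructFragments(1L, 40L), dy)
    expect_error(dyadLevels(calls), "zero coverage")
    some <- countDyadStatuses(
        constructFragments(c(58L, 1L, 58L, 1L), c(89L, 89L, 146L, 146L)),
        dy, CallerConfig(minDyadCoverage = 1L))
    lv <- dyadLevels(some)
    expect_equal(lv$fracMe, 0.25)
    expect_equal(lv$methWatson, 0.5)
})
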