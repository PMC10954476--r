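test_that("the cut model leaves a 4 nt 5' overhang at 9/13 nt downstream", {
    cm <- mspjiCutModel()
    expect_equal(cm$nearOffset, 9L)
    expect_equal(cm$farOffset, 13L)
    expect_equal(cm$overhang, 4L)
})

test_that("breakpoints fall 17 bp past the Watson C and 16 bp before the Crick C", {
    g <- plantConstruct()   # Watson C at 0-based 72, Crick partner at 73
    mW <- uniformDyadMethylome(g, "hemiW")
    molW <- sampleMolecules(mW, 1L, seed = 1L)
    expect_equal(breakpointsForMolecule(g, molW, unitDigestion())$construct,
                 89L)                     # 72 + 17
    mB <- uniformDyadMethylome(g, "me")
    molB <- sampleMolecules(mB, 1L, seed = 1L)
    expect_equal(breakpointsForMolecule(g, molB, unitDigestion())$construct,
                 c(57L, 89L))             # 73 - 16 and 72 + 17
    mU <- uniformDyadMethylome(g, "unme")
    molU <- sampleMolecules(mU, 1L, seed = 1L)
    expect_length(breakpointsForMolecule(g, molU, unitDigestion()), 0L)
})

test_that("a methylated site outside CNNR context is a model violation", {
    g <- dna(c(chr = "AAAACAAAAA"))   # C at 5 with A at 8: valid CNNR
    m <- siteMethylome(g, "chr", 5L, "+", prob = 1)
    mol <- sampleMolecules(m, 1L, seed = 1L)
    expect_silent(breakpointsForMolecule(g, mol, unitDigestion()))
    gBad <- dna(c(chr = "AAAACAATAA"))  # T at the R position
    expect_error(breakpointsForMolecule(gBad, mol, unitDigestion()),
                 "CNNR")
})

test_that("digestion partitions the molecule and conserves length", {
    expect_equal(width(digestMolecule(146L, c(57L, 89L))), c(57L, 32L, 57L))
    expect_equal(width(digestMolecule(146L, 89L)), c(89L, 57L))
    expect_equal(width(digestMolecule(146L)), 146L)
    for (k in c(0L, 1L, 5L, 20L)) {
        bp <- sort(sample.int(999L, k))
        w <- width(digestMolecule(1000L, bp))
        expect_length(w, k + 1L)
        expect_equal(sum(w), 1000L)
    }
    expect_error(digestMolecule(100L, c(50L, 40L)), "increasing")
    expect_error(digestMolecule(100L, 100L), "strictly inside")
})

test_that("a fully methylated resolvable dyad releases the centered 32-mer", {
    g <- plantConstruct()
    m <- uniformDyadMethylome(g, "me")
    frags <- simulateLibrary(g, m, unitDigestion(),
                             LibraryParams(nMolecules = 100L), seed = 3L)
    mid <- frags[width(frags) == 32L]
    expect_equal(length(mid), 100L)
    # [p - 15, p + 17) in 0-based terms, p = 72
    expect_true(all(start(mid) == 58L & end(mid) == 89L))
    # the YNCGNR 6-mer occupies offsets 13-18 of the 32-mer (0-based)
    seq32 <- substr(as.character(g[[1]]), 58L, 89L)
    expect_equal(substr(seq32, 14L, 19L), "TTCGAA")
})

test_that("a fully methylated CWG dyad releases a 31 bp fragment", {
    bg <- rep("A", 146L)
    bg[71] <- "T"                   # Y upstream of the Crick motif
    bg[72] <- "C"; bg[74] <- "G"    # C-A-G dyad, Watson C at 1-based 72
    g <- dna(c(construct = paste(bg, collapse = "")))
    dy <- scanDyads(g, "CWG")
    expect_true(mcols(dy)$resolvable)
    m <- uniformDyadMethylome(g, "me", kind = "CWG")
    mol <- sampleMolecules(m, 1L, seed = 1L)
    w <- width(digestMolecule(146L,
                              breakpointsForMolecule(g, mol,
                                                     unitDigestion())$construct))
    expect_true(31L %in% w)
    expect_equal(sum(w), 146L)
})

test_that("purification efficiency removes 32 bp fragments when zero", {
    g <- plantConstruct()
    m <- uniformDyadMethylome(g, "me")
    frags <- simulateLibrary(g, m, unitDigestion(),
                             LibraryParams(nMolecules = 50L, ePu = 0),
                             seed = 4L)
    expect_false(any(width(frags) == 32L))
    expect_true(any(width(frags) == 57L))
})

test_that("duplicate emission is reversed by position+UMI dedup", {
    g <- plantConstruct()
    m <- uniformDyadMethylome(g, "me")
    base <- simulateLibrary(g, m, unitDigestion(),
                            LibraryParams(nMolecules = 300L,
                                          duplicateRate = 0),
                            seed = 5L)
    dup <- simulateLibrary(g, m, unitDigestion(),
                           LibraryParams(nMolecules = 300L,
                                         duplicateRate = 0.5),
                           seed = 5L)
    expect_gt(length(dup), length(base))
    # duplicate copies vanish under dedup; the handful of genuine UMI
    # collisions (identical coordinates on a 146 bp construct) collapse
    # identically in both libraries
    expect_equal(length(dedupFragments(dup)), length(dedupFragments(base)))
    expect_gte(length(dedupFragments(base)) / length(base), 0.98)
})

test_that("raising cutting efficiency never lowers expected breakpoints", {
    g <- makeGenome(1L, 20000L, gc = 0.5, seed = 106L)
    mm <- makeMethylome(g, methylomeDesign(), seed = 107L)
    nFragsAt <- function(effA) {
        fr <- simulateLibrary(g, mm$methylome,
                              DigestionParams(efficiencyByR = c(A = effA,
                                                                G = effA)),
                              LibraryParams(nMolecules = 20L,
                                            sizeMax = 10000L),
                              seed = 9L)
        length(fr)
    }
    # more cuts => more retained fragments at a generous size window
    expect_lte(nFragsAt(0.3), nFragsAt(0.9))
})

test_that("simulated libraries are reproducible under a fixed seed", {
    g <- plantConstruct()
    m <- uniformDyadMethylome(g, "me")
    f1 <- simulateLibrary(g, m, DigestionParams(),
                          LibraryParams(nMolecules = 30L), seed = 11L)
    f2 <- simulateLibrary(g, m, DigestionParams(),
                          LibraryParams(nMolecules = 30L), seed = 11L)
    expect_identical(as.data.frame(f1), as.data.frame(f2))
})

test_that("in-silico digest lengths follow the cut-site spacing", {
    pos <- seq(0L, by = 100L, length.out = 11L)
    expect_equal(nrow(insilicoDigestLengths(pos, 0, seed = 1L)), 0L)
    allCut <- insilicoDigestLengths(pos, 1, seed = 1L)
    expect_equal(allCut$length, 100L)
    expect_equal(allCut$count, 10L)
    # p = 0.5 at 100 bp spacing: gaps are geometric with mean 200
    posBig <- seq(0L, by = 100L, length.out = 100000L)
    h <- insilicoDigestLengths(posBig, 0.5, seed = 2L)
    meanLen <- sum(as.numeric(h$length) * h$count) / sum(h$count)
    expect_lt(abs(meanLen - 200) / 200, 0.02)
    expect_error(insilicoDigestLengths(c(3L, 1L), 0.5), "ordered")
})
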