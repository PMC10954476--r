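suppressPackageStartupMessages({
    library(GenomicRanges)
    library(Biostrings)
    library(S4Vectors)
})

# unit-efficiency digestion (no stochastic cutting)
unitDigestion <- function() DigestionParams(efficiencyByR = c(A = 1, G = 1))

dna <- function(...) {
    x <- c(...)
    if (is.null(names(x))) names(x) <- paste0("chr", seq_along(x))
    DNAStringSet(x)
}

# methylome carrying probability `prob` at explicit (pos, strand) sites
siteMethylome <- function(genome, chrom, pos, strandChar, prob = 1,
                          context = "CGNR", rBase = "A") {
    gr <- GRanges(chrom, IRanges(pos, pos), strand = strandChar,
                  context = context, rBase = rBase,
                  prob = rep_len(prob, length(pos)))
    seqlengths(gr) <- setNames(width(genome), names(genome))[seqlevels(gr)]
    Methylome(gr)
}

# digest the 146 bp construct with a given dyad status at unit efficiency
digestConstruct <- function(status, motif = "TTCGAA") {
    g <- plantConstruct(motif = motif)
    m <- uniformDyadMethylome(g, status)
    mol <- sampleMolecules(m, 1L, seed = 1L)
    bp <- breakpointsForMolecule(g, mol, unitDigestion())
    off <- if ("construct" %in% names(bp)) bp$construct else integer()
    width(digestMolecule(146L, off))
}

# fragment GRanges on the construct with sequential UMIs
constructFragments <- function(starts1, ends1, umi = NULL) {
    if (is.null(umi)) umi <- sprintf("UMI%04d", seq_along(starts1))
    GRanges(rep("construct", length(starts1)), IRanges(starts1, ends1),
            umi = umi)
}
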