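# Internal helpers shared across modules.

.A <- charToRaw("A"); .C <- charToRaw("C")
.G <- charToRaw("G"); .T <- charToRaw("T")

# Raw-byte view of one chromosome; raw comparisons are an order of
# magnitude faster than character indexing at Mb scale.
.seqBytes <- function(genome, chrom) {
    charToRaw(as.character(genome[[chrom]]))
}

.isY <- function(b) b == .C | b == .T
.isR <- function(b) b == .A | b == .G

# Complement of a vector of raw bases; N (or anything else) stays
# non-matching by mapping to itself.
.complementRaw <- function(b) {
    out <- b
    out[b == .A] <- .T
    out[b == .T] <- .A
    out[b == .C] <- .G
    out[b == .G] <- .C
    out
}

.withSeed <- function(seed, code) {
    if (is.null(seed)) code else withr::with_seed(seed, code)
}

.chromNames <- function(genome) {
    nm <- names(genome)
    if (is.null(nm)) stop("genome sequences must be named")
    nm
}

.chromLengths <- function(genome) {
    stats::setNames(Biostrings::width(genome), .chromNames(genome))
}

# GRanges with seqlengths taken from a DNAStringSet genome.
.genomeGRanges <- function(genome, chrom, start, end, ...) {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), ...)
    GenomeInfoDb::seqlengths(gr) <-
        .chromLengths(genome)[GenomeInfoDb::seqlevels(gr)]
    gr
}

.assertGenome <- function(genome) {
    if (!methods::is(genome, "DNAStringSet"))
        stop("genome must be a DNAStringSet (see readGenome/makeGenome)")
    if (length(genome) == 0L) stop("genome is empty")
    invisible(genome)
}

.randomUMIs <- function(n, umiLength) {
    if (n == 0L) return(character())
    m <- matrix(sample(c("A", "C", "G", "T"), n * umiLength, replace = TRUE),
                nrow = n)
    do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}
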