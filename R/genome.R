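#' Read / write a genome as FASTA
#'
#' Thin wrappers around \pkg{Biostrings}. Sequences are kept uppercase;
#' anything outside A/C/G/T is treated as N by the motif scanners (an N
#' never matches Y, R, C or G).
#'
#' @param path FASTA file (wrapped or unwrapped, multi-contig).
#' @return \code{readGenome}: a named \code{DNAStringSet}.
#' @export
readGenome <- function(path) {
    g <- Biostrings::readDNAStringSet(path)
    names(g) <- sub("\\s.*$", "", names(g))
    g
}

#' @rdname readGenome
#' @param genome a named \code{DNAStringSet}.
#' @export
writeGenome <- function(genome, path) {
    .assertGenome(genome)
    Biostrings::writeXStringSet(genome, path)
    invisible(path)
}

#' Scan a genome for CNNR cytosines on both strands
#'
#' MspJI recognizes a methylated CNNR motif (R = A/G). A Watson-strand site
#' sits at a top-strand C whose base three positions downstream is A or G; a
#' Crick-strand site is reported at the Watson coordinate of the paired
#' base, i.e. at a top-strand G whose base three positions upstream is C or
#' T (so that the bottom strand reads C..R). Sites too close to a contig
#' end to complete the motif are omitted.
#'
#' @param genome a named \code{DNAStringSet}.
#' @return a \code{GRanges} of width-1 sites, strand \code{+} (Watson) or
#'   \code{-} (Crick), with metadata columns \code{context} (\code{"CGNR"}
#'   if the cytosine belongs to a CpG dinucleotide, else \code{"CHNR"}) and
#'   \code{rBase} (the motif's downstream R base on the motif strand).
#' @export
scanCNNRSites <- function(genome) {
    .assertGenome(genome)
    res <- lapply(.chromNames(genome), function(chrom) {
        b <- .seqBytes(genome, chrom)
        L <- length(b)
        if (L < 4L)
            return(NULL)
        # Watson: C at p with R at p+3
        pw <- which(b == .C)
        pw <- pw[pw + 3L <= L]
        pw <- pw[.isR(b[pw + 3L])]
        # Crick: G at q with Y at q-3 (bottom strand reads CNNR)
        qc <- which(b == .G)
        qc <- qc[qc - 3L >= 1L]
        qc <- qc[.isY(b[qc - 3L])]
        # CpG membership: Watson C followed by G; Crick G preceded by C
        wCtx <- ifelse(pw < L & b[pmin(pw + 1L, L)] == .G, "CGNR", "CHNR")
        cCtx <- ifelse(qc > 1L & b[pmax(qc - 1L, 1L)] == .C, "CGNR", "CHNR")
        pos <- c(pw, qc)
        if (!length(pos)) return(NULL)
        data.frame(chrom = chrom, pos = pos,
                   strand = rep(c("+", "-"), c(length(pw), length(qc))),
                   context = c(wCtx, cCtx),
                   rBase = rawToChar(c(b[pw + 3L],
                                       .complementRaw(b[qc - 3L])),
                                     multiple = TRUE),
                   stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    if (is.null(res) || nrow(res) == 0L)
        return(.genomeGRanges(genome, character(), integer(), integer(),
                              strand = character(),
                              context = character(), rBase = character()))
    gr <- .genomeGRanges(genome, res$chrom, res$pos, res$pos,
                         strand = res$strand,
                         context = res$context, rBase = res$rBase)
    sort(gr, ignore.strand = TRUE)
}

#' Scan a genome for CpG or CWG dyads
#'
#' A CpG dyad pairs the Watson-strand C with the C opposite the Watson G
#' (Watson coordinate \code{watsonC + 1}); a CWG dyad (W = A/T) pairs
#' cytosines three bases apart (\code{watsonC + 2}). A dyad is
#' \emph{resolvable} -- both strands independently detectable by MspJI --
#' iff its context is YNCGNR (CpG) or YCWGR with flanks (CWG): Y upstream
#' of the Crick C's motif and R downstream of the Watson C's motif.
#'
#' @param genome a named \code{DNAStringSet}.
#' @param kind \code{"CpG"} or \code{"CWG"}.
#' @return a \code{GRanges} spanning [watson C, partner C Watson
#'   coordinate] with metadata columns \code{kind}, \code{resolvable},
#'   \code{rWatson} and \code{rCrick} (downstream R base of each strand's
#'   CNNR motif; \code{NA} where the flank is truncated or non-R).
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr = "TACGTG"))
#' scanDyads(g, "CpG")   # one resolvable dyad, watson C at position 3
#' @export
scanDyads <- function(genome, kind = c("CpG", "CWG")) {
    kind <- match.arg(kind)
    .assertGenome(genome)
    gap <- if (kind == "CpG") 1L else 2L
    res <- lapply(.chromNames(genome), function(chrom) {
        b <- .seqBytes(genome, chrom)
        L <- length(b)
        p <- which(b == .C)
        p <- p[p + gap <= L]
        if (kind == "CpG") {
            p <- p[b[p + 1L] == .G]
        } else {
            p <- p[(b[p + 1L] == .A | b[p + 1L] == .T) & b[p + 2L] == .G]
        }
        if (!length(p))
            return(NULL)
        # R base downstream of the Watson motif (position p+3)
        rw <- rep(NA_character_, length(p))
        ok <- p + 3L <= L
        rwb <- b[p[ok] + 3L]
        rw[ok][.isR(rwb)] <- rawToChar(rwb[.isR(rwb)], multiple = TRUE)
        # Y upstream of the Crick motif sits at p - 2 (CpG) or p - 1 (CWG)
        # on the Watson strand; its complement is the Crick-strand R base.
        yoff <- if (kind == "CpG") 2L else 1L
        rc <- rep(NA_character_, length(p))
        ok <- p - yoff >= 1L
        ycb <- b[p[ok] - yoff]
        rc[ok][.isY(ycb)] <- rawToChar(.complementRaw(ycb[.isY(ycb)]),
                                       multiple = TRUE)
        data.frame(chrom = chrom, watsonC = p, crickC = p + gap,
                   rWatson = rw, rCrick = rc,
                   resolvable = !is.na(rw) & !is.na(rc),
                   stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    if (is.null(res) || nrow(res) == 0L)
        return(.genomeGRanges(genome, character(), integer(), integer(),
                              kind = character(), resolvable = logical(),
                              rWatson = character(),
                              rCrick = character()))
    .genomeGRanges(genome, res$chrom, res$watsonC, res$crickC,
                   kind = kind, resolvable = res$resolvable,
                   rWatson = res$rWatson, rCrick = res$rCrick)
}

#' Realize a methylome as per-molecule binary states
#'
#' Each site of the methylome is methylated independently on each molecule
#' with its site probability.
#'
#' @param methylome a \linkS4class{Methylome}.
#' @param n number of duplex molecules (>= 1).
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return a \linkS4class{MoleculeMethylation}.
#' @export
sampleMolecules <- function(methylome, n, seed = NULL) {
    stopifnot(methods::is(methylome, "Methylome"), n >= 1)
    n <- as.integer(n)
    S <- length(methylome)
    states <- .withSeed(seed, {
        matrix(stats::runif(n * S) < rep(mcols(methylome)$prob, each = n),
               nrow = n, ncol = S)
    })
    new("MoleculeMethylation", sites = methylome, states = states)
}
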