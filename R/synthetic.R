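#' Generate a random genome
#'
#' I.i.d. bases at a stated GC content; reproducible under a fixed seed.
#' On such a sequence the resolvable fraction of CpG dyads converges to
#' 25\% at \code{gc = 0.5} (Y upstream and R downstream each with
#' probability 1/2, independently).
#'
#' @param nChroms number of chromosomes (named \code{chr1}, ...).
#' @param length length of each chromosome in bp.
#' @param gc GC content in (0, 1); \code{gc = 0} yields an A/T-only
#'   sequence.
#' @param seed optional integer seed.
#' @return a named \code{DNAStringSet}.
#' @export
makeGenome <- function(nChroms = 1L, length = 1e6, gc = 0.5, seed = NULL) {
    stopifnot(length > 0, gc >= 0, gc < 1)
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    .withSeed(seed, {
        seqs <- vapply(seq_len(nChroms), function(i) {
            paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
                         prob = p), collapse = "")
        }, character(1L))
        g <- Biostrings::DNAStringSet(seqs)
        names(g) <- paste0("chr", seq_len(nChroms))
        g
    })
}

#' Build the 146 bp single-dyad validation construct
#'
#' A 146 bp duplex carrying exactly one CpG dyad, resolvable (YNCGNR
#' context), with the Watson-strand C at 0-based position 72 (1-based 73),
#' mirroring the synthesized oligo used to validate the cut geometry:
#' full methylation digests to 57/32/57, Watson-only methylation to 89/57,
#' and the unmethylated duplex stays intact at 146 bp.
#'
#' The default motif context is \code{TTCGAA}: with any G at the inner N
#' or outer R positions the construct would gain an extra Crick-strand
#' CNNR site, so \code{TTCGAA} (or \code{TTCGTA}) on an A/T background is
#' the only way to satisfy "no other CNNR site on either strand". Other
#' YNCGNR 6-mers are accepted (e.g. \code{TTCGGG} to obtain a
#' CGNG-type Watson motif) at the cost of extra -- always unmethylated --
#' strand-level sites.
#'
#' @param motif the 6-mer to plant at 0-based positions 70..75; must be
#'   YNCGNR.
#' @param seed optional integer seed for the A/T background.
#' @return a \code{DNAStringSet} with one sequence named
#'   \code{"construct"}.
#' @export
plantConstruct <- function(motif = "TTCGAA", seed = 0L) {
    ch <- strsplit(toupper(motif), "")[[1]]
    if (length(ch) != 6L || !(ch[1] %in% c("C", "T")) ||
        ch[3] != "C" || ch[4] != "G" || !(ch[6] %in% c("A", "G")))
        stop("motif must be a YNCGNR 6-mer")
    bg <- .withSeed(seed, sample(c("A", "T"), 146L, replace = TRUE))
    bg[71:76] <- ch
    g <- Biostrings::DNAStringSet(paste(bg, collapse = ""))
    names(g) <- "construct"
    dy <- scanDyads(g, "CpG")
    if (length(dy) != 1L || start(dy) != 73L ||
        !mcols(dy)$resolvable)
        stop("construct generation failed its own geometry check")
    g
}

#' Methylome design for the synthetic generator
#'
#' @param statusProbs named probabilities over the four dyad statuses
#'   (\code{unme}, \code{hemiW}, \code{hemiC}, \code{me}); must sum to 1.
#' @param cphRate per-molecule methylation probability applied to
#'   strand-level CHNR sites (default 0).
#' @param minGap minimum distance in bp between dyads carrying a designed
#'   status (default 50). MspJI cuts land up to 17 bp from the cytosine,
#'   so statuses on dyads closer than ~33 bp are not geometrically
#'   identifiable from fragment edges; the generator therefore designs
#'   isolated dyads.
#' @param kind dyad kind to design (\code{"CpG"} or \code{"CWG"}).
#' @return a list with class \code{"MethylomeDesign"}.
#' @export
methylomeDesign <- function(statusProbs = c(unme = 0.25, hemiW = 0.25,
                                            hemiC = 0.25, me = 0.25),
                            cphRate = 0, minGap = 50L,
                            kind = c("CpG", "CWG")) {
    kind <- match.arg(kind)
    if (!all(sort(names(statusProbs)) == sort(.DYAD_STATUSES)))
        stop("statusProbs must name unme, hemiW, hemiC, me")
    if (abs(sum(statusProbs) - 1) > 1e-8)
        stop("statusProbs must sum to 1")
    if (cphRate < 0 || cphRate > 1) stop("cphRate must lie in [0, 1]")
    structure(list(statusProbs = statusProbs, cphRate = cphRate,
                   minGap = as.integer(minGap), kind = kind),
              class = "MethylomeDesign")
}

# Greedy left-to-right selection keeping dyads at least minGap apart.
.spaceDyads <- function(dyads, minGap) {
    keep <- logical(length(dyads))
    chrom <- as.character(seqnames(dyads))
    s <- start(dyads)
    e <- end(dyads)
    for (ch in unique(chrom)) {
        idx <- which(chrom == ch)
        idx <- idx[order(s[idx])]
        last <- -Inf
        for (i in idx) {
            if (s[i] - last >= minGap) {
                keep[i] <- TRUE
                last <- e[i]
            }
        }
    }
    keep
}

#' Generate a designed methylome with a per-dyad truth table
#'
#' Resolvable dyads are selected with a minimum spacing and each assigned
#' a true status drawn from the design's status distribution; the
#' methylome then carries probability 1 on each strand the status
#' methylates and 0 otherwise, so that every sampled molecule is in the
#' designed state. Strand-level CHNR sites optionally receive a uniform
#' per-molecule methylation rate.
#'
#' @param genome a named \code{DNAStringSet}.
#' @param design a \code{\link{methylomeDesign}}.
#' @param seed optional integer seed.
#' @return a list with \code{methylome} (a \linkS4class{Methylome}) and
#'   \code{truth} (the selected dyads as a \code{GRanges} with a
#'   \code{status} metadata column).
#' @export
makeMethylome <- function(genome, design = methylomeDesign(), seed = NULL) {
    .assertGenome(genome)
    dyads <- scanDyads(genome, design$kind)
    dyads <- dyads[mcols(dyads)$resolvable]
    keep <- .spaceDyads(dyads, design$minGap)
    sel <- dyads[keep]
    .withSeed(seed, {
        status <- sample(names(design$statusProbs), length(sel),
                         replace = TRUE, prob = design$statusProbs)
        mcols(sel)$status <- status
        pw <- as.numeric(status %in% c("me", "hemiW"))
        pc <- as.numeric(status %in% c("me", "hemiC"))
        ctx <- if (design$kind == "CpG") "CGNR" else "CHNR"
        siteDf <- data.frame(
            chrom = rep(as.character(seqnames(sel)), 2L),
            pos = c(start(sel), end(sel)),
            strand = rep(c("+", "-"), each = length(sel)),
            context = ctx,
            rBase = c(mcols(sel)$rWatson, mcols(sel)$rCrick),
            prob = c(pw, pc), stringsAsFactors = FALSE)
        if (design$cphRate > 0) {
            cnnr <- scanCNNRSites(genome)
            cph <- cnnr[mcols(cnnr)$context == "CHNR"]
            # keep CpH sites clear of the designed dyads so their cuts
            # cannot collide with dyad fragment edges
            if (length(sel)) {
                lens <- .chromLengths(genome)
                halo <- GRanges(
                    seqnames(sel),
                    IRanges(pmax(1L, start(sel) - design$minGap),
                            pmin(lens[as.character(seqnames(sel))],
                                 end(sel) + design$minGap)))
                near <- GenomicRanges::countOverlaps(
                    cph, halo, ignore.strand = TRUE) > 0
                cph <- cph[!near]
            }
            if (length(cph))
                siteDf <- rbind(siteDf, data.frame(
                    chrom = as.character(seqnames(cph)),
                    pos = start(cph),
                    strand = as.character(strand(cph)),
                    context = "CHNR", rBase = mcols(cph)$rBase,
                    prob = design$cphRate, stringsAsFactors = FALSE))
        }
        gr <- .genomeGRanges(genome, siteDf$chrom, siteDf$pos, siteDf$pos,
                             strand = siteDf$strand,
                             context = siteDf$context,
                             rBase = siteDf$rBase, prob = siteDf$prob)
        list(methylome = Methylome(sort(gr, ignore.strand = TRUE)),
             truth = sel)
    })
}

#' Methylome putting a fixed status on every resolvable dyad
#'
#' Convenience for worked examples: e.g. an all-\code{me} methylome on the
#' 146 bp construct.
#'
#' @param genome a named \code{DNAStringSet}.
#' @param status one of \code{"unme"}, \code{"hemiW"}, \code{"hemiC"},
#'   \code{"me"}.
#' @param kind dyad kind.
#' @return a \linkS4class{Methylome}.
#' @export
uniformDyadMethylome <- function(genome, status = "me", kind = "CpG") {
    stopifnot(status %in% .DYAD_STATUSES)
    probs <- stats::setNames(as.numeric(.DYAD_STATUSES == status),
                             .DYAD_STATUSES)
    makeMethylome(genome, methylomeDesign(statusProbs = probs,
                                          minGap = 0L, kind = kind),
                  seed = 0L)$methylome
}

#' Synthetic allele model for allele-specific methylation testing
#'
#' Draws per-SNP maternal/paternal fragment counts: balanced SNPs at
#' proportion 0.5, imprinted SNPs at \code{imprintedProp} (default 0.95),
#' with the truth recorded.
#'
#' @param nSnps number of SNPs.
#' @param imprintFraction fraction of SNPs that are imprinted.
#' @param coverage total fragments per SNP.
#' @param imprintedProp maternal proportion at imprinted SNPs.
#' @param seed optional integer seed.
#' @return a data.frame with columns \code{snp}, \code{chrom}, \code{pos},
#'   \code{maternal}, \code{paternal}, \code{imprinted}.
#' @export
makeAlleleModel <- function(nSnps, imprintFraction = 0, coverage = 20L,
                            imprintedProp = 0.95, seed = NULL) {
    stopifnot(imprintFraction >= 0, imprintFraction <= 1)
    .withSeed(seed, {
        imprinted <- stats::runif(nSnps) < imprintFraction
        prop <- ifelse(imprinted, imprintedProp, 0.5)
        m <- stats::rbinom(nSnps, coverage, prop)
        data.frame(snp = paste0("snp", seq_len(nSnps)), chrom = "chr1",
                   pos = sort(sample.int(1e6, nSnps)),
                   maternal = m, paternal = coverage - m,
                   imprinted = imprinted)
    })
}
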