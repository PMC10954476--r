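#' The MspJI cut geometry
#'
#' MspJI cleaves 9 nt downstream of the methylated CNNR motif on the
#' methylated strand and 13 nt downstream on the opposite strand, leaving a
#' 4 nt 5' overhang. Fragment boundaries ("breakpoints") are modelled at
#' the far (13 nt) cut only; the overhang is bookkeeping. Breakpoints are
#' expressed as 0-based half-open boundary offsets: a breakpoint \code{k}
#' is the boundary after the k-th base. Under this rule a methylated
#' Watson C at 0-based position \code{p} yields breakpoint \code{p + 17},
#' and a methylated Crick C at Watson coordinate \code{q} yields breakpoint
#' \code{q - 16}; a fully methylated resolvable CpG dyad therefore releases
#' the characteristic 32 bp fragment with the YNCGNR 6-mer at its center,
#' and each cut-created fragment edge has its CNNR motif ending exactly
#' 13 bp inside the fragment.
#'
#' @return a list with \code{nearOffset} (9), \code{farOffset} (13) and
#'   \code{overhang} (4).
#' @export
mspjiCutModel <- function() {
    list(nearOffset = 9L, farOffset = 13L, overhang = 13L - 9L)
}

# Breakpoint offsets for width-1 sites given 1-based Watson positions.
# A 0-based Watson C p maps to 1-based P = p + 1, so p + 17 == P + 16;
# a Crick site at Watson coordinate q maps to q - 16 == Q - 17.
.breakpointOffsets <- function(pos1, strandChar) {
    ifelse(strandChar == "+", pos1 + 16L, pos1 - 17L)
}

#' Breakpoints induced by one molecule's methylation
#'
#' Applies the MspJI cut model to the methylated sites of a single sampled
#' molecule. Each methylated site whose Bernoulli(efficiency) draw succeeds
#' contributes one breakpoint; with \code{starActivity > 0}, every
#' unmethylated CNNR site in the genome may additionally fire. Breakpoints
#' are deduplicated, sorted, and clipped to the open interval
#' (0, chromosome length).
#'
#' @param genome a named \code{DNAStringSet}.
#' @param molecules a \linkS4class{MoleculeMethylation}.
#' @param params a \linkS4class{DigestionParams}.
#' @param molecule which molecule (row) to digest.
#' @param cnnrSites optional pre-computed \code{scanCNNRSites(genome)}
#'   (only consulted when \code{starActivity > 0}).
#' @return a named list (one element per chromosome with at least one
#'   breakpoint) of sorted integer breakpoint offsets.
#' @export
breakpointsForMolecule <- function(genome, molecules,
                                   params = DigestionParams(),
                                   molecule = 1L, cnnrSites = NULL) {
    .assertGenome(genome)
    stopifnot(methods::is(molecules, "MoleculeMethylation"),
              methods::is(params, "DigestionParams"))
    sites <- methSites(molecules)
    state <- methStates(molecules)[molecule, ]
    .validateSiteContexts(genome, sites)
    meth <- sites[state]
    eff <- params@efficiencyByR[mcols(meth)$rBase]
    cut <- meth[stats::runif(length(meth)) < eff]
    bp <- data.frame(chrom = as.character(seqnames(cut)),
                     offset = .breakpointOffsets(start(cut),
                                                 as.character(strand(cut))))
    if (params@starActivity > 0) {
        if (is.null(cnnrSites)) cnnrSites <- scanCNNRSites(genome)
        methKey <- paste(seqnames(meth), start(meth), strand(meth))
        allKey <- paste(seqnames(cnnrSites), start(cnnrSites),
                        strand(cnnrSites))
        un <- cnnrSites[!(allKey %in% methKey)]
        un <- un[stats::runif(length(un)) < params@starActivity]
        bp <- rbind(bp, data.frame(
            chrom = as.character(seqnames(un)),
            offset = .breakpointOffsets(start(un),
                                        as.character(strand(un)))))
    }
    lens <- .chromLengths(genome)
    bp <- bp[bp$offset > 0L & bp$offset < lens[bp$chrom], , drop = FALSE]
    lapply(split(bp$offset, bp$chrom), function(x) sort(unique(x)))
}

# Model precondition: every methylated site must sit in a CNNR context on
# its strand (MspJI cannot produce a cut elsewhere).
.validateSiteContexts <- function(genome, sites) {
    if (!length(sites)) return(invisible(TRUE))
    for (chrom in unique(as.character(seqnames(sites)))) {
        b <- .seqBytes(genome, chrom)
        s <- sites[seqnames(sites) == chrom]
        p <- start(s)
        w <- as.character(strand(s)) == "+"
        okW <- b[p[w]] == .C & p[w] + 3L <= length(b) & .isR(b[p[w] + 3L])
        okC <- b[p[!w]] == .G & p[!w] - 3L >= 1L & .isY(b[p[!w] - 3L])
        if (!all(okW) || !all(okC))
            stop("methylome site(s) on '", chrom,
                 "' lie outside a CNNR context on their strand")
    }
    invisible(TRUE)
}

#' Partition a molecule into restriction fragments
#'
#' @param chromLength molecule (chromosome) length in bp.
#' @param breakpoints sorted 0-based boundary offsets strictly inside
#'   (0, chromLength).
#' @return an \code{IRanges} of \code{length(breakpoints) + 1} fragments
#'   (1-based closed coordinates) partitioning the molecule; widths sum to
#'   \code{chromLength}.
#' @examples
#' # fully methylated dyad on a 146 bp duplex: cuts at 57 and 89
#' width(digestMolecule(146, c(57, 89)))   # 57 32 57
#' @export
digestMolecule <- function(chromLength, breakpoints = integer()) {
    breakpoints <- as.integer(breakpoints)
    if (is.unsorted(breakpoints, strictly = TRUE))
        stop("breakpoints must be strictly increasing")
    if (length(breakpoints) &&
        (breakpoints[1L] <= 0L || breakpoints[length(breakpoints)] >= chromLength))
        stop("breakpoints must lie strictly inside (0, chromLength)")
    bounds <- c(0L, breakpoints, as.integer(chromLength))
    IRanges::IRanges(start = utils::head(bounds, -1L) + 1L,
                     end = utils::tail(bounds, -1L))
}

#' Simulate a sequencing library of MspJI fragments
#'
#' End-to-end emitter: samples molecules from the methylome, digests each
#' with per-site cutting efficiencies, applies the size-selection window
#' and the 32 bp purification efficiency, attaches random UMIs, and
#' optionally emits PCR-duplicate copies.
#'
#' @param genome a named \code{DNAStringSet}.
#' @param methylome a \linkS4class{Methylome}.
#' @param digestion a \linkS4class{DigestionParams}.
#' @param library a \linkS4class{LibraryParams}.
#' @param seed optional integer seed.
#' @return a \code{GRanges} of fragment records with metadata columns
#'   \code{molecule} (source molecule index) and \code{umi}.
#' @export
simulateLibrary <- function(genome, methylome,
                            digestion = DigestionParams(),
                            library = LibraryParams(), seed = NULL) {
    .withSeed(seed, {
        mol <- sampleMolecules(methylome, library@nMolecules)
        libraryFromMolecules(genome, mol, digestion, library)
    })
}

#' @rdname simulateLibrary
#' @param molecules a \linkS4class{MoleculeMethylation} (already sampled;
#'   useful when the per-molecule truth is needed alongside the library).
#' @export
libraryFromMolecules <- function(genome, molecules,
                                 digestion = DigestionParams(),
                                 library = LibraryParams()) {
    .assertGenome(genome)
    stopifnot(methods::is(molecules, "MoleculeMethylation"),
              methods::is(library, "LibraryParams"))
    lens <- .chromLengths(genome)
    sites <- methSites(molecules)
    .validateSiteContexts(genome, sites)
    # flat per-site arrays: GRanges accessors are too slow per molecule
    sChr <- as.character(seqnames(sites))
    sOff <- .breakpointOffsets(start(sites), as.character(strand(sites)))
    sEff <- unname(digestion@efficiencyByR[mcols(sites)$rBase])
    sKey <- paste(sChr, sOff)
    states <- methStates(molecules)
    star <- NULL
    if (digestion@starActivity > 0) {
        cnnr <- scanCNNRSites(genome)
        star <- list(chr = as.character(seqnames(cnnr)),
                     off = .breakpointOffsets(start(cnnr),
                                              as.character(strand(cnnr))),
                     key = paste(as.character(seqnames(cnnr)),
                                 .breakpointOffsets(
                                     start(cnnr),
                                     as.character(strand(cnnr)))))
    }
    n <- nrow(states)
    S <- ncol(states)
    accChr <- vector("list", n); accS <- vector("list", n)
    accE <- vector("list", n); accM <- vector("list", n)
    chromNames <- names(lens)
    for (i in seq_len(n)) {
        cut <- states[i, ] & (stats::runif(S) < sEff)
        chr <- sChr[cut]; off <- sOff[cut]
        if (!is.null(star)) {
            un <- !(star$key %in% sKey[states[i, ]])
            fire <- un & (stats::runif(length(un)) < digestion@starActivity)
            chr <- c(chr, star$chr[fire]); off <- c(off, star$off[fire])
        }
        for (chrom in chromNames) {
            len <- lens[[chrom]]
            o <- off[chr == chrom]
            o <- sort(unique(o[o > 0L & o < len]))
            bounds <- c(0L, o, len)
            s <- bounds[-length(bounds)] + 1L
            e <- bounds[-1L]
            w <- e - s + 1L
            keep <- w >= library@sizeMin & w <= library@sizeMax
            if (library@ePu < 1)
                keep <- keep & (w != 32L |
                                    stats::runif(length(w)) < library@ePu)
            if (!any(keep)) next
            accChr[[i]] <- c(accChr[[i]], rep(chrom, sum(keep)))
            accS[[i]] <- c(accS[[i]], s[keep])
            accE[[i]] <- c(accE[[i]], e[keep])
            accM[[i]] <- c(accM[[i]], rep(i, sum(keep)))
        }
    }
    df <- data.frame(chrom = unlist(accChr), start = unlist(accS),
                     end = unlist(accE), molecule = unlist(accM))
    if (nrow(df) == 0L)
        return(.genomeGRanges(genome, character(), integer(), integer(),
                              molecule = integer(), umi = character()))
    df$umi <- .randomUMIs(nrow(df), library@umiLength)
    if (library@duplicateRate > 0) {
        dup <- df[stats::runif(nrow(df)) < library@duplicateRate, ,
                  drop = FALSE]
        df <- rbind(df, dup)
    }
    .genomeGRanges(genome, df$chrom, df$start, df$end,
                   molecule = df$molecule, umi = df$umi)
}

#' In-silico whole-genome digest from per-site cut probabilities
#'
#' Each candidate cut site is independently set to cut (1) with its
#' probability; the distance between two neighbouring cut sites defines a
#' fragment length. Mirrors the genome-scale digest simulation used to
#' compare expected and observed library insert-size distributions.
#'
#' @param positions cut-site coordinates, ordered increasingly.
#' @param probs per-site cut probabilities in [0, 1] (recycled).
#' @param seed optional integer seed.
#' @return a data.frame with columns \code{length} and \code{count}
#'   (the fragment-length histogram).
#' @export
insilicoDigestLengths <- function(positions, probs, seed = NULL) {
    if (is.unsorted(positions))
        stop("positions must be ordered by coordinate")
    probs <- rep_len(probs, length(positions))
    if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
    cut <- .withSeed(seed, stats::runif(length(positions)) < probs)
    lens <- diff(positions[cut])
    tab <- table(lens)
    data.frame(length = as.integer(names(tab)),
               count = as.integer(tab))
}
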