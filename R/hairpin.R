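#' Default hairpin linker template
#'
#' A short linker sequence with four cytosines, all unmethylated by
#' construction; after bisulfite treatment the fraction of linker Cs read
#' as T estimates the conversion rate of the library.
#' @export
DEFAULT_HAIRPIN_LINKER <- "CGCTATCAGCTT"

.linkerCPositions <- function(linker) {
    which(strsplit(linker, "")[[1]] == "C")
}

# Convert one strand's template characters for a block of molecules.
# template: character vector (one char per position); methState: logical
# matrix molecules x nC giving the methylation state at each C position.
.convertStrand <- function(template, cPos, methState, params) {
    n <- nrow(methState)
    reads <- matrix(rep(template, each = n), nrow = n)
    if (length(cPos)) {
        pConv <- ifelse(methState, params@failureRate, params@conversionRate)
        toT <- matrix(stats::runif(length(pConv)) < pConv, nrow = n)
        sub <- reads[, cPos, drop = FALSE]
        sub[toT] <- "T"
        reads[, cPos] <- sub
    }
    apply(reads, 1L, paste, collapse = "")
}

#' Simulate hairpin-bisulfite reads over genomic windows
#'
#' Emulates the dyad-resolving readout in which both strands of one
#' molecule are sequenced after hairpin ligation: for every molecule and
#' window, the Watson-strand and Crick-strand sequences are emitted after
#' applying C-to-T bisulfite conversion according to each cytosine's
#' per-molecule methylation state, together with the converted linker.
#' \code{crickSeq} is reported as the Crick-strand base at each Watson
#' coordinate (complement, not reverse-complement), so both strings index
#' identically.
#'
#' @param genome a named \code{DNAStringSet}.
#' @param molecules a \linkS4class{MoleculeMethylation}.
#' @param windows a \code{GRanges} of windows within the genome.
#' @param params a \linkS4class{ConversionParams}.
#' @param linker linker template string; its cytosines are unmethylated.
#' @param seed optional integer seed.
#' @return a \code{DataFrame} with columns \code{molecule}, \code{window},
#'   \code{chrom}, \code{start}, \code{end}, \code{watsonSeq},
#'   \code{crickSeq}, \code{linkerSeq}.
#' @export
simulateHairpinReads <- function(genome, molecules, windows,
                                 params = ConversionParams(),
                                 linker = DEFAULT_HAIRPIN_LINKER,
                                 seed = NULL) {
    .assertGenome(genome)
    stopifnot(methods::is(molecules, "MoleculeMethylation"),
              methods::is(params, "ConversionParams"))
    lens <- .chromLengths(genome)
    if (any(start(windows) < 1L) ||
        any(end(windows) > lens[as.character(seqnames(windows))]))
        stop("windows must lie within the genome")
    sites <- methSites(molecules)
    states <- methStates(molecules)
    n <- nrow(states)
    linkChars <- strsplit(linker, "")[[1]]
    linkC <- .linkerCPositions(linker)
    winChrom <- as.character(seqnames(windows))
    siteChrom <- as.character(seqnames(sites))
    sitePos <- start(sites)
    siteStr <- as.character(strand(sites))
    bytesByChrom <- lapply(stats::setNames(nm = unique(winChrom)),
                           function(chrom) .seqBytes(genome, chrom))
    .withSeed(seed, {
        nw <- length(windows)
        wSeq <- cSeq <- lSeq <- vector("list", nw)
        for (wi in seq_len(nw)) {
            chrom <- winChrom[wi]
            ws <- start(windows)[wi]; we <- end(windows)[wi]
            b <- bytesByChrom[[chrom]][ws:we]
            wTmpl <- rawToChar(b, multiple = TRUE)
            cTmpl <- rawToChar(.complementRaw(b), multiple = TRUE)
            wC <- which(wTmpl == "C")
            cC <- which(cTmpl == "C")
            # per-molecule methylation state at each strand's cytosines:
            # a C is methylated iff the methylome carries a site there and
            # that molecule's state is TRUE
            inWin <- which(siteChrom == chrom & sitePos >= ws &
                               sitePos <= we)
            sPos <- sitePos[inWin] - ws + 1L
            sStr <- siteStr[inWin]
            wState <- matrix(FALSE, n, length(wC))
            idx <- match(sPos[sStr == "+"], wC)
            wState[, idx[!is.na(idx)]] <-
                states[, inWin[sStr == "+"][!is.na(idx)], drop = FALSE]
            cState <- matrix(FALSE, n, length(cC))
            idx <- match(sPos[sStr == "-"], cC)
            cState[, idx[!is.na(idx)]] <-
                states[, inWin[sStr == "-"][!is.na(idx)], drop = FALSE]
            lState <- matrix(FALSE, n, length(linkC))
            wSeq[[wi]] <- .convertStrand(wTmpl, wC, wState, params)
            cSeq[[wi]] <- .convertStrand(cTmpl, cC, cState, params)
            lSeq[[wi]] <- .convertStrand(linkChars, linkC, lState, params)
        }
        DataFrame(molecule = rep(seq_len(n), nw),
                  window = rep(seq_len(nw), each = n),
                  chrom = rep(winChrom, each = n),
                  start = rep(start(windows), each = n),
                  end = rep(end(windows), each = n),
                  watsonSeq = unlist(wSeq), crickSeq = unlist(cSeq),
                  linkerSeq = unlist(lSeq))
    })
}

#' Estimate the bisulfite conversion rate from linker cytosines
#'
#' The linker carries only unmethylated cytosines, so the fraction of
#' linker C positions read as T across all reads estimates the library's
#' conversion rate.
#'
#' @param reads output of \code{\link{simulateHairpinReads}}.
#' @param linker the linker template the reads were generated with.
#' @return the estimated rate in [0, 1].
#' @export
estimateConversionRate <- function(reads,
                                   linker = DEFAULT_HAIRPIN_LINKER) {
    cPos <- .linkerCPositions(linker)
    if (!length(cPos) || !nrow(reads))
        stop("no linker cytosines to estimate from")
    obs <- vapply(cPos, function(p) substr(reads$linkerSeq, p, p),
                  character(nrow(reads)))
    mean(obs == "T")
}

#' Extract the dyad status from one hairpin read
#'
#' The Watson strand is methylated iff \code{watsonSeq} retains C at the
#' dyad's Watson coordinate; the Crick strand iff \code{crickSeq} retains C
#' at the partner coordinate.
#'
#' @param read one row of \code{\link{simulateHairpinReads}} output.
#' @param dyad a single dyad (row of \code{\link{scanDyads}} output).
#' @return one of \code{"me"}, \code{"hemiW"}, \code{"hemiC"},
#'   \code{"unme"}.
#' @export
extractDyadStatus <- function(read, dyad) {
    stopifnot(length(dyad) == 1L)
    if (as.character(seqnames(dyad)) != read$chrom ||
        start(dyad) < read$start || end(dyad) > read$end)
        stop("dyad lies outside the read window")
    wcol <- start(dyad) - read$start + 1L
    ccol <- end(dyad) - read$start + 1L
    wM <- substr(read$watsonSeq, wcol, wcol) == "C"
    cM <- substr(read$crickSeq, ccol, ccol) == "C"
    if (wM && cM) "me" else if (wM) "hemiW" else if (cM) "hemiC" else "unme"
}

#' Predominant status per dyad
#'
#' Dyads observed fewer than \code{minCount} times are excluded; otherwise
#' the unique most frequent of the four statuses is returned, and ties are
#' excluded (status not definitively determined).
#'
#' @param counts a matrix/data.frame with columns \code{unme},
#'   \code{hemiW}, \code{hemiC}, \code{me} (rows are dyads), or a single
#'   named vector.
#' @param minCount minimum total observations (default 3).
#' @return character vector: a status or \code{"excluded"} per row.
#' @export
aggregatePredominant <- function(counts, minCount = 3L) {
    x <- .asCountMatrix(counts)
    unname(apply(x, 1L, function(r) {
        if (sum(r) < minCount) return("excluded")
        mx <- max(r)
        top <- names(r)[r == mx]
        if (length(top) != 1L) "excluded" else top
    }))
}

#' Dyad status calls from hairpin reads
#'
#' Classifies every (read, dyad-in-window) pair and aggregates to the
#' predominant status per dyad. Output schema matches
#' \code{\link{countDyadStatuses}}-style counting for direct comparison
#' with the fragment-based caller.
#'
#' @param reads output of \code{\link{simulateHairpinReads}}.
#' @param dyads resolvable dyads (\code{\link{scanDyads}} output).
#' @param minCount minimum observations per dyad (default 3).
#' @return \code{dyads} with added count columns \code{unme},
#'   \code{hemiW}, \code{hemiC}, \code{me} and \code{status} (predominant
#'   or \code{"excluded"}).
#' @export
hairpinDyadCalls <- function(reads, dyads, minCount = 3L) {
    readGr <- GRanges(reads$chrom, IRanges(reads$start, reads$end))
    hits <- GenomicRanges::findOverlaps(dyads, readGr, type = "within",
                                        ignore.strand = TRUE)
    di <- S4Vectors::queryHits(hits)
    ri <- S4Vectors::subjectHits(hits)
    # vectorized form of extractDyadStatus over all (read, dyad) pairs
    wcol <- start(dyads)[di] - reads$start[ri] + 1L
    ccol <- end(dyads)[di] - reads$start[ri] + 1L
    wM <- substr(reads$watsonSeq[ri], wcol, wcol) == "C"
    cM <- substr(reads$crickSeq[ri], ccol, ccol) == "C"
    status <- ifelse(wM & cM, "me",
                     ifelse(wM, "hemiW", ifelse(cM, "hemiC", "unme")))
    tab <- table(factor(di, levels = seq_along(dyads)),
                 factor(status, levels = .DYAD_STATUSES))
    counts <- DataFrame(as.data.frame.matrix(tab))
    rownames(counts) <- NULL
    out <- dyads
    mcols(out) <- cbind(mcols(out), counts)
    mcols(out)$status <- aggregatePredominant(counts, minCount)
    out
}
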