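#' Remove duplicate fragment records
#'
#' One record is retained per (chrom, start, end, UMI) key -- the
#' position+UMI rule needed because 32 bp fragments have low sequence
#' complexity. Retention is deterministic: records are stably sorted by
#' (chrom, start, end, umi) and the first occurrence of each key is kept.
#'
#' @param fragments a \code{GRanges} with a \code{umi} metadata column.
#' @return the deduplicated \code{GRanges}.
#' @export
dedupFragments <- function(fragments) {
    if (!length(fragments)) return(fragments)
    if (is.null(mcols(fragments)$umi))
        stop("fragments must carry a 'umi' metadata column")
    ord <- order(as.character(seqnames(fragments)), start(fragments),
                 end(fragments), mcols(fragments)$umi)
    fragments <- fragments[ord]
    key <- paste(seqnames(fragments), start(fragments), end(fragments),
                 mcols(fragments)$umi, sep = "\r")
    fragments[!duplicated(key)]
}

# Core classification on 0-based half-open fragment [s0, e0) against the
# dyad's left/right cut offsets L0 (Crick-side) and R0 (Watson-side).
.classifyPairs <- function(s0, e0, L0, R0) {
    status <- rep("no_call", length(s0))
    status[s0 == L0 & e0 == R0] <- "me"
    status[e0 == R0 & s0 < L0] <- "hemiW"
    status[s0 == L0 & e0 > R0] <- "hemiC"
    status[s0 < L0 & e0 > R0] <- "unme"
    status[e0 == R0 & s0 > L0] <- "strandOnlyW"
    status[s0 == L0 & e0 < R0] <- "strandOnlyC"
    status
}

.dyadCutOffsets <- function(dyads) {
    # L0 = crickC - 16 in 0-based terms = (1-based crickC) - 17;
    # R0 = watsonC + 17 in 0-based terms = (1-based watsonC) + 16.
    list(L0 = end(dyads) - 17L, R0 = start(dyads) + 16L)
}

#' Classify one fragment against one resolvable dyad
#'
#' A fully methylated dyad is cut on both sides, releasing exactly the
#' 32 bp (CpG) interval between the two far cuts; a hemi-methylated dyad is
#' cut on one side only, so one fragment edge matches that strand's cut and
#' the fragment extends past the other cut; an unmethylated dyad is spanned
#' with neither edge matching. Fragments with a matching edge whose other
#' end falls short of the partner cut carry single-strand evidence only
#' (\code{strandOnlyW}/\code{strandOnlyC}): the partner strand's state is
#' unobservable on that molecule.
#'
#' @param fragments a \code{GRanges} of fragment records.
#' @param dyad a single resolvable dyad (one row of
#'   \code{\link{scanDyads}} output).
#' @return character vector, one status per fragment, in
#'   \{\code{me}, \code{hemiW}, \code{hemiC}, \code{unme},
#'   \code{strandOnlyW}, \code{strandOnlyC}, \code{no_call}\}.
#' @export
classifyFragmentVsDyad <- function(fragments, dyad) {
    stopifnot(length(dyad) == 1L)
    if (!isTRUE(mcols(dyad)$resolvable))
        stop("dyad is not resolvable; filter dyads before classification")
    off <- .dyadCutOffsets(dyad)
    status <- .classifyPairs(start(fragments) - 1L, end(fragments),
                             off$L0, off$R0)
    status[as.character(seqnames(fragments)) !=
               as.character(seqnames(dyad))] <- "no_call"
    status
}

#' Tally dyad statuses from deduplicated fragments
#'
#' Every (fragment, overlapping resolvable dyad) pair is classified with
#' the cut-edge rule and tallied. Coverage is the sum of the four status
#' counts; single-strand (\code{strandOnly*}) evidence is kept separately
#' and never enters coverage. Dyads with coverage below
#' \code{minDyadCoverage} are flagged \code{excluded}.
#'
#' @param fragments a \code{GRanges} with a \code{umi} metadata column.
#' @param dyads output of \code{\link{scanDyads}} (non-resolvable dyads are
#'   dropped).
#' @param config a \linkS4class{CallerConfig}.
#' @return a \linkS4class{DyadCalls}.
#' @export
countDyadStatuses <- function(fragments, dyads, config = CallerConfig()) {
    stopifnot(methods::is(config, "CallerConfig"))
    if (config@dedup) fragments <- dedupFragments(fragments)
    dyads <- dyads[mcols(dyads)$resolvable &
                       mcols(dyads)$kind %in% config@kinds]
    off <- .dyadCutOffsets(dyads)
    # A fragment can only produce a non-no_call status if it overlaps the
    # inter-cut interval (1-based [L0+1, R0]).
    cutIv <- GRanges(seqnames(dyads), IRanges(off$L0 + 1L, off$R0))
    hits <- GenomicRanges::findOverlaps(fragments, cutIv,
                                        ignore.strand = TRUE)
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    status <- .classifyPairs(start(fragments)[qi] - 1L,
                             end(fragments)[qi],
                             off$L0[si], off$R0[si])
    lv <- c(.DYAD_STATUSES, "strandOnlyW", "strandOnlyC")
    keep <- status %in% lv
    tab <- table(factor(si[keep], levels = seq_along(dyads)),
                 factor(status[keep], levels = lv))
    counts <- DataFrame(as.data.frame.matrix(tab))
    rownames(counts) <- NULL
    mcols(dyads) <- cbind(mcols(dyads)[, c("kind", "rWatson", "rCrick")],
                          counts)
    cov <- rowSums(as.matrix(counts[, .DYAD_STATUSES]))
    mcols(dyads)$excluded <- cov < config@minDyadCoverage
    new("DyadCalls", dyads)
}

#' Strand-level methylation calls at CNNR sites
#'
#' For each strand-level CNNR cytosine, methylated evidence is the number
#' of fragments whose edge matches that site's breakpoint (Watson: the
#' fragment ends at the cut; Crick: the fragment starts at it);
#' unmethylated evidence is the number of fragments strictly spanning the
#' breakpoint. The level is methylated / (methylated + unmethylated).
#'
#' @param fragments a \code{GRanges} with a \code{umi} metadata column.
#' @param sites width-1 site \code{GRanges} as from
#'   \code{\link{scanCNNRSites}} (or a \linkS4class{Methylome}).
#' @param config a \linkS4class{CallerConfig}; \code{minDyadCoverage} also
#'   acts as the site coverage threshold.
#' @return \code{sites} with added metadata columns \code{meth},
#'   \code{unmeth}, \code{level} and \code{excluded}.
#' @export
callCytosineLevels <- function(fragments, sites, config = CallerConfig()) {
    stopifnot(methods::is(config, "CallerConfig"))
    if (config@dedup) fragments <- dedupFragments(fragments)
    b <- .breakpointOffsets(start(sites), as.character(strand(sites)))
    chrom <- as.character(seqnames(sites))
    fchrom <- as.character(seqnames(fragments))
    # methylated: edge matches the breakpoint on the motif side
    isW <- as.character(strand(sites)) == "+"
    endKey <- paste(fchrom, end(fragments), sep = "\r")
    startKey <- paste(fchrom, start(fragments) - 1L, sep = "\r")
    siteKey <- paste(chrom, b, sep = "\r")
    meth <- integer(length(sites))
    meth[isW] <- as.integer(table(factor(endKey,
                                         levels = siteKey[isW]))[siteKey[isW]])
    meth[!isW] <- as.integer(table(factor(startKey,
                                          levels = siteKey[!isW]))[siteKey[!isW]])
    # unmethylated: fragment strictly spans the boundary (contains both
    # flanking bases b and b+1)
    bGr <- GRanges(chrom, IRanges(b, b + 1L))
    unmeth <- GenomicRanges::countOverlaps(bGr, fragments, type = "within",
                                           ignore.strand = TRUE)
    out <- sites
    mcols(out)$meth <- meth
    mcols(out)$unmeth <- as.integer(unmeth)
    covn <- meth + unmeth
    mcols(out)$level <- ifelse(covn > 0, meth / covn, NA_real_)
    mcols(out)$excluded <- covn < config@minDyadCoverage
    out
}

#' Per-dyad status fractions and strand methylation levels
#'
#' @param calls a \linkS4class{DyadCalls}; every dyad must have coverage
#'   \eqn{\ge 1} (call on \code{calls[!isExcluded(calls)]}).
#' @return a \code{DataFrame} with the four status fractions
#'   (\code{fracUnme}, \code{fracHemiW}, \code{fracHemiC}, \code{fracMe};
#'   they sum to 1) and per-strand methylation levels
#'   (\code{methWatson} = (me + hemiW)/coverage, \code{methCrick} =
#'   (me + hemiC)/coverage). Single-strand evidence never alters them.
#' @export
dyadLevels <- function(calls) {
    cnt <- unname(dyadCounts(calls))
    colnames(cnt) <- .DYAD_STATUSES
    cov <- unname(rowSums(cnt))
    if (any(cov == 0))
        stop("dyad(s) with zero coverage; filter excluded dyads first")
    DataFrame(fracUnme = unname(cnt[, "unme"] / cov),
              fracHemiW = unname(cnt[, "hemiW"] / cov),
              fracHemiC = unname(cnt[, "hemiC"] / cov),
              fracMe = unname(cnt[, "me"] / cov),
              methWatson = unname((cnt[, "me"] + cnt[, "hemiW"]) / cov),
              methCrick = unname((cnt[, "me"] + cnt[, "hemiC"]) / cov),
              coverage = as.integer(cov))
}
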