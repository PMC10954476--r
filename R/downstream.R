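#' Classify a motif/region by the predominant status of a designated dyad
#'
#' Regions (e.g. 19 bp TF motifs) carry an orientation: the motif strand
#' (\code{+}/\code{-} in the BED strand column). The dyad at the
#' designated 0-based offset along the motif strand is located, its
#' predominant status computed, and mapped to clusters: 1 = unmethylated,
#' 2 = motif-strand hemi, 3 = opposite-strand hemi, 4 = fully methylated.
#' For \code{-}-oriented regions hemiW/hemiC swap roles relative to the
#' motif strand.
#'
#' @param regions a stranded \code{GRanges} of motif regions.
#' @param calls a \linkS4class{DyadCalls} (or any dyad \code{GRanges} with
#'   the four status-count columns).
#' @param offset 0-based dyad offset along the motif strand.
#' @param minCount minimum observations for a definitive status
#'   (default 3).
#' @return a \code{DataFrame} with one row per region: \code{cluster}
#'   (1-4 or \code{NA}), \code{status}, and \code{reason}
#'   (\code{"ok"}, \code{"no_dyad"} or \code{"excluded"}).
#' @export
assignRegionCluster <- function(regions, calls, offset, minCount = 3L) {
    orient <- as.character(strand(regions))
    if (any(orient == "*"))
        stop("regions must carry a motif-strand orientation (+/-)")
    pos <- ifelse(orient == "+", start(regions) + offset,
                  end(regions) - offset)
    posGr <- GRanges(seqnames(regions), IRanges(pos, pos))
    hits <- GenomicRanges::findOverlaps(posGr, calls, select = "first",
                                        ignore.strand = TRUE)
    status <- rep("no_dyad", length(regions))
    has <- !is.na(hits)
    if (any(has))
        status[has] <- aggregatePredominant(
            dyadCounts(calls)[hits[has], , drop = FALSE], minCount)
    # motif-strand mapping: on '-' regions the Watson strand is the
    # opposite strand
    cluster <- rep(NA_integer_, length(regions))
    cluster[status == "unme"] <- 1L
    cluster[status == "me"] <- 4L
    cluster[status == "hemiW"] <- ifelse(orient[status == "hemiW"] == "+",
                                         2L, 3L)
    cluster[status == "hemiC"] <- ifelse(orient[status == "hemiC"] == "+",
                                         3L, 2L)
    DataFrame(cluster = cluster, status = status,
              reason = ifelse(status %in% .DYAD_STATUSES, "ok", status))
}

#' Orientation-aware hemi-methylation profile around regions
#'
#' Dyads within \code{flank} of each region center are binned by signed
#' offset from the center (sign flipped for \code{-}-oriented regions) and
#' their hemi-methylation fractions averaged per offset, separating hemi
#' on the motif strand (\code{same}) from the opposite strand
#' (\code{oppo}). Flipping every orientation mirrors the profile around 0
#' and swaps the two curves.
#'
#' @param calls a \linkS4class{DyadCalls}; excluded dyads are ignored.
#' @param regions a stranded \code{GRanges}.
#' @param flank half-width of the profiled window in bp.
#' @return a data.frame with columns \code{offset}, \code{same},
#'   \code{oppo}, \code{n} (number of contributing dyads).
#' @export
orientedHemiProfile <- function(calls, regions, flank) {
    stopifnot(flank >= 0)
    use <- calls[!isExcluded(calls)]
    if (!length(use) || !length(regions))
        return(data.frame(offset = integer(), same = numeric(),
                          oppo = numeric(), n = integer()))
    lv <- dyadLevels(use)
    center <- floor((start(regions) + end(regions)) / 2)
    win <- GRanges(seqnames(regions),
                   IRanges(center - flank, center + flank))
    dyadPos <- GRanges(seqnames(use), IRanges(start(use), start(use)))
    hits <- GenomicRanges::findOverlaps(dyadPos, win, ignore.strand = TRUE)
    di <- S4Vectors::queryHits(hits)
    ri <- S4Vectors::subjectHits(hits)
    if (!length(di))
        return(data.frame(offset = integer(), same = numeric(),
                          oppo = numeric(), n = integer()))
    plus <- as.character(strand(regions))[ri] == "+"
    off <- ifelse(plus, start(use)[di] - center[ri],
                  center[ri] - start(use)[di])
    same <- ifelse(plus, lv$fracHemiW[di], lv$fracHemiC[di])
    oppo <- ifelse(plus, lv$fracHemiC[di], lv$fracHemiW[di])
    agg <- data.frame(offset = off, same = same, oppo = oppo)
    res <- stats::aggregate(cbind(same, oppo) ~ offset, data = agg,
                            FUN = mean)
    res$n <- as.integer(table(factor(off, levels = res$offset)))
    res[order(res$offset), , drop = FALSE]
}

#' Mean track signal in windows around region centers
#'
#' @param track a per-base numeric track: an \code{RleList} (e.g. from
#'   \code{coverage()}) or a named list of numeric vectors, one per
#'   chromosome.
#' @param regions a \code{GRanges}.
#' @param halfWindow half-width in bp; the window is
#'   \code{[center - halfWindow, center + halfWindow]} around the region
#'   center base.
#' @return numeric vector of per-region window means.
#' @export
signalOverRegions <- function(track, regions, halfWindow) {
    stopifnot(halfWindow >= 0)
    if (!length(regions)) return(numeric())
    center <- floor((start(regions) + end(regions)) / 2)
    chrom <- as.character(seqnames(regions))
    vapply(seq_along(regions), function(i) {
        v <- track[[chrom[i]]]
        if (is.null(v)) stop("track has no data for ", chrom[i])
        from <- center[i] - halfWindow
        to <- center[i] + halfWindow
        if (from < 1L || to > length(v))
            stop("region window [", from, ", ", to, "] outside track on ",
                 chrom[i])
        mean(as.numeric(v[from:to]))
    }, numeric(1L))
}

#' Binomial test for allele-biased SNP coverage
#'
#' SNPs with total (maternal + paternal) coverage of at least
#' \code{minCoverage} (default 11, i.e. strictly more than 10) are tested
#' two-sided against a balanced 0.5 proportion with an exact binomial
#' test; p-values are adjusted across tested SNPs and a SNP is flagged
#' biased when its adjusted value falls below \code{alpha}.
#'
#' @param counts a data.frame with columns \code{maternal} and
#'   \code{paternal} (other columns are carried through).
#' @param minCoverage minimum total coverage to test (default 11).
#' @param alpha FDR threshold (default 0.05).
#' @param method multiple-testing procedure for \code{stats::p.adjust}
#'   (default \code{"BH"}).
#' @return \code{counts} with added columns \code{tested}, \code{p},
#'   \code{q} and \code{bias} (untested SNPs get \code{NA} p/q and
#'   \code{FALSE} bias).
#' @export
binomialBiasTest <- function(counts, minCoverage = 11L, alpha = 0.05,
                             method = "BH") {
    stopifnot(all(c("maternal", "paternal") %in% colnames(counts)))
    m <- counts$maternal
    p <- counts$paternal
    if (any(m < 0 | p < 0)) stop("allele counts must be non-negative")
    total <- m + p
    tested <- total >= minCoverage
    pv <- rep(NA_real_, nrow(counts))
    pv[tested] <- vapply(which(tested), function(i) {
        stats::binom.test(m[i], total[i], p = 0.5,
                          alternative = "two.sided")$p.value
    }, numeric(1L))
    qv <- rep(NA_real_, nrow(counts))
    qv[tested] <- stats::p.adjust(pv[tested], method = method)
    counts$tested <- tested
    counts$p <- pv
    counts$q <- qv
    counts$bias <- !is.na(qv) & qv < alpha
    counts
}

#' Flag regions containing at least one bias-SNP
#'
#' @param regions a \code{GRanges} (genes, peaks, ...).
#' @param biasCalls output of \code{\link{binomialBiasTest}} with
#'   \code{chrom} and \code{pos} columns (1-based SNP positions).
#' @return \code{regions} with a logical metadata column
#'   \code{alleleSpecific}.
#' @export
flagAlleleSpecificRegions <- function(regions, biasCalls) {
    stopifnot(all(c("chrom", "pos") %in% colnames(biasCalls)))
    hot <- biasCalls[biasCalls$bias, , drop = FALSE]
    if (nrow(hot)) {
        snps <- GRanges(hot$chrom, IRanges(hot$pos, hot$pos))
        n <- GenomicRanges::countOverlaps(regions, snps,
                                          ignore.strand = TRUE)
    } else {
        n <- integer(length(regions))
    }
    mcols(regions)$alleleSpecific <- n > 0
    regions
}
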