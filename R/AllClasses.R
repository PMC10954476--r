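#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#'   strand<- sort
#' @importFrom IRanges IRanges
NULL

setClassUnion("integerOrNull", c("integer", "NULL"))

#' Per-site methylome
#'
#' A \code{Methylome} is a set of width-1 cytosine sites on a genome, each
#' carrying a per-molecule methylation probability. Sites live in a single
#' Watson-based coordinate system: a \code{+} (Watson) site sits on a C of
#' the top strand; a \code{-} (Crick) site is indexed by the Watson
#' coordinate of the paired base, whose top-strand base is G. Required
#' metadata columns:
#' \describe{
#'   \item{\code{context}}{\code{"CGNR"} for sites whose cytosine is part of
#'     a CpG dinucleotide, \code{"CHNR"} otherwise.}
#'   \item{\code{rBase}}{the downstream R base (\code{A} or \code{G}) of the
#'     site's CNNR motif, read on the motif strand; governs MspJI cutting
#'     efficiency.}
#'   \item{\code{prob}}{methylation probability in [0, 1].}
#' }
#'
#' @slot elementMetadata,seqnames,ranges,strand,seqinfo,metadata inherited
#'   from \linkS4class{GRanges}.
#' @seealso \code{\link{makeMethylome}}, \code{\link{sampleMolecules}}
#' @export
setClass("Methylome", contains = "GRanges")

setValidity("Methylome", function(object) {
    msg <- character()
    mc <- mcols(object)
    need <- c("context", "rBase", "prob")
    if (!all(need %in% colnames(mc)))
        return(paste("missing metadata column(s):",
                     paste(setdiff(need, colnames(mc)), collapse = ", ")))
    if (length(object)) {
        if (any(width(object) != 1L))
            msg <- c(msg, "all sites must have width 1")
        if (!all(as.character(strand(object)) %in% c("+", "-")))
            msg <- c(msg, "strand must be '+' (Watson) or '-' (Crick)")
        if (any(is.na(mc$prob)) || any(mc$prob < 0) || any(mc$prob > 1))
            msg <- c(msg, "prob must lie in [0, 1]")
        if (!all(mc$rBase %in% c("A", "G")))
            msg <- c(msg, "rBase must be 'A' or 'G'")
        if (!all(mc$context %in% c("CGNR", "CHNR")))
            msg <- c(msg, "context must be 'CGNR' or 'CHNR'")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a Methylome from a site GRanges
#'
#' @param sites a \code{GRanges} of width-1 sites with metadata columns
#'   \code{context}, \code{rBase} and \code{prob} (see
#'   \linkS4class{Methylome}).
#' @return a \code{Methylome}.
#' @export
Methylome <- function(sites = GRanges(context = character(),
                                      rBase = character(),
                                      prob = numeric())) {
    new("Methylome", sites)
}

setMethod("show", "Methylome", function(object) {
    cat("Methylome with", length(object), "site(s) on",
        length(unique(as.character(seqnames(object)))), "sequence(s)\n")
    if (length(object)) {
        cat("  contexts:",
            paste(sprintf("%s=%d", names(table(mcols(object)$context)),
                          table(mcols(object)$context)), collapse = ", "),
            "\n")
        cat(sprintf("  mean methylation probability: %.3f\n",
                    mean(mcols(object)$prob)))
    }
    invisible(NULL)
})

#' Per-molecule methylation states
#'
#' Binary methylation states for every site of a \linkS4class{Methylome}
#' realized on \code{n} independent DNA duplex copies, as produced by
#' \code{\link{sampleMolecules}}. Rows are molecules, columns are sites (in
#' the order of \code{sites}).
#'
#' @slot sites the \linkS4class{Methylome} the states refer to.
#' @slot states logical matrix, \code{n} molecules by \code{length(sites)}.
#' @export
setClass("MoleculeMethylation",
         representation(sites = "Methylome", states = "matrix"))

setValidity("MoleculeMethylation", function(object) {
    if (!is.logical(object@states))
        return("states must be a logical matrix")
    if (ncol(object@states) != length(object@sites))
        return("ncol(states) must equal length(sites)")
    TRUE
})

#' @describeIn MoleculeMethylation number of sampled molecules.
#' @param x,object a \code{MoleculeMethylation}.
#' @export
nMolecules <- function(x) nrow(x@states)

#' @describeIn MoleculeMethylation the underlying site \code{Methylome}.
#' @export
methSites <- function(x) x@sites

#' @describeIn MoleculeMethylation the logical state matrix
#'   (molecules x sites).
#' @export
methStates <- function(x) x@states

setMethod("show", "MoleculeMethylation", function(object) {
    cat("MoleculeMethylation:", nrow(object@states), "molecule(s) x",
        ncol(object@states), "site(s)\n")
    if (length(object@states))
        cat(sprintf("  overall methylated fraction: %.3f\n",
                    mean(object@states)))
    invisible(NULL)
})

#' Per-dyad status counts
#'
#' A \code{DyadCalls} object holds, for each resolvable CpG or CWG dyad, the
#' tallies of fragment-derived status observations. Ranges span
#' [watson C, partner C Watson-coordinate]. Metadata columns:
#' \code{kind} (\code{"CpG"}/\code{"CWG"}), \code{rWatson}, \code{rCrick}
#' (downstream R base per strand), the four status counts \code{unme},
#' \code{hemiW}, \code{hemiC}, \code{me}, the edge-only tallies
#' \code{strandOnlyW}, \code{strandOnlyC} (partner cut site outside the
#' fragment; never part of coverage), and \code{excluded} (coverage below
#' the caller's threshold).
#'
#' @slot elementMetadata,seqnames,ranges,strand,seqinfo,metadata inherited
#'   from \linkS4class{GRanges}.
#' @seealso \code{\link{countDyadStatuses}}, \code{\link{dyadLevels}}
#' @export
setClass("DyadCalls", contains = "GRanges")

.DYAD_STATUSES <- c("unme", "hemiW", "hemiC", "me")

setValidity("DyadCalls", function(object) {
    mc <- mcols(object)
    need <- c("kind", "rWatson", "rCrick", .DYAD_STATUSES,
              "strandOnlyW", "strandOnlyC", "excluded")
    if (!all(need %in% colnames(mc)))
        return(paste("missing metadata column(s):",
                     paste(setdiff(need, colnames(mc)), collapse = ", ")))
    cnt <- as.matrix(mc[, c(.DYAD_STATUSES, "strandOnlyW", "strandOnlyC")])
    if (length(object) && (any(is.na(cnt)) || any(cnt < 0)))
        return("all counts must be non-negative")
    TRUE
})

#' @describeIn DyadCalls the four status counts as an integer matrix with
#'   columns \code{unme}, \code{hemiW}, \code{hemiC}, \code{me}.
#' @param x,object a \code{DyadCalls}.
#' @export
dyadCounts <- function(x) {
    as.matrix(mcols(x)[, .DYAD_STATUSES])
}

#' @describeIn DyadCalls per-dyad coverage: the sum of the four status
#'   counts (edge-only evidence never counts).
#' @export
dyadCoverage <- function(x) {
    as.integer(rowSums(dyadCounts(x)))
}

#' @describeIn DyadCalls logical; dyads failing the coverage filter.
#' @export
isExcluded <- function(x) mcols(x)$excluded

setMethod("show", "DyadCalls", function(object) {
    cov <- dyadCoverage(object)
    cat("DyadCalls with", length(object), "dyad(s);",
        sum(!mcols(object)$excluded), "passing coverage filter\n")
    if (length(object))
        cat(sprintf("  coverage: median %d, max %d\n",
                    as.integer(stats::median(cov)), max(cov)))
    invisible(NULL)
})

#' MspJI digestion parameters
#'
#' @slot efficiencyByR named numeric; per-site cutting probability given the
#'   downstream R base of the CNNR motif. Defaults \code{c(A = 0.80,
#'   G = 0.97)}: digestion at methylated CGNG-type sites is near-complete
#'   (~97\%) while CGNA-type sites are cut at ~80\%.
#' @slot starActivity probability of cutting at an unmethylated CNNR site
#'   (off-target activity); default 0.
#' @export
setClass("DigestionParams",
         representation(efficiencyByR = "numeric", starActivity = "numeric"))

setValidity("DigestionParams", function(object) {
    p <- c(object@efficiencyByR, object@starActivity)
    if (!all(c("A", "G") %in% names(object@efficiencyByR)))
        return("efficiencyByR must name probabilities for 'A' and 'G'")
    if (any(is.na(p)) || any(p < 0) || any(p > 1))
        return("all probabilities must lie in [0, 1]")
    TRUE
})

#' @describeIn DigestionParams constructor.
#' @param efficiencyByR,starActivity see slot documentation.
#' @export
DigestionParams <- function(efficiencyByR = c(A = 0.80, G = 0.97),
                            starActivity = 0) {
    new("DigestionParams", efficiencyByR = efficiencyByR,
        starActivity = starActivity)
}

#' Sequencing-library simulation parameters
#'
#' @slot nMolecules number of duplex molecules sampled from the methylome.
#' @slot sizeMin,sizeMax fragment size window retained after purification
#'   (defaults 32 and 1000; the doubly-cut fully-methylated CpG product is
#'   exactly 32 bp, so \code{sizeMin} may not exceed 32).
#' @slot ePu capture probability applied to 32 bp fragments relative to
#'   longer ones (purification efficiency; default 1).
#' @slot umiLength length of the random unique molecular identifier
#'   attached to each fragment (default 8).
#' @slot duplicateRate probability that a fragment record is emitted a
#'   second time with identical coordinates and UMI (PCR duplicate;
#'   default 0).
#' @export
setClass("LibraryParams",
         representation(nMolecules = "integer", sizeMin = "integer",
                        sizeMax = "integer", ePu = "numeric",
                        umiLength = "integer", duplicateRate = "numeric"))

setValidity("LibraryParams", function(object) {
    msg <- character()
    if (object@nMolecules < 1L) msg <- c(msg, "nMolecules must be >= 1")
    if (object@sizeMin > 32L)
        msg <- c(msg, "sizeMin must be <= 32 (the doubly-cut product size)")
    if (object@sizeMin > object@sizeMax)
        msg <- c(msg, "sizeMin must be <= sizeMax")
    if (object@ePu < 0 || object@ePu > 1)
        msg <- c(msg, "ePu must lie in [0, 1]")
    if (object@duplicateRate < 0 || object@duplicateRate > 1)
        msg <- c(msg, "duplicateRate must lie in [0, 1]")
    if (object@umiLength < 1L) msg <- c(msg, "umiLength must be >= 1")
    if (length(msg)) msg else TRUE
})

#' @describeIn LibraryParams constructor.
#' @param nMolecules,sizeMin,sizeMax,ePu,umiLength,duplicateRate see slot
#'   documentation.
#' @export
LibraryParams <- function(nMolecules = 100L, sizeMin = 32L, sizeMax = 1000L,
                          ePu = 1, umiLength = 8L, duplicateRate = 0) {
    new("LibraryParams", nMolecules = as.integer(nMolecules),
        sizeMin = as.integer(sizeMin), sizeMax = as.integer(sizeMax),
        ePu = ePu, umiLength = as.integer(umiLength),
        duplicateRate = duplicateRate)
}

#' Dyad caller configuration
#'
#' @slot minDyadCoverage minimum number of classified fragments a dyad (or
#'   strand-level site) needs to enter statistical analysis; default 5
#'   ("more than four reads").
#' @slot dedup whether to deduplicate fragments by (position, UMI) before
#'   counting; default \code{TRUE}.
#' @slot kinds dyad kinds to call: subset of \code{c("CpG", "CWG")}.
#' @export
setClass("CallerConfig",
         representation(minDyadCoverage = "integer", dedup = "logical",
                        kinds = "character"))

setValidity("CallerConfig", function(object) {
    msg <- character()
    if (object@minDyadCoverage < 1L)
        msg <- c(msg, "minDyadCoverage must be >= 1")
    if (!all(object@kinds %in% c("CpG", "CWG")))
        msg <- c(msg, "kinds must be a subset of c('CpG', 'CWG')")
    if (length(msg)) msg else TRUE
})

#' @describeIn CallerConfig constructor.
#' @param minDyadCoverage,dedup,kinds see slot documentation.
#' @export
CallerConfig <- function(minDyadCoverage = 5L, dedup = TRUE,
                         kinds = "CpG") {
    new("CallerConfig", minDyadCoverage = as.integer(minDyadCoverage),
        dedup = dedup, kinds = kinds)
}

#' Per-dyad efficiency parameters for count normalization
#'
#' Parameters of the expected-count equations: \code{eWatson} and
#' \code{eCrick} are the MspJI cutting efficiencies on the two strands of a
#' dyad (each determined by that strand's downstream R base, CGNA-type vs
#' CGNG-type), and \code{ePu} is the purification efficiency of the 32 bp
#' doubly-cut fragment. Slots are parallel numeric vectors (recycled to a
#' common length).
#'
#' @slot eWatson,eCrick,ePu numeric vectors in [0, 1].
#' @export
setClass("EfficiencyParams",
         representation(eWatson = "numeric", eCrick = "numeric",
                        ePu = "numeric"))

setValidity("EfficiencyParams", function(object) {
    p <- c(object@eWatson, object@eCrick, object@ePu)
    if (any(is.na(p)) || any(p < 0) || any(p > 1))
        return("all efficiencies must lie in [0, 1]")
    n <- c(length(object@eWatson), length(object@eCrick),
           length(object@ePu))
    if (any(n == 0L))
        return("efficiency vectors must be non-empty")
    if (length(unique(n[n > 1L])) > 1L)
        return("eWatson, eCrick, ePu must be recyclable to a common length")
    TRUE
})

#' @describeIn EfficiencyParams constructor.
#' @param eWatson,eCrick,ePu see slot documentation.
#' @export
EfficiencyParams <- function(eWatson = 1, eCrick = 1, ePu = 1) {
    new("EfficiencyParams", eWatson = eWatson, eCrick = eCrick, ePu = ePu)
}

#' Bisulfite conversion parameters for the hairpin readout
#'
#' @slot conversionRate probability that an unmethylated cytosine reads as T
#'   after bisulfite treatment (default 0.99).
#' @slot failureRate probability that a methylated cytosine reads as T
#'   (over-conversion; default 0).
#' @export
setClass("ConversionParams",
         representation(conversionRate = "numeric", failureRate = "numeric"))

setValidity("ConversionParams", function(object) {
    p <- c(object@conversionRate, object@failureRate)
    if (any(is.na(p)) || any(p < 0) || any(p > 1))
        return("rates must lie in [0, 1]")
    TRUE
})

#' @describeIn ConversionParams constructor.
#' @param conversionRate,failureRate see slot documentation.
#' @export
ConversionParams <- function(conversionRate = 0.99, failureRate = 0) {
    new("ConversionParams", conversionRate = conversionRate,
        failureRate = failureRate)
}
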