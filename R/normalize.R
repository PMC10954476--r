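.asCountMatrix <- function(x) {
    if (methods::is(x, "DyadCalls")) return(dyadCounts(x))
    if (is.numeric(x) && is.null(dim(x))) {
        if (!all(.DYAD_STATUSES %in% names(x)))
            stop("count vector must be named with unme, hemiW, hemiC, me")
        return(matrix(x[.DYAD_STATUSES], nrow = 1L,
                      dimnames = list(NULL, .DYAD_STATUSES)))
    }
    x <- as.matrix(as.data.frame(x))
    if (!all(.DYAD_STATUSES %in% colnames(x)))
        stop("counts must have columns unme, hemiW, hemiC, me")
    x[, .DYAD_STATUSES, drop = FALSE]
}

#' Expected observed counts given true counts and efficiencies
#'
#' The four expected-count equations: with true per-dyad counts M (me),
#' W (hemiW), C (hemiC), U (unme), per-strand cutting efficiencies
#' \eqn{E_W, E_C} and 32 bp purification efficiency \eqn{E_{pu}},
#' \deqn{M_{exp} = M E_W E_C E_{pu}}
#' \deqn{W_{exp} = W + M E_W (1 - E_C)}
#' \deqn{C_{exp} = C + M (1 - E_W) E_C}
#' \deqn{U_{exp} = U + M (1 - E_W)(1 - E_C)}
#' A fully methylated dyad is observed as \code{me} only when both strands
#' are cut and the 32 bp product survives purification; single-cut
#' molecules masquerade as hemi, uncut ones as unmethylated. In the
#' printed form the true hemi counts carry no efficiency factor of their
#' own; \code{mode = "extended"} additionally scales them by their single
#' cut's efficiency (\eqn{W E_W}, \eqn{C E_C}).
#'
#' @param real true counts: a \linkS4class{DyadCalls}, a matrix/data.frame
#'   with columns \code{unme}, \code{hemiW}, \code{hemiC}, \code{me}, or a
#'   single named numeric vector.
#' @param params an \linkS4class{EfficiencyParams} (slots recycled across
#'   rows).
#' @param mode \code{"printed"} (default) or \code{"extended"}.
#' @return a numeric matrix of expected counts with the same four columns.
#' @export
forwardExpected <- function(real, params = EfficiencyParams(),
                            mode = c("printed", "extended")) {
    mode <- match.arg(mode)
    stopifnot(methods::is(params, "EfficiencyParams"))
    x <- .asCountMatrix(real)
    if (any(x < 0)) stop("true counts must be non-negative")
    n <- nrow(x)
    eW <- rep_len(params@eWatson, n)
    eC <- rep_len(params@eCrick, n)
    ePu <- rep_len(params@ePu, n)
    m <- x[, "me"]; w <- x[, "hemiW"]; cc <- x[, "hemiC"]; u <- x[, "unme"]
    if (mode == "extended") {
        w <- w * eW
        cc <- cc * eC
    }
    cbind(unme = u + m * (1 - eW) * (1 - eC),
          hemiW = w + m * eW * (1 - eC),
          hemiC = cc + m * (1 - eW) * eC,
          me = m * eW * eC * ePu)
}

#' Invert the expected-count equations
#'
#' Algebraic inversion of \code{\link{forwardExpected}}: estimates the true
#' counts from observed ones. \eqn{\hat M = M_{exp}/(E_W E_C E_{pu})},
#' then the leakage terms \eqn{\hat M E_W (1-E_C)} etc. are subtracted from
#' the observed hemi/unme counts. Small-count noise can drive estimates
#' negative; these are clamped to 0 and flagged.
#'
#' @param observed observed counts (same accepted forms as
#'   \code{\link{forwardExpected}}).
#' @param params an \linkS4class{EfficiencyParams}; every
#'   \eqn{E_W E_C E_{pu}} product must be positive.
#' @param mode \code{"printed"} or \code{"extended"} (must match the
#'   forward model).
#' @return a numeric matrix of estimated true counts with columns
#'   \code{unme}, \code{hemiW}, \code{hemiC}, \code{me} and a logical
#'   column \code{clamped}.
#' @export
invertObserved <- function(observed, params = EfficiencyParams(),
                           mode = c("printed", "extended")) {
    mode <- match.arg(mode)
    stopifnot(methods::is(params, "EfficiencyParams"))
    x <- .asCountMatrix(observed)
    n <- nrow(x)
    eW <- rep_len(params@eWatson, n)
    eC <- rep_len(params@eCrick, n)
    ePu <- rep_len(params@ePu, n)
    denom <- eW * eC * ePu
    if (any(denom <= 0))
        stop("eWatson * eCrick * ePu must be positive to invert")
    mHat <- x[, "me"] / denom
    wHat <- x[, "hemiW"] - mHat * eW * (1 - eC)
    cHat <- x[, "hemiC"] - mHat * (1 - eW) * eC
    uHat <- x[, "unme"] - mHat * (1 - eW) * (1 - eC)
    if (mode == "extended") {
        wHat <- wHat / eW
        cHat <- cHat / eC
    }
    est <- cbind(unme = uHat, hemiW = wHat, hemiC = cHat, me = mHat)
    # negatives beyond float jitter indicate genuine small-count noise
    clamped <- apply(est < -1e-9, 1L, any)
    if (any(clamped))
        warning(sum(clamped),
                " dyad(s) produced negative estimates; clamped to 0")
    est[est < 0] <- 0
    cbind(est, clamped = as.numeric(clamped))
}

#' Look up per-dyad efficiencies from the downstream R bases
#'
#' Each strand of a resolvable dyad carries its own CNNR motif whose
#' downstream R base (A or G) determines the cutting efficiency class
#' (CGNA-type vs CGNG-type).
#'
#' @param dyads resolvable dyads (\code{\link{scanDyads}} output or a
#'   \linkS4class{DyadCalls}) with \code{rWatson}/\code{rCrick} metadata.
#' @param efficiencyByR named probabilities for R bases \code{A} and
#'   \code{G}.
#' @param ePu purification efficiency of 32 bp fragments.
#' @return an \linkS4class{EfficiencyParams} with vectorized
#'   \code{eWatson}/\code{eCrick}.
#' @export
assignEfficiencies <- function(dyads, efficiencyByR = c(A = 0.80, G = 0.97),
                               ePu = 1) {
    rw <- mcols(dyads)$rWatson
    rc <- mcols(dyads)$rCrick
    if (any(is.na(rw)) || any(is.na(rc)) ||
        !all(c(rw, rc) %in% names(efficiencyByR)))
        stop("dyads must be resolvable with R bases among ",
             paste(names(efficiencyByR), collapse = "/"))
    EfficiencyParams(eWatson = unname(efficiencyByR[rw]),
                     eCrick = unname(efficiencyByR[rc]), ePu = ePu)
}

#' Efficiency-correct observed dyad counts
#'
#' Convenience wrapper: assigns per-dyad efficiencies from the R bases and
#' inverts the expected-count equations for every dyad of a
#' \linkS4class{DyadCalls}.
#'
#' @param calls a \linkS4class{DyadCalls}.
#' @param efficiencyByR,ePu see \code{\link{assignEfficiencies}}.
#' @param mode see \code{\link{forwardExpected}}.
#' @return \code{calls} with added metadata columns \code{corrUnme},
#'   \code{corrHemiW}, \code{corrHemiC}, \code{corrMe} and \code{clamped}.
#' @export
normalizeDyadCalls <- function(calls, efficiencyByR = c(A = 0.80, G = 0.97),
                               ePu = 1, mode = c("printed", "extended")) {
    mode <- match.arg(mode)
    params <- assignEfficiencies(calls, efficiencyByR, ePu)
    est <- invertObserved(calls, params, mode)
    mcols(calls)$corrUnme <- est[, "unme"]
    mcols(calls)$corrHemiW <- est[, "hemiW"]
    mcols(calls)$corrHemiC <- est[, "hemiC"]
    mcols(calls)$corrMe <- est[, "me"]
    mcols(calls)$clamped <- est[, "clamped"] > 0
    calls
}
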