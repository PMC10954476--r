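# Thin command-line interface over the package functions; the shipped
# entry point is inst/scripts/hemidyad-cli.R.

.parseCliArgs <- function(args) {
    if (!length(args)) stop("no subcommand given; see hemidyadCLI help")
    opts <- list(subcommand = args[[1L]])
    args <- args[-1L]
    while (length(args)) {
        key <- args[[1L]]
        if (!grepl("^--", key)) stop("unexpected argument: ", key)
        if (length(args) < 2L) stop("missing value for ", key)
        opts[[sub("^--", "", key)]] <- args[[2L]]
        args <- args[-(1:2)]
    }
    opts
}

.optInt <- function(opts, name, default) {
    if (is.null(opts[[name]])) default else as.integer(opts[[name]])
}
.optNum <- function(opts, name, default) {
    if (is.null(opts[[name]])) default else as.numeric(opts[[name]])
}
.optChr <- function(opts, name, default = NULL) {
    v <- opts[[name]]
    if (is.null(v)) {
        if (is.null(default)) stop("missing required option --", name)
        default
    } else v
}

#' Command-line pipeline driver
#'
#' Subcommands: \code{make-fixtures} (write a complete seeded demo data
#' set), \code{simulate} (digest a methylome into a fragment BED),
#' \code{call} (dedup + dyad/site calling + optional normalization),
#' \code{analyze} (region clusters, oriented profiles, allele-specific
#' tests). All thresholds surface as flags with the method's defaults
#' (coverage > 4 reads, predominant status at >= 3 counts, SNP coverage
#' > 10, FDR 0.05). Identical options and seed give byte-identical
#' outputs.
#'
#' @param args character vector, e.g.
#'   \code{c("simulate", "--genome", "g.fa", ...)}.
#' @return invisibly, a named list of the files written.
#' @export
hemidyadCLI <- function(args = commandArgs(trailingOnly = TRUE)) {
    opts <- .parseCliArgs(args)
    switch(opts$subcommand,
           "make-fixtures" = .cliMakeFixtures(opts),
           "simulate" = .cliSimulate(opts),
           "call" = .cliCall(opts),
           "analyze" = .cliAnalyze(opts),
           stop("unknown subcommand: ", opts$subcommand))
}

.cliMakeFixtures <- function(opts) {
    out <- .optChr(opts, "out")
    seed <- .optInt(opts, "seed", 1L)
    paths <- writeFixtures(out, seed = seed,
                           genomeLength = .optInt(opts, "genome-length",
                                                  50000L),
                           nMolecules = .optInt(opts, "n-molecules", 30L))
    message("wrote ", length(paths), " fixture files under ", out)
    invisible(paths)
}

.cliSimulate <- function(opts) {
    genome <- readGenome(.optChr(opts, "genome"))
    methylome <- readMethylomeTsv(.optChr(opts, "methylome"), genome)
    dig <- DigestionParams(
        efficiencyByR = c(A = .optNum(opts, "eff-a", 0.80),
                          G = .optNum(opts, "eff-g", 0.97)),
        starActivity = .optNum(opts, "star-activity", 0))
    lib <- LibraryParams(nMolecules = .optInt(opts, "n-molecules", 100L),
                         sizeMin = .optInt(opts, "size-min", 32L),
                         sizeMax = .optInt(opts, "size-max", 1000L),
                         ePu = .optNum(opts, "epu", 1),
                         duplicateRate = .optNum(opts, "duplicate-rate", 0))
    frags <- simulateLibrary(genome, methylome, dig, lib,
                             seed = .optInt(opts, "seed", 1L))
    out <- .optChr(opts, "out")
    writeFragmentsBed(frags, out)
    message("wrote ", length(frags), " fragment records to ", out)
    invisible(list(fragments = out))
}

.cliCall <- function(opts) {
    genome <- readGenome(.optChr(opts, "genome"))
    frags <- readFragmentsBed(.optChr(opts, "fragments"), genome)
    cfg <- CallerConfig(minDyadCoverage = .optInt(opts, "min-coverage", 5L),
                        dedup = !identical(opts[["no-dedup"]], "true"),
                        kinds = .optChr(opts, "kinds", "CpG"))
    prefix <- .optChr(opts, "out-prefix")
    dyads <- do.call(rbind, lapply(cfg@kinds, function(k) {
        as.data.frame(scanDyads(genome, k))
    }))
    dyGr <- .genomeGRanges(genome, dyads$seqnames, dyads$start, dyads$end,
                           kind = dyads$kind, resolvable = dyads$resolvable,
                           rWatson = dyads$rWatson, rCrick = dyads$rCrick)
    calls <- countDyadStatuses(frags, dyGr, cfg)
    if (identical(opts[["normalize"]], "true"))
        calls <- normalizeDyadCalls(
            calls,
            efficiencyByR = c(A = .optNum(opts, "eff-a", 0.80),
                              G = .optNum(opts, "eff-g", 0.97)),
            ePu = .optNum(opts, "epu", 1))
    sites <- callCytosineLevels(frags, scanCNNRSites(genome), cfg)
    paths <- list(dyads = paste0(prefix, ".dyads.tsv"),
                  sites = paste0(prefix, ".sites.tsv"))
    writeDyadCallsTsv(calls, paths$dyads)
    con <- .openOut(paths$sites)
    utils::write.table(
        data.frame(chrom = as.character(seqnames(sites)),
                   pos = start(sites) - 1L,
                   strand = as.character(strand(sites)),
                   context = mcols(sites)$context,
                   meth = mcols(sites)$meth, unmeth = mcols(sites)$unmeth,
                   level = mcols(sites)$level,
                   excluded = mcols(sites)$excluded),
        con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    paths <- c(paths, as.list(exportDyadBedGraphs(calls, prefix)))
    message("called ", sum(!isExcluded(calls)), " dyad(s) passing coverage")
    invisible(paths)
}

.cliAnalyze <- function(opts) {
    prefix <- .optChr(opts, "out-prefix")
    paths <- list()
    if (!is.null(opts$calls) && !is.null(opts$regions)) {
        calls <- readDyadCallsTsv(opts$calls)
        regions <- readRegionsBed(opts$regions)
        cl <- assignRegionCluster(regions, calls,
                                  offset = .optInt(opts, "offset", 5L),
                                  minCount = .optInt(opts, "min-count", 3L))
        paths$clusters <- paste0(prefix, ".clusters.tsv")
        con <- .openOut(paths$clusters)
        utils::write.table(
            cbind(data.frame(chrom = as.character(seqnames(regions)),
                             start = start(regions) - 1L,
                             end = end(regions),
                             orientation = as.character(strand(regions))),
                  as.data.frame(cl)),
            con, sep = "\t", quote = FALSE, row.names = FALSE)
        close(con)
        prof <- orientedHemiProfile(calls, regions,
                                    flank = .optInt(opts, "flank", 100L))
        paths$profile <- paste0(prefix, ".profile.tsv")
        con <- .openOut(paths$profile)
        utils::write.table(prof, con, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        close(con)
    }
    if (!is.null(opts$alleles)) {
        al <- utils::read.table(opts$alleles, header = TRUE, sep = "\t")
        res <- binomialBiasTest(al,
                                minCoverage = .optInt(opts,
                                                      "min-snp-coverage",
                                                      11L),
                                alpha = .optNum(opts, "alpha", 0.05))
        paths$asm <- paste0(prefix, ".asm.tsv")
        con <- .openOut(paths$asm)
        utils::write.table(res, con, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        close(con)
    }
    if (!length(paths))
        stop("analyze needs --calls/--regions and/or --alleles")
    message("wrote ", length(paths), " analysis file(s) with prefix ",
            prefix)
    invisible(paths)
}
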