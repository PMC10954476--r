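# Plain-text I/O. Coordinates on disk follow the BED/bedGraph convention
# (0-based half-open); in-memory GRanges are 1-based closed.

.openOut <- function(path) {
    if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
}

#' Write / read fragment records as BED6 + UMI
#'
#' Columns: chrom, start (0-based), end, name (\code{molecule:index}),
#' score (\code{.}), strand (\code{.}), umi. Files end with a newline;
#' gzip output is selected by a \code{.gz} suffix and gzip input is
#' auto-detected.
#'
#' @param fragments a \code{GRanges} with \code{umi} (and optionally
#'   \code{molecule}) metadata.
#' @param path output file.
#' @export
writeFragmentsBed <- function(fragments, path) {
    mol <- mcols(fragments)$molecule
    if (is.null(mol)) mol <- rep(NA_integer_, length(fragments))
    nm <- paste0(ifelse(is.na(mol), "frag", paste0("mol", mol)), ":",
                 seq_along(fragments))
    df <- data.frame(chrom = as.character(seqnames(fragments)),
                     start = start(fragments) - 1L, end = end(fragments),
                     name = nm, score = ".", strand = ".",
                     umi = mcols(fragments)$umi)
    con <- .openOut(path)
    on.exit(close(con))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' @rdname writeFragmentsBed
#' @param genome optional \code{DNAStringSet} providing sequence lengths.
#' @return \code{readFragmentsBed}: a \code{GRanges} with \code{umi}
#'   metadata.
#' @export
readFragmentsBed <- function(path, genome = NULL) {
    gr <- tryCatch(
        rtracklayer::import(path, format = "BED",
                            extraCols = c(umi = "character")),
        error = function(e) stop("malformed BED at '", path, "': ",
                                 conditionMessage(e)))
    strand(gr) <- "*"
    mcols(gr) <- mcols(gr)[, "umi", drop = FALSE]
    if (!is.null(genome))
        GenomeInfoDb::seqlengths(gr) <-
            .chromLengths(genome)[GenomeInfoDb::seqlevels(gr)]
    gr
}

#' Write / read a methylome as TSV
#'
#' Columns: chrom, pos (0-based Watson coordinate), strand, context,
#' rBase, prob.
#'
#' @param methylome a \linkS4class{Methylome}.
#' @param path output file.
#' @export
writeMethylomeTsv <- function(methylome, path) {
    df <- data.frame(chrom = as.character(seqnames(methylome)),
                     pos = start(methylome) - 1L,
                     strand = as.character(strand(methylome)),
                     context = mcols(methylome)$context,
                     rBase = mcols(methylome)$rBase,
                     prob = mcols(methylome)$prob)
    con <- .openOut(path)
    on.exit(close(con))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' @rdname writeMethylomeTsv
#' @param genome optional \code{DNAStringSet} providing sequence lengths.
#' @export
readMethylomeTsv <- function(path, genome = NULL) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            colClasses = c(chrom = "character",
                                           strand = "character",
                                           context = "character",
                                           rBase = "character"))
    gr <- GRanges(df$chrom, IRanges(df$pos + 1L, df$pos + 1L),
                  strand = df$strand, context = df$context,
                  rBase = df$rBase, prob = df$prob)
    if (!is.null(genome))
        GenomeInfoDb::seqlengths(gr) <-
            .chromLengths(genome)[GenomeInfoDb::seqlevels(gr)]
    Methylome(gr)
}

#' Export per-strand methylome probabilities as bedGraph tracks
#'
#' Writes one bedGraph per strand (Watson/Crick), suffixed
#' \code{.watson.bedGraph} / \code{.crick.bedGraph}.
#'
#' @param methylome a \linkS4class{Methylome}.
#' @param prefix path prefix.
#' @return invisibly, the two file paths.
#' @export
exportMethylomeBedGraph <- function(methylome, prefix) {
    paths <- c(watson = paste0(prefix, ".watson.bedGraph"),
               crick = paste0(prefix, ".crick.bedGraph"))
    for (s in c("+", "-")) {
        sub <- methylome[strand(methylome) == s]
        gr <- GRanges(seqnames(sub), IRanges(start(sub), end(sub)),
                      score = mcols(sub)$prob)
        rtracklayer::export(gr, paths[[if (s == "+") "watson" else "crick"]],
                            format = "bedGraph")
    }
    invisible(paths)
}

#' Write / read dyad calls as TSV
#'
#' Columns: chrom, watsonC (0-based), crickC (0-based), kind, rWatson,
#' rCrick, the four status counts, the two strand-only tallies, coverage
#' and the excluded flag; any correction columns present are carried.
#'
#' @param calls a \linkS4class{DyadCalls}.
#' @param path output file.
#' @export
writeDyadCallsTsv <- function(calls, path) {
    mc <- as.data.frame(mcols(calls))
    df <- cbind(data.frame(chrom = as.character(seqnames(calls)),
                           watsonC = start(calls) - 1L,
                           crickC = end(calls) - 1L),
                mc, coverage = dyadCoverage(calls))
    con <- .openOut(path)
    on.exit(close(con))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' @rdname writeDyadCallsTsv
#' @export
readDyadCallsTsv <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            colClasses = c(chrom = "character"))
    gr <- GRanges(df$chrom, IRanges(df$watsonC + 1L, df$crickC + 1L))
    mcols(gr) <- df[, !(colnames(df) %in%
                            c("chrom", "watsonC", "crickC", "coverage")),
                    drop = FALSE]
    new("DyadCalls", gr)
}

#' Export dyad status fractions as bedGraph tracks
#'
#' One track per status (\code{me}, \code{hemiW}, \code{hemiC},
#' \code{unme}), computed over non-excluded dyads.
#'
#' @param calls a \linkS4class{DyadCalls}.
#' @param prefix path prefix; files are
#'   \code{<prefix>.<status>.bedGraph}.
#' @return invisibly, the file paths.
#' @export
exportDyadBedGraphs <- function(calls, prefix) {
    use <- calls[!isExcluded(calls)]
    lv <- dyadLevels(use)
    frac <- list(me = lv$fracMe, hemiW = lv$fracHemiW,
                 hemiC = lv$fracHemiC, unme = lv$fracUnme)
    paths <- character()
    for (st in names(frac)) {
        p <- paste0(prefix, ".", st, ".bedGraph")
        gr <- GRanges(seqnames(use), IRanges(start(use), end(use)),
                      score = frac[[st]])
        rtracklayer::export(gr, p, format = "bedGraph")
        paths[st] <- p
    }
    invisible(paths)
}

#' Read a BED6 region file with orientation
#'
#' @param path BED file whose strand column carries the motif orientation.
#' @return a stranded \code{GRanges}.
#' @export
readRegionsBed <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    if (any(as.character(strand(gr)) == "*"))
        stop("region file '", path,
             "' is missing orientation in the strand column")
    gr
}

#' Write a fragment-length histogram as two-column TSV
#'
#' @param histogram data.frame with columns \code{length} and
#'   \code{count} (as returned by \code{\link{insilicoDigestLengths}}).
#' @param path output file.
#' @export
writeHistogramTsv <- function(histogram, path) {
    con <- .openOut(path)
    on.exit(close(con))
    utils::write.table(histogram, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' Write a complete demo fixture set
#'
#' Generates, under one seed, a small genome with a designed methylome, a
#' simulated fragment library, motif regions, an allele table and an
#' in-silico digest histogram, and writes them all in plain-text formats.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @param genomeLength genome size in bp.
#' @param nMolecules molecules in the simulated library.
#' @return invisibly, a named list of file paths.
#' @export
writeFixtures <- function(dir, seed = 1L, genomeLength = 50000L,
                          nMolecules = 30L) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    genome <- makeGenome(1L, genomeLength, gc = 0.5, seed = seed)
    mm <- makeMethylome(genome, methylomeDesign(), seed = seed + 1L)
    frags <- simulateLibrary(genome, mm$methylome,
                             DigestionParams(efficiencyByR = c(A = 1, G = 1)),
                             LibraryParams(nMolecules = nMolecules),
                             seed = seed + 2L)
    truth <- mm$truth
    # 19 bp motif regions placing the dyad at motif-strand offset 5
    orient <- rep(c("+", "-"), length.out = length(truth))
    regions <- GRanges(seqnames(truth),
                       IRanges(ifelse(orient == "+", start(truth) - 5L,
                                      start(truth) - 13L),
                               ifelse(orient == "+", start(truth) + 13L,
                                      start(truth) + 5L)),
                       strand = orient)
    alleles <- makeAlleleModel(200L, imprintFraction = 0.1,
                               coverage = 20L, seed = seed + 3L)
    sites <- scanCNNRSites(genome)
    hist <- insilicoDigestLengths(
        start(sites)[as.character(strand(sites)) == "+"],
                                  0.5, seed = seed + 4L)
    paths <- list(
        genome = file.path(dir, "genome.fa"),
        methylome = file.path(dir, "methylome.tsv"),
        truth = file.path(dir, "dyad_truth.tsv"),
        fragments = file.path(dir, "fragments.bed"),
        regions = file.path(dir, "regions.bed"),
        alleles = file.path(dir, "alleles.tsv"),
        histogram = file.path(dir, "insilico_lengths.tsv"))
    writeGenome(genome, paths$genome)
    writeMethylomeTsv(mm$methylome, paths$methylome)
    con <- .openOut(paths$truth)
    utils::write.table(
        data.frame(chrom = as.character(seqnames(truth)),
                   watsonC = start(truth) - 1L, crickC = end(truth) - 1L,
                   status = mcols(truth)$status),
        con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    writeFragmentsBed(frags, paths$fragments)
    con <- .openOut(paths$regions)
    utils::write.table(
        data.frame(chrom = as.character(seqnames(regions)),
                   start = start(regions) - 1L, end = end(regions),
                   name = paste0("motif", seq_along(regions)), score = 0,
                   strand = as.character(strand(regions))),
        con, sep = "\t", quote = FALSE, row.names = FALSE,
        col.names = FALSE)
    close(con)
    con <- .openOut(paths$alleles)
    utils::write.table(alleles, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    writeHistogramTsv(hist, paths$histogram)
    invisible(paths)
}
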