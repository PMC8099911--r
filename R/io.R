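#' Read an expression matrix with sample time labels
#'
#' Expression TSV: first column gene id, header = sample ids. Sidecar
#' TSV: two columns, sample id and time label (earliest first defines
#' the level order unless \code{levels} is given).
#'
#' @param path expression TSV.
#' @param timePath sample -> time sidecar TSV.
#' @param levels optional explicit time-level order.
#' @param logScale flag stored in metadata (default TRUE).
#' @return \code{SummarizedExperiment} (see [expressionExperiment()]).
#' @export
readExpressionMatrix <- function(path, timePath, levels = NULL,
                                 logScale = TRUE) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  vals <- as.matrix(tab[, -1, drop = FALSE])
  rownames(vals) <- tab[[1]]
  tt <- utils::read.delim(timePath, header = TRUE,
                          stringsAsFactors = FALSE)
  time <- tt[[2]][match(colnames(vals), tt[[1]])]
  if (anyNA(time)) stop("time labels missing for some samples")
  expressionExperiment(vals, time, levels = levels, logScale = logScale)
}

#' @export
writeExpressionMatrix <- function(se, path, timePath) {
  x <- SummarizedExperiment::assay(se, "exprs")
  utils::write.table(data.frame(gene = rownames(x), x,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = colnames(x),
                                time = as.character(
                                  SummarizedExperiment::colData(se)$time)),
                     timePath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#' @param path GMT file (term, description, members...).
#' @return named list term -> character vector.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t")[[1]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(ln)
    strsplit(ln, "\t")[[1]][1], character(1))
  sets
}

#' @export
writeGMT <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(tn)
    paste(c(tn, description, sets[[tn]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph coverage track
#' @param path bedGraph file (0-based half-open intervals).
#' @return sorted \code{GRanges} with a \code{score} column.
#' @export
readBedGraphTrack <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  sort(gr)
}

#' @export
writeBedGraphTrack <- function(track, path) {
  rtracklayer::export(track, path, format = "bedGraph")
  invisible(path)
}

#' Read BED intervals
#' @param path BED file.
#' @return \code{GRanges}.
#' @export
readBedRegions <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' @export
writeBedRegions <- function(regions, path) {
  rtracklayer::export(regions, path, format = "BED")
  invisible(path)
}

#' Read sparse Hi-C contacts (chrom, bin_i, bin_j, count TSV)
#' @param path TSV with header.
#' @param ... passed to [HiCContacts()] (resolution, gamma,
#'   pseudocount).
#' @return a [HiCContacts-class].
#' @export
readHiCContacts <- function(path, ...) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  HiCContacts(tab[, c("chrom", "bin_i", "bin_j", "count")], ...)
}

#' @export
writeHiCContacts <- function(hic, path) {
  utils::write.table(hic@entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene table (id, chrom, tss, strand TSV)
#' @param path TSV with header.
#' @export
readGeneTable <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @export
writeGeneTable <- function(geneTable, path) {
  utils::write.table(geneTable, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an interaction edge list (node_a, node_b[, evidence] TSV)
#' @param path TSV with header.
#' @export
readInteractions <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @export
writeTSV <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
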