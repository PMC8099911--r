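#' Extrapolated total axon count in the medullary pyramid
#'
#' Labeled axons are counted on sampling lines spanning part of the
#' pyramid cross-section; the total is extrapolated by the ratio of the
#' full pyramid area to the sampled area:
#' \eqn{total = \sum counts \times (A_{pyramid} / A_{sampled})}.
#'
#' @param lineCounts axon counts per sampling line.
#' @param sampledArea total sampled area (um^2), > 0.
#' @param pyramidArea full pyramid cross-section area (um^2), >=
#'   sampledArea.
#' @return extrapolated axon count.
#' @export
medullaTotal <- function(lineCounts, sampledArea, pyramidArea) {
  if (sampledArea <= 0) stop("sampledArea must be > 0")
  if (pyramidArea < sampledArea)
    stop("pyramidArea must be >= sampledArea")
  if (any(lineCounts < 0)) stop("counts must be >= 0")
  sum(lineCounts) * (pyramidArea / sampledArea)
}

#' Fiber index: normalised cross-midline axon counts
#'
#' For each distance from the midline, the mean count across replicate
#' sections divided by the extrapolated total axon count in the
#' medullary pyramid ([medullaTotal()]).
#'
#' @param counts data.frame with columns \code{section},
#'   \code{distance} (um) and \code{count}.
#' @param medulla extrapolated pyramid axon total, > 0.
#' @return named numeric vector, fiber index per distance.
#' @export
fiberIndex <- function(counts, medulla) {
  if (medulla <= 0) stop("medulla total must be > 0; index undefined")
  cts <- as.data.frame(counts)
  if (any(cts$count < 0)) stop("counts must be >= 0")
  means <- tapply(cts$count, cts$distance, mean)
  out <- as.numeric(means) / medulla
  stats::setNames(out, names(means))
}

#' Branch frequency of traced axon segments (branches per mm)
#'
#' Segments shorter than \code{minSegment} um are rejected before
#' summation; the frequency is total branch count over total accepted
#' traced length in mm. If the accepted length is below
#' \code{minTotal} um the value is still computed but a warning notes
#' the sampling guideline was not met.
#'
#' @param segments data.frame with columns \code{length_um} and
#'   \code{branches}.
#' @param minSegment minimum accepted segment length in um (default
#'   100).
#' @param minTotal guideline minimum total traced length in um
#'   (default 5000).
#' @return branches per mm.
#' @export
branchFrequency <- function(segments, minSegment = 100,
                            minTotal = 5000) {
  seg <- as.data.frame(segments)
  keep <- seg$length_um >= minSegment
  seg <- seg[keep, , drop = FALSE]
  totalLen <- sum(seg$length_um)
  if (totalLen <= 0) stop("no accepted traced length")
  if (totalLen < minTotal)
    warning("total accepted length ", totalLen, " um is below the ",
            minTotal, " um sampling guideline")
  sum(seg$branches) / (totalLen / 1000)
}

#' Filter animals by lesion-completeness criterion
#'
#' Pyramidotomy analyses exclude animals whose PKCg ablation is
#' incomplete; the criterion is recorded as a per-animal boolean flag.
#'
#' @param table data.frame with an \code{animal} column.
#' @param included named logical vector per animal (TRUE = keep).
#' @return filtered table.
#' @export
applyExclusion <- function(table, included) {
  tab <- as.data.frame(table)
  keep <- included[as.character(tab$animal)]
  keep[is.na(keep)] <- FALSE
  tab[keep, , drop = FALSE]
}
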