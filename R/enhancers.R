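#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#'   pintersect reduce mcols mcols<-
#' @importFrom IRanges IRanges
NULL

#' Select the n strongest coverage windows (simplified peak picking)
#'
#' Stand-in for an external peak caller keeping only its downstream
#' contract: the n strongest regions. Slides \code{width}-bp windows
#' (step \code{width / 2}) across the covered extent of each
#' chromosome, scores each window by summed coverage
#' (value x overlap), greedily keeps top-scoring non-overlapping
#' windows (ties broken by (chrom, start) ascending), merges book-ended
#' survivors, and returns the top \code{n} regions ranked by their best
#' window score. Fully deterministic.
#'
#' @param track \code{GRanges} with a numeric \code{score} column
#'   (non-overlapping, sorted coverage intervals, e.g. from
#'   [readBedGraphTrack()]).
#' @param n number of regions to return.
#' @param width window width in bp (default 500).
#' @return \code{GRanges} of selected regions with a \code{score}
#'   column; empty (with a warning) for a flat-zero track.
#' @export
selectStrongestRegions <- function(track, n, width = 500L) {
  stopifnot(n >= 1, width >= 50)
  step <- as.integer(width / 2)
  if (length(track) == 0 || all(mcols(track)$score == 0)) {
    warning("flat-zero track: no regions selected")
    return(GRanges())
  }
  wins <- GRanges()
  for (chr in unique(as.character(seqnames(track)))) {
    tr <- track[as.character(seqnames(track)) == chr]
    lo <- min(start(tr))
    hi <- max(end(tr))
    starts <- seq.int(lo, max(lo, hi - 1L), by = step)
    w <- GRanges(chr, IRanges(start = starts, width = width))
    wins <- c(wins, w)
  }
  sc <- countSignal(wins, track)
  keepIdx <- integer()
  ord <- order(-sc, as.character(seqnames(wins)), start(wins))
  taken <- logical(length(wins))
  for (i in ord) {
    if (sc[i] <= 0) break
    if (taken[i]) next
    keepIdx <- c(keepIdx, i)
    ov <- findOverlaps(wins[i], wins)
    taken[S4Vectors::subjectHits(ov)] <- TRUE
  }
  if (!length(keepIdx)) {
    warning("flat-zero track: no regions selected")
    return(GRanges())
  }
  kept <- wins[keepIdx]
  mcols(kept)$score <- sc[keepIdx]
  merged <- reduce(kept, min.gapwidth = 1L)   # merge book-ended survivors
  ov <- findOverlaps(merged, kept)
  best <- tapply(mcols(kept)$score[S4Vectors::subjectHits(ov)],
                 S4Vectors::queryHits(ov), max)
  mcols(merged)$score <- as.numeric(best[as.character(seq_along(merged))])
  ord2 <- order(-mcols(merged)$score, as.character(seqnames(merged)),
                start(merged))
  merged[utils::head(ord2, n)]
}

#' Coverage-weighted signal in a region
#'
#' Sum over track intervals of value x overlap length with the query
#' region(s); 0 where nothing overlaps.
#'
#' @param regions \code{GRanges} query region(s).
#' @param track coverage \code{GRanges} with \code{score}.
#' @return numeric vector, one value per query region.
#' @export
countSignal <- function(regions, track) {
  out <- numeric(length(regions))
  if (!length(track)) return(out)
  ov <- findOverlaps(regions, track)
  if (!length(ov)) return(out)
  q <- S4Vectors::queryHits(ov)
  s <- S4Vectors::subjectHits(ov)
  pw <- width(pintersect(regions[q], track[s]))
  contrib <- pw * mcols(track)$score[s]
  agg <- rowsum(contrib, q)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

#' Element activity: geometric mean of accessibility and acetylation
#'
#' @param atac,h3k27ac nonnegative read-count signals (vectorised).
#' @return \code{sqrt(atac * h3k27ac)}.
#' @export
elementActivity <- function(atac, h3k27ac) {
  if (any(atac < 0) || any(h3k27ac < 0))
    stop("activity inputs must be nonnegative")
  sqrt(atac * h3k27ac)
}

powerLaw <- function(d, resolution, gamma) {
  (resolution / pmax(d, resolution))^gamma
}

#' Hi-C contact value between two positions
#'
#' Positions are binned at the object's resolution. With no stored
#' entries the expected power-law contact
#' \eqn{(res / \max(d, res))^{\gamma}} is returned. With entries, the
#' looked-up count (0 if the pair is absent) plus the pseudocount is
#' rescaled so that the distance-binned mean of observed counts matches
#' the power-law curve; distances with no observed pairs fall back to
#' the power-law value. Cross-chromosome queries return 0 with a
#' warning.
#'
#' @param hic a [HiCContacts-class].
#' @param chrom chromosome of both positions.
#' @param posA,posB bp positions (vectorised, recycled).
#' @return numeric contact value(s).
#' @export
contactValue <- function(hic, chrom, posA, posB) {
  res <- hic@resolution
  n <- max(length(posA), length(posB), length(chrom))
  chrom <- rep_len(chrom, n)
  binA <- floor(rep_len(posA, n) / res)
  binB <- floor(rep_len(posB, n) / res)
  d <- abs(binA - binB) * res
  pl <- powerLaw(d, res, hic@gamma)
  ent <- hic@entries
  if (!nrow(ent)) return(pl)
  out <- numeric(n)
  entD <- abs(ent$bin_j - ent$bin_i) * res
  meanByDist <- tapply(ent$count, entD, mean)
  lo <- pmin(binA, binB)
  hi <- pmax(binA, binB)
  key <- paste(chrom, lo, hi)
  entKey <- paste(ent$chrom, ent$bin_i, ent$bin_j)
  m <- match(key, entKey)
  sameChromHasData <- chrom %in% unique(ent$chrom)
  for (i in seq_len(n)) {
    if (!sameChromHasData[i]) {
      warning("no Hi-C data for chromosome ", chrom[i],
              "; contact set to 0")
      out[i] <- 0
      next
    }
    mu <- meanByDist[as.character(d[i])]
    if (is.na(mu) || mu + hic@pseudocount <= 0) {
      out[i] <- pl[i]                  # no observed pairs at this distance
      next
    }
    cnt <- if (is.na(m[i])) 0 else ent$count[m[i]]
    s <- pl[i] / (as.numeric(mu) + hic@pseudocount)
    out[i] <- (cnt + hic@pseudocount) * s
  }
  out
}

#' Activity-by-contact (ABC) scores for one gene
#'
#' For candidate elements whose midpoint lies within \code{window} of
#' the gene's TSS, \eqn{score_i = A_i C_i / \sum_k A_k C_k} where
#' \eqn{A} is element activity and \eqn{C} the Hi-C contact with the
#' TSS. Scores over all in-window elements sum to 1; pairs with
#' score >= \code{threshold} are retained. Promoter elements contribute
#' to the denominator but promoter self-pairs are excluded from the
#' returned enhancer report.
#'
#' @param gene list or one-row data.frame with \code{id}, \code{chrom},
#'   \code{tss}.
#' @param elements data.frame with columns \code{chrom}, \code{start},
#'   \code{end}, \code{activity}, \code{is_promoter}.
#' @param hic a [HiCContacts-class].
#' @param window candidate window around the TSS in bp (default 5e6).
#' @param threshold retention threshold on the score (default 0.01).
#' @return data.frame (gene, chrom, start, end, activity, contact,
#'   score, distance_to_tss, is_promoter, retained). All in-window
#'   elements are returned (so score sums can be checked); the enhancer
#'   pair list is the subset with \code{retained} TRUE.
#' @export
abcScores <- function(gene, elements, hic, window = 5e6,
                      threshold = 0.01) {
  stopifnot(window > 0)
  el <- as.data.frame(elements)
  el <- el[el$chrom == gene$chrom, , drop = FALSE]
  mid <- floor((el$start + el$end) / 2)
  inWin <- abs(mid - gene$tss) <= window
  el <- el[inWin, , drop = FALSE]
  mid <- mid[inWin]
  if (!nrow(el)) {
    warning("gene ", gene$id, ": no candidate elements in window")
    return(emptyAbc())
  }
  contact <- contactValue(hic, gene$chrom, mid, rep(gene$tss, nrow(el)))
  ac <- el$activity * contact
  tot <- sum(ac)
  if (tot <= 0) {
    warning("gene ", gene$id, ": sum of activity x contact is 0; ",
            "no pairs")
    return(emptyAbc())
  }
  score <- ac / tot
  out <- data.frame(gene = gene$id, chrom = el$chrom, start = el$start,
                    end = el$end, activity = el$activity,
                    contact = contact, score = score,
                    distance_to_tss = abs(mid - gene$tss),
                    is_promoter = el$is_promoter,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$retained <- out$score >= threshold & !out$is_promoter
  out
}

emptyAbc <- function() {
  data.frame(gene = character(), chrom = character(), start = integer(),
             end = integer(), activity = numeric(), contact = numeric(),
             score = numeric(), distance_to_tss = numeric(),
             is_promoter = logical(), retained = logical(),
             stringsAsFactors = FALSE)
}

#' Summarise retained enhancer-gene pairs
#'
#' @param pairs row-bound output of [abcScores()] across genes,
#'   restricted (internally) to retained enhancer pairs.
#' @param band distance band of interest in bp (default 10 kb - 1500
#'   kb, the band the full-data analysis reports 80\% of pairs in).
#' @return list(per_gene = counts, mean, min, max,
#'   band_fraction).
#' @export
pairSummary <- function(pairs, band = c(1e4, 1.5e6)) {
  pr <- pairs[pairs$retained, , drop = FALSE]
  if (!nrow(pr))
    return(list(per_gene = integer(), mean = NA_real_, min = NA_integer_,
                max = NA_integer_, band_fraction = NA_real_))
  cnt <- table(pr$gene)
  inBand <- pr$distance_to_tss >= band[1] & pr$distance_to_tss <= band[2]
  list(per_gene = cnt, mean = mean(as.integer(cnt)),
       min = min(as.integer(cnt)), max = max(as.integer(cnt)),
       band_fraction = mean(inBand))
}
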