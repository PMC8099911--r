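#' @importFrom Biostrings DNAStringSet reverseComplement subseq
NULL

#' Strand-aware promoter windows with sequences
#'
#' Assigns each gene the window [TSS - upstream, TSS + downstream) on
#' the + strand, mirrored for - strand genes, clipped to the
#' chromosome; - strand sequences are reverse-complemented so the TSS
#' end is consistent. The default 1500/300 window is the convention of
#' the discovery analyses; 1000/300 is a common alternative preset for
#' single-TF motif scans.
#'
#' @param geneTable data.frame with columns \code{id}, \code{chrom},
#'   \code{tss} (0-based), \code{strand} (+/-).
#' @param genome named \code{DNAStringSet} of chromosome sequences.
#' @param upstream,downstream window extent in bp (defaults 1500/300).
#' @return list(regions = \code{GRanges} named by gene,
#'   seqs = named \code{DNAStringSet}). Genes on missing contigs are
#'   skipped with a warning.
#' @export
makePromoters <- function(geneTable, genome, upstream = 1500L,
                          downstream = 300L) {
  gt <- as.data.frame(geneTable)
  ok <- gt$chrom %in% names(genome)
  if (any(!ok))
    warning("skipping genes on missing contigs: ",
            paste(gt$id[!ok], collapse = ", "))
  gt <- gt[ok, , drop = FALSE]
  clen <- stats::setNames(Biostrings::width(genome), names(genome))
  s0 <- ifelse(gt$strand == "+", gt$tss - upstream, gt$tss - downstream)
  e0 <- ifelse(gt$strand == "+", gt$tss + downstream, gt$tss + upstream)
  s0 <- pmax(s0, 0L)
  e0 <- pmin(e0, clen[gt$chrom])
  gr <- GRanges(gt$chrom, IRanges(start = s0 + 1L, end = e0),
                strand = gt$strand)
  names(gr) <- gt$id
  seqs <- DNAStringSet(vapply(seq_along(gr), function(i) {
    as.character(subseq(genome[[gt$chrom[i]]], start = s0[i] + 1L,
                        end = e0[i]))
  }, character(1)))
  names(seqs) <- gt$id
  neg <- gt$strand == "-"
  if (any(neg)) seqs[neg] <- reverseComplement(seqs[neg])
  list(regions = gr, seqs = seqs)
}

#' Build anchored scan windows around anchor hits
#'
#' Per sequence: union of [start - D, end + D] flanks over all anchor
#' hits, minus the anchor footprints themselves, clipped to the
#' sequence. D is the maximum inter-binding distance between anchor and
#' partner sites (default 100 bp).
#'
#' @param anchorHits data.frame from [scanSequences()] (columns
#'   \code{seq_id}, \code{start} 0-based, \code{width}).
#' @param seqLengths named integer vector of sequence lengths.
#' @param D flank size in bp (default 100).
#' @return an [AnchoredWindowSet-class]; zero anchor hits anywhere
#'   yields an empty set flagged with attribute \code{anchor_absent}.
#' @export
anchoredWindows <- function(anchorHits, seqLengths, D = 100L) {
  stopifnot(D >= 1)
  seqLengths <- stats::setNames(as.integer(seqLengths),
                                names(seqLengths))
  wins <- list()
  ancs <- list()
  for (sid in names(seqLengths)) {
    h <- anchorHits[anchorHits$seq_id == sid, , drop = FALSE]
    L <- seqLengths[[sid]]
    if (!nrow(h)) {
      wins[[sid]] <- IRanges()
      ancs[[sid]] <- IRanges()
      next
    }
    # 0-based half-open [start, start+width) -> 1-based closed
    foot <- IRanges::reduce(IRanges(start = h$start + 1L,
                                    width = h$width))
    flank <- IRanges::reduce(IRanges(
      start = pmax(IRanges::start(foot) - D, 1L),
      end = pmin(IRanges::end(foot) + D, L)))
    wins[[sid]] <- IRanges::setdiff(flank, foot)
    ancs[[sid]] <- foot
  }
  obj <- new("AnchoredWindowSet", windows = wins, anchors = ancs,
             seqLengths = seqLengths)
  if (sum(vapply(ancs, length, 1L)) == 0L)
    attr(obj, "anchor_absent") <- TRUE
  obj
}

#' Total searchable length of an AnchoredWindowSet (nt)
#' @param windows an [AnchoredWindowSet-class].
#' @export
searchableLength <- function(windows) {
  sum(vapply(windows@windows, function(w) sum(IRanges::width(w)), 1))
}

#' Count partner hits inside anchored windows
#'
#' A partner hit is counted when its footprint overlaps a window; hits
#' whose footprint overlaps an anchor footprint are excluded. Overlap
#' (rather than the start coordinate) keeps the count exactly invariant
#' under reverse-complementing every input sequence.
#'
#' @param partnerHits data.frame from [scanSequences()].
#' @param windows an [AnchoredWindowSet-class].
#' @param perSeq return a named per-sequence count vector instead of
#'   the total (default FALSE).
#' @return integer count (or named integer vector).
#' @export
anchoredHitCount <- function(partnerHits, windows, perSeq = FALSE) {
  counts <- stats::setNames(integer(length(windows@seqLengths)),
                            names(windows@seqLengths))
  if (nrow(partnerHits)) {
    for (sid in unique(partnerHits$seq_id)) {
      w <- windows@windows[[sid]]
      if (is.null(w) || !length(w)) next
      h <- partnerHits[partnerHits$seq_id == sid, , drop = FALSE]
      body <- IRanges(start = h$start + 1L, width = h$width)
      inWin <- IRanges::overlapsAny(body, w)
      foot <- windows@anchors[[sid]]
      onAnchor <- if (length(foot)) IRanges::overlapsAny(body, foot)
                  else rep(FALSE, nrow(h))
      counts[sid] <- sum(inWin & !onAnchor)
    }
  }
  if (perSeq) counts else sum(counts)
}

#' Anchored over-representation Z statistic
#'
#' Binomial Z for the partner hit count in the anchored foreground
#' against the background per-nt hit rate:
#' \eqn{u = bg_{hits} / bg_{nt}}, \eqn{\mu = u \cdot fg_{nt}},
#' \eqn{\sigma = \sqrt{fg_{nt} \, u (1 - u)}},
#' \eqn{z = (fg_{hits} - \mu) / \sigma}. Candidate partners are those
#' with z at or above the threshold (10 by convention here).
#'
#' @param fgHits,fgNt foreground hit count and searchable nt.
#' @param bgHits,bgNt background hit count and scanned nt.
#' @return z value; +Inf (with attribute \code{degenerate}) when the
#'   background rate is 0 but foreground hits exist; 0 when both rates
#'   are degenerate and equal.
#' @export
enrichmentZ <- function(fgHits, fgNt, bgHits, bgNt) {
  stopifnot(fgNt > 0, bgNt > 0)
  u <- bgHits / bgNt
  mu <- u * fgNt
  if (u <= 0 || u >= 1) {
    if (fgHits == mu) return(0)
    z <- if (fgHits > mu) Inf else -Inf
    attr(z, "degenerate") <- TRUE
    return(z)
  }
  (fgHits - mu) / sqrt(fgNt * u * (1 - u))
}

#' One-tailed Fisher exact enrichment p
#'
#' Upper-tail p on the 2x2 table of sequences with/without an anchored
#' partner hit in foreground vs background. Companion statistic to
#' [enrichmentZ()].
#'
#' @param fgPos,fgNeg,bgPos,bgNeg nonnegative table counts.
#' @return p-value (1 for an all-zero table).
#' @export
fisherEnrichment <- function(fgPos, fgNeg, bgPos, bgNeg) {
  tab <- matrix(c(fgPos, fgNeg, bgPos, bgNeg), 2L, 2L, byrow = TRUE)
  if (all(tab == 0)) return(1)
  stats::fisher.test(tab, alternative = "greater")$p.value
}

#' Anchored co-occupancy enrichment over one compartment
#'
#' The core anchored motif analysis: scans the sequences for the anchor
#' motif, builds +/- D windows around anchor hits, counts each
#' candidate partner's hits inside those windows (foreground), and
#' compares against the partner's hit rate in background sequences —
#' by default a seeded per-sequence dinucleotide shuffle of the
#' foreground. Partners below \code{minIc} bits of specificity are
#' excluded up front.
#'
#' @param seqs named \code{DNAStringSet} (or character vector), e.g.
#'   promoter or enhancer sequences of the selected genes.
#' @param anchor anchor motif, a [PFMModel-class].
#' @param partners named list of candidate [PFMModel-class]s.
#' @param D anchored window half-width in bp (default 100).
#' @param relThreshold PWM relative-score threshold (default 0.9).
#' @param minIc minimum motif specificity in bits (default 8).
#' @param background optional background sequences; default NULL uses
#'   \code{nShuffles} dinucleotide shuffles of \code{seqs}.
#' @param nShuffles shuffles per sequence for the default background
#'   (default 5).
#' @param masks optional per-sequence conservation masks (see
#'   [scanSequence()]).
#' @param seed integer seed for the shuffle background.
#' @return data.frame (tf, fg_hits, fg_nt, bg_hits, bg_nt, z,
#'   fisher_p) sorted by z descending, with attribute
#'   \code{anchor_absent} when no anchor hit was found.
#' @export
anchoredEnrichment <- function(seqs, anchor, partners, D = 100L,
                               relThreshold = 0.9, minIc = 8,
                               background = NULL, nShuffles = 5L,
                               masks = NULL, seed = 1L) {
  if (is.null(names(seqs)))
    names(seqs) <- paste0("seq", seq_along(seqs))
  seqChar <- stats::setNames(as.character(seqs), names(seqs))
  seqLen <- stats::setNames(nchar(seqChar), names(seqChar))
  keep <- vapply(partners, function(p)
    informationContent(p) >= minIc, logical(1))
  partners <- partners[keep]
  anchorHits <- scanSequences(seqChar, anchor, relThreshold,
                              masks = masks)
  fgWin <- anchoredWindows(anchorHits, seqLen, D = D)
  fgNt <- searchableLength(fgWin)
  if (is.null(background)) {
    withSeed(seed, {
      background <- unlist(lapply(seq_len(nShuffles), function(r)
        vapply(seqChar, dinucShuffle, character(1))))
    })
    names(background) <- paste0("shuf", seq_along(background))
  } else {
    background <- stats::setNames(as.character(background),
      if (is.null(names(background)))
        paste0("bg", seq_along(background)) else names(background))
  }
  bgLen <- stats::setNames(nchar(background), names(background))
  # background rate: partner hit density per scanned nt of background
  bgNt <- sum(bgLen)
  res <- lapply(names(partners), function(tf) {
    pfm <- partners[[tf]]
    fgHitsAll <- scanSequences(seqChar, pfm, relThreshold, masks = masks)
    fgBySeq <- anchoredHitCount(fgHitsAll, fgWin, perSeq = TRUE)
    fgHits <- sum(fgBySeq)
    bgHitsAll <- scanSequences(background, pfm, relThreshold)
    bgHits <- nrow(bgHitsAll)
    z <- if (fgNt > 0 && bgNt > 0)
      enrichmentZ(fgHits, fgNt, bgHits, bgNt) else NA_real_
    fgPos <- sum(fgBySeq > 0)
    bgPos <- length(unique(bgHitsAll$seq_id))
    fisher <- fisherEnrichment(
      fgPos, length(seqChar) - fgPos,
      bgPos, length(background) - bgPos)
    data.frame(tf = tf, fg_hits = fgHits, fg_nt = fgNt,
               bg_hits = bgHits, bg_nt = bgNt, z = as.numeric(z),
               fisher_p = fisher, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(-out$z, out$tf), , drop = FALSE]
  rownames(out) <- NULL
  if (isTRUE(attr(fgWin, "anchor_absent")))
    attr(out, "anchor_absent") <- TRUE
  out
}

#' Categorise candidate TFs by compartment of over-representation
#'
#' A TF is \code{both} when z reaches the threshold in promoters and
#' enhancers, \code{promoter_only} / \code{enhancer_only} when in one,
#' \code{none} otherwise (strict >= threshold; exact ties included).
#' TFs absent from one compartment are treated as z = -Inf there and
#' flagged.
#'
#' @param promoterResults,enhancerResults data.frames from
#'   [anchoredEnrichment()] (columns \code{tf}, \code{z}).
#' @param zThreshold the Z bar (default 10).
#' @return data.frame (tf, z_promoter, z_enhancer, category, flagged)
#'   sorted by max z descending.
#' @export
categorizeTFs <- function(promoterResults, enhancerResults,
                          zThreshold = 10) {
  tfs <- sort(union(promoterResults$tf, enhancerResults$tf))
  zp <- promoterResults$z[match(tfs, promoterResults$tf)]
  ze <- enhancerResults$z[match(tfs, enhancerResults$tf)]
  flagged <- is.na(zp) | is.na(ze)
  zp[is.na(zp)] <- -Inf
  ze[is.na(ze)] <- -Inf
  pOk <- zp >= zThreshold
  eOk <- ze >= zThreshold
  category <- ifelse(pOk & eOk, "both",
               ifelse(pOk, "promoter_only",
                ifelse(eOk, "enhancer_only", "none")))
  out <- data.frame(tf = tfs, z_promoter = zp, z_enhancer = ze,
                    category = category, flagged = flagged,
                    stringsAsFactors = FALSE)
  out[order(-pmax(out$z_promoter, out$z_enhancer), out$tf), ,
      drop = FALSE]
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  eval.parent(substitute(expr))
}
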