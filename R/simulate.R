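# Seeded generators producing inputs with the statistical structure the
# analysis stages assume, so the pipeline is testable end to end without
# downloads. Every generator is a pure function of its arguments and
# seed (bit-reproducible).

#' Simulate block-correlated expression time courses
#'
#' Genes are organised in modules sharing a module-specific random
#' sample effect (intra-module correlation) on top of a per-module time
#' trend; designated "down" modules decay \code{downFold}-fold from the
#' earliest to the latest time point on the linear scale. Values are on
#' log2 scale with Gaussian noise.
#'
#' @param seed integer seed.
#' @param moduleSizes genes per planted module (default c(40, 40, 30)).
#' @param nBackground unstructured background genes (default 90).
#' @param downModules indices of modules planted as developmentally
#'   downregulated (default 1:2).
#' @param timepoints ordered time labels (default 4 developmental
#'   stages).
#' @param repsPerTime replicates per time point (default 3).
#' @param downFold linear-scale early/late decay of down modules
#'   (default 4).
#' @param moduleEffectSd sd of the shared module-sample effect
#'   (default 0.5); centred within time groups so the planted fold
#'   change is exact at the module level.
#' @param profileSd sd of the module-specific random time profile over
#'   interior time points (default 1.5); drives intra-module
#'   correlation while keeping modules mutually decorrelated.
#' @param noiseSd per-gene residual sd (default 0.3).
#' @param baseMean log2 expression of the late state (default 5).
#' @return \code{SummarizedExperiment} with
#'   \code{metadata()$truth} holding the planted module labels.
#' @export
simExpression <- function(seed = 1L, moduleSizes = c(40L, 40L, 30L),
                          nBackground = 90L, downModules = 1:2,
                          timepoints = c("E15", "E18", "P1", "P3",
                                         "P7", "P14"),
                          repsPerTime = 2L, downFold = 4,
                          moduleEffectSd = 0.5, profileSd = 1.5,
                          noiseSd = 0.3, baseMean = 5) {
  nMod <- length(moduleSizes)
  nGenes <- sum(moduleSizes) + nBackground
  if (any(moduleSizes < 1)) stop("module sizes must be positive")
  withSeed(seed, {
    time <- rep(timepoints, each = repsPerTime)
    nS <- length(time)
    tIdx <- match(time, timepoints)
    genes <- sprintf("gene%04d", seq_len(nGenes))
    truth <- c(rep(paste0("M", seq_len(nMod)), moduleSizes),
               rep("0", nBackground))
    x <- matrix(0, nGenes, nS,
                dimnames = list(genes, sprintf("s%02d", seq_len(nS))))
    row <- 1L
    for (m in seq_len(nMod)) {
      sz <- moduleSizes[m]
      drop <- if (m %in% downModules) log2(downFold) else 0
      # linear decay from baseMean + drop (earliest) down to baseMean,
      # plus a module-specific profile over the interior time points;
      # profiles are mutually orthogonal (Helmert contrasts) so modules
      # decorrelate, and endpoints stay fixed so the planted fold is
      # exact
      nT <- length(timepoints)
      nI <- nT - 2L
      shapeI <- if (nI >= 1 && m <= max(nI - 1L, 1L) && nI >= 2) {
        h <- stats::contr.helmert(nI)[, min(m, nI - 1L)]
        h / sqrt(mean(h^2)) * profileSd
      } else stats::rnorm(nI, 0, profileSd)
      shape <- c(0, shapeI, 0)
      trend <- baseMean + drop * (1 - (tIdx - 1) / (nT - 1)) +
        shape[tIdx]
      eff <- stats::rnorm(nS, 0, moduleEffectSd)
      eff <- eff - stats::ave(eff, tIdx)   # keep the planted fold exact
      for (g in seq_len(sz)) {
        x[row, ] <- trend + eff + stats::rnorm(nS, 0, noiseSd) +
          stats::rnorm(1, 0, 0.2)
        row <- row + 1L
      }
    }
    if (nBackground > 0) {
      for (g in seq_len(nBackground)) {
        x[row, ] <- baseMean + stats::rnorm(nS, 0, 1)
        row <- row + 1L
      }
    }
    se <- expressionExperiment(x, time, levels = timepoints,
                               logScale = TRUE)
    S4Vectors::metadata(se)$truth <- stats::setNames(truth, genes)
    se
  })
}

consensusPFM <- function(name, consensus, strength = 91,
                         soft = 3, pseudocount = 0.25) {
  b <- strsplit(consensus, "")[[1]]
  cts <- matrix(soft, 4L, length(b), dimnames = list(BASES, NULL))
  cts[cbind(match(b, BASES), seq_along(b))] <- strength
  PFMModel(name, cts, pseudocount = pseudocount)
}

# Partner TFs named after the screen's hit TFs for readability; the
# motifs themselves are synthetic consensus models, not JASPAR entries.
defaultPartnerPlan <- function() {
  c(Nr5a2 = "both", Rarb = "both", Eomes = "promoter_only",
    Stat3 = "enhancer_only", Myc = "none", Jun = "none")
}

plantAt <- function(chars, pos0, motif) {
  m <- strsplit(motif, "")[[1]]
  chars[(pos0 + 1L):(pos0 + length(m))] <- m
  chars
}

#' Simulate a regulatory genome with planted anchor/partner motifs
#'
#' One synthetic chromosome of i.i.d. uniform background sequence with
#' growth genes whose promoters and enhancers carry planted anchor
#' motif instances; for each partner motif with a compartment plan
#' ("both", "promoter_only", "enhancer_only"), instances are planted
#' within \code{D} bp of anchors so the local rate is
#' \code{multiplier} x the motif's chance rate. \code{multiplier = 1}
#' plants nothing beyond chance occurrences (the null condition).
#' Decoy element positions at matched TSS distances (opposite side) are
#' emitted for the ABC fixtures.
#'
#' @param seed integer seed.
#' @param nGrowthGenes,nOtherGenes gene counts (defaults 20 / 10).
#' @param geneSpacing TSS spacing in bp (default 50000).
#' @param promoterUpstream,promoterDownstream promoter window
#'   (defaults 1500/300).
#' @param enhancersPerGene enhancers per growth gene (default 2).
#' @param enhancerWidth enhancer width in bp (default 500).
#' @param enhancerDistRange TSS distance range for enhancers in bp
#'   (default 10-60 kb).
#' @param anchorsPerRegion anchor instances planted per growth
#'   promoter/enhancer (default 2).
#' @param D anchored window half-width (default 100).
#' @param multiplier partner planting rate multiplier (default 10).
#' @param plan named character vector partner -> compartment plan
#'   (default [defaultPartnerPlan()]: 2 both, 1 promoter_only,
#'   1 enhancer_only, 2 none).
#' @param growthIds,otherIds optional gene ids to use for the growth /
#'   non-growth genes (to tie the genome to an expression fixture).
#' @return list(genome, geneTable, promoters, enhancers, decoys,
#'   anchor, partners, plan, params).
#' @export
simRegulatoryGenome <- function(seed = 1L, nGrowthGenes = 20L,
                                nOtherGenes = 10L, geneSpacing = 50000L,
                                promoterUpstream = 1500L,
                                promoterDownstream = 300L,
                                enhancersPerGene = 2L,
                                enhancerWidth = 500L,
                                enhancerDistRange = c(10000L, 45000L),
                                anchorsPerRegion = 2L, D = 100L,
                                multiplier = 10,
                                plan = defaultPartnerPlan(),
                                growthIds = NULL, otherIds = NULL) {
  stopifnot(multiplier >= 1)
  nGenes <- nGrowthGenes + nOtherGenes
  margin <- 60000L
  L <- 2L * margin + (nGenes - 1L) * geneSpacing
  anchor <- consensusPFM("Klf6", "AGGGGCGGGG", strength = 97, soft = 1)
  consPool <- c("TGACTC", "CCATTA", "GATAAG", "AACCGT", "CTGAGA",
                "TGCATA", "GTCCAA", "TCGGAT")
  if (length(plan) > length(consPool))
    stop("at most ", length(consPool), " partner motifs supported")
  cons <- stats::setNames(consPool[seq_along(plan)], names(plan))
  partners <- lapply(names(plan), function(p) consensusPFM(p, cons[[p]]))
  names(partners) <- names(plan)
  withSeed(seed, {
    chars <- sample(BASES, L, replace = TRUE)
    tss <- margin + (seq_len(nGenes) - 1L) * geneSpacing
    strand <- sample(c("+", "-"), nGenes, replace = TRUE)
    isGrowth <- c(rep(TRUE, nGrowthGenes), rep(FALSE, nOtherGenes))[
      sample.int(nGenes)]
    ids <- sprintf("gene%03d", seq_len(nGenes))
    if (!is.null(growthIds)) {
      stopifnot(length(growthIds) == nGrowthGenes,
                length(otherIds) == nOtherGenes)
      ids[isGrowth] <- growthIds
      ids[!isGrowth] <- otherIds
    }
    geneTable <- data.frame(
      id = ids, chrom = "chr1",
      tss = tss, strand = strand, is_growth = isGrowth,
      stringsAsFactors = FALSE)
    promS <- ifelse(strand == "+", tss - promoterUpstream,
                    tss - promoterDownstream + 1L)
    promE <- ifelse(strand == "+", tss + promoterDownstream,
                    tss + promoterUpstream + 1L)
    enh <- NULL
    dec <- NULL
    # elements must not invade any promoter window (or each other), so
    # anchors planted in enhancers cannot leak into promoter scans
    occupied <- IRanges(start = pmin(promS, promE),
                        end = pmax(promS, promE))
    free <- function(s, e) {
      hit <- IRanges::overlapsAny(IRanges(start = s + 1L, end = e),
                                  occupied)
      if (any(hit)) return(FALSE)
      occupied <<- c(occupied, IRanges(start = s + 1L, end = e))
      TRUE
    }
    for (i in which(isGrowth)) {
      placed <- 0L
      tries <- 0L
      while (placed < enhancersPerGene && tries < 200L) {
        tries <- tries + 1L
        dist <- sample(seq(enhancerDistRange[1], enhancerDistRange[2]),
                       1L)
        side <- sample(c(-1L, 1L), 1L)
        es <- tss[i] + side * dist - as.integer(enhancerWidth / 2)
        ds <- tss[i] - side * dist - as.integer(enhancerWidth / 2)
        if (es < 0 || ds < 0 || es + enhancerWidth > L ||
            ds + enhancerWidth > L) next
        if (!free(es, es + enhancerWidth)) next
        if (!free(ds, ds + enhancerWidth)) next
        enh <- rbind(enh, data.frame(gene = geneTable$id[i],
                                     start = es,
                                     end = es + enhancerWidth))
        dec <- rbind(dec, data.frame(gene = geneTable$id[i],
                                     start = ds,
                                     end = ds + enhancerWidth))
        placed <- placed + 1L
      }
      if (placed < enhancersPerGene)
        stop("could not place enhancers without promoter overlap; ",
             "increase geneSpacing or narrow enhancerDistRange")
    }
    # plant anchors + planned partners inside a region [s, e) (0-based)
    anchorW <- motifWidth(anchor)
    plantRegion <- function(chars, s, e, partnersHere) {
      width <- e - s
      reg <- chars[(s + 1L):e]
      planted <- IRanges()      # keep plantings from destroying each other
      takeIfFree <- function(p0, w) {
        iv <- IRanges(start = p0 + 1L, width = w)
        if (IRanges::overlapsAny(iv, planted)) return(FALSE)
        planted <<- c(planted, iv)
        TRUE
      }
      aPos <- integer()
      tries <- 0L
      while (length(aPos) < anchorsPerRegion && tries < 100L) {
        tries <- tries + 1L
        ap <- sample.int(width - anchorW - 2L * D, 1L) + D  # flanks inside
        if (takeIfFree(ap, anchorW)) aPos <- c(aPos, ap)
      }
      aPos <- sort(aPos)
      for (ap in aPos) reg <- plantAt(reg, ap,
                                      consensusSequence(anchor))
      if (multiplier > 1 && length(partnersHere)) {
        for (pn in partnersHere) {
          w <- motifWidth(partners[[pn]])
          chance <- 2 * 0.25^w              # both strands, uniform bg
          nPlant <- max(1L, round((multiplier - 1) * chance * 2 * D))
          for (ap in aPos) {
            for (k in seq_len(nPlant)) {
              tries <- 0L
              repeat {
                tries <- tries + 1L
                off <- sample(c(-sample(w:D, 1L),
                                sample(anchorW:(anchorW + D - w), 1L)),
                              1L)
                if (takeIfFree(ap + off, w) || tries >= 50L) break
              }
              if (tries < 50L)
                reg <- plantAt(reg, ap + off,
                               consensusSequence(partners[[pn]]))
            }
          }
        }
      }
      chars[(s + 1L):e] <- reg
      chars
    }
    promPartners <- names(plan)[plan %in% c("both", "promoter_only")]
    enhPartners <- names(plan)[plan %in% c("both", "enhancer_only")]
    for (i in which(isGrowth))
      chars <- plantRegion(chars, promS[i], promE[i], promPartners)
    if (!is.null(enh))
      for (r in seq_len(nrow(enh)))
        chars <- plantRegion(chars, enh$start[r], enh$end[r],
                             enhPartners)
    genome <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
    names(genome) <- "chr1"
    enhGR <- GRanges("chr1", IRanges(start = enh$start + 1L,
                                     end = enh$end))
    names(enhGR) <- sprintf("%s_e%d", enh$gene,
                            stats::ave(seq_len(nrow(enh)), enh$gene,
                                       FUN = seq_along))
    mcols(enhGR)$gene <- enh$gene
    decGR <- GRanges("chr1", IRanges(start = dec$start + 1L,
                                     end = dec$end))
    names(decGR) <- sprintf("%s_d%d", dec$gene,
                            stats::ave(seq_len(nrow(dec)), dec$gene,
                                       FUN = seq_along))
    mcols(decGR)$gene <- dec$gene
    proms <- makePromoters(geneTable, genome,
                           upstream = promoterUpstream,
                           downstream = promoterDownstream)
    list(genome = genome, geneTable = geneTable,
         promoters = proms$regions, promoterSeqs = proms$seqs,
         enhancers = enhGR, decoys = decGR, anchor = anchor,
         partners = partners, plan = plan,
         params = list(D = D, multiplier = multiplier,
                       genomeLength = L,
                       promoterUpstream = promoterUpstream,
                       promoterDownstream = promoterDownstream))
  })
}

#' Simulate coverage tracks and Hi-C contacts for the ABC stage
#'
#' Accessibility and acetylation coverage peaks are placed at
#' promoters, planted enhancers and decoy elements (Poisson peak
#' heights over a low background); Hi-C bin-pair counts follow the
#' distance power law \eqn{d^{-\gamma}} with a \code{loopBoost}-fold
#' boost at true enhancer-gene bin pairs. \code{loopBoost = 1} makes
#' planted pairs indistinguishable from decoys.
#'
#' @param genomeFixture output of [simRegulatoryGenome()].
#' @param seed integer seed.
#' @param resolution Hi-C bin size (default 5000).
#' @param gamma power-law exponent (default 0.87).
#' @param loopBoost contact boost at true pairs (default 10).
#' @param baseContact expected count at zero distance (default 100).
#' @param peakValue mean per-bp coverage at element peaks (default 50).
#' @param backgroundValue per-bp background coverage (default 0.05).
#' @return list(atac, h3k27ac (\code{GRanges} tracks),
#'   hic ([HiCContacts-class]), elements (candidate element
#'   data.frame), truePairs).
#' @export
simTracksAndHiC <- function(genomeFixture, seed = 1L, resolution = 5000,
                            gamma = 0.87, loopBoost = 10,
                            baseContact = 100, peakValue = 50,
                            backgroundValue = 0.05) {
  gf <- genomeFixture
  gt <- gf$geneTable
  L <- gf$params$genomeLength
  withSeed(seed, {
    regions <- data.frame(
      name = c(gt$id, names(gf$enhancers), names(gf$decoys)),
      chrom = "chr1",
      gene = c(gt$id, mcols(gf$enhancers)$gene, mcols(gf$decoys)$gene),
      start = c(start(gf$promoters)[match(gt$id, names(gf$promoters))] - 1L,
                start(gf$enhancers) - 1L, start(gf$decoys) - 1L),
      end = c(end(gf$promoters)[match(gt$id, names(gf$promoters))],
              end(gf$enhancers), end(gf$decoys)),
      is_promoter = c(rep(TRUE, nrow(gt)),
                      rep(FALSE, length(gf$enhancers) +
                            length(gf$decoys))),
      stringsAsFactors = FALSE)
    mkTrack <- function() {
      v <- stats::rpois(nrow(regions), peakValue * 10) / 10
      peaks <- GRanges("chr1", IRanges(start = regions$start + 1L,
                                       end = regions$end))
      mcols(peaks)$value <- v
      cov <- GenomicRanges::coverage(peaks, weight = "value",
                                     width = L)
      gr <- GRanges(cov)
      mcols(gr)$score <- mcols(gr)$score + backgroundValue
      names(mcols(gr)) <- "score"
      sort(gr)
    }
    atac <- mkTrack()
    h3k <- mkTrack()
    # Hi-C: entries for every gene TSS x candidate element midpoint
    growth <- gt$id[gt$is_growth]
    tssBin <- floor(gt$tss / resolution)
    midBin <- floor(((regions$start + regions$end) / 2) / resolution)
    truePairs <- data.frame(gene = mcols(gf$enhancers)$gene,
                            element = names(gf$enhancers),
                            stringsAsFactors = FALSE)
    ent <- NULL
    for (i in seq_len(nrow(gt))) {
      for (r in seq_len(nrow(regions))) {
        bi <- tssBin[i]
        bj <- midBin[r]
        d <- abs(bi - bj) * resolution
        lam <- baseContact * powerLaw(d, resolution, gamma)
        isTrue <- regions$gene[r] == gt$id[i] && !regions$is_promoter[r] &&
          regions$name[r] %in% truePairs$element
        if (isTrue) lam <- lam * loopBoost
        ent <- rbind(ent, data.frame(chrom = "chr1", bin_i = bi,
                                     bin_j = bj,
                                     count = stats::rpois(1L, lam)))
      }
    }
    hic <- HiCContacts(ent, resolution = resolution, gamma = gamma)
    list(atac = atac, h3k27ac = h3k, hic = hic, elements = regions,
         truePairs = truePairs)
  })
}

#' Simulate TF target sets with a planted core and a held-out anchor
#'
#' Core TFs share a large common target pool (plus mutual edges), so
#' they and the shared targets dominate the degree ranking; peripheral
#' TFs get small disjoint target sets. A held-out anchor-like TF is
#' absent from the target sets but linked to many core targets in the
#' interaction list, so one-level expansion pulls it into the network
#' and it lands in the core.
#'
#' @param seed integer seed.
#' @param coreTFs names of the planted core TFs (default Nr5a2, Rarb,
#'   Eomes).
#' @param anchor held-out anchor TF name (default Klf6).
#' @param nPeripheral peripheral (non-core) hit TFs (default 9, for 12
#'   hit TFs in total).
#' @param poolSize shared core target pool size (default 40).
#' @param coreTargetsEach targets per core TF from the pool (default
#'   36).
#' @param peripheralTargets targets per peripheral TF (default 3).
#' @param anchorLinks interaction links from the anchor into the core
#'   pool (default 25).
#' @return list(sets, interactions, coreTFs, anchor).
#' @export
simTFTargetSets <- function(seed = 1L,
                            coreTFs = c("Nr5a2", "Rarb", "Eomes"),
                            anchor = "Klf6", nPeripheral = 9L,
                            poolSize = 40L, coreTargetsEach = 36L,
                            peripheralTargets = 3L, anchorLinks = 25L) {
  stopifnot(coreTargetsEach <= poolSize, anchorLinks <= poolSize)
  withSeed(seed, {
    pool <- sprintf("Tgt%03d", seq_len(poolSize))
    sets <- list()
    for (tf in coreTFs)
      sets[[tf]] <- c(sample(pool, coreTargetsEach),
                      setdiff(coreTFs, tf))
    periph <- sprintf("pTF%02d", seq_len(nPeripheral))
    for (k in seq_along(periph))
      sets[[periph[k]]] <- sprintf("pTgt%02d_%d", k,
                                   seq_len(peripheralTargets))
    ia <- data.frame(node_a = anchor,
                     node_b = sample(pool, anchorLinks),
                     evidence = "chip", stringsAsFactors = FALSE)
    # decoy externals with a single link each (must not be added)
    decoys <- data.frame(node_a = sprintf("ext%02d", 1:3),
                         node_b = sample(pool, 3),
                         evidence = "chip", stringsAsFactors = FALSE)
    list(sets = sets, interactions = rbind(ia, decoys),
         coreTFs = coreTFs, anchor = anchor)
  })
}
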