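oneHot <- function(consensus, count = 8) {
  b <- strsplit(consensus, "")[[1]]
  cts <- matrix(0, 4, length(b),
                dimnames = list(c("A", "C", "G", "T"), NULL))
  cts[cbind(match(b, c("A", "C", "G", "T")), seq_along(b))] <- count
  cts
}

test_that("JASPAR text parses, reorders rows, and rejects bad records", {
  txt <- c(">MA0001.1 TOY",
           "A [ 8 0 0 0 ]", "C [ 0 8 0 0 ]",
           "G [ 0 0 8 0 ]", "T [ 0 0 0 8 ]")
  m <- readJaspar(text = txt)
  expect_length(m, 1)
  expect_equal(motifWidth(m$TOY), 4)
  expect_equal(consensusSequence(m$TOY), "ACGT")
  # rows out of order, honoured by label
  txt2 <- c(">x x", "C [ 0 8 0 0 ]", "A [ 8 0 0 0 ]",
            "T [ 0 0 0 8 ]", "G [ 0 0 8 0 ]")
  expect_equal(m$TOY@counts, readJaspar(text = txt2)$x@counts)
  # multi-record
  multi <- readJaspar(text = c(txt, txt2))
  expect_length(multi, 2)
  expect_error(readJaspar(text = c(">bad b", "A [ 1 2 ]", "C [ 1 ]",
                                   "G [ 1 2 ]", "T [ 1 2 ]")),
               "ragged")
  expect_error(readJaspar(text = c(">bad b", "A [ 1 -2 ]", "C [ 1 2 ]",
                                   "G [ 1 2 ]", "T [ 1 2 ]")),
               "negative")
  # round trip through the writer
  tmp <- tempfile(fileext = ".jaspar")
  writeJaspar(m, tmp)
  expect_equal(readJaspar(tmp)$TOY@counts, m$TOY@counts)
})

test_that("information content matches direct evaluation", {
  unif <- PFMModel("u", matrix(2, 4, 5,
                               dimnames = list(c("A", "C", "G", "T"),
                                               NULL)),
                   pseudocount = 0)
  expect_equal(informationContent(unif), 0)
  hot <- PFMModel("h", oneHot("ACGT"), pseudocount = 0)
  expect_equal(informationContent(hot), 8)
  onecol <- PFMModel("o", oneHot("A")[, 1, drop = FALSE] |>
                       (\(x) cbind(x, x, x, x))(), pseudocount = 0.25)
  # one column (8,0,0,0), pseudocount 0.25 -> 1.454 bits per column
  p <- c(8.25, .25, .25, .25) / 9
  percol <- 2 + sum(p * log2(p))
  expect_equal(informationContent(onecol), 4 * percol)
  expect_equal(percol, 1.454, tolerance = 1e-3)
})

test_that("scanning finds consensus on both strands with rel score 1", {
  pfm <- PFMModel("p", oneHot("TGACTC"))
  s <- paste0(strrep("A", 30), "TGACTC", strrep("C", 30))
  h <- scanSequence(s, pfm, 0.9)
  expect_equal(nrow(h), 1)
  expect_equal(h$start, 30)
  expect_equal(h$strand, "+")
  expect_equal(h$rel_score, 1)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  h2 <- scanSequence(rc, pfm, 0.9)
  expect_equal(h2$strand, "-")
  expect_equal(h2$rel_score, 1)
  expect_equal(nrow(scanSequence("ACG", pfm, 0.9)), 0)  # shorter than w
  # windows containing N are skipped
  hN <- scanSequence(paste0("TGANTC"), pfm, 0.5)
  expect_equal(nrow(hN), 0)
})

test_that("scanner equals exhaustive per-window rescoring", {
  set.seed(41)
  for (r in 1:8) {
    pfm <- randomPFM(width = sample(5:10, 1))
    s <- randomDNA(300)
    for (thr in c(0.8, 0.9)) {
      got <- scanSequence(s, pfm, thr)
      exp <- bruteScan(s, pfm, thr)
      rownames(got) <- rownames(exp) <- NULL
      expect_equal(got, exp, tolerance = 1e-9)
    }
  }
})

test_that("anchored windows are flank unions minus footprints, clipped", {
  ah <- data.frame(seq_id = "s1", start = 100, width = 10)
  w <- anchoredWindows(ah, c(s1 = 500), D = 100)
  expect_equal(searchableLength(w), 200)
  ir <- w@windows$s1
  expect_equal(IRanges::start(ir), c(1, 111))   # [0,100) u [110,210)
  expect_equal(IRanges::end(ir), c(100, 210))
  # anchor at sequence start: left flank clipped
  w0 <- anchoredWindows(data.frame(seq_id = "s1", start = 0, width = 10),
                        c(s1 = 500), D = 100)
  expect_equal(searchableLength(w0), 100)
  # overlapping flanks counted once: per-base oracle
  ah2 <- data.frame(seq_id = c("s1", "s1"), start = c(100, 160),
                    width = 10)
  w2 <- anchoredWindows(ah2, c(s1 = 500), D = 100)
  covered <- logical(500)
  for (a in c(100, 160)) {
    lo <- max(0, a - 100); hi <- min(500, a + 10 + 100)
    covered[(lo + 1):hi] <- TRUE
  }
  for (a in c(100, 160)) covered[(a + 1):(a + 10)] <- FALSE
  expect_equal(searchableLength(w2), sum(covered))
  # no anchors at all
  w3 <- anchoredWindows(data.frame(seq_id = character(),
                                   start = integer(), width = integer()),
                        c(s1 = 500), D = 100)
  expect_true(isTRUE(attr(w3, "anchor_absent")))
  expect_equal(searchableLength(w3), 0)
})

test_that("anchored hit counting respects windows and footprints", {
  ah <- data.frame(seq_id = "s1", start = 100, width = 10)
  w <- anchoredWindows(ah, c(s1 = 500), D = 100)
  hit <- function(st) data.frame(seq_id = "s1", start = st, width = 6,
                                 strand = "+", score = 1, rel_score = 1)
  expect_equal(anchoredHitCount(hit(150), w), 1L)
  expect_equal(anchoredHitCount(hit(300), w), 0L)
  # overlapping the anchor footprint: excluded
  expect_equal(anchoredHitCount(hit(105), w), 0L)
  # brute-force membership oracle at random positions: footprint
  # [st, st+6) must overlap a window and miss the anchor [100, 110)
  set.seed(55)
  sts <- sample(0:494, 100, replace = TRUE)
  got <- anchoredHitCount(do.call(rbind, lapply(sts, hit)), w)
  inWin <- (sts < 100) | (sts + 6 > 110 & sts < 210)
  onAnchor <- (sts + 6 > 100) & (sts < 110)
  expect_equal(got, sum(inWin & !onAnchor))
})

test_that("the Z statistic follows the binomial formula and edge rules", {
  expect_equal(enrichmentZ(50, 5000, 100, 10000), 0)  # equal rates
  expect_equal(enrichmentZ(200, 10000, 100, 10000), 100 / sqrt(99),
               tolerance = 1e-9)
  expect_equal(100 / sqrt(99), 10.0504, tolerance = 1e-4)
  z1 <- enrichmentZ(30, 1000, 100, 10000)
  z2 <- enrichmentZ(60, 2000, 200, 20000)
  expect_equal(z2 / z1, sqrt(2), tolerance = 1e-9)
  zInf <- enrichmentZ(5, 1000, 0, 10000)
  expect_equal(as.numeric(zInf), Inf)
  expect_true(isTRUE(attr(zInf, "degenerate")))
  expect_equal(enrichmentZ(0, 1000, 0, 10000), 0)
})

test_that("Fisher enrichment matches the hypergeometric tail", {
  expect_equal(fisherEnrichment(10, 0, 0, 10), 1 / choose(20, 10),
               tolerance = 1e-12)
  # direct tail sum oracle for a balanced table
  p <- fisherEnrichment(5, 5, 5, 5)
  tail <- sum(dhyper(5:10, 10, 10, 10))
  expect_equal(p, tail, tolerance = 1e-12)
  expect_equal(fisherEnrichment(0, 10, 5, 5), 1)  # empty foreground
  expect_equal(fisherEnrichment(0, 0, 0, 0), 1)   # all-zero table
})

test_that("TF categorisation applies the strict Z threshold per compartment", {
  pr <- data.frame(tf = c("a", "b", "c", "d"),
                   z = c(12, 12, 9.9, 3))
  en <- data.frame(tf = c("a", "b", "c", "e"),
                   z = c(15, 3, 9.9, 11))
  out <- categorizeTFs(pr, en, zThreshold = 10)
  got <- setNames(out$category, out$tf)
  expect_identical(got[["a"]], "both")
  expect_identical(got[["b"]], "promoter_only")
  expect_identical(got[["c"]], "none")      # 9.9 strict
  expect_identical(got[["d"]], "none")
  expect_identical(got[["e"]], "enhancer_only")
  expect_true(out$flagged[out$tf == "d"])   # missing from enhancers
  # exact ties at the threshold are included
  tie <- categorizeTFs(data.frame(tf = "t", z = 10),
                       data.frame(tf = "t", z = 10))
  expect_identical(tie$category, "both")
})

test_that("hit counts and Z are invariant to reverse-complementing inputs", {
  gf <- simRegulatoryGenome(seed = 9, nGrowthGenes = 6, nOtherGenes = 2,
                            geneSpacing = 8000)
  growth <- gf$geneTable$id[gf$geneTable$is_growth]
  seqs <- gf$promoterSeqs[growth]
  rcs <- Biostrings::reverseComplement(seqs)
  names(rcs) <- names(seqs)
  bg <- Biostrings::DNAStringSet(vapply(as.character(seqs), dinucShuffle,
                                        character(1)))
  e1 <- anchoredEnrichment(seqs, gf$anchor, gf$partners,
                           background = bg)
  e2 <- anchoredEnrichment(rcs, gf$anchor, gf$partners,
                           background = bg)
  expect_equal(e1$fg_hits, e2$fg_hits)
  expect_equal(e1$fg_nt, e2$fg_nt)
  expect_equal(e1$z, e2$z, tolerance = 1e-9)
})

test_that("promoter windows are strand-aware and clipped", {
  genome <- Biostrings::DNAStringSet(c(chr1 = randomDNA(20000)))
  gt <- data.frame(id = c("plus", "minus", "edge"), chrom = "chr1",
                   tss = c(10000, 10000, 100), strand = c("+", "-", "+"))
  pr <- makePromoters(gt, genome, upstream = 1500, downstream = 300)
  expect_equal(GenomicRanges::start(pr$regions["plus"]), 8501)  # [8500,10300)
  expect_equal(GenomicRanges::end(pr$regions["plus"]), 10300)
  expect_equal(GenomicRanges::start(pr$regions["minus"]), 9701)  # [9700,11500)
  expect_equal(GenomicRanges::end(pr$regions["minus"]), 11500)
  expect_equal(GenomicRanges::start(pr$regions["edge"]), 1)      # clipped
  minusSeq <- pr$seqs[["minus"]]
  raw <- Biostrings::subseq(genome[["chr1"]], 9701, 11500)
  expect_equal(as.character(minusSeq),
               as.character(Biostrings::reverseComplement(raw)))
  # off-contig genes skipped with a warning
  gt2 <- rbind(gt, data.frame(id = "lost", chrom = "chrX", tss = 5,
                              strand = "+"))
  expect_warning(pr2 <- makePromoters(gt2, genome), "lost")
  expect_false("lost" %in% names(pr2$seqs))
})

test_that("conservation masks restrict scanning to conserved windows", {
  pfm <- PFMModel("p", oneHot("TGACTC"))
  s <- paste0(strrep("A", 20), "TGACTC", strrep("A", 20), "TGACTC",
              strrep("A", 20))
  mask <- rep(1, nchar(s))
  mask[21:26] <- 0.1                     # first instance unconserved
  h <- scanSequence(s, pfm, 0.9, mask = mask, maskCutoff = 0.40)
  expect_equal(h$start, 46)
})
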