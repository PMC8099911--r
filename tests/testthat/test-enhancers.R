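library(GenomicRanges)

mkTrack <- function(starts, ends, values, chrom = "chr1") {
  gr <- GRanges(chrom, IRanges(start = starts + 1L, end = ends))
  mcols(gr)$score <- values
  sort(gr)
}

test_that("signal counting is value x overlap, per-base exact", {
  tr <- mkTrack(0, 1000, 2)
  reg <- GRanges("chr1", IRanges(101, 200))   # fully inside, length 100
  expect_equal(countSignal(reg, tr), 200)
  expect_equal(countSignal(GRanges("chr1", IRanges(2001, 2100)), tr), 0)
  # straddling two intervals: per-base expansion oracle
  tr2 <- mkTrack(c(0, 100), c(100, 250), c(1.5, 3))
  reg2 <- GRanges("chr1", IRanges(51, 180))
  perBase <- sum(rep(c(1.5, 3), c(100, 150))[51:180])
  expect_equal(countSignal(reg2, tr2), perBase)
})

test_that("strongest-window selection is deterministic and matches enumeration", {
  # triangular peak: apex at 500
  vals <- c(1:10, 9:1)
  tr <- mkTrack(seq(0, 1800, by = 100), seq(100, 1900, by = 100), vals)
  top <- selectStrongestRegions(tr, n = 1, width = 500)
  expect_length(top, 1)
  apex <- 950
  expect_true(start(top) <= apex && end(top) >= apex)
  # two equal peaks -> smaller coordinate wins
  tr2 <- mkTrack(c(1000, 5000), c(1500, 5500), c(7, 7))
  top2 <- selectStrongestRegions(tr2, n = 1, width = 500)
  expect_lte(end(top2), 2000)
  # flat-zero track
  expect_warning(z <- selectStrongestRegions(mkTrack(0, 100, 0), 3),
                 "flat")
  expect_length(z, 0)
  # brute-force enumeration oracle on a random track
  set.seed(21)
  tr3 <- mkTrack(seq(0, 9900, by = 100), seq(100, 10000, by = 100),
                 round(runif(100, 0, 10), 2))
  got <- selectStrongestRegions(tr3, n = 5, width = 500)
  # oracle: enumerate the same window grid, same greedy rule
  starts <- seq(min(start(tr3)) - 1L, max(end(tr3)) - 1L, by = 250)
  wins <- GRanges("chr1", IRanges(starts + 1L, width = 500))
  sc <- countSignal(wins, tr3)
  kept <- integer()
  ord <- order(-sc, start(wins))
  for (i in ord) {
    if (sc[i] <= 0) break
    if (length(kept) &&
        any(start(wins[i]) <= end(wins[kept]) &
            end(wins[i]) >= start(wins[kept]))) next
    kept <- c(kept, i)
  }
  mrg <- reduce(wins[kept], min.gapwidth = 1L)
  best <- sapply(seq_along(mrg), function(k)
    max(sc[kept][subjectHits(findOverlaps(mrg[k], wins[kept]))]))
  expGR <- mrg[head(order(-best, start(mrg)), 5)]
  expect_equal(sort(start(got)), sort(start(expGR)))
  expect_equal(sort(end(got)), sort(end(expGR)))
})

test_that("element activity is the geometric mean with guardrails", {
  expect_equal(elementActivity(100, 400), 200)
  expect_equal(elementActivity(0, 123), 0)
  expect_equal(elementActivity(7, 11), sqrt(77), tolerance = 1e-9)
  expect_error(elementActivity(-1, 5), "nonnegative")
})

test_that("power-law contact values follow the distance decay", {
  hic <- HiCContacts(resolution = 5000, gamma = 1)
  expect_equal(contactValue(hic, "chr1", 0, 4000), 1)        # d <= res
  expect_equal(contactValue(hic, "chr1", 0, 50000), 0.1)     # gamma 1
  hic2 <- HiCContacts(resolution = 5000, gamma = 0.87)
  expect_equal(contactValue(hic2, "chr1", 0, 50000), 10^-0.87,
               tolerance = 1e-9)
})

test_that("observed contacts are rescaled onto the power-law curve", {
  # two pairs at the same binned distance, counts 10 and 30
  ent <- data.frame(chrom = "chr1", bin_i = c(0, 5), bin_j = c(4, 9),
                    count = c(10, 30))
  hic <- HiCContacts(ent, resolution = 5000, gamma = 0.87,
                     pseudocount = 0)
  pl <- (5000 / 20000)^0.87
  # mean count at d = 20 kb is 20 -> s = pl / 20
  expect_equal(contactValue(hic, "chr1", 2500, 22500), 10 * pl / 20)
  expect_equal(contactValue(hic, "chr1", 27500, 47500), 30 * pl / 20)
  expect_warning(v <- contactValue(hic, "chr2", 0, 5000), "chromosome")
  expect_equal(v, 0)
})

mkElements <- function(acts, starts = NULL, width = 500) {
  n <- length(acts)
  if (is.null(starts)) starts <- seq(20000, by = 20000, length.out = n)
  data.frame(chrom = "chr1", start = starts, end = starts + width,
             activity = acts, is_promoter = FALSE)
}

test_that("ABC scores normalise per gene and follow activity ratios", {
  hic <- HiCContacts(resolution = 5000, gamma = 0)  # flat contact = 1
  gene <- list(id = "g", chrom = "chr1", tss = 10000)
  one <- abcScores(gene, mkElements(5), hic)
  expect_equal(one$score, 1)
  expect_true(one$retained)
  two <- abcScores(gene, mkElements(c(3, 3)), hic)
  expect_equal(two$score, c(0.5, 0.5))
  three <- abcScores(gene, mkElements(c(1, 2, 7)), hic)
  expect_equal(three$score, c(0.1, 0.2, 0.7))
  expect_true(all(three$retained))
  expect_equal(sum(three$score), 1, tolerance = 1e-9)
  # promoter elements stay in the denominator but are not reported pairs
  els <- mkElements(c(5, 5))
  els$is_promoter[1] <- TRUE
  pr <- abcScores(gene, els, hic)
  expect_equal(sum(pr$score), 1)
  expect_identical(pr$retained, c(FALSE, TRUE))
  # zero activity everywhere -> no pairs, warning
  expect_warning(none <- abcScores(gene, mkElements(c(0, 0)), hic),
                 "no pairs")
  expect_equal(nrow(none), 0)
})

test_that("raising one element's activity raises its score and lowers the rest", {
  hic <- HiCContacts(resolution = 5000, gamma = 0.87)
  gene <- list(id = "g", chrom = "chr1", tss = 10000)
  base <- abcScores(gene, mkElements(c(4, 4, 4)), hic)
  up <- abcScores(gene, mkElements(c(8, 4, 4)), hic)
  expect_gt(up$score[1], base$score[1])
  expect_true(all(up$score[2:3] <= base$score[2:3]))
  expect_equal(sum(up$score), 1, tolerance = 1e-9)
})

test_that("pair summaries tally counts and the distance band", {
  pairs <- data.frame(gene = "g1",
                      distance_to_tss = c(5e3, 5e4, 2e6),
                      retained = TRUE)
  ps <- pairSummary(pairs)
  expect_equal(as.integer(ps$per_gene), 3L)
  expect_equal(ps$band_fraction, 1 / 3)
  all100 <- data.frame(gene = c("a", "a", "b"),
                       distance_to_tss = rep(1e5, 3), retained = TRUE)
  expect_equal(pairSummary(all100)$band_fraction, 1)
  # counting oracle on a random pair set
  set.seed(31)
  rp <- data.frame(gene = sample(letters[1:4], 60, TRUE),
                   distance_to_tss = 10^runif(60, 3, 6.5),
                   retained = sample(c(TRUE, FALSE), 60, TRUE,
                                     prob = c(.8, .2)))
  ps2 <- pairSummary(rp)
  keep <- rp[rp$retained, ]
  expect_equal(ps2$band_fraction,
               sum(keep$distance_to_tss >= 1e4 &
                     keep$distance_to_tss <= 1.5e6) / nrow(keep))
  expect_equal(ps2$mean, mean(table(keep$gene)[table(keep$gene) > 0]))
})
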