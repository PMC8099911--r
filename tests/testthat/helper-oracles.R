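# Independent brute-force oracles; kept deliberately naive so they stay
# independent of the implementation paths they check.

bruteTOM <- function(a) {
  n <- nrow(a)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { out[i, j] <- 1; next }
    s <- 0
    for (u in seq_len(n)) if (u != i && u != j) s <- s + a[i, u] * a[u, j]
    ki <- sum(a[i, -i])
    kj <- sum(a[j, -j])
    out[i, j] <- (s + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  out
}

randomAdjacency <- function(n) {
  a <- matrix(stats::runif(n * n), n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  a
}

# exhaustive per-window PWM rescoring on both strands
bruteScan <- function(seq, pfm, relThreshold) {
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(toupper(seq), "")[[1]]
  lo <- logOddsMatrix(pfm)
  w <- ncol(lo)
  smin <- sum(apply(lo, 2, min))
  smax <- sum(apply(lo, 2, max))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rows <- list()
  if (length(chars) >= w) {
    for (st in 0:(length(chars) - w)) {
      win <- chars[(st + 1):(st + w)]
      if (any(!win %in% bases)) next
      for (strand in c("+", "-")) {
        ww <- if (strand == "+") win else rev(unname(comp[win]))
        sc <- sum(lo[cbind(match(ww, bases), seq_len(w))])
        rel <- if (is.finite(smax - smin) && smax > smin)
          (sc - smin) / (smax - smin) else as.numeric(is.finite(sc))
        if (!is.na(rel) && rel >= relThreshold)
          rows[[length(rows) + 1]] <-
            data.frame(start = st, width = w, strand = strand,
                       score = sc, rel_score = rel,
                       stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(), width = integer(),
                      strand = character(), score = numeric(),
                      rel_score = numeric()))
  out <- do.call(rbind, rows)
  out[order(out$start, out$strand), , drop = FALSE]
}

randomPFM <- function(name = "rnd", width = sample(5:12, 1)) {
  cts <- matrix(stats::rpois(4 * width, 5) + stats::runif(4 * width),
                4, width, dimnames = list(c("A", "C", "G", "T"), NULL))
  PFMModel(name, cts)
}

randomDNA <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# adjusted Rand index for recovery checks (mclust is the oracle)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

extractRegionSeqs <- function(genome, gr) {
  out <- Biostrings::DNAStringSet(vapply(seq_along(gr), function(i)
    as.character(Biostrings::subseq(
      genome[[as.character(GenomicRanges::seqnames(gr)[i])]],
      GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i])),
    character(1)))
  names(out) <- names(gr)
  out
}
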