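mkSE <- function(x, time = rep(c("early", "late"), each = ncol(x) / 2),
                 levels = NULL) {
  if (is.null(rownames(x))) rownames(x) <- paste0("g", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("s", seq_len(ncol(x)))
  expressionExperiment(x, time, levels = levels)
}

test_that("preprocessing is the identity on clean data", {
  set.seed(1)
  x <- matrix(rnorm(10 * 6, 5), 10, 6)
  se <- mkSE(x)
  out <- preprocessExpression(se)
  expect_equal(SummarizedExperiment::assay(out, "exprs"),
               SummarizedExperiment::assay(se, "exprs"))
  expect_length(S4Vectors::metadata(out)$preprocess$dropped_genes, 0)
})

test_that("genes over the missingness threshold are dropped, the rest imputed", {
  set.seed(2)
  x <- matrix(rnorm(5 * 6, 5), 5, 6)
  x[1, 1:3] <- NA              # 50% missing
  x[2, 1] <- NA                # 17% missing -> imputed
  se <- mkSE(x)
  out <- preprocessExpression(se)
  expect_false("g1" %in% rownames(out))
  expect_equal(SummarizedExperiment::assay(out)["g2", 1],
               mean(x[2, -1]))
  expect_identical(S4Vectors::metadata(out)$preprocess$dropped_genes,
                   "g1")
})

test_that("a strongly shifted sample is flagged as a clustering outlier", {
  # with only a handful of samples the single outlier inflates the sd
  # of merge heights enough to hide itself; 12 samples is the regime
  # the mean + 2 sd rule is meant for
  set.seed(3)
  x <- matrix(rnorm(10 * 12, 5, 1), 10, 12)
  colnames(x) <- paste0("s", 1:12)
  x[, 12] <- x[, 12] + 10
  se <- mkSE(x, time = rep(c("early", "late"), 6))
  out <- preprocessExpression(se)
  expect_identical(S4Vectors::metadata(out)$preprocess$dropped_samples,
                   "s12")
  # brute-force recomputation of first-merge heights
  hc <- hclust(dist(t(x)), method = "average")
  firstMerge <- sapply(seq_len(ncol(x)), function(s) {
    for (i in seq_len(nrow(hc$merge)))
      if (-s %in% hc$merge[i, ]) return(hc$height[i])
  })
  bar <- mean(hc$height) + 2 * sd(hc$height)
  expect_identical(colnames(x)[firstMerge > bar], "s12")
  expect_identical(S4Vectors::metadata(out)$preprocess$dropped_samples,
                   colnames(x)[firstMerge > bar])
})

test_that("soft-power adjacency follows the unsigned |cor|^beta convention", {
  # two anticorrelated genes, cor exactly -1 -> adjacency 1
  x <- rbind(g1 = c(1, 2, 3, 4), g2 = c(4, 3, 2, 1),
             g3 = c(1, 3, 2, 4))
  a <- computeAdjacency(x, softPower = 10)
  expect_equal(a["g1", "g2"], 1)
  expect_equal(diag(a), c(g1 = 1, g2 = 1, g3 = 1))
  c13 <- cor(x["g1", ], x["g3", ])
  expect_equal(a["g1", "g3"], abs(c13)^10)
  x2 <- rbind(x, flat = c(2, 2, 2, 2))
  a2 <- computeAdjacency(x2, softPower = 10)
  expect_equal(unname(a2["flat", c("g1", "g2", "g3")]), rep(0, 3))
  expect_identical(attr(a2, "zero_variance"), "flat")
})

test_that("TOM matches its definition on degenerate and random matrices", {
  ones <- matrix(1, 3, 3)
  expect_equal(computeTOM(ones), ones)
  eye <- diag(3)
  expect_equal(computeTOM(eye), eye)
  set.seed(4)
  for (r in 1:5) {
    a <- randomAdjacency(5)
    expect_equal(computeTOM(a), bruteTOM(a), tolerance = 1e-12)
  }
  bad <- matrix(runif(9), 3)
  expect_error(computeTOM(bad), "symmetric")
})

test_that("module detection obeys the size rule and recovers planted blocks", {
  # all genes mutually identical -> one module
  x <- matrix(rnorm(8), 40, 8, byrow = TRUE)
  rownames(x) <- paste0("g", 1:40)
  tom <- computeTOM(computeAdjacency(x, 10))
  mods <- detectModules(tom, selectionConfig(minModuleSize = 30))
  expect_setequal(unique(mods$module), "M1")
  # fewer genes than the minimum size -> all unassigned
  tom10 <- computeTOM(randomAdjacency(10))
  expect_warning(m10 <- detectModules(tom10,
                                      selectionConfig(minModuleSize = 30)),
                 "unassigned")
  expect_setequal(unique(m10$module), "0")
  # planted two-block fixture
  se <- simExpression(seed = 11, moduleSizes = c(40L, 40L),
                      nBackground = 0L, downModules = 1)
  mods2 <- detectModules(computeTOM(computeAdjacency(se)))
  truth <- S4Vectors::metadata(se)$truth
  expect_equal(length(setdiff(unique(mods2$module), "0")), 2L)
  expect_gte(ari(truth[mods2$gene], mods2$module), 0.9)
})

test_that("module fold change equals independent summation", {
  x <- rbind(g1 = c(8, 8, 2, 2), g2 = c(10, 6, 3, 1))
  se <- mkSE(log2(x))             # stored on log2 scale
  fc <- moduleFoldChange(c("g1", "g2"), se, "early", "late")
  expect_equal(fc, mean(x[, 1:2]) / mean(x[, 3:4]))
  # early mean 8, late mean 2 -> 4
  seA <- mkSE(log2(rbind(g1 = c(8, 8, 2, 2))))
  expect_equal(moduleFoldChange("g1", seA), 4)
  seB <- mkSE(log2(rbind(g1 = c(3, 3, 3, 3))))
  expect_equal(moduleFoldChange("g1", seB), 1)
})

test_that("time-course DE calls separated genes and respects error modes", {
  x <- rbind(const = rep(5, 6),
             sep = c(8, 8.01, 7.99, 2, 2.01, 1.99))
  se <- mkSE(x, time = rep(c("early", "late"), each = 3))
  de <- timecourseDE(se)
  expect_equal(de$p[de$gene == "const"], 1)
  expect_identical(de$direction[de$gene == "const"], "ns")
  expect_lt(de$p[de$gene == "sep"], 1e-6)
  expect_identical(de$direction[de$gene == "sep"], "down")
  se1 <- mkSE(x[, c(1, 4), drop = FALSE],
              time = c("early", "late"))
  expect_error(timecourseDE(se1), "fold-change-only")
})

test_that("type-I error of the F test is nominal on a null matrix", {
  set.seed(99)
  x <- matrix(rnorm(5000 * 6, 5), 5000, 6)
  se <- mkSE(x, time = rep(c("early", "late"), each = 3))
  de <- timecourseDE(se)
  expect_lt(abs(mean(de$p < 0.05) - 0.05), 0.01)
})

test_that("gene-set intersection normalises identifiers", {
  expect_setequal(intersectDown(c("a", "b", "c"), c("b", "c", "d")),
                  c("b", "c"))
  expect_warning(out <- intersectDown(c("a"), c("b")), "empty")
  expect_length(out, 0)
  expect_identical(intersectDown("Sox11", "SOX11"), "Sox11")
  expect_identical(intersectDown("Sox11", "Srxn1",
                                 synonyms = c(Srxn1 = "Sox11")),
                   "Sox11")
})

test_that("hypergeometric term enrichment matches enumeration and BH identities", {
  universe <- paste0("u", 1:20)
  term <- universe[1:5]
  ann <- list(hit = term)
  res <- goEnrichSelect(universe[1:5], ann, universe,
                        whitelist = "hit")
  expect_equal(res$terms$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$terms$q, res$terms$p)       # single term: q = p
  expect_setequal(res$selected, term)
  resD <- goEnrichSelect(universe[6:10], ann, universe,
                         whitelist = "hit")
  expect_equal(resD$terms$p, 1)
  expect_error(goEnrichSelect(universe[1:5], ann, universe,
                              whitelist = character(0)),
               "whitelist")
})

test_that("BH q-values are monotone in p-rank and bounded below by p", {
  set.seed(7)
  p <- runif(50)^2
  q <- p.adjust(p, "BH")
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-15))
  expect_true(all(q >= p - 1e-15))
})

test_that("module assignment is deterministic for identical inputs", {
  se <- simExpression(seed = 5)
  m1 <- detectModules(computeTOM(computeAdjacency(se)))
  m2 <- detectModules(computeTOM(computeAdjacency(se)))
  expect_identical(m1, m2)
})
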