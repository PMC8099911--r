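#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Build an expression experiment with ordered time labels
#'
#' Wraps a genes x samples matrix in a \code{SummarizedExperiment} with
#' an ordered \code{time} factor in \code{colData} and a
#' \code{log_scale} flag in \code{metadata}.
#'
#' @param values numeric genes x samples matrix, rownames = gene ids,
#'   colnames = sample ids; missing entries allowed.
#' @param time per-sample ordinal label (character or factor); order of
#'   levels taken from \code{levels} if given, else first appearance.
#' @param levels optional explicit level order, earliest first.
#' @param logScale are values already on a log scale? (default TRUE)
#' @return a \code{SummarizedExperiment} with assay \code{exprs}.
#' @export
expressionExperiment <- function(values, time, levels = NULL,
                                 logScale = TRUE) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    stop("values must have gene ids as rownames")
  if (anyDuplicated(rownames(values)))
    stop("duplicated gene ids")
  if (length(time) != ncol(values))
    stop("one time label per sample required")
  if (is.null(levels)) levels <- unique(as.character(time))
  if (length(levels) < 2L)
    stop("sample_time must cover >= 2 distinct ordered levels")
  se <- SummarizedExperiment(
    assays = list(exprs = values),
    colData = DataFrame(time = factor(as.character(time),
                                      levels = levels, ordered = TRUE),
                        row.names = colnames(values)))
  metadata(se)$log_scale <- isTRUE(logScale)
  se
}

#' Selection configuration for module detection and DE
#'
#' @param softPower soft-thresholding power for the adjacency (default
#'   10).
#' @param minModuleSize minimum genes per module; smaller clusters go to
#'   the unassigned pool (default 30).
#' @param cutHeightFrac dendrogram cut height as a fraction of the
#'   maximum merge height (default 0.99).
#' @param maxMissingFrac genes missing in more than this fraction of
#'   samples are dropped (default 0.2).
#' @param downregFold early/late fold-change bar for calling a module or
#'   gene developmentally downregulated (default 2).
#' @param alpha nominal p-value cutoff (default 0.05).
#' @param fdr BH q-value cutoff (default 0.05).
#' @export
selectionConfig <- function(softPower = 10L, minModuleSize = 30L,
                            cutHeightFrac = 0.99, maxMissingFrac = 0.2,
                            downregFold = 2, alpha = 0.05, fdr = 0.05) {
  stopifnot(softPower >= 1, minModuleSize >= 1,
            cutHeightFrac > 0, cutHeightFrac <= 1,
            maxMissingFrac >= 0, maxMissingFrac <= 1,
            downregFold > 0, alpha > 0, alpha <= 1, fdr > 0, fdr <= 1)
  list(softPower = as.integer(softPower),
       minModuleSize = as.integer(minModuleSize),
       cutHeightFrac = cutHeightFrac, maxMissingFrac = maxMissingFrac,
       downregFold = downregFold, alpha = alpha, fdr = fdr)
}

# height at which each leaf first merges in an hclust tree
leafMergeHeights <- function(hc) {
  n <- length(hc$labels)
  h <- numeric(n)
  for (i in seq_len(nrow(hc$merge))) {
    for (m in hc$merge[i, ]) {
      if (m < 0) h[-m] <- hc$height[i]
    }
  }
  stats::setNames(h, hc$labels)
}

#' Pre-process an expression experiment
#'
#' Drops genes whose missing fraction exceeds
#' \code{cfg$maxMissingFrac}, imputes remaining missing entries with the
#' gene mean, and removes outlier samples: samples whose first merge
#' height in an average-linkage clustering of samples exceeds
#' mean + 2 sd of all merge heights. A removal report is attached in
#' \code{metadata(se)$preprocess}.
#'
#' @param se expression experiment from [expressionExperiment()].
#' @param cfg a [selectionConfig()].
#' @return filtered/imputed \code{SummarizedExperiment}.
#' @export
preprocessExpression <- function(se, cfg = selectionConfig()) {
  x <- assay(se, "exprs")
  if (ncol(x) < 3L) stop("need >= 3 samples")
  if (nrow(x) < 2L) stop("need >= 2 genes")
  missFrac <- rowMeans(is.na(x))
  dropGenes <- rownames(x)[missFrac > cfg$maxMissingFrac]
  keep <- setdiff(rownames(x), dropGenes)
  if (!length(keep)) stop("all genes removed by the missingness filter")
  x <- x[keep, , drop = FALSE]
  if (anyNA(x)) {
    gm <- rowMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- gm[idx[, 1L]]
  }
  dropSamples <- character()
  if (ncol(x) >= 3L) {
    hc <- stats::hclust(stats::dist(t(x)), method = "average")
    mh <- leafMergeHeights(hc)
    bar <- mean(hc$height) + 2 * stats::sd(hc$height)
    dropSamples <- names(mh)[mh > bar]
  }
  keepS <- setdiff(colnames(x), dropSamples)
  if (length(keepS) < 2L)
    stop("fewer than 2 samples remain after outlier removal")
  out <- se[keep, keepS]
  SummarizedExperiment::assay(out, "exprs") <- x[, keepS, drop = FALSE]
  metadata(out)$preprocess <- list(dropped_genes = dropGenes,
                                   dropped_samples = dropSamples)
  out
}

#' Soft-power (unsigned) co-expression adjacency
#'
#' \eqn{a_{ij} = |cor(x_i, x_j)|^{\beta}} from pairwise Pearson
#' correlation of gene profiles; diagonal set to 1. Zero-variance genes
#' get adjacency 0 to all others (flagged via attribute
#' \code{zero_variance}).
#'
#' @param se expression experiment (no missing values) or plain matrix.
#' @param softPower the power \eqn{\beta} (default 10).
#' @return symmetric genes x genes matrix in [0, 1].
#' @export
computeAdjacency <- function(se, softPower = 10L) {
  x <- if (is(se, "SummarizedExperiment")) assay(se, "exprs") else as.matrix(se)
  if (anyNA(x)) stop("missing values present; run preprocessExpression first")
  if (ncol(x) < 3L) stop("need >= 3 samples")
  sds <- apply(x, 1L, stats::sd)
  flat <- sds == 0
  co <- suppressWarnings(stats::cor(t(x)))
  co[is.na(co)] <- 0
  a <- abs(co)^softPower
  diag(a) <- 1
  attr(a, "zero_variance") <- rownames(x)[flat]
  a
}

#' Topological overlap matrix
#'
#' \eqn{TOM_{ij} = (\sum_{u \ne i,j} a_{iu} a_{uj} + a_{ij}) /
#' (\min(k_i, k_j) + 1 - a_{ij})} with \eqn{k_i = \sum_{u \ne i} a_{iu}};
#' unit diagonal. Network-smoothed similarity used for module detection.
#'
#' @param adjacency symmetric matrix in [0, 1] with unit diagonal.
#' @return symmetric TOM with values in [0, 1].
#' @export
computeTOM <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (nrow(a) != ncol(a)) stop("adjacency must be square")
  if (max(abs(a - t(a))) > 1e-10) stop("adjacency must be symmetric")
  if (any(a < -1e-12) || any(a > 1 + 1e-12))
    stop("adjacency values must lie in [0, 1]")
  a0 <- a
  diag(a0) <- 0
  k <- colSums(a0)
  shared <- a0 %*% a0                       # Sum_{u != i,j} a_iu a_uj
  num <- shared + a0
  den <- outer(k, k, pmin) + 1 - a0
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect co-expression modules by tree cut of TOM dissimilarity
#'
#' Average-linkage clustering of \eqn{1 - TOM}, cut at
#' \code{cutHeightFrac} of the maximum merge height; clusters smaller
#' than \code{minModuleSize} are pooled as unassigned (module "0").
#' Modules are labelled "M1", "M2", ... by decreasing size (ties broken
#' by smallest member id), so the assignment is deterministic.
#'
#' @param tom matrix from [computeTOM()].
#' @param cfg a [selectionConfig()].
#' @return data.frame (gene, module) with attribute \code{sizes}.
#' @export
detectModules <- function(tom, cfg = selectionConfig()) {
  genes <- rownames(tom)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(tom)))
  if (nrow(tom) < cfg$minModuleSize) {
    warning("fewer genes than minModuleSize; all genes unassigned")
    out <- data.frame(gene = genes, module = "0",
                      stringsAsFactors = FALSE)
    attr(out, "sizes") <- c("0" = nrow(tom))
    return(out)
  }
  d <- stats::as.dist(1 - tom)
  hc <- stats::hclust(d, method = "average")
  cutH <- cfg$cutHeightFrac * max(hc$height)
  cl <- stats::cutree(hc, h = cutH)
  sizes <- table(cl)
  small <- names(sizes)[sizes < cfg$minModuleSize]
  lab <- as.character(cl)
  lab[lab %in% small] <- "0"
  kept <- setdiff(unique(lab), "0")
  if (length(kept)) {
    ord <- order(-as.integer(table(lab)[kept]),
                 vapply(kept, function(k) min(genes[lab == k]), ""))
    newLab <- stats::setNames(paste0("M", seq_along(kept)), kept[ord])
    lab[lab != "0"] <- newLab[lab[lab != "0"]]
  }
  out <- data.frame(gene = genes, module = lab, stringsAsFactors = FALSE)
  attr(out, "sizes") <- table(lab)
  out
}

#' Early/late fold change of a gene module
#'
#' Mean expression of the module genes in the early samples divided by
#' the mean in the late samples, on the linear scale (log-scale data are
#' unlogged first); > 1 means downregulated with maturation.
#'
#' @param genes character vector of module member genes.
#' @param se expression experiment.
#' @param earlyLabel,lateLabel time levels to contrast (defaults: first
#'   and last level).
#' @return fold change (single number).
#' @export
moduleFoldChange <- function(genes, se, earlyLabel = NULL,
                             lateLabel = NULL) {
  tm <- colData(se)$time
  if (is.null(earlyLabel)) earlyLabel <- levels(tm)[1L]
  if (is.null(lateLabel)) lateLabel <- levels(tm)[nlevels(tm)]
  if (!earlyLabel %in% tm || !lateLabel %in% tm)
    stop("early/late labels must be present in sample_time")
  x <- assay(se, "exprs")[intersect(genes, rownames(se)), , drop = FALSE]
  if (!nrow(x)) stop("none of the module genes are in the experiment")
  if (isTRUE(metadata(se)$log_scale)) x <- 2^x
  early <- mean(x[, tm == earlyLabel, drop = FALSE])
  late <- mean(x[, tm == lateLabel, drop = FALSE])
  if (late <= 0) stop("late mean <= 0 on the linear scale; ratio undefined")
  early / late
}

#' Per-gene time-course differential expression
#'
#' One-way F test (equal-variance \code{oneway.test}) across time groups
#' on log-scale values, Benjamini-Hochberg correction over all genes,
#' and a "down" call when q < fdr, p < alpha and the early/late fold
#' change reaches \code{downregFold}.
#'
#' @param se expression experiment with >= 2 time groups and >= 2
#'   replicates per group.
#' @param cfg a [selectionConfig()].
#' @param earlyLabel,lateLabel levels used for the fold change
#'   (defaults: first/last).
#' @return data.frame (gene, p, q, fold_change, direction).
#' @export
timecourseDE <- function(se, cfg = selectionConfig(), earlyLabel = NULL,
                         lateLabel = NULL) {
  tm <- colData(se)$time
  if (nlevels(droplevels(tm)) < 2L) stop("need >= 2 time groups")
  if (any(table(tm)[table(tm) > 0] < 2L))
    stop("single replicate in a group; use the fold-change-only path ",
         "(moduleFoldChange) instead")
  x <- assay(se, "exprs")
  if (!isTRUE(metadata(se)$log_scale)) x <- log2(x + 1)
  grp <- droplevels(tm)
  p <- apply(x, 1L, function(y) {
    if (stats::sd(y) == 0) return(1)
    ft <- try(stats::oneway.test(y ~ grp, var.equal = TRUE),
              silent = TRUE)
    if (inherits(ft, "try-error") || is.na(ft$p.value)) 1 else ft$p.value
  })
  q <- stats::p.adjust(p, method = "BH")
  if (is.null(earlyLabel)) earlyLabel <- levels(tm)[1L]
  if (is.null(lateLabel)) lateLabel <- levels(tm)[nlevels(tm)]
  lin <- 2^x
  fc <- rowMeans(lin[, tm == earlyLabel, drop = FALSE]) /
    rowMeans(lin[, tm == lateLabel, drop = FALSE])
  down <- q < cfg$fdr & p < cfg$alpha & fc >= cfg$downregFold
  data.frame(gene = rownames(x), p = p, q = q, fold_change = fc,
             direction = ifelse(down, "down", "ns"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Intersect two gene sets under identifier normalisation
#'
#' Case-folds identifiers (and applies an optional synonym map, e.g.
#' for cross-species symbols) before the exact set intersection.
#' Returned ids keep the casing of \code{setA}.
#'
#' @param setA,setB character vectors.
#' @param synonyms optional named character vector mapping alternate ids
#'   to canonical ids (applied case-insensitively to both sets).
#' @return character vector of common genes; empty with a warning when
#'   the sets are disjoint.
#' @export
intersectDown <- function(setA, setB, synonyms = NULL) {
  norm <- function(v) {
    lv <- tolower(v)
    if (!is.null(synonyms)) {
      m <- match(lv, tolower(names(synonyms)))
      lv[!is.na(m)] <- tolower(synonyms)[m[!is.na(m)]]
    }
    lv
  }
  a <- norm(setA)
  common <- setA[a %in% norm(setB)]
  common <- common[!duplicated(norm(common))]
  if (!length(common)) warning("gene-set intersection is empty")
  common
}

#' GO-style hypergeometric enrichment and whitelist gating
#'
#' For each annotation term, the upper-tail hypergeometric p for the
#' overlap between the query genes and the term members within the
#' universe; BH q across tested terms. The selected genes are the query
#' genes belonging to whitelisted terms with q < fdr — mirroring a
#' literature-review selection of growth-relevant terms, which is why an
#' empty whitelist is an error.
#'
#' @param genes query gene set (subset of universe).
#' @param annotation named list term -> member genes (e.g. [readGMT()]).
#' @param universe background gene set.
#' @param whitelist term names to gate selection on (mandatory).
#' @param cfg a [selectionConfig()] (uses \code{fdr}).
#' @return list(selected = genes, terms = data.frame(term, size,
#'   overlap, p, q, whitelisted)).
#' @export
goEnrichSelect <- function(genes, annotation, universe, whitelist,
                           cfg = selectionConfig()) {
  if (missing(whitelist) || !length(whitelist))
    stop("a non-empty term whitelist is required (user selection of ",
         "growth-relevant terms is a mandatory step)")
  genes <- intersect(genes, universe)
  N <- length(universe)
  res <- lapply(names(annotation), function(tn) {
    members <- intersect(annotation[[tn]], universe)
    k <- length(intersect(genes, members))
    p <- stats::phyper(k - 1L, length(members), N - length(members),
                       length(genes), lower.tail = FALSE)
    data.frame(term = tn, size = length(members), overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  tab$q <- stats::p.adjust(tab$p, method = "BH")
  tab$whitelisted <- tab$term %in% whitelist
  hitTerms <- tab$term[tab$whitelisted & tab$q < cfg$fdr]
  selected <- sort(unique(unlist(lapply(hitTerms, function(tn)
    intersect(genes, annotation[[tn]])))))
  list(selected = selected, terms = tab[order(tab$p), , drop = FALSE])
}
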