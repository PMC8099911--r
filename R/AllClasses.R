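#' @import methods
NULL

#' Position frequency matrix model
#'
#' Container for a transcription-factor binding motif as a position
#' frequency matrix (PFM) with the pseudocount and background used to
#' derive probability and log-odds forms.
#'
#' @slot tfName character(1), motif / TF label.
#' @slot counts 4 x w nonnegative matrix, rows \code{A,C,G,T}.
#' @slot pseudocount per-base pseudocount added when forming column
#'   probabilities (default 0.25).
#' @slot background base composition, length-4 probability vector
#'   summing to 1 (default uniform).
#'
#' @seealso [PFMModel()], [informationContent()], [scanSequence()]
#' @export
setClass("PFMModel",
  representation(
    tfName = "character",
    counts = "matrix",
    pseudocount = "numeric",
    background = "numeric"
  )
)

setValidity("PFMModel", function(object) {
  msgs <- character()
  cts <- object@counts
  if (!is.numeric(cts) || nrow(cts) != 4L)
    msgs <- c(msgs, "counts must be a numeric 4 x w matrix")
  if (is.numeric(cts) && nrow(cts) == 4L) {
    if (!identical(rownames(cts), c("A", "C", "G", "T")))
      msgs <- c(msgs, "counts rows must be named A, C, G, T in that order")
    if (ncol(cts) < 4L)
      msgs <- c(msgs, "motif width must be >= 4")
    if (any(cts < 0))
      msgs <- c(msgs, "counts must be nonnegative")
    if (ncol(cts) >= 1L && any(colSums(cts) <= 0))
      msgs <- c(msgs, "every column needs at least one positive count")
  }
  if (length(object@tfName) != 1L || is.na(object@tfName))
    msgs <- c(msgs, "tfName must be a single string")
  if (length(object@pseudocount) != 1L || object@pseudocount < 0)
    msgs <- c(msgs, "pseudocount must be a single nonnegative number")
  if (length(object@background) != 4L || any(object@background < 0) ||
      abs(sum(object@background) - 1) > 1e-6)
    msgs <- c(msgs, "background must be 4 probabilities summing to 1")
  if (length(msgs)) msgs else TRUE
})

#' Construct a PFMModel
#'
#' @param tfName motif label.
#' @param counts 4 x w nonnegative matrix; rows are taken in the order
#'   A, C, G, T (rownames, if present, are used to reorder).
#' @param pseudocount per-base pseudocount (default 0.25).
#' @param background length-4 background composition (default uniform).
#' @return A [PFMModel-class] object.
#' @examples
#' m <- PFMModel("toy", matrix(c(8, 0, 0, 0), 4, 4,
#'   dimnames = list(c("A", "C", "G", "T"), NULL)))
#' motifWidth(m)
#' @export
PFMModel <- function(tfName, counts, pseudocount = 0.25,
                     background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  if (!is.null(rownames(counts))) {
    rn <- toupper(rownames(counts))
    if (!setequal(rn, c("A", "C", "G", "T")))
      stop("counts rownames must be a permutation of A, C, G, T")
    counts <- counts[match(c("A", "C", "G", "T"), rn), , drop = FALSE]
  }
  rownames(counts) <- c("A", "C", "G", "T")
  new("PFMModel", tfName = as.character(tfName), counts = counts,
      pseudocount = pseudocount, background = background)
}

setMethod("show", "PFMModel", function(object) {
  cat("PFMModel", object@tfName, "\n")
  cat("  width:", ncol(object@counts),
      " IC:", round(informationContent(object), 2), "bits\n")
  cat("  consensus:", consensusSequence(object), "\n")
})

#' Sparse Hi-C contact set at fixed resolution
#'
#' Bin-pair contact counts plus the power-law parameters used to fall
#' back to (and rescale toward) the expected distance decay
#' \eqn{(res / max(d, res))^{\gamma}}. An object with zero entries acts
#' in pure power-law mode.
#'
#' @slot resolution bin size in bp.
#' @slot entries data.frame with columns chrom, bin_i, bin_j, count.
#' @slot gamma power-law exponent (default 0.87).
#' @slot pseudocount added to counts on lookup (default 0.3).
#' @seealso [HiCContacts()], [contactValue()]
#' @export
setClass("HiCContacts",
  representation(
    resolution = "numeric",
    entries = "data.frame",
    gamma = "numeric",
    pseudocount = "numeric"
  )
)

setValidity("HiCContacts", function(object) {
  msgs <- character()
  if (length(object@resolution) != 1L || object@resolution <= 0)
    msgs <- c(msgs, "resolution must be a single positive number")
  need <- c("chrom", "bin_i", "bin_j", "count")
  if (!all(need %in% names(object@entries)))
    msgs <- c(msgs, paste("entries needs columns",
                          paste(need, collapse = ", ")))
  else if (nrow(object@entries) && any(object@entries$count < 0))
    msgs <- c(msgs, "contact counts must be >= 0")
  if (object@gamma < 0) msgs <- c(msgs, "gamma must be nonnegative")
  if (object@pseudocount < 0) msgs <- c(msgs, "pseudocount must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct a HiCContacts object
#'
#' @param entries data.frame (chrom, bin_i, bin_j, count); may be empty
#'   for pure power-law mode.
#' @param resolution bin size in bp (default 5000, the resolution used
#'   for ABC scoring).
#' @param gamma distance-decay exponent (default 0.87).
#' @param pseudocount added to looked-up counts (default 0.3).
#' @return A [HiCContacts-class] object. Entries are stored with
#'   \code{bin_i <= bin_j} so lookup is symmetric.
#' @export
HiCContacts <- function(entries = data.frame(chrom = character(),
                                             bin_i = integer(),
                                             bin_j = integer(),
                                             count = numeric()),
                        resolution = 5000, gamma = 0.87,
                        pseudocount = 0.3) {
  entries <- as.data.frame(entries)
  if (nrow(entries)) {
    lo <- pmin(entries$bin_i, entries$bin_j)
    hi <- pmax(entries$bin_i, entries$bin_j)
    entries$bin_i <- lo
    entries$bin_j <- hi
    # collapse duplicate symmetric records
    key <- paste(entries$chrom, lo, hi)
    if (anyDuplicated(key)) {
      agg <- rowsum(entries$count, key)
      first <- !duplicated(key)
      entries <- entries[first, , drop = FALSE]
      entries$count <- agg[match(paste(entries$chrom, entries$bin_i,
                                       entries$bin_j), rownames(agg)), 1L]
    }
  }
  new("HiCContacts", resolution = resolution, entries = entries,
      gamma = gamma, pseudocount = pseudocount)
}

setMethod("show", "HiCContacts", function(object) {
  cat("HiCContacts:", nrow(object@entries), "bin pairs at",
      object@resolution, "bp resolution\n")
  cat("  gamma:", object@gamma, " pseudocount:", object@pseudocount,
      if (nrow(object@entries) == 0) " (power-law-only mode)" else "", "\n")
})

#' TF-target network with core/shell annotation
#'
#' Undirected graph over transcription factors and their target genes.
#' Vertices carry \code{isSeed} (member of an input TF target set),
#' \code{addedByExpansion}, and after [rankShells()] a \code{shell}
#' number (1 = core).
#'
#' @slot graph an \pkg{igraph} undirected simple graph.
#' @slot seeds character vector of seed TF names.
#' @seealso [mergeNetworks()], [expandNetwork()], [rankShells()],
#'   [networkNodeTable()]
#' @export
setClass("TFNetwork",
  representation(graph = "ANY", seeds = "character")
)

setValidity("TFNetwork", function(object) {
  if (!igraph::is_igraph(object@graph))
    return("graph slot must be an igraph object")
  if (igraph::is_directed(object@graph))
    return("graph must be undirected")
  TRUE
})

setMethod("show", "TFNetwork", function(object) {
  g <- object@graph
  sh <- igraph::vertex_attr(g, "shell")
  cat("TFNetwork:", igraph::vcount(g), "nodes,", igraph::ecount(g),
      "edges;", length(object@seeds), "seed TFs\n")
  if (!is.null(sh) && any(!is.na(sh))) {
    core <- sort(igraph::V(g)$name[!is.na(sh) & sh == 1L])
    cat("  shells:", max(sh, na.rm = TRUE), "; core (shell 1):",
        paste(utils::head(core, 8), collapse = ", "),
        if (length(core) > 8) "..." else "", "\n")
  }
})

#' Anchored scan windows around anchor motif hits
#'
#' Per sequence, the union of \eqn{\pm D} flanks around each anchor
#' motif hit, minus the anchor footprints themselves, clipped to the
#' sequence. Partner motif hits are counted inside these windows.
#'
#' @slot windows named list of \linkS4class{IRanges} (1-based, one per
#'   sequence) holding the searchable intervals.
#' @slot anchors named list of \linkS4class{IRanges} anchor footprints.
#' @slot seqLengths named integer vector of sequence lengths.
#' @seealso [anchoredWindows()], [anchoredHitCount()],
#'   [searchableLength()]
#' @export
setClass("AnchoredWindowSet",
  representation(
    windows = "list",
    anchors = "list",
    seqLengths = "integer"
  )
)

setMethod("show", "AnchoredWindowSet", function(object) {
  cat("AnchoredWindowSet over", length(object@seqLengths), "sequences;",
      sum(vapply(object@anchors, length, 1L)), "anchor hits;",
      "searchable nt:", searchableLength(object), "\n")
})
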