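#' Merge TF target-gene sets into one network
#'
#' Node set = TFs plus all targets; one undirected edge per TF-target
#' membership; duplicate edges collapsed, self-loops dropped. Mirrors
#' the merge of per-TF target lists retrieved from a regulatory
#' interaction compendium.
#'
#' @param sets named list TF -> character vector of target genes
#'   ([readGMT()] output works directly).
#' @return a [TFNetwork-class] with the input TFs as seeds.
#' @export
mergeNetworks <- function(sets) {
  if (!length(sets)) stop("at least one TF target set is required")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be named by TF")
  edges <- do.call(rbind, lapply(names(sets), function(tf) {
    tg <- setdiff(unique(as.character(sets[[tf]])), tf)
    if (!length(tg)) return(NULL)
    cbind(tf, tg)
  }))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  igraph::V(g)$isSeed <- igraph::V(g)$name %in% names(sets)
  igraph::V(g)$addedByExpansion <- FALSE
  new("TFNetwork", graph = g, seeds = names(sets))
}

#' One-level network expansion from an interaction list
#'
#' External nodes with at least \code{minLinks} interaction edges into
#' the current network are added (flagged \code{addedByExpansion})
#' together with those edges. Single pass: nodes brought in by this
#' step do not recruit further nodes.
#'
#' @param net a [TFNetwork-class].
#' @param interactions data.frame with two columns (node a, node b);
#'   extra columns (evidence) ignored for topology.
#' @param minLinks minimum links into the existing network (default 2).
#' @return expanded [TFNetwork-class].
#' @export
expandNetwork <- function(net, interactions, minLinks = 2L) {
  stopifnot(minLinks >= 1)
  g <- net@graph
  cur <- igraph::V(g)$name
  ia <- as.data.frame(interactions)[, 1:2]
  names(ia) <- c("a", "b")
  ia <- ia[ia$a != ia$b, , drop = FALSE]
  # orient so that 'ext' is the candidate outside node
  m1 <- ia[!(ia$a %in% cur) & ia$b %in% cur, c("a", "b")]
  m2 <- ia[!(ia$b %in% cur) & ia$a %in% cur, c("b", "a")]
  names(m1) <- names(m2) <- c("ext", "inside")
  cand <- unique(rbind(m1, m2))
  if (!nrow(cand)) return(net)
  nLinks <- table(cand$ext)
  add <- names(nLinks)[nLinks >= minLinks]
  if (!length(add)) return(net)
  g <- igraph::add_vertices(g, length(add), name = add,
                            isSeed = FALSE, addedByExpansion = TRUE)
  newEdges <- cand[cand$ext %in% add, , drop = FALSE]
  g <- igraph::add_edges(g, as.vector(t(as.matrix(newEdges))))
  g <- igraph::simplify(g)
  new("TFNetwork", graph = g, seeds = net@seeds)
}

#' Rank nodes into connectivity shells
#'
#' Sorts nodes by degree descending and partitions the ranking into
#' \code{nShells} equal-frequency bins; shell 1 is the
#' highest-connectivity core, higher shells are progressively more
#' peripheral. Nodes with equal degree always share a shell (the worst
#' provisional bin of their tie group), so a node enters the core only
#' by strictly out-ranking others — a star's hub is core, its leaves
#' never are. Occupied shells are renumbered contiguously from 1.
#'
#' @param net a [TFNetwork-class].
#' @param nShells number of shells (default 4: core + 3 shells).
#' @return the network with a \code{shell} vertex attribute set.
#' @export
rankShells <- function(net, nShells = 4L) {
  stopifnot(nShells >= 2)
  g <- net@graph
  n <- igraph::vcount(g)
  if (n < nShells) {
    warning("fewer nodes than shells; shells collapse")
    nShells <- max(1L, n)
  }
  deg <- igraph::degree(g)
  ord <- order(-deg, igraph::V(g)$name)
  prov <- integer(n)
  prov[ord] <- ceiling(seq_len(n) * nShells / n)
  worst <- tapply(prov, deg, max)             # tie groups share a bin
  shell <- as.integer(worst[as.character(deg)])
  shell <- match(shell, sort(unique(shell)))  # contiguous from 1
  igraph::V(g)$shell <- shell
  new("TFNetwork", graph = g, seeds = net@seeds)
}

#' Node table of a TFNetwork
#'
#' @param net a [TFNetwork-class] (shells present after
#'   [rankShells()]).
#' @return data.frame (node, degree, shell, is_seed_set_member,
#'   added_by_expansion) sorted by degree descending, name ascending.
#' @export
networkNodeTable <- function(net) {
  g <- net@graph
  sh <- igraph::vertex_attr(g, "shell")
  if (is.null(sh)) sh <- rep(NA_integer_, igraph::vcount(g))
  out <- data.frame(node = igraph::V(g)$name,
                    degree = as.integer(igraph::degree(g)),
                    shell = sh,
                    is_seed_set_member = igraph::V(g)$isSeed,
                    added_by_expansion = igraph::V(g)$addedByExpansion,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$degree, out$node), , drop = FALSE]
}

#' Is a query TF in the network core (shell 1)?
#' @param net a shell-ranked [TFNetwork-class].
#' @param tf node name.
#' @return TRUE/FALSE (FALSE when absent from the network).
#' @export
inCore <- function(net, tf) {
  tab <- networkNodeTable(net)
  tf %in% tab$node[!is.na(tab$shell) & tab$shell == 1L]
}

#' Per-subnetwork motif enrichment
#'
#' Runs the anchored co-occupancy enrichment separately for each
#' functional subnetwork batch (gene grouping), over that batch's
#' promoter sequences; batches with fewer than 3 genes holding
#' sequences are skipped with a warning. Returns the per-TF z ranking
#' per batch (a "top motifs per subnetwork" table).
#'
#' @param batches named list of gene-id vectors (one per subnetwork).
#' @param promoterSeqs named \code{DNAStringSet}, one per gene.
#' @param anchor anchor [PFMModel-class].
#' @param partners named list of candidate [PFMModel-class]s.
#' @param ... passed to [anchoredEnrichment()].
#' @return data.frame with a \code{subnetwork} column prepended.
#' @export
subnetworkMotifEnrichment <- function(batches, promoterSeqs, anchor,
                                      partners, ...) {
  res <- lapply(names(batches), function(bn) {
    genes <- intersect(batches[[bn]], names(promoterSeqs))
    if (length(genes) < 3L) {
      warning("subnetwork '", bn, "' has < 3 genes with promoters; ",
              "skipped")
      return(NULL)
    }
    enr <- anchoredEnrichment(promoterSeqs[genes], anchor, partners,
                              ...)
    cbind(data.frame(subnetwork = bn, stringsAsFactors = FALSE), enr)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- cbind(data.frame(subnetwork = character()),
                 data.frame(tf = character(), fg_hits = integer(),
                            fg_nt = numeric(), bg_hits = integer(),
                            bg_nt = numeric(), z = numeric(),
                            fisher_p = numeric()))
  rownames(out) <- NULL
  out
}
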