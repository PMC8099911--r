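pipelineDefaults <- function() {
  list(
    anchor_tf = "Klf6",
    out_dir = "anchorTF_out",
    seed = 1L,
    inputs = list(
      expression = NULL, expression_time = NULL, genome_fasta = NULL,
      gene_table = NULL, annotation_gmt = NULL, atac_bedgraph = NULL,
      h3k27ac_bedgraph = NULL, hic_tsv = NULL, motifs_jaspar = NULL,
      tf_target_gmt = NULL, interactions_tsv = NULL),
    go_whitelist = NULL,
    stages = list(geneselect = TRUE, network = TRUE),
    params = list(
      promoter_upstream = 1500, promoter_downstream = 300,
      D = 100, z_threshold = 10, rel_threshold = 0.9, min_ic = 8,
      abc_threshold = 0.01, abc_window = 5e6, hic_resolution = 5000,
      hic_gamma = 0.87, hic_pseudocount = 0.3, n_strongest = 150,
      peak_width = 500, n_shells = 4, min_links = 2, soft_power = 10,
      min_module_size = 30, cut_height_frac = 0.99, downreg_fold = 2,
      alpha = 0.05, fdr = 0.05, n_shuffles = 5)
  )
}

paramRanges <- function() {
  list(promoter_upstream = c(0, Inf), promoter_downstream = c(0, Inf),
       D = c(1, Inf), z_threshold = c(0, Inf),
       rel_threshold = c(1e-9, 1), min_ic = c(0, Inf),
       abc_threshold = c(0, 1), abc_window = c(1, Inf),
       hic_resolution = c(1, Inf), hic_gamma = c(1e-9, Inf),
       hic_pseudocount = c(0, Inf), n_strongest = c(1, Inf),
       peak_width = c(50, Inf), n_shells = c(2, Inf),
       min_links = c(1, Inf), soft_power = c(1, Inf),
       min_module_size = c(1, Inf), cut_height_frac = c(1e-9, 1),
       downreg_fold = c(0, Inf), alpha = c(0, 1), fdr = c(0, 1),
       n_shuffles = c(1, Inf))
}

#' Validate a pipeline configuration
#'
#' Reads a YAML config (or takes a list), reports all problems at once
#' (unknown keys, out-of-range parameters, missing referenced files),
#' injects defaults for everything unset and returns the canonical
#' config.
#'
#' @param config path to a YAML file, or a config list.
#' @param checkFiles verify referenced input files exist (default
#'   TRUE).
#' @return canonical config list; errors (all listed) on any problem.
#' @export
validateConfig <- function(config, checkFiles = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a file path or a list")
  def <- pipelineDefaults()
  errs <- character()
  unknownTop <- setdiff(names(config), names(def))
  if (length(unknownTop))
    errs <- c(errs, paste("unknown config keys:",
                          paste(unknownTop, collapse = ", ")))
  for (sec in c("inputs", "params", "stages")) {
    if (!is.null(config[[sec]])) {
      unk <- setdiff(names(config[[sec]]), names(def[[sec]]))
      if (length(unk))
        errs <- c(errs, paste0("unknown ", sec, " keys: ",
                               paste(unk, collapse = ", ")))
    }
  }
  cfg <- def
  for (k in intersect(names(config), names(def))) {
    if (k %in% c("inputs", "params", "stages")) {
      for (kk in intersect(names(config[[k]]), names(def[[k]])))
        cfg[[k]][[kk]] <- config[[k]][[kk]]
    } else cfg[[k]] <- config[[k]]
  }
  rng <- paramRanges()
  for (k in names(rng)) {
    v <- cfg$params[[k]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) ||
        v < rng[[k]][1] || v > rng[[k]][2])
      errs <- c(errs, sprintf("params.%s = %s out of range [%g, %g]",
                              k, format(v), rng[[k]][1], rng[[k]][2]))
  }
  if (checkFiles) {
    for (k in names(cfg$inputs)) {
      p <- cfg$inputs[[k]]
      if (!is.null(p) && !file.exists(p))
        errs <- c(errs, sprintf("inputs.%s: file not found: %s", k, p))
    }
  }
  if (length(errs))
    stop("invalid configuration:\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  cfg
}

canonicalConfigJson <- function(cfg) {
  srt <- function(x) if (is.list(x)) lapply(x[order(names(x))], srt)
                     else x
  jsonlite::toJSON(srt(cfg), auto_unbox = TRUE, null = "null",
                   digits = NA)
}

stageFail <- function(outDir, stage, err) {
  writeLines(paste("FAILED at stage:", stage, "-",
                   conditionMessage(err)),
             file.path(outDir, "FAILED"))
  stop("pipeline failed at stage '", stage, "': ",
       conditionMessage(err), call. = FALSE)
}

#' Run the anchored co-occupancy discovery pipeline
#'
#' Executes gene selection (co-expression modules, fold-change and GO
#' gating), promoter assembly, ABC enhancer-gene pairing, anchored
#' motif co-occupancy enrichment over both compartments with
#' categorisation, and (optionally) TF-network core ranking. Writes
#' plain-text TSV outputs plus a machine-readable run manifest into
#' \code{cfg$out_dir}.
#'
#' @param config path to a YAML config or a config list (validated via
#'   [validateConfig()]).
#' @return (invisibly) a list with the selected genes, ABC pairs,
#'   candidate TF table, network node table and manifest path.
#' @export
runDiscovery <- function(config) {
  cfg <- validateConfig(config)
  p <- cfg$params
  outDir <- cfg$out_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(outDir, "FAILED"))
  selCfg <- selectionConfig(
    softPower = p$soft_power, minModuleSize = p$min_module_size,
    cutHeightFrac = p$cut_height_frac, downregFold = p$downreg_fold,
    alpha = p$alpha, fdr = p$fdr)

  ## stage: gene selection -------------------------------------------
  geneTable <- tryCatch(readGeneTable(cfg$inputs$gene_table),
                        error = function(e)
                          stageFail(outDir, "inputs", e))
  selected <- geneTable$id
  modTab <- NULL
  termTab <- NULL
  if (isTRUE(cfg$stages$geneselect) &&
      !is.null(cfg$inputs$expression)) {
    gs <- tryCatch({
      se <- readExpressionMatrix(cfg$inputs$expression,
                                 cfg$inputs$expression_time)
      se <- preprocessExpression(se, selCfg)
      adj <- computeAdjacency(se, selCfg$softPower)
      tom <- computeTOM(adj)
      mods <- detectModules(tom, selCfg)
      fcs <- vapply(setdiff(unique(mods$module), "0"), function(m)
        moduleFoldChange(mods$gene[mods$module == m], se),
        numeric(1))
      downMods <- names(fcs)[fcs >= p$downreg_fold]
      mt <- data.frame(
        gene = mods$gene, module = mods$module,
        fold_change = unname(fcs[mods$module]),
        stringsAsFactors = FALSE)
      writeTSV(mt, file.path(outDir, "modules.tsv"))
      genes <- mods$gene[mods$module %in% downMods]
      tt <- NULL
      if (!is.null(cfg$inputs$annotation_gmt) &&
          length(cfg$go_whitelist)) {
        ge <- goEnrichSelect(genes, readGMT(cfg$inputs$annotation_gmt),
                             universe = rownames(se),
                             whitelist = cfg$go_whitelist, cfg = selCfg)
        tt <- ge$terms
        writeTSV(tt, file.path(outDir, "go_terms.tsv"))
        genes <- ge$selected
      }
      list(genes = genes, modTab = mt, termTab = tt)
    }, error = function(e) stageFail(outDir, "geneselect", e))
    selected <- gs$genes
    modTab <- gs$modTab
    termTab <- gs$termTab
  }
  selected <- intersect(selected, geneTable$id)
  if (!length(selected))
    stageFail(outDir, "geneselect",
              simpleError("no selected genes present in the gene table"))
  writeLines(selected, file.path(outDir, "selected_genes.txt"))

  ## stage: promoters + ABC enhancers --------------------------------
  enh <- tryCatch({
    genome <- Biostrings::readDNAStringSet(cfg$inputs$genome_fasta)
    names(genome) <- sub("\\s.*", "", names(genome))
    gsel <- geneTable[geneTable$id %in% selected, , drop = FALSE]
    proms <- makePromoters(gsel, genome,
                           upstream = p$promoter_upstream,
                           downstream = p$promoter_downstream)
    atac <- readBedGraphTrack(cfg$inputs$atac_bedgraph)
    h3k <- readBedGraphTrack(cfg$inputs$h3k27ac_bedgraph)
    hic <- readHiCContacts(cfg$inputs$hic_tsv,
                           resolution = p$hic_resolution,
                           gamma = p$hic_gamma,
                           pseudocount = p$hic_pseudocount)
    cands <- selectStrongestRegions(atac, n = p$n_strongest,
                                    width = p$peak_width)
    promGR <- proms$regions
    elements <- rbind(
      data.frame(chrom = as.character(seqnames(promGR)),
                 start = start(promGR) - 1L, end = end(promGR),
                 is_promoter = TRUE, stringsAsFactors = FALSE),
      if (length(cands))
        data.frame(chrom = as.character(seqnames(cands)),
                   start = start(cands) - 1L, end = end(cands),
                   is_promoter = FALSE, stringsAsFactors = FALSE))
    elements$activity <- elementActivity(
      countSignal(GRanges(elements$chrom,
                          IRanges(elements$start + 1L, elements$end)),
                  atac),
      countSignal(GRanges(elements$chrom,
                          IRanges(elements$start + 1L, elements$end)),
                  h3k))
    pairs <- do.call(rbind, lapply(seq_len(nrow(gsel)), function(i)
      suppressWarnings(abcScores(
        list(id = gsel$id[i], chrom = gsel$chrom[i], tss = gsel$tss[i]),
        elements, hic, window = p$abc_window,
        threshold = p$abc_threshold))))
    retained <- pairs[pairs$retained, , drop = FALSE]
    writeTSV(retained[, c("gene", "chrom", "start", "end", "score",
                          "distance_to_tss")],
             file.path(outDir, "enhancer_gene_pairs.tsv"))
    uniq <- unique(retained[, c("chrom", "start", "end")])
    enhSeqs <- Biostrings::DNAStringSet(vapply(seq_len(nrow(uniq)),
      function(i) as.character(Biostrings::subseq(
        genome[[uniq$chrom[i]]], uniq$start[i] + 1L, uniq$end[i])),
      character(1)))
    names(enhSeqs) <- sprintf("%s_%d_%d", uniq$chrom, uniq$start,
                              uniq$end)
    list(pairs = pairs, retained = retained, promoters = proms,
         enhSeqs = enhSeqs)
  }, error = function(e) stageFail(outDir, "enhancers", e))

  ## stage: anchored co-occupancy ------------------------------------
  candTab <- tryCatch({
    motifs <- readJaspar(cfg$inputs$motifs_jaspar)
    if (!cfg$anchor_tf %in% names(motifs))
      stop("anchor motif '", cfg$anchor_tf, "' not in motif file")
    anchor <- motifs[[cfg$anchor_tf]]
    partners <- motifs[setdiff(names(motifs), cfg$anchor_tf)]
    promEnr <- anchoredEnrichment(
      enh$promoters$seqs, anchor, partners, D = p$D,
      relThreshold = p$rel_threshold, minIc = p$min_ic,
      nShuffles = p$n_shuffles, seed = cfg$seed)
    enhEnr <- anchoredEnrichment(
      enh$enhSeqs, anchor, partners, D = p$D,
      relThreshold = p$rel_threshold, minIc = p$min_ic,
      nShuffles = p$n_shuffles, seed = cfg$seed + 1L)
    writeTSV(promEnr, file.path(outDir, "enrichment_promoters.tsv"))
    writeTSV(enhEnr, file.path(outDir, "enrichment_enhancers.tsv"))
    cand <- categorizeTFs(promEnr, enhEnr,
                          zThreshold = p$z_threshold)
    writeTSV(cand, file.path(outDir, "candidate_tfs.tsv"))
    cand
  }, error = function(e) stageFail(outDir, "cooccupancy", e))

  ## stage: TF network (optional) ------------------------------------
  nodeTab <- NULL
  anchorInCore <- NA
  if (isTRUE(cfg$stages$network) &&
      !is.null(cfg$inputs$tf_target_gmt)) {
    nw <- tryCatch({
      sets <- readGMT(cfg$inputs$tf_target_gmt)
      net <- mergeNetworks(sets)
      if (!is.null(cfg$inputs$interactions_tsv)) {
        ia <- readInteractions(cfg$inputs$interactions_tsv)
        net <- expandNetwork(net, ia, minLinks = p$min_links)
      }
      net <- rankShells(net, nShells = p$n_shells)
      tab <- networkNodeTable(net)
      writeTSV(tab, file.path(outDir, "network_nodes.tsv"))
      list(tab = tab, inCore = inCore(net, cfg$anchor_tf))
    }, error = function(e) stageFail(outDir, "tfnetwork", e))
    nodeTab <- nw$tab
    anchorInCore <- nw$inCore
  }

  ## manifest ---------------------------------------------------------
  cj <- canonicalConfigJson(cfg)
  tmp <- file.path(outDir, "config.canonical.json")
  writeLines(cj, tmp)
  manifest <- list(
    package = "anchorTF",
    version = as.character(utils::packageVersion("anchorTF")),
    seed = cfg$seed,
    config_hash = unname(tools::md5sum(tmp)),
    n_selected_genes = length(selected),
    n_enhancer_pairs = nrow(enh$retained),
    anchor_in_core = anchorInCore,
    outputs = list.files(outDir))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(selected = selected, modules = modTab,
                 terms = termTab, pairs = enh$pairs,
                 retained = enh$retained, candidates = candTab,
                 network = nodeTab, anchor_in_core = anchorInCore,
                 manifest = file.path(outDir, "manifest.json")))
}
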