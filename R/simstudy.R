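#' Write a complete synthetic study to disk
#'
#' Generates one internally consistent set of pipeline inputs — the
#' expression time course, the regulatory genome whose growth genes are
#' drawn from the planted down-modules, coverage tracks and Hi-C, the
#' motif file (anchor + partners), a GO-style annotation whose
#' growth-relevant term holds exactly the growth genes, TF target sets
#' with a planted core, and a ready-to-run YAML config — in
#' \code{dir}. This is the "simulate" entry point for end-to-end runs
#' and tests.
#'
#' @param dir output directory (created).
#' @param seed integer master seed; stage seeds are derived from it.
#' @param multiplier partner planting multiplier (default 10; 1 =
#'   null).
#' @param loopBoost Hi-C boost at true enhancer-gene pairs (default
#'   10).
#' @param nGrowthGenes growth genes in the genome (default 20).
#' @param nOtherGenes non-growth genes in the genome (default 10).
#' @param ... passed to [simRegulatoryGenome()].
#' @return list(config = path to YAML, paths, truth).
#' @export
simulateStudy <- function(dir, seed = 1L, multiplier = 10,
                          loopBoost = 10, nGrowthGenes = 20L,
                          nOtherGenes = 10L, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  se <- simExpression(seed)
  truthMods <- S4Vectors::metadata(se)$truth
  downGenes <- names(truthMods)[truthMods %in% c("M1", "M2")]
  bgGenes <- names(truthMods)[truthMods == "0"]
  growthIds <- downGenes[seq_len(nGrowthGenes)]
  nOther <- nOtherGenes
  otherIds <- bgGenes[seq_len(nOther)]
  gfix <- simRegulatoryGenome(seed = seed + 1L,
                              nGrowthGenes = nGrowthGenes,
                              nOtherGenes = nOther,
                              multiplier = multiplier,
                              growthIds = growthIds,
                              otherIds = otherIds, ...)
  trk <- simTracksAndHiC(gfix, seed = seed + 2L, loopBoost = loopBoost)
  tfs <- simTFTargetSets(seed = seed + 3L)
  paths <- list(
    expression = file.path(dir, "expression.tsv"),
    expression_time = file.path(dir, "samples.tsv"),
    genome_fasta = file.path(dir, "genome.fa"),
    gene_table = file.path(dir, "genes.tsv"),
    annotation_gmt = file.path(dir, "annotation.gmt"),
    atac_bedgraph = file.path(dir, "atac.bedGraph"),
    h3k27ac_bedgraph = file.path(dir, "h3k27ac.bedGraph"),
    hic_tsv = file.path(dir, "hic.tsv"),
    motifs_jaspar = file.path(dir, "motifs.jaspar"),
    tf_target_gmt = file.path(dir, "tf_targets.gmt"),
    interactions_tsv = file.path(dir, "interactions.tsv"))
  writeExpressionMatrix(se, paths$expression, paths$expression_time)
  Biostrings::writeXStringSet(gfix$genome, paths$genome_fasta)
  writeGeneTable(gfix$geneTable, paths$gene_table)
  ann <- list(axon_growth_like = growthIds,
              unrelated_term_1 = bgGenes[nOther + 1:20],
              unrelated_term_2 = bgGenes[nOther + 21:40])
  writeGMT(ann, paths$annotation_gmt)
  writeBedGraphTrack(trk$atac, paths$atac_bedgraph)
  writeBedGraphTrack(trk$h3k27ac, paths$h3k27ac_bedgraph)
  writeHiCContacts(trk$hic, paths$hic_tsv)
  writeJaspar(c(list(gfix$anchor), gfix$partners),
              paths$motifs_jaspar)
  writeGMT(tfs$sets, paths$tf_target_gmt)
  writeTSV(tfs$interactions, paths$interactions_tsv)
  cfg <- list(anchor_tf = tfs$anchor,
              out_dir = file.path(dir, "out"),
              seed = seed,
              inputs = paths,
              go_whitelist = list("axon_growth_like"))
  cfgPath <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfgPath)
  list(config = cfgPath, paths = paths,
       truth = list(growth_genes = growthIds, plan = gfix$plan,
                    anchor = tfs$anchor, core_tfs = tfs$coreTFs,
                    true_pairs = trk$truePairs,
                    modules = truthMods))
}
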