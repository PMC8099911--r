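---
title: "Anchored TF co-occupancy discovery: models and methods"
author: "anchorTF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchored TF co-occupancy discovery: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anchorTF)
```

# The problem

Transcription factors (TFs) that act cooperatively often do so by
binding regulatory DNA in close proximity. Given one "anchor" TF known
to promote a phenotype — the motivating case is Klf6, which drives
axon growth in corticospinal neurons — anchorTF asks which other TFs
are statistically over-represented *near the anchor's binding sites*
in the regulatory DNA of phenotype-relevant genes. The pipeline has
four computational stages, each usable on its own:

1. **Gene selection** (`detectModules()` and friends): find
   developmentally downregulated, growth-relevant genes from an
   expression time course.
2. **Regulatory DNA assembly** (`makePromoters()`, `abcScores()`):
   fixed promoter windows plus enhancers paired to genes by the
   activity-by-contact (ABC) model.
3. **Anchored co-occupancy** (`anchoredEnrichment()`,
   `categorizeTFs()`): motif scanning, anchored windows, and a
   binomial Z statistic per candidate partner TF.
4. **Network corroboration** (`mergeNetworks()`, `expandNetwork()`,
   `rankShells()`): merge the candidates' target-gene sets and ask
   which TFs sit in the connectivity core.

The package also fixes the arithmetic of the in vivo readouts used to
validate such predictions (fiber index, branch frequency), so those
quantifications are auditable.

# Gene selection

## Model

Genes x samples expression values (log2 scale) are wrapped in a
`SummarizedExperiment` with an ordered `time` factor. After
preprocessing, a weighted co-expression network is built:

- adjacency \(a_{ij} = |\mathrm{cor}(x_i, x_j)|^{\beta}\) with soft
  power \(\beta = 10\) (unsigned: the direction filter is applied
  afterwards on raw expression, so signedness adds nothing here);
- topological overlap
  \(\mathrm{TOM}_{ij} = \frac{\sum_{u \neq i,j} a_{iu}a_{uj} + a_{ij}}
  {\min(k_i, k_j) + 1 - a_{ij}}\), which smooths the adjacency by
  shared neighbourhoods;
- average-linkage clustering of \(1 - \mathrm{TOM}\), cut at a fixed
  fraction (default 0.99) of the maximum merge height; clusters under
  `minModuleSize` (default 30) genes form the unassigned pool. This is
  the static-height member of the tree-cut family: parameters are
  explicit and results are deterministic, at the cost of the adaptive
  splitting a dynamic cut provides.

A module is carried forward when its early/late mean expression ratio
on the linear scale reaches `downregFold` (default 2), and the gene
list is then gated by hypergeometric GO-term enrichment restricted to
a user-supplied whitelist of growth-relevant terms (BH-corrected
q < 0.05). The whitelist is mandatory by design: term choice encodes a
literature judgement the software must not silently make.

## Preprocessing choices

Genes missing in more than 20% of samples are dropped; remaining
missing values are imputed with the gene mean (simple, and inert for
correlation-based downstream steps). Outlier samples are detected on
the average-linkage sample tree: a sample whose first merge height
exceeds mean + 2 sd of all merge heights is removed. Note the rule
needs a reasonable number of samples to have power — with, say, six
samples a single extreme outlier inflates the sd of the five merge
heights enough to mask itself; from roughly nine samples upwards the
rule behaves as intended. The per-gene time-course test is an
equal-variance one-way F test on log values with BH correction; it is
a deliberately plain stand-in for a full count-model fit, documented
as such.

# Promoters and ABC enhancers

Promoters are fixed strand-aware windows around the TSS, default
1500 bp upstream / 300 bp downstream (the convention of the discovery
analyses; `upstream = 1000` is the documented alternative preset used
by some single-TF scanners — both are exposed rather than silently
reconciled).

Candidate enhancers come from a deliberately simple strongest-window
selector over a coverage track (500-bp windows, 250-bp step, greedy
non-overlapping selection, book-ended merge): only the "n strongest
regions" contract of an external peak caller matters downstream, so
that contract is implemented directly. Element activity is the
geometric mean \(\sqrt{\mathrm{ATAC} \times \mathrm{H3K27ac}}\) of the
two coverage signals.

Contact comes from sparse fixed-resolution Hi-C (default 5 kb). With
no contact data the expected power-law decay
\((res/\max(d, res))^{\gamma}\), \(\gamma = 0.87\), is used directly;
with data, observed counts (plus a 0.3 pseudocount) are rescaled so
their distance-binned means sit on the power-law curve, which is what
"scaling Hi-C using the power law" amounts to at this resolution.
Distances with no observed pairs fall back to the curve. KR/ICE matrix
balancing is out of scope.

The ABC score of element \(i\) for a gene is
\(A_i C_i / \sum_k A_k C_k\) over all candidate elements within a 5-Mb
window of the TSS; scores sum to 1 per gene by construction, and pairs
with score ≥ 0.01 are retained. Promoter elements participate in the
denominator but promoter self-pairs are excluded from the enhancer
report.

# Anchored co-occupancy

Motifs are position frequency matrices (JASPAR text format), scored as
log2 odds against a background composition with a 0.25 pseudocount.
Candidates need at least 8 bits of information content. A window is a
hit when its *relative score* — \((s - s_{min})/(s_{max} - s_{min})\)
over the attainable score range — reaches 0.9, the standard meaning of
a "90% matrix score" threshold; ties at any threshold are included. An
optional per-base conservation mask (scan only where mask ≥ 0.40)
supports precomputed conservation tracks.

Anchor hits define the foreground: the union of ±D flanks (default
D = 100 bp, the conventional anchored-analysis scale; configurable)
around each anchor hit, minus the anchor footprints. A partner hit
counts when its footprint overlaps a window and does not overlap an
anchor footprint — footprint overlap rather than start-coordinate
membership, because only the former is exactly invariant when every
input sequence is reverse-complemented (a property the test suite
enforces).

With \(u\) the partner's background hit rate per nucleotide,
foreground hits are modelled binomially:
\(z = (h - u\,n_{fg}) / \sqrt{n_{fg}\, u (1-u)}\). Partners reaching
z ≥ 10 in promoters and enhancers are category `both`; one compartment
gives `promoter_only` / `enhancer_only`. The default background is a
seeded per-sequence dinucleotide shuffle (Altschul–Erikson) of the
foreground — self-contained and composition-matched; a user-supplied
background sequence set is also accepted. A one-tailed Fisher exact
test on per-sequence presence/absence is reported as a companion
statistic.

# TF network core

Per-TF target gene sets (GMT) are merged into one undirected simple
graph; an interaction edge list then expands the network one level:
an outside node joins when it has at least `minLinks = 2` interaction
edges into the current network (multi-evidence attachment avoids a
halo of degree-1 nodes), with no recursion. Connectivity is plain
degree. Nodes are ranked into `nShells = 4` equal-frequency shells,
with two refinements: equal-degree nodes always share a shell (a node
enters the core only by strictly out-ranking others, so a star's
leaves can never join its hub), and occupied shells are renumbered
contiguously from 1. Shell 1 is the core. The qualitative check the
pipeline mirrors: a held-out anchor TF connected to many core targets
should enter the network *only* through expansion and land in the
core.

# In vivo quantification

Two formulas are fixed so downstream statistics are reproducible from
count tables (images and tracing stay manual):

- **Fiber index**: mean axon count per midline distance across
  replicate sections, divided by the extrapolated total of labelled
  axons in the medullary pyramid
  (\(\sum \text{line counts} \times A_{pyramid}/A_{sampled}\)).
- **Branch frequency**: total branches over total traced length in
  mm, after rejecting segments under 100 µm; totals under the 5-mm
  sampling guideline warn but still compute. A per-animal boolean
  records the lesion-completeness exclusion.

# Synthetic fixtures: what they emulate, and what not

Every stage ships a seeded generator (`simExpression()`,
`simRegulatoryGenome()`, `simTracksAndHiC()`, `simTFTargetSets()`,
bundled by `simulateStudy()`), pure functions of their seed:

- **Expression**: modules share a sample-level random effect plus a
  module-specific time profile; profiles are mutually orthogonal
  Helmert contrasts over interior time points, with endpoints pinned
  so planted down-modules decay exactly 4-fold (≥ the 2-fold filter).
  Twelve samples over six developmental stages, two replicates each.
- **Genome**: one chromosome of i.i.d. uniform sequence (a
  dinucleotide background is the shuffle's job, not the genome's);
  anchor consensus planted in growth-gene promoters and enhancers;
  partner consensus planted within D of anchors so the local rate is
  `multiplier` × the motif's chance rate. `multiplier = 1` plants
  nothing — the null condition. Plantings never overwrite each other
  or leak into other compartments.
- **Tracks / Hi-C**: Poisson coverage peaks at promoters, enhancers
  and distance-matched decoy elements; Hi-C counts follow
  \(d^{-0.87}\) with a loop boost at true enhancer–gene bin pairs
  only.
- **TF sets**: a small core sharing a large target pool (plus mutual
  edges), sparse disjoint peripheral TFs, and a held-out anchor wired
  to core targets through the interaction list.

Passing tests on these fixtures shows the statistics are calibrated
and the planted structure is recovered under the stated models. It
does not show robustness to what real data add: probe-level noise and
batch effects, nucleosome-scale coverage structure, Hi-C matrix
artefacts, motif redundancy between TF families, or cross-species
identifier mess beyond a synonym table. Fixture scale is capped
(genomes of a few hundred kb to ~1.6 Mb, tens of genes) so the full
suite runs in minutes.

# Numerical and degenerate-input conventions

- Zero-variance genes get adjacency 0 (flagged), not an error.
- Relative motif scores with zero-count columns and no pseudocount
  have \(s_{min} = -\infty\); any finite-scoring window then counts as
  maximal. With the default pseudocount this never triggers.
- `enrichmentZ` with background rate 0 and foreground hits returns
  +Inf with a `degenerate` flag; rate-0-and-expectation-met returns 0.
- Cross-chromosome Hi-C queries are 0 with a warning; flat-zero
  coverage tracks yield an empty peak set with a warning.
- Ties: strict ≥ at every threshold (8 bits, 0.9 relative score,
  Z = 10, ABC 0.01); window selection ties break by (chrom, start);
  module labels order by size then smallest member id; shell ties
  share a shell. All pipelines are deterministic given config + seed.

# Problem sizes

The bundled tests and the acceptance script use: 200 random matrices
up to 12×12 for the TOM oracle; 20 two-block expression replicates for
module recovery; 100 random 500-nt sequences × 10 PFMs for the scanner
oracle; 50 (tests) / 30 (script) null genomes of 12 growth genes for Z
calibration; one 20-gene, ~1.6-Mb genome for planted-partner recovery;
15 genes × 4 elements for ABC recovery; 10–20 seeds for network
recovery. These sizes make each property check run in seconds to a
couple of minutes while keeping every estimate's sampling error well
inside the asserted bands.

# Known limitations

- The static-height tree cut will not reproduce a published module
  count obtained with an adaptive dynamic cut; the parameters are
  configurable, not claimed equivalent.
- The Z statistic assumes independent per-position hits; strongly
  self-overlapping or palindromic motifs clump and inflate variance.
- ABC here omits Hi-C balancing and uses a single activity definition;
  exact reproduction of published enhancer counts additionally depends
  on the reference implementation's defaults (candidate window,
  γ, promoter conventions).
- Expansion evidence is unweighted; connectivity is degree, not a
  weighted or betweenness centrality.
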