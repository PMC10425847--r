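---
title: "Phylogenetic profiling of ciliary genes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic profiling of ciliary genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliaprofile)
```

## The problem

Cilia are ancient eukaryotic organelles that many lineages have abandoned:
fungi other than chytrids, flowering plants, red algae, slime molds and
several alveolate and stramenopile lineages all build no cilium. Genes whose
only job is to build or move the cilium become dispensable the moment the
organelle is lost, so across a broad panel of genomes their
presence/absence profile tracks the organelle rather than the species
phylogeny. ciliaprofile implements this logic as a reusable pipeline: call
gene-level orthologs by bidirectional best alignment hits, assemble a binary
gene-by-genome matrix, co-cluster both axes, pull out the gene cluster
anchored on a core centriolar seed gene, and interrogate that cluster —
how often was the cilium lost, which functional sub-modules were lost
together, and what does a gene's footprint predict about its function.

Every stage is testable without downloading a single proteome because the
package ships a generative model of the whole setting (see *The simulator*
below).

## Orthology calls

A gene is marked present (1) in a target genome when (i) the forward search
of its representative protein returns an admissible hit, and (ii) the best
reverse hit of that subject protein maps back to the *same gene* — any
isoform counts, since reciprocity is established at the gene level.

Two parameter decisions matter here:

* **E-value threshold, default 0.1.** Admissibility is `e_value <= 0.1`.
  This deliberately permissive cutoff keeps highly divergent orthologs
  (fast-evolving core centriolar components are the canonical casualties of
  strict cutoffs) in the matrix; the reciprocity requirement supplies the
  specificity that the threshold gives up.
* **One representative protein per gene.** The forward search uses a single
  representative isoform per human gene (the gene map designates it; by
  convention the longest). Whether one queries every isoform or one
  representative is not decidable from the published description; the
  single-representative choice is cheaper, deterministic, and the reverse
  direction still accepts any isoform. This is a documented decision, not a
  claim about the original run.

Best hits are chosen by maximal bit score; ties break by lower E-value,
then lexicographically smaller subject id. With genuine alignment output
E-values are monotone in bit score for a fixed query, which gives the
useful invariant that *raising* the threshold can only turn 0s into 1s,
never the reverse — the test suite checks this on fabricated tables.

## Distances and clustering

Profiles are binary, so Euclidean distance is `sqrt(hamming)`. The
`mean_squared` dialect (`hamming / n_species`) is also offered because the
legacy clustering tool that popularised this workflow computes its
"Euclidean" as the *average* squared difference; the two are monotone
transforms of each other but average linkage is not invariant under
monotone transforms, so topologies can differ. Euclidean is the default;
both are tested. Prokaryote outgroup columns take part in the distance
computation like any other genome.

Average linkage (UPGMA-style, unweighted: the distance between clusters is
the mean over all member pairs) is implemented in compiled code as a
nearest-neighbour chain. Binary data produce many exactly tied distances,
and tie handling in off-the-shelf implementations depends on input order.
Here every candidate pair is ordered by the strict key *(distance, smaller
member-label rank, larger member-label rank)*; label ranks use C-locale
sorting. This key is a strict total order that satisfies the reducibility
property for average linkage, so the chain algorithm provably returns the
same dendrogram as global minimum selection — determinism over
faithfulness to any particular historical tool, whose internal order is
unknowable. The test suite verifies exact agreement with a naive cubic
implementation of the global rule on both tie-free and heavily tied
instances, and with `stats::hclust` where ties are absent.

### Ciliated-left leaf ordering

For display, the species dendrogram is reordered so ciliated genomes sit
as far left as the tree structure allows: at every internal node the child
subtree with the higher *density* of ciliated leaves is placed first, ties
keeping input order. By the standard exchange argument this greedy rule
minimises the sum of positions of ciliated leaves over all orderings
consistent with the dendrogram; tests confirm optimality exhaustively on
trees up to eight leaves ($2^{n-1}$ orderings).

### Seed-anchored extraction

The ciliary cluster is defined as a clade of the gene dendrogram
containing the seed gene. Three cut rules are provided:

* `fixed_height` — largest seed clade with merge height at most the cut;
* `target_size` — smallest seed clade with at least *k* leaves, the mode
  used to pin a cluster of a prescribed published size;
* `elbow` (default) — automatic. The growth trace (clade size at each
  merge on the seed-to-root path) grows gradually while the cluster is
  coherent, then jumps when the cluster is absorbed into the unrelated
  bulk of broadly conserved genes. The cut is placed just below the *last*
  merge at which the clade size grows by more than a factor of 2
  (`growth_factor`).

An earlier design cut at the largest *relative gap in merge heights* on
the seed path. That rule works on noise-free data but fails at realistic
detection noise: average-linkage merge heights inside a noisy module of a
few hundred genes creep upward smoothly, and the height increment at the
module/background boundary (about 2% relative, in simulations at a 5%
false-negative rate) is smaller than the relative increments between the
first few noisy merges. The size-jump criterion is scale-free in height
and identifies the absorption event directly; the height-gap rule is kept
only as a fallback when no merge doubles the clade. The assumption it
encodes — the anchored module is much smaller than a coherent conserved
background — matches this analysis setting. The growth trace itself is
always returned, as the honest surface for judging any cut.

### Robustness by stratified subsampling

`robustness_subsample()` removes a fraction of genomes from every major
group (never a whole group — the removal is stratified precisely because
losing an entire branch of the tree changes the question, not just the
power), re-clusters, re-extracts and reports the overlap with the
full-matrix cluster. The removal draw is seeded explicitly and performed
on a private RNG stream, so results are reproducible and the caller's
random state is never touched.

## Evolutionary inference

**Loss counting** assumes the trait (cilia) was present in the eukaryotic
ancestor and is never regained — the appropriate model for a complex
multi-gene organelle. Under this no-regain rule the minimum-loss
explanation is unique and structural: one loss on the edge above every
maximal all-absent clade. The implementation is linear-time over a
post-order pass; tests check it against an exhaustive search over loss-edge
covers on trees up to ten leaves, and check invariance under child
rotation and under polytomy refinements that keep absent leaves together.
Prokaryote outgroups never had the trait and are dropped before counting.
When no resolved species tree is available, `group_polytomy_tree()` builds
one from major-group memberships (groups as polytomous clades); any Newick
tree can be supplied instead.

**Loss patterns.** Per species and per functional gene category, the
fraction of category genes present is discretised at 2/3 and 1/3:
`high` above 2/3, `low` below 1/3, `mid` between. The two boundary points
are not assigned by the published strict inequalities; both are placed in
`mid`, the conservative reading. The number of distinct discretised
vectors is the pattern count.

**Function prediction.** A gene present in fewer than 50% of ciliated
species yields `no_prediction` — too little footprint to call. Otherwise
it is `motility` when absent from *every* ciliated species whose cilia are
nonmotile (in real panels: nematodes and the tick) while present in at
least 50% of motile-ciliated species, else `biogenesis`. Both 0.5
thresholds are exposed as parameters: the original cutoffs were chosen
manually against known genes and are not recoverable, so the defaults here
are parameters, not claims. Annotation flags for reduced-complement
lineages and similar special cases are carried through the data structures
for custom rules but do not enter the default decision.

## Screen scoring

The fly and worm phenotype rubrics are implemented exactly as printed,
with one documented repair: the dye-fill bins are published at one-decimal
resolution, which leaves invisible gaps (for example 10.9–11.0 amphid
neurons). Bins are therefore half-open with each gap attached to the
adjacent *worse* score: amphids `[11.5,12]→0, [11,11.5)→1, [10,11)→2,
[6,10)→3, [0,6)→4`; phasmids `[3.85,4]→0, [3.75,3.85)→1, [3.5,3.75)→2,
[0.25,3.5)→3, [0,0.25)→4`. The overall dye-fill phenotype is the numeric
maximum (strongest) of the amphid and phasmid scores. Fertility bins pupae
counts at 90/60/30/10. The scolopidium rule marks a gene abnormal only
when *strictly more than* 20% of scolopidia are defective. Qualitative
rubric clauses ("strong lethality with a few survivors", "several
individuals") are operationalised as documented fraction thresholds with
optional count guards. In aggregation a gene is significant when any assay
score is strictly greater than 1; missing assays are skipped, never
imputed as zero, and percentages are reported as integer percent.

## The simulator

`simulate_ciliome()` generates the full study setting so that every
upstream stage has a ground truth:

* a rooted species tree with eight eukaryotic major groups as clades
  (random binary structure within groups, unit branch lengths) and a
  prokaryote outgroup clade — defaults: 147 eukaryotes
  (40/8/25/4/20/20/18/12 across the groups) plus 12 prokaryotes;
* cilium loss placed on 13 edges distributed 4/1/3/2/3 over five groups,
  the documented pattern of independent losses in this genome panel. Loss
  edges are sampled inside group clades, never nested, never jointly
  covering a parent clade (each loss must remain an independent event for
  parsimony), and never exhausting a group's species; two further
  motility-only losses model lineages that kept cilia but shed the beat
  machinery;
* a ciliary complement of 386 genes in three co-lost modules — core
  biogenesis (200), motility (140, lost wherever motility is lost) and a
  BBSome-like module (46) — plus 4,614 background genes conserved across
  the whole tree, for 5,000 genes total. The published analysis clustered
  the complete human protein-coding complement; 5,000 genes preserves the
  module-to-background ratio regime at a size every stage handles in
  seconds, and is the scale all simulation-based tests and the acceptance
  script use;
* sporadic per-gene Dollo loss on random branches (probability 0.01 per
  gene per branch) so background genes are not trivially constant and
  module genes have ragged edges;
* detection noise: each present cell is dropped with probability 0.05
  (false-negative ortholog calls — the dominant error mode for divergent
  sequences), each absent cell turned on with probability 0.002. An
  optional per-group multiplier raises the false-negative rate for
  designated fast-evolving groups (off by default);
* optionally one "reduced complement" ciliated species that loses a random
  half of its ciliary genes, emulating parasites that build a cilium with
  a drastically trimmed toolkit.

All randomness flows from the single mandatory `rng_seed` through a
private stream. `fabricate_hit_tables()` closes the loop: it emits forward
and reverse 12-column hit tables whose reciprocal-best calls reproduce a
given matrix *exactly*, including inadmissible decoys and decoys whose
reverse hit lands on the wrong gene — so the orthology stage is tested
end-to-end, not just on happy paths.

What the simulator does **not** model: sequence-level evolution (noise is
i.i.d. per cell, not phylogenetically correlated); heterogeneous branch
lengths; gene duplication and paralog interference beyond the fabricated
decoys; correlated absence of module genes *within* a genome beyond the
module structure itself; and screen phenotypes. A passing recovery test
therefore demonstrates that the pipeline's logic is sound under the stated
noise regime, not that any particular biological matrix will yield a
clean cluster.

## Numerical choices and degenerate inputs

* Merge heights are monotone nondecreasing (average linkage is reducible);
  the dendrogram invariant is asserted in tests.
* Distances are Hamming-count based and exact in integer arithmetic before
  the final square root; no tolerance is needed in the distance itself.
* A single-gene matrix yields a TreeView gene tree with zero merge lines;
  a cut below the first merge yields the seed alone; an empty gene list
  yields a 0-row matrix.
* TreeView output uses 6 significant digits and the de-facto
  `GENE{k}X`/`ARRY{k}X`/`NODE{k}X` id convention (0-based input indices),
  with merge heights rescaled to `1 - h/max(h)` similarity scores.
* Subsampling refuses any fraction that would remove an entire major
  group; per-group removal counts are rounded.

## Problem sizes

The default simulation (5,000 genes x 159 genomes) clusters in under two
seconds; the end-to-end recovery study in the acceptance tests runs 50
replicates at 5,000 genes x 120 genomes (300-gene planted module, 13
losses, 5% false negatives) in under two minutes and requires the median
planted-cluster Jaccard to reach 0.9. Exhaustive oracles cap their
instances at 10 items (linkage, loss counting) and 8 leaves (leaf
ordering), the sizes at which enumeration is still exact and fast.

## Known limitations

* The elbow rule assumes one coherent background much larger than the
  anchored module; a background split into several comparably sized,
  mutually distant blocks could shift the absorption point. Use
  `target_size` or `fixed_height` with the growth trace when in doubt.
* Dollo counting is structural, not probabilistic: it reports the minimal
  loss set, with no uncertainty and no rate model, and is only as good as
  the supplied tree. With the default group-polytomy tree, losses that a
  resolved within-group topology would merge or split are counted at the
  resolution of the polytomy.
* The function-prediction rule inherits the biases of its footprint:
  genes lost in ecdysozoa for reasons unrelated to cilia deflate
  conservation fractions and can push biogenesis genes toward the
  no-prediction bin (or, with sparse nonmotile-ciliated panels, toward
  motility).
* Screen rubric clauses that are qualitative in print are necessarily
  quantified here; the chosen thresholds are documented above and in the
  function reference, and tests pin them.
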