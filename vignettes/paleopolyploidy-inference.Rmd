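---
title: "Inferring and dating recursive paleopolyploidy from gene colinearity"
author: "ploidscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring and dating recursive paleopolyploidy from gene colinearity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ploidscan)
```

## The problem

Plant genomes carry layered records of ancient whole-genome multiplications
(paleopolyploidies).  After each event most duplicated genes are lost again
(fractionation), but the survivors remain in colinear (syntenic) blocks —
runs of genes whose order is conserved between two chromosomal segments.
Three signals read from those blocks identify and date the events:

1. **Ks age distributions.**  The synonymous divergence (Ks) of a duplicate
   pair is a molecular clock proxy.  All pairs created by one event share an
   age, so the Ks values of within-genome colinear pairs pile up into peaks,
   one per event.
2. **Orthology / outparalogy depth ratios.**  Using a slowly evolving
   reference genome (grape here, which retains much of the ancestral
   eudicot structure), each reference region has one *orthologous* region
   per surviving subgenome of the target produced after the two lineages
   split, and additional *outparalogous* regions produced by duplications
   predating the split.  The modal number of such regions per reference
   window is a direct readout of the target's relative ploidy: a 1:3
   orthology ratio means a lineage-specific triplication.
3. **Region-similarity of fractionation patterns.**  If two genomes went
   through the *same* polyploidy, matched subgenome regions share their
   gene-loss pattern; if the events were independent, no column pairing
   stands out.

This package implements that workflow for a four-taxon setting —
grape, (cacao, (durian, cotton)) — in which all four genomes share an
ancient hexaploidization (ECH), the durian lineage underwent its own
hexaploidization (DSH) and the cotton lineage a decaploidization (GSD)
accompanied by a marked acceleration of substitution rates.  The central
analytical difficulty it addresses is that rate acceleration makes the
young cotton event *look* older than the young durian event, which
historically led to the two being conflated into one shared event; the
two-step rate correction below resolves this, and the gene-tree module
shows why naive phylogenetic trees cannot.

Because the real genome assemblies are outside the scope of a test suite,
the package includes a first-class simulator that generates genomes with
exactly the statistical structure the pipeline assumes, plus the ground
truth needed for parameter-recovery tests.

## The simulator

`sim_config()` / `scenario_config()` define a scenario on the fixed
topology `(grape,(cacao,(durian,cotton)))`.  All positions are expressed in
expected-Ks units at unit substitution rate: a speciation with `split_ks =
0.25` means two orthologs sampled today are expected to differ by Ks 0.25,
and an event with `time = 0.17` creates duplicates with expected pairwise
Ks 0.17.  This makes event times map linearly onto the Ks axis, which is
exactly the assumption the dating step uses.

Default scenario parameters (the study conditions):

| quantity                        | default | rationale                                     |
|---------------------------------|---------|-----------------------------------------------|
| ECH time                        | 1.04    | rate-corrected ECH peak scale of the slowest (grape) lineage |
| DSH time (durian triplication)  | 0.17    | corrected durian duplicate peak               |
| GSD time (cotton decaploidy)    | 0.12    | corrected cotton duplicate peak               |
| cacao–(durian,cotton) split     | 0.25    | durian–cacao ortholog peak                    |
| durian–cotton split             | 0.22    | consistent with the relative split dates      |
| grape split                     | 0.80    | keeps simulated ortholog blocks (< 0.95) separable from ECH blocks, as in real dotplots |
| cotton rate multiplier (`full`) | 1.64    | the reported cotton-vs-durian elevation       |
| codons per gene                 | 500     | typical CDS length; Ks noise sd ≈ 0.02 at Ks 0.2 |

Rate multipliers are attached to named branches of the tree.  A multiplier
on the cotton terminal branch elevates every divergence whose path crosses
that branch — cotton's ECH paralogs, the GSD duplicates (fully), and the
cotton side of cross-species comparisons (partially).  This is the
phylogenetically consistent reading of a lineage-specific acceleration; a
terminal-branch multiplier of 1.64 therefore produces a cross-species
elevation smaller than 64%; the reported 64% figure is the ratio of two
observed outgroup peaks (0.41/0.25), which the arithmetic of
`rate_elevation()` reproduces exactly.

**Sequence model.**  Genes are codon sequences drawn from the six
fourfold-degenerate codon families that have no synonymous single-step
neighbour outside the family (GTN, TCN, CCN, ACN, GCN, GGN).  Third
positions evolve under Jukes–Cantor with the branch's rate-scaled length;
nonsynonymous change is modelled as occasional codon-family swaps at
`ka_ratio` (default 0.2) times the synonymous rate.  Two properties follow
by construction: no sequence ever contains a stop codon, and each codon
contributes exactly one synonymous site under Nei–Gojobori counting, so
the expected Ks of a pair equals the rate-scaled path length separating it
on the true gene tree (the test suite verifies this against a closed-form
path-length oracle).  The model is deliberately minimal: it produces
controllable Ks-scale divergence, which is all the pipeline consumes.  It
does not emulate codon-usage bias, indels, GC drift, or rate variation
across sites, so passing tests say nothing about robustness to alignment
error or compositional heterogeneity in real data.

**Gene content.**  Each polyploidy multiplies the genome; the copy
designated parental at each event is always retained, every other
duplicate survives with `retention_prob` (drawn once, in the ancestor, so
losses are shared by all descendant lineages — this is what makes the
shared-event similarity signature testable).  Optional per-taxon
`lineage_loss` adds post-speciation fractionation (never removing a locus'
last copy), `tandem_rate` creates rank-adjacent tandem copies, and
`inversion_rate` applies segmental inversions.  `simulate_history()` is
separate from `evolve_sequences()`, and two independent RNG streams are
derived from the seed, so gene content is byte-identical whether or not
sequences are evolved.

## Colinear block detection

`detect_blocks()` chains homolog hits (tabular BLAST dialect, E ≤ 1e-5) on
gene-rank coordinates.  A block is a strictly monotone run — parallel or
antiparallel, both diagonals occur in real dotplots — with consecutive
pairs separated by at most `max_gap = 50` ranks on each chromosome and at
least `min_pairs = 4` pairs.  Within a chromosome pair, chains are
extracted greedily, best first, and each hit joins at most one block; a
gene may still appear in blocks on different chromosome pairs, which is
required for outparalogy.  Ties between equal-length chains are broken by
smaller total rank span, then by two additive, genome-swap-invariant keys
(the summed rank coordinate and the summed diagonal offset), which makes
`detect_blocks(A, B)` and `detect_blocks(B, A)` provably mirror images and
lets an exhaustive search oracle reproduce the output exactly.

Significance is a Poisson chain-probability model: with *N* hits on an
`la x lb` rank grid, each extension must land in a `max_gap`² successor
window, giving per-step intensities `(N - k) g² / (la lb)`, an edge factor
for starts near the boundary, and a declumping factor `(1 - mu)`; the
p-value is `1 - exp(-E)` over both orientations.  Validation against
permutation (shuffled gene orders) shows agreement within a factor of ~1.5
in the regime where permutation p-values are measurable.

## Ks estimation and mixture decomposition

`nei_gojobori()` implements the classical counting method: synonymous site
fractions per codon from single-step neighbours (mutations to stop codons
count as nonsynonymous), observed differences averaged over all minimal
mutational pathways excluding those through stop codons (unless all are
blocked), and the Jukes–Cantor correction `d = -3/4 log(1 - 4p/3)` applied
to both proportions.  Pairs at or beyond `p = 3/4` are flagged saturated
and excluded from fitting.  `align_codons()` provides protein-guided codon
alignment for unequal-length input; simulator output is already in frame
and uses the fast vectorised path in `ks_pairs()`.

`fit_ks_distribution()` follows the kernel-density-plus-curve-fit recipe:
a Gaussian KDE with bandwidth 0.05 evaluated on 300 grid points over
[0, 3] (values above 3 are discarded as saturated noise), then a sum of
Gaussians fitted to the density curve by Levenberg–Marquardt least
squares.  The component count is the smallest reaching R² ≥ 0.95; if the
target is unreachable by `max_components` the best fit is returned with
`converged = FALSE`.  Components are initialised at the KDE's local
maxima, sorted by mean, and the highest-weight component is the *principal*
peak representing the event.  Note the kernel widens fitted component
standard deviations by roughly the bandwidth in quadrature; component
*means* — the quantities used downstream — are unaffected.  Block median
Ks uses the even-count convention (mean of the central two).

## Two-step rate correction and dating

Step 1 aligns every lineage's ECH-duplicate peak to grape's (the slowest):
`c1 = mu_grape / mu_lineage`, applied multiplicatively to that lineage's
Ks values; cross-species samples use the algebraic mean of the two
lineages' coefficients (`correct_between()`).  Step 1 is idempotent — a
second pass yields coefficients of 1 — and after it all ECH peaks refit to
grape's within ±0.01 on simulated data.

Step 1 cannot remove an acceleration confined to the recent, post-split
era: the ECH sample's path is dominated by shared ancestral branches, so
`c1` under-corrects cotton.  Step 2 therefore aligns the cotton–cacao
ortholog distribution to the durian–cacao one: `c2 = mu_dc / mu_cc` on the
step-1-corrected peaks.  For cross-species samples `c2` applies directly.
For within-cotton duplicate samples (the GSD peak) the package applies the
equivalent duplicate-pair coefficient `c2 / (2 - c2)`: a cross-species
path is elevated on one of its two halves (so `c2 = 2 / (1 + r)` for
residual rate `r`), while both halves of a duplicate pair's path run
through the elevated lineage (so the appropriate factor is `1/r`).  The
two forms coincide at `c2 = 1`.  This distinction is the package's design
choice where the method description leaves the duplicate-sample treatment
open; with it, simulations that plant DSH at Ks-time 0.17 and GSD at 0.12
under a 1.64x cotton acceleration recover both values within ±0.02,
whereas applying `c2` directly to the duplicate sample leaves the GSD peak
~20% too old.

`date_event()` converts a corrected peak to an age range by linear scaling
against the ECH calibration (115–130 million years): `date = peak /
ech_peak x [t_lo, t_hi]`.  On the default scenario this brackets the
durian event at roughly 19–21 mya and the cotton event at 13–15 mya,
younger than the durian event despite its larger uncorrected Ks.

## Ploidy profiling

`classify_blocks_by_ks()` labels blocks orthologous below `ortholog_max`
and outparalogous above `outparalog_min`; blocks between the thresholds
(or exactly at one) are ambiguous and excluded.  The thresholds are a
per-genome-pair calibration placed between the expected ortholog and
outparalog divergences.  For real grape–durian data the reported values
are (0.95, 1.30); for the simulator's default geometry (ortholog Ks 0.80–0.87,
ECH Ks 1.04–1.18) the pipeline uses (0.92, 0.97).  Classification acts on
block *medians*, so pair-level noise is suppressed by the block size and
the two groups separate cleanly in both calibrations.

`depth_profile()` operationalises reading diagonals off a dotplot: the
reference is cut into windows of 20 genes; per window it counts distinct
target regions whose orthologous (resp. outparalogous) blocks overlap it,
after merging blocks that are breakage/rearrangement complements (same
chromosome pair, rank-adjacent on both genomes within `merge_gap`).  The
modal counts over non-empty windows are the orthology and outparalogy
ratios.  Under no loss these equal the analytic products of event
multiplicities (1:3 and 1:6 for a shared triplication followed by a
lineage triplication; 1:2 and 1:4 for a lineage tetraploidization; 1:1 and
1:2 with no later event), and the mode is robust: at 30% gene loss the
1:3 reading persists in at least 80% of simulation seeds.
`render_dotplot()` draws the underlying best/secondary/other scatter with
block overlays annotated by median Ks.

## Alignment tables and fractionation

`build_alignment_table()` anchors every target genome to the reference
gene list, one column per orthologous subgenome; ortholog blocks are
assigned to columns by interval-graph coloring on their reference
intervals, longest block first, so blocks from one post-event subgenome
share a column without any explicit phasing input.  `count_missing()`
reports the fraction of reference genes with no colinear gene in any
column of a target — the whole-genome fractionation statistic.
`region_similarity()` computes, for a durian column `dz` and cotton column
`gr`, the fraction of `gr`-filled reference positions also filled in `dz`,
and `similarity_profile()` evaluates all column pairs (3 x 5 in the full
scenario) with best-match means and best-minus-second margins.  The
diagnostic contrast: a shared post-ECH triplication with subsequent
no-loss evolution gives matched columns with similarity ≈ 1 and a large
margin, while independent DSH + GSD events give uniformly moderate
similarities (the retention probability) and a near-zero margin.

## Gene trees and the distortion analysis

`make_homolog_groups()` assembles per-locus groups of one grape gene
(outgroup), one cacao ortholog, ≥ 3 cotton and ≥ 2 durian genes.
`build_tree()` computes p-distances (Jukes–Cantor optional) on the codon
alignment, reconstructs NJ (or UPGMA) trees, roots on grape, and attaches
bootstrap percentages from codon-column resampling.  p-distance is the
default deliberately: it reproduces the model misspecification that makes
distance trees vulnerable to unequal rates.  `classify_topology()` assigns
the four types by the cacao gene's position — A: cacao sister to all
cotton+durian genes (the expected phylogeny); B: cacao inside the durian
cluster (the smallest clade containing cacao and every durian gene holds
no cotton gene); C: likewise for cotton; D: mixed.  The classifier is
total: exhaustive enumeration of all 10,395 labelled topologies at minimal
group size yields exactly one type each.  `cluster_pattern()` asks, over
clades with ≥ 70% support, whether all durian (or all cotton) genes form
an exclusive cluster (the independent-events signature) or durian and
cotton genes pair into mixed cherries (the shared-event, 1:1 signature).

On simulated groups with equal rates the expected type A dominates;
raising the duplicate-era rates of cotton and durian (1x, 2.5x, 5x with
150-codon genes) drives the non-A fraction up monotonically
(≈ 0.08 → 0.53 → 0.75 in the test conditions), reproducing the mechanism
by which rate elevation, not true history, dictates distance-tree
topology, and separate durian/cotton clusters far outnumber 1:1 pairings
throughout.

## Orchestration, determinism and problem sizes

`run_pipeline()` chains simulate/load → colinearity → Ks → fitting →
ploidy profiling → fractionation → correction/dating → trees, writes every
stage as TSV/JSON/SVG/Newick under one output directory, and records a
manifest (package version, seed, thresholds, stages completed).  In the
dating stage the oldest component of each genome's paralog-Ks mixture is
its ECH peak and a younger component counts as a lineage event only if it
sits below half the ECH peak; with no qualifying component the stage
reports that no post-speciation event was detected (the `no_event`
scenario).  All randomness flows from the single config seed, so reruns
are byte-identical.  A thin command-line wrapper (`inst/cli/ploidscan.R`,
dispatching through `cli_main()`) exposes `simulate`, `blocks`, `ks`,
`fit`, `date` and `run-all`.

Test and acceptance runs use 100–200 ancestral genes on 4 chromosomes
(600–1800 genes per polyploid genome), 500-codon genes, and 60–100
bootstrap replicates; these sizes put every Monte-Carlo assertion several
standard errors inside its band while keeping the whole suite around a
minute of CPU.  The depth-ratio results are modal counts and are exact at
these sizes; the recovery of event Ks-times is accurate to ≈ ±0.005 at
600-pair samples, well inside the ±0.02 contract.

## Known limitations

- The species topology is fixed at four taxa; the correction logic
  generalises conceptually (slowest lineage as reference, one outgroup
  contrast per accelerated lineage) but the implementation does not.
- The simulator's sequence model omits indels, codon-usage and rate
  heterogeneity; `align_codons()` handles real, gappy CDS pairs, but the
  fast Ks path assumes in-frame equal-length sequences.
- The linear Ks-to-age dating inherits all molecular-clock caveats; the
  correction aligns distribution means and cannot fix rate variation
  *within* a lineage's gene set.
- The chain-significance model is an approximation validated against
  permutation within a factor of ~3; for publication-grade p-values on
  real genomes a permutation test on the actual gene orders is preferable
  (`score_block_significance()` accepts any background you supply).
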