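---
title: "Methods: residue interaction networks for factor VIII"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: residue interaction networks for factor VIII}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fviiiRIN)
```

## The model

A residue interaction network (RIN) represents a protein structure as an
undirected, unweighted graph: one node per amino-acid residue, and an edge
between two residues whenever at least one pair of their heavy atoms lies
within a distance cutoff (default 5.0 Å). Edges are annotated by which
chain parts touch — main-chain/main-chain, main-chain/side-chain,
side-chain/side-chain — but these classes do not weight the graph; every
centrality is computed on the simple graph. For factor VIII (FVIII), the
nodes carry the legacy mature-protein numbering taken directly from the
author numbering of the PDB file, and the canonical domain architecture
(A1, a1, A2, a2, A3, C1, C2) is available as a node label.

The premise the package operationalizes is that graph position predicts
biological importance: residues with many contacts (degree), residues that
bridge otherwise separate parts of the fold (betweenness), and residues a
short distance from everything else (closeness) are the ones whose
substitution is most likely to destabilize the protein, reduce its
secretion, or abolish cofactor activity, and the ones most often seen
mutated in hemophilia A.

### Contact rule

Two residues interact when any heavy-atom pair is closer than the cutoff,
excluding atom pairs that are covalently bonded: the peptide-bond
C(i)–N(i+1) pair and disulfide SG–SG pairs closer than 2.5 Å. Hydrogens
are ignored throughout (heavy-atom convention): hydrogen placement is not
reproducible from most deposited structures, and the ~5 Å cutoff subsumes
typical hydrogen-mediated contact geometry. This distance rule replaces
probe-rolling contact detection (a ~0.25 Å probe on the van der Waals
surface, as done by RIN construction servers); the probe algorithm is not
specified in reproducible detail, so the package uses the simplest rule
with one interpretable parameter. The consequence is that edge counts on
real structures approximate, rather than equal, probe-based edge counts;
node counts are unaffected. The cutoff is configurable and recorded in the
network's provenance.

### Centrality measures

Seven measures are always computed per node:

* **degree** — neighbor count;
* **betweenness** — unnormalized Brandes pair-dependency counts on
  unweighted shortest paths, each unordered pair counted once (raw
  magnitudes, matching the igraph default);
* **closeness** — `(n_comp − 1) / Σ d(v, u)` within the node's connected
  component; isolated nodes get 0. Computing within the component avoids
  infinite distances while preserving ranking inside the giant component;
* **Burt's constraint** — neighborhood redundancy with `p_ij = 1/degree(i)`;
  undefined (NA) for isolated nodes, and NA rows are later removed by the
  classifier's missing-value rule;
* **PageRank** — uniform teleport, damping 0.85 (configurable);
* **k-core** — the largest k such that the node survives iterative
  peeling of degree-< k nodes;
* **HITS authority** — power iteration of the adjacency map from the
  uniform vector, max-normalized, tolerance 1e-12: deterministic, and on
  undirected graphs proportional to eigenvector centrality. Only the
  authority vector is computed (on an undirected graph the hub vector is
  identical).

The measures are substantially correlated on real structures;
`measureCorrelations()` reports the Pearson matrix so an analyst can see
the redundancy, but all seven are always computed — reducing to a subset
(degree, betweenness, closeness) is a downstream choice, not a gate.

### Criticality groups and super-critical residues

With quantile thresholds on degree and betweenness, residues fall into
high-degree/high-betweenness (HDHB), low-degree/high-betweenness (LDHB)
and low-degree/low-betweenness (LDLB) groups. Published figures of this
partition use hand-drawn regions without numeric thresholds, so the
package defaults to scale-free quantiles — high = 90th percentile, low =
50th — which approximate the published partition and are invariant under
rank-preserving rescaling; both are configurable. Quartile summaries use
the linear-interpolation convention (R type 7), recorded in the output
metadata.

*Super-critical* residues are the Pareto front of (degree, betweenness,
closeness): residues not weakly dominated (with at least one strict
inequality) by any other residue. Exact ties on all three measures keep
both residues — no arbitrary tie-break. The front is computed on the
largest connected component of the network, since closeness ranks are
only comparable within a component.

### Surface exposure

Per-residue solvent-accessible surface area (SASA) is computed with the
Shrake–Rupley quadrature: each heavy atom's sphere (van der Waals radius +
probe radius, default probe 1.4 Å) is sampled with a deterministic
golden-spiral point set (default 960 points/atom), and the accessible
fraction times the sphere area is the atom's contribution. Residue areas
are sums of atom areas, so they are additive by construction. Relative
exposure divides each residue's area by the reference area of the same
residue type in an extended Gly-X-Gly tripeptide (the shipped table is the
Tien et al. 2013 theoretical-maximum scale; the CSV can be swapped for an
empirical scale). Ratios are not clamped and can exceed 1 in extended
conformations.

A deliberate design choice: the package computes solvent-*accessible*
area, not the solvent-*excluded* area some visualization tools report.
SASA has a standard, independently testable algorithm, and the downstream
use — a monotone burial ranking — is insensitive to the choice. At 960
points the per-residue quadrature noise under rigid-body rotation is
roughly 1–2%; the invariance tests use 3840 points, where it is below 1%.

### Activity classifier

Alanine-scan mutant records are labeled High (> 50% of wild-type
chromogenic activity) or Low (< 50%); records exactly at 50% are assigned
Low by default (conservative: borderline constructs are treated as
impaired; configurable). Features are per-residue centralities (the seven
by default, configurable — published descriptions say only that "network
properties" were the inputs, so the package defaults to all of them and
lets degenerate columns fail loudly). Three members are trained: an
RBF-kernel SVM (gamma tuned), naive Bayes (nothing to tune), and
gradient-boosted trees (depth, learning rate, L2 penalty tuned). Model
selection is grid search under stratified 10-fold cross-validation,
maximizing mean fold Kappa with mean AUC as tie-break; normalization
parameters (z-score by default) are estimated on training folds only and
applied to the held-out fold, avoiding leakage. The default grids are
scaled down for speed (gamma in 0.05 steps to 1.5; odd depths 1–25;
learning rate 0.3 with the L2 penalty at 0 and 1); `classifierGrids(full
= TRUE)` gives the dense grids (gamma step 0.01, all depths, 0.1-step
lattices).

The ensemble prediction is the **median** of the three member
probabilities of the High class — the middle order statistic, always
bounded by the member outputs — with label High at median ≥ 0.5 and an
uncertainty flag when the median falls inside a closed band, default
[0.4, 0.6]. The band is an invention of this package (the behaviour it
implements is "flag mutations not clearly predicted either way") and is
reported in output metadata. Accuracy is reported both overall and on
unflagged instances.

### Clinical table sanitation and enrichment

Raw hemophilia A mutation exports carry free-text activity strings. The
sanitizer applies, in order: keep Point/Polymorphism + Missense records;
drop signal-peptide/out-of-mature positions (legacy position outside
1–2332); drop any record with a reported activity above 100; substitute
the bound markers "> 5"→5, "< 10"→10, "< 11"→11, "< 1"→0 (implemented
literally as published, including the odd direction of the "> 5" rule —
it caps values above 5); replace ranges "a to b" by their midpoint unless
the endpoints fall in different severity bands (severe < 1, moderate 1–5,
mild > 5–40 FVIII:C), in which case the range is an ambiguous diagnostic
and the record is dropped; finally drop non-numeric leftovers (including
unlisted "< x" markers), records missing activity, records whose two
assay columns disagree, stop codons, and ambiguous severity strings
("mild/moderate"). Parsing tolerates irregular and non-breaking spacing.
Every removed record is logged once with its rule, so input count =
output + exclusions and the operation is idempotent. The severity bands
are configuration constants used only for the ambiguity rule, never to
re-derive severity.

Positional enrichment uses Fisher's exact test on the 2×2 table {group} ×
{position has ≥ 1 reported mutation, has none}, with the sample
cross-product odds ratio (Inf markers on zero cells). HGVS numbering is
legacy + 19 (the signal peptide).

## The synthetic generators

The generators exist so that every stage can be tested against known
ground truth; their defaults are the study conditions used by the
acceptance checks and were fixed before those checks were run.

* **Structures.** Ideal backbones built by natural-extension-reference-
  frame chaining with standard bond geometry (N–CA 1.458 Å, CA–C 1.525 Å,
  C–N 1.329 Å, C=O 1.231 Å) at α-helical (φ = −57°, ψ = −47°) or extended
  (φ = −139°, ψ = 135°) torsions; `two_domain` places two helices on
  separate chains with a controllable spatial gap (default 40 Å: zero
  inter-domain contacts at 5 Å, hence ≥ 2 network components). Each
  non-glycine residue gets a single pseudo side-chain atom 2.4 Å from the
  Cα pointing outward — enough to exercise main-chain/side-chain edge
  typing without rotamer modelling. Residue types are drawn
  deterministically from the seed unless a sequence is supplied. An ideal
  helix yields the characteristic (i, i+1), (i, i+3), (i, i+4) contact
  pattern.
* **Activity tables.** P(Low) = logistic(β · z) with z the z-scored value
  of a chosen centrality (β = 4 on closeness under the default study
  conditions; β is the planted effect). Activity percentages are drawn
  from triangular distributions — mode 10 on [0, 50] for Low, mode 90 on
  [50, 100] for High — so the 50% rule sees realistic spread. Each table
  records the per-instance Bayes probability and Bayes-optimal label; the
  achievable (Bayes) accuracy computed from these is what the recovery
  thresholds were derived from (≈ 0.91 at β = 4, comfortably above the
  0.80 acceptance threshold).
* **Clinical tables.** Positions acquire reports with odds multiplied by
  the planted enrichment (default 3×) inside a designated harmful set;
  records are distributed over reported positions, and seven messy rows
  (range, bound marker, ambiguous severity, stop codon, > 100 value,
  boundary-spanning range, non-numeric) are planted at recorded row ids so
  the sanitation log can be checked exactly.

What the generators do *not* emulate: real packing heterogeneity (every
helix residue has nearly identical contacts, so k-core is constant and is
excluded from the recovery experiment's features by the zero-variance
rule), rotamer-level side-chain geometry, experimental noise structure in
activity assays, and the correlated reporting biases of real clinical
databases. Passing the synthetic checks therefore demonstrates that the
algorithms are implemented correctly and recover planted signals at
realistic sizes — not that the biological claims transfer to arbitrary
proteins.

## Problem sizes and numerical choices

The recovery experiments use a 400-residue structure with one mutant per
residue and ten label redraws (and ten null redraws), clinical tables of
500 records over 400 positions with a 100-position harmful set and 100
replicates per condition, and oracle-equivalence sweeps over 50 random
graphs of up to 40 nodes and 200 random 50-point Pareto tables. These
sizes keep a full run on a single CPU in minutes while leaving the
statistical checks well-powered.

Deterministic details: power iterations stop at 1e-12 (PageRank via
igraph's exact solver; HITS in-package); altloc conformers resolve to the
highest occupancy with ties broken by altloc letter; quantiles and
quartiles use linear interpolation; Wilcoxon tests are exact for tie-free
groups of ≤ 25 and tie-corrected normal otherwise, with p = 1 returned
for degenerate all-equal inputs; k-fold assignment is stratified and
seeded; xgboost runs single-threaded, making every fit reproducible.

## Known limitations

* The contact rule is a distance cutoff, not probe contact: edge counts
  on deposited structures are approximate (node counts are exact).
* SASA is accessible, not excluded, area; relative exposures differ in
  level (not in ranking) from excluded-area pipelines.
* The starter binding-site file is deliberately minimal; a full curation
  must be supplied by the user.
* Conservation scores are accepted only as a precomputed per-residue
  column; the package never queries external servers.
* The classifier's reported performance on synthetic data bounds nothing
  about real alanine-scan tables, which are external to this package.
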