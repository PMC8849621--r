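---
title: "Methods and modelling choices in cladomorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and modelling choices in cladomorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cladomorph)
```

`cladomorph` packages the quantitative toolkit used when describing
fragmentary theropod skeletons: parsimony cladistics on merged morphological
matrices, PCA-based morphometric comparison of teeth and unguals, dentary
alveolus profiling, and seriation of associated caudal vertebrae by the
Anterior Surface Index (ASI). This vignette records the models, conventions
and numerical choices behind each module — the decisions a reader needs in
order to know exactly what a reported number means and what a passing test
does and does not establish.

## 1. Character matrices

A `character_matrix` stores taxa × characters of discrete states. Cells are
*state sets*: a singleton is an ordinary observation, a larger set a
polymorphism, and two special values mark **missing** (`?`) and
**inapplicable** (`-`) data. The two specials are kept distinct so files
round-trip exactly, but both are scored as "any state": mainstream parsimony
programs treat gaps as missing by default, and the matrix-merging protocols
this package supports give no contrary instruction.

Conventions worth knowing:

* **User-facing character indices are 1-based** ("Character 180" style, as in
  published character lists). TNT `ccode` commands inside files use TNT's
  0-based indices; the parser translates.
* `ccode`/`TYPESET` ordering flags, activation and weights are parsed,
  honoured in bookkeeping, and written back out. **Ordered (additive)
  characters are nevertheless scored as unordered**: step matrices are out of
  scope, and none of the supported workflows state ordering assumptions. The
  flag is preserved so no information is lost on round-trip.
* `merge_matrices()` refuses taxon sets that differ, rather than silently
  intersecting. Matrix-merge protocols (drop redundant characters, drop taxa
  absent from the other source, then merge) are full of judgement calls, and
  forcing the harmonisation step to be explicit keeps each deletion visible
  and auditable. The pipeline's `merge_with` option performs the intersection
  explicitly and logs it.

## 2. Parsimony engine

### Scoring

Tree length is the minimum number of state changes over all internal-node
assignments, summed over active characters × weights. The implementation is
Hartigan's generalisation of Fitch optimization: at each node, each state
receives one vote per child whose state set contains it; the node keeps the
maximal-vote states and adds (children − max votes) steps. This is exact for
unordered multistate characters **on polytomies as well as binary nodes**, so
consensus trees are scored as given, never secretly resolved. Missing and
inapplicable cells contribute the union of states observed in the character.
Identical character patterns are pooled with summed weights before scoring —
a pure speed optimisation with no effect on results (tested).

### Ensemble indices

With `L` the observed length, `CI = M/L` and `RI = (G−L)/(G−M)`:

* `G` (`max_steps`) is the character's length on the star tree: scored cells
  minus the frequency of the most common state, a polymorphic cell counting
  toward every state it contains. This is the exact star-tree length under
  any-of scoring, so `L ≤ G` always.
* `M` (`min_steps`) is the smallest length *any* tree could achieve. With
  fixed cells only this is (distinct observed states − 1). With polymorphic
  cells the exact minimum is (size of the smallest state set hitting every
  scored cell) − 1, found by subset enumeration over the observed states
  (at most a handful, so this is cheap). We use the exact form because the
  plausible alternative — counting a polymorphic cell toward every state —
  can exceed the true minimum and break the defining invariant `M ≤ L`,
  which would allow CI > 1.

Whether published CI/RI values include parsimony-uninformative characters is
often unstated; both variants are available
(`parsimony_stats(..., informative_only = )`), with all-active-characters as
the default (the common TNT convention).

### Search

`heuristic_search()` runs random-addition-sequence replicates followed by
branch swapping (NNI, SPR, or TBR = SPR with re-rooting of the pruned
subtree) to a local optimum, holding up to `hold` equally parsimonious trees
per replicate and pooling across replicates. Topological identity is decided
by canonical bipartition sets, so rooting artifacts cannot duplicate trees.
Every returned tree is re-scored and asserted equal to the reported length
before the function returns. All randomness flows from one integer seed;
identical seeds give byte-identical output. MPT *counts* additionally depend
on zero-length-branch collapsing rules that differ between programs, so tree
length — not tree count — is the reliable cross-program quantity; treat
counts as diagnostics.

### Consensus, agreement, supports

* `strict_consensus()` builds the tree whose internal edges are exactly the
  intersection of the input trees' bipartition sets (tested against that set
  algebra and against an independent implementation).
* `agreement_subtree()` is exact (largest-first subset enumeration) up to 12
  leaves; beyond that a deterministic greedy leaf-elimination heuristic runs,
  and the output is flagged `"exact"` or `"greedy"` accordingly.
* `bootstrap_support()` resamples characters with replacement and counts, per
  replicate, the *fraction* of that replicate's equally parsimonious trees
  containing each bipartition (Felsenstein's frequency convention). We chose
  fractional counting over "present in the replicate's strict consensus"
  because consensus counting under-credits symmetric conflicts: with two
  equally supported resolutions, tied replicates have an unresolved consensus
  and both supports land near 39% rather than the expected 50%. The default
  of 1000 replicates at reduced search effort (10 additions, SPR) is
  configurable.
* `bremer_support()` performs one reverse-constraint search per consensus
  clade (trees containing the clade are inadmissible) with the same search
  machinery; decay = constrained optimum − `L`, capped and flagged at
  `max_decay`. On small cases this is verified against exhaustive topology
  enumeration.

### Synapomorphies

`map_synapomorphies()` runs a unit-cost Sankoff dynamic program per character
(inside costs by postorder, outside costs by preorder), which yields exactly
the set of states each node takes across *all* most-parsimonious
reconstructions. A change is reported **unambiguous** when constraining the
edge's two endpoints to share a state forces extra steps — i.e. the change
occurs in every reconstruction; this is verified against explicit enumeration
of all optimal assignments in the tests. ACCTRAN/DELTRAN modes resolve ties
in a preorder walk (accelerate: prefer a change at the current edge; delay:
keep the parental state when optimal) and report one concrete reconstruction,
labelled with the convention used.

## 3. Morphometrics

* Crown ratios (`CBR = CBW/CBL`, `CHR = CH/CBL`) are recomputed from raw
  measurements, never stored, so they can never drift out of sync; both are
  dimensionless and unit-invariant.
* `run_pca()` defaults to **covariance of raw measurements**. Tooth and
  ungual tables are dominated by overall size, and a covariance PCA on raw
  values is what concentrates >90% of variance on PC1 as published analyses
  of such tables report; correlation and log-covariance scalings are exposed
  for sensitivity checks. Loadings are signed so the largest-magnitude
  loading per component is positive — reproducible, but remember that only
  *relative* signs are meaningful.
* "Within the range of variability of taxon X" is operationalised as
  membership (boundary inclusive) in the convex hull of X's (PC1, PC2)
  scores. This is an interpretation of what is usually a visual claim; with
  fewer than 3 non-collinear points the hull is degenerate and the function
  falls back to a PC1 interval test, flagged in the output.
* `nearest_specimen()` z-scores curvature (degrees) and length (mm) before
  computing Euclidean distance, since the axes are incommensurable; ties
  break toward the smaller row index, deterministically. The curvature
  measurement protocol itself is upstream of this package — curvature is
  consumed as a given column.
* Alveolus profiles report labiolingual/mesiodistal diameter ratios and the
  mean of labial and lingual dentary heights per socket position.

## 4. Caudal seriation (ASI)

`ASI = anterior facet area / centrum length²` is dimensionless; the tests
include explicit unit-invariance properties. When a table supplies facet
diameters rather than areas, the facet is modelled as an **ellipse**
(`π·dv·ml/4`; centrum facets are sub-elliptical). The model choice rescales
all ASIs in a series by one shared constant, so `%ASI` — the quantity the
seriation actually uses — is provably model-invariant, and this invariance is
tested rather than assumed.

Seriation is: anchor (the qualitatively identified anteriormost vertebra,
taken as input — anatomical judgement is not inferred) first, then descending
ASI, ties broken by descending centrum length then id, with ties logged.
`%ASI` values are reported rounded to integers (the conventional precision)
with full precision retained.

Template position assignment is formalised as a monotone nearest-`%ASI`
alignment: choose strictly increasing template positions minimising the total
absolute `%ASI` discrepancy, subject to every diapophysis-bearing vertebra
sitting at or before the template's last-diapophysis upper bound
(`diapophysis_bounds()` ships the published comparative table:
*Dilophosaurus* 17, *Spinosaurus* 16–19, *Concavenator* 19–20,
*Majungasaurus* 25, *Gorgosaurus* 12, *Tyrannosaurus* 17). The alignment is
solved by dynamic programming and tested against brute-force enumeration on
all instances with ≤ 8 vertebrae; infeasible constraint systems raise an
error rather than silently violating a constraint. Only the *presence* of a
diapophysis constrains: absence may be taphonomic (broken processes), so it
is deliberately uninformative.

## 5. Synthetic data: what the generators emulate

The generators provide the statistical structure each stage assumes, with
known ground truth:

* `simulate_matrix()` — characters evolved on a known tree. Homoplasy-free
  mode places exactly one change per character on a branch drawn
  proportionally to branch length; this yields the analytic anchors
  `L(true tree) = n_characters` and `CI = 1`, tying the generator to the
  scoring engine without any substitution-model machinery. Poisson mode
  draws per-branch change counts at a configurable rate over a k-state
  space, producing controllable homoplasy; missing cells are masked
  uniformly at random.
* `simulate_caudal_series()` — geometric ASI decay (default 0.92/position,
  anchor ASI 0.9, ~90 mm anterior centrum: values in the range seen in
  stout-tailed large theropods) with lognormal multiplicative noise
  (positivity- and unit-preserving), a fixed dorsoventral:mediolateral facet
  aspect of 1.15, and a diapophysis cutoff position. The default 5% noise
  level in tests matches realistic measurement + individual variation for
  associated vertebrae.
* `simulate_measurements()` — per-group multivariate normals multiplied by a
  shared lognormal size factor; the shared factor is what produces the
  size-dominated PC1 (≥ 90% variance in the tests) typical of real tooth
  tables. Positivity is enforced by rejection sampling.

What a green test does **not** establish: the generators make no attempt to
mimic real morphological correlation structure (character non-independence,
ontogenetic allometry, taphonomic missingness patterns are all absent), so
passing recovery tests demonstrate algorithmic correctness, not robustness to
real-data pathologies.

## 6. Numerical conventions and degenerate inputs

* Percentages and ratios are reported at conventional precision (integers
  for %ASI, 2 decimals for crown ratios, 3 for CI/RI) with full precision
  retained in the objects.
* `ensemble_indices()` reports `NA` with an explanatory note when `L = 0`
  (all characters constant) or `G = M` (no potential homoplasy), rather than
  dividing by zero.
* Equality comparisons in search pooling use an absolute tolerance of 1e-9
  to be safe under fractional character weights; with integer weights all
  lengths are exact integers.
* Every stochastic function takes an explicit integer seed and is
  byte-reproducible; the pipeline echoes config + seed into its report so
  any reported number can be regenerated.

## 7. Known limitations

* No molecular data, no step matrices/ordered scoring, no implied weighting,
  no likelihood or Bayesian inference.
* The greedy agreement-subtree path (> 12 leaves) is a heuristic; its output
  is labelled and should be treated as a lower bound on agreement.
* ACCTRAN/DELTRAN tie resolution is the local preorder rule described above;
  it always yields a most-parsimonious reconstruction (asserted in tests),
  but other programs may pick a different member of the optimum set.
* Heuristic search carries the usual caveat of local optima; the defaults
  (10 random addition sequences, TBR) are sized for matrices of a few dozen
  taxa, and the admissibility assertion guards only against scoring bugs,
  not against an undiscovered global optimum.
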