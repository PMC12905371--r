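---
title: "Leakage-aware dataset splitting: model, solver and design notes"
author: "leakSplit maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Leakage-aware dataset splitting: model, solver and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leakSplit)
```

## The problem

Benchmarks for molecular property prediction, protein-ligand binding and
protein-protein interaction (PPI) prediction are routinely inflated by
*information leakage*: near-identical molecules or homologous protein
sequences end up on both sides of the train/test boundary, so a model can
score well by memorizing rather than generalizing. leakSplit does two
things about this:

1. it **scores** any given split with a scaled leakage statistic in
   [0, 1], so published splits and automatic splits can be compared on the
   same similarity matrix; and
2. it **produces** splits that minimize that statistic, for a single
   entity type (the S1 mode) or jointly for the two sides of an
   interaction dataset (the S2 mode).

## The leakage score

For entities $i$ with weights $w_i$, pairwise similarities
$s_{ij} \in [0,1]$ and a split assignment $\pi$, the scaled leakage is

$$
L(\pi) \;=\;
\frac{\sum_{i<j,\; \pi(i) \ne \pi(j)} w_i w_j s_{ij}}
     {\sum_{i<j} w_i w_j s_{ij}},
$$

the fraction of the weighted pairwise similarity mass that crosses a
split boundary. Conventions: self pairs never count; unordered pairs are
used (for symmetric $s$ the ratio is the same either way); $0/0$ is 0;
entities marked `UNASSIGNED` are dropped from both numerator and
denominator, and the assigned fraction is reported alongside so discarded
information stays visible. Uniform weights cancel. The formula lives in
exactly one function (`scaledLeakage()`) so a different normalization or
weighting can be swapped in at a single point if a different definition
of the score is preferred.

Two properties make the score interpretable:

* For a *homogeneous* dataset (all off-diagonal similarities equal) and
  unit weights, $L$ depends only on the split-size fractions
  $f_k$: $L = 1 - \sum_k f_k (f_k n - 1)/(n - 1)$, which approaches
  $1 - \sum_k f_k^2$ for large $n$. A random 80/10/10 split therefore
  scores about 0.34 no matter the dataset — the familiar baseline value
  for random splits of large benchmark collections.
* $L = 0$ iff no similarity mass is shared between splits; $L = 1$ iff
  all of it is.

`maxInterSplitSimilarity()` complements the aggregate score with the
constraint-style check used by hand-curated splits ("no more than 50%
sequence identity between training and any other split").

## Similarities

* **Sequences**: Needleman-Wunsch global alignment identity, defined as
  identical aligned residue pairs over the alignment length (gap columns
  included). Default scoring is match +1, mismatch −1, linear gap −2 — a
  deliberately simple scheme whose DP table can be checked by hand; it is
  configurable via `alignmentScoring()`. The identity denominator
  (alignment length rather than shorter-sequence length) and the gap
  penalties are declared choices, not community standards; both matter
  near a threshold. The DP traceback prefers diagonal over up over left,
  so exactly one optimal alignment is reported; tied optima can have
  different identities, and this tie-break pins down which one you get.
  The alignment kernel is implemented in C++ (Rcpp); tests cross-check
  its scores against `Biostrings::pairwiseAlignment()`.
* **Molecules**: Morgan (extended-connectivity) fingerprints via
  OpenBabel/ChemmineOB, compared with Tanimoto ($|A \cap B|/|A \cup B|$,
  the ECFP4 convention) or Dice ($2|A \cap B|/(|A|+|B|)$). ECFP4 is
  radius 2, 2048 bits — the defaults. OpenBabel hashes these fingerprints
  at fixed diameters (0/2/4/6/10) into 4096 bits, which we fold to
  `nBits` by index modulo; supported radii are therefore 0, 1, 2, 3
  and 5. The binary variant is used (the count variant is a known
  alternative; binary is assumed here). Two empty bit sets count as
  identical (similarity 1); empty versus non-empty scores 0. For every
  pair, Tanimoto $= d/(2-d)$ where $d$ is Dice, hence Tanimoto ≤ Dice.
* **Anything else** (structure-based similarities, precomputed
  clusterings): supplied as a precomputed matrix. Values are clipped into
  $[0,1]$ only when within $10^{-6}$ of the range and the diagonal is
  snapped to 1 under the same tolerance; larger violations are rejected,
  because silent clipping hides data errors.

## Clustering

`clusterByThreshold()` builds the graph with an edge wherever
$s_{ij} \ge t$ and takes connected components (single linkage). Single
linkage is the default because it gives the guarantee the whole package
is about: after clustering, *no pair of entities at or above the
threshold can ever straddle a split boundary*, whatever the solver does.
Complete linkage is available for users who prefer compact clusters over
that guarantee. Inter-cluster similarity is aggregated by the maximum
(a bound on the worst single leak) or by the mean; the mean makes the
cluster-level total-leak objective *exactly* equal to the entity-level
cross-cluster similarity mass under unit weights, so it is the natural
partner of the `"total"` objective, while `"max"` pairs with the min-max
objective. Clusters are ordered by decreasing weight (ties by smallest
member id) so solver runs are reproducible. The threshold has no magic
default at the API level: it is data- and metric-dependent (0.8 identity
for the sequence fixtures, 0.5 Tanimoto for the molecule fixtures used
in the tests; the CLI defaults to 0.5).

## The solver

`solveS1()` assigns whole clusters to splits subject to
$|\hat f_s - f_s| \le \varepsilon$ for every split $s$ (realized versus
target weight fraction; default $\varepsilon = 0.05$), minimizing either

* `"total"` — the summed cross-split cluster-pair mass
  $w_c w_d \, s_{cd}$, reported scaled to $[0,1]$; or
* `"max"` — the largest single inter-split cluster-pair similarity
  (min-max), matching the constraint-style philosophy of hand-curated
  splits.

While the search space (splits^clusters) stays within `exactNodes`
(default $2^{21}$), a branch-and-bound enumeration in C++ finds the true
optimum, with ties broken lexicographically (cluster order, then split
order) so equally optimal instances always return the same answer. The
bound prunes on the partial objective, on split capacity, and on whether
the remaining weight can still fill every split's lower bound. Beyond
`exactNodes` a deterministic heuristic runs: greedy seeding (largest
cluster into the split with the largest remaining target weight)
followed by steepest-descent single-cluster moves on a penalized
objective, with seeded random restarts. The search-space cap (rather
than a fixed cluster count) is used because enumeration cost depends on
both the number of clusters and the number of splits. Either way, the
returned assignment is *re-checked* against the fraction windows and
stratification constraints — solver output is verified, not trusted.

Stratification (`solveS1Stratified()`) additionally requires each
label's share within every split to sit within `stratifyTolerance` of
its global share — e.g. keeping positive and negative interactions
balanced. A label wholly contained in one cluster is reported as the
reason when this is infeasible.

### Two-dimensional splits

`solveS2()` jointly assigns the clusters of both interaction dimensions.
An interaction is kept in split $S$ iff both endpoints land in $S$
(`induceInteractionSplit()`); everything else is returned as discarded,
never silently dropped. The objective is the sum of the two dimensions'
scaled leakages, equally weighted by default (`dimWeights` exposes the
balance because no principled universal weighting exists). Fraction
targets are measured in kept interaction rows — what downstream training
actually consumes — rather than entity weight, and every split must keep
at least one interaction. The exact path enumerates the joint space
(vectorized) while splits^(clustersA+clustersB) ≤ `exactNodes`; beyond
that a penalized local search over the joint assignment runs with seeded
restarts.

The alternative route for PPI data — where the two dimensions share one
entity type — is `weightedUnionReduction()`: pool the proteins of both
columns, weight each by the number of interactions it participates in,
run S1 on the pooled set, then induce the interaction split. Full
assignment is the default; the package does not leave entities
unassigned to lower the score (an `UNASSIGNED` label is honored when
scoring external splits).

## Baselines

`randomSplit()` (seeded shuffle, largest-remainder rounding with ties in
split order), `stratifiedSplit()` (random split independently per label
stratum; strata smaller than the split count warn and fall back to
best-effort), and `scaffoldSplit()` (Bemis-Murcko scaffolds). The
scaffold convention is the common deterministic greedy fill: groups
sorted by size descending (ties by canonical scaffold key), filled into
splits in spec order until each split reaches its largest-remainder
count target; no group ever straddles splits, so a dominant scaffold can
leave later splits empty (warned, mirroring what scaffold splits do to
skewed real datasets). Acyclic molecules form one shared empty-scaffold
group rather than singletons, matching common practice.

Scaffolds are computed by iteratively pruning degree-1 atoms from the
OpenBabel-parsed molecular graph (leaving ring systems plus linkers) and
canonicalized as a colored-graph key via igraph's BLISS canonical
permutation, with bond orders encoded as colored edge-subdivision
vertices. The key is a canonical string, not a SMILES; two molecules
share a key iff their scaffold graphs are isomorphic as element- and
bond-order-colored graphs, which is exactly what the splitter needs.

## Synthetic data

The generators exist so every claim above is testable without external
downloads, and their defaults define the package's test conditions:

* `generateSequenceFamilies()` plants families from family-specific
  sub-alphabets (disjoint across families while the 20-letter alphabet
  allows), then substitutes each position independently with probability
  `withinDivergence` (default 0.05, length 120). At that divergence,
  pairwise within-family identity concentrates near 0.9, comfortably
  above the 0.8 clustering threshold used in the tests, while
  cross-family identity stays near the mutation floor — so the planted
  partition is unambiguous. No indels are generated: the model controls
  identity structure, not realistic evolution.
* `generateMoleculeFamilies()` decorates one of 24 built-in multi-ring
  scaffolds per family with 1-2 small substituent chains. Multi-ring
  systems are used deliberately: they dominate the hashed fingerprint
  bit set, so family members are measurably more similar than
  cross-family pairs, giving the solver real structure to exploit.
* `generateInteractionNetwork()` samples positives uniformly at the
  requested density and negatives by configuration-model stub matching,
  so every entity's negative degree equals its positive degree exactly —
  the degree-preserving negative sampling used by curated PPI
  benchmarks. Collisions are rejected and the pass restarts; a positive
  draw that admits no simple degree-preserving negative set (a hub
  interacting with nearly every counterpart) is redrawn. Exact two-sided
  preservation fixes the positive:negative ratio at 1:1, which is why
  the generator takes no positive-fraction parameter.

What passing tests on these fixtures do **not** show: real datasets have
similarity structure far messier than planted families (fuzzy family
boundaries, hubs, similarity metrics that disagree), and the magnitude
of the leakage reduction observed on fixtures does not transfer.
The *direction* of the effect — optimized splits leaking no more than
random or scaffold splits on the same matrix — is the tested claim.

## Numerical choices and degenerate inputs

* Matrix validation: symmetry within $10^{-9}$, unit diagonal, values in
  $[0,1]$; precomputed inputs get the $10^{-6}$ clip-or-reject rule.
* Weight conservation in clustering is asserted to $10^{-9}$.
* Solver feasibility comparisons carry a $10^{-9}$ slack so window
  boundaries are not lost to floating point.
* Degenerate cases: an all-unassigned scoring request, an empty split in
  `maxInterSplitSimilarity()`, a cluster heavier than every split
  capacity, a label trapped in one cluster, and a saturated interaction
  network all raise typed errors (`leakSplit_invalid_input`,
  `leakSplit_infeasible_error`, ...) rather than returning NAs; the CLI
  maps infeasibility to exit code 1 and input errors to exit code 2.

## Scales used in the shipped tests

The test-suite and the acceptance script run at deliberately small
scales chosen to exercise every code path: leakage-oracle comparisons on
200 random instances with up to 50 entities; solver-versus-enumeration
on 50 instances with 6-10 clusters and 2-3 splits; dominance checks on
20 planted-family fixtures (40-60 entities each); 100 family-recovery
runs; 50 generated networks. These sizes are the package's own test
design; the solver itself handles much larger instances through the
heuristic path.

## Known limitations

* Pairwise similarity computation is $O(n^2)$ with no sketching or
  pre-clustering; beyond ~$10^4$ entities, compute the matrix externally
  and use the precomputed pathway.
* Structure-based similarity (FoldSeek/MMseqs clusterings, pocket
  pharmacophores, interaction fingerprints) is out of scope; feed such
  similarities in as precomputed matrices.
* The exact solver's optimality guarantee stops at `exactNodes`; the
  heuristic carries no approximation bound (its outputs are still
  feasibility-checked).
* Fingerprint radii are limited to OpenBabel's diameters, and hashed
  fingerprints of small fragments collide; scaffold-level identity uses
  the exact graph key, not fingerprints, for that reason.
* Temporal splits and topology-annotation splits are not implemented;
  they are external baselines, not leakage-minimizing procedures.
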