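# leakSplit

Leakage-aware train/validation/test splitting — and split scoring — for
molecular and protein-sequence datasets.

## The problem

Benchmarks in cheminformatics and protein science are routinely inflated
by **information leakage**: near-duplicate molecules or homologous
sequences sit on both sides of the train/test boundary, so models score
well by memorization. leakSplit addresses both halves of the problem:

* **Scoring.** Any split assignment π is scored with the scaled leakage

  L(π) = Σ<sub>i&lt;j, π(i)≠π(j)</sub> w<sub>i</sub>w<sub>j</sub>s<sub>ij</sub> / Σ<sub>i&lt;j</sub> w<sub>i</sub>w<sub>j</sub>s<sub>ij</sub> ∈ [0, 1],

  the fraction of the weighted pairwise similarity mass that crosses a
  split boundary. A random 80/10/10 split of a homogeneous dataset
  scores ≈ 1 − Σ f<sub>k</sub>² = 0.34; a perfectly cold split scores 0.
  The largest single inter-split similarity ("max single leak") is
  reported alongside.

* **Splitting.** Entities are clustered at a similarity threshold
  (single-linkage components, so no pair at or above the threshold can
  straddle a boundary) and whole clusters are assigned to splits,
  minimizing either the total leaked mass or the maximum single leak,
  subject to split-size windows (±ε) and optional label stratification.
  Small instances are solved exactly (branch and bound); larger ones by
  a seeded deterministic heuristic. One-dimensional datasets use
  `solveS1()`; interaction datasets (drug-target, protein-protein) use
  `solveS2()`, which assigns both dimensions jointly and keeps an
  interaction only when both endpoints share its split.

Similarity metrics built in: Needleman-Wunsch global alignment identity
for sequences, Morgan/ECFP fingerprint Dice and Tanimoto for molecules
(via OpenBabel), and a validated precomputed-matrix pathway for anything
else (structure-based similarities, external clusterings). Reference
baselines — random, stratified, and Bemis-Murcko scaffold splits — are
included so optimized splits can be compared against the field's
conventional techniques, plus synthetic-data generators (planted
sequence/molecule families, bipartite interaction networks with
degree-preserving negatives) that make the whole pipeline testable
offline.

## Worked example

Five planted sequence families, split 80/20 by the exact solver, then
compared against a random split on the same similarity matrix:

```r
library(leakSplit)

fam  <- generateSequenceFamilies(5, 8, withinDivergence = 0.05,
                                 length = 80, seed = 42)
m    <- buildSimilarityMatrix(fam, "nw-identity")
cs   <- clusterByThreshold(m, 0.8, aggregation = "mean")
spec <- splitSpec(c(train = 0.8, test = 0.2), epsilon = 0.1, seed = 42)

s1 <- solveS1(cs, spec)
scaledLeakage(m, s1)
#> LeakageReport: scaled total leakage 0.0083, max single leak 0.0370
#>   assigned fraction: 1.000
#>   leaked mass per split pair:
#>     train ~ test: 1.084

scaledLeakage(m, randomSplit(fam, spec))
#> LeakageReport: scaled total leakage 0.3117, max single leak 0.9375
#>   assigned fraction: 1.000
#>   leaked mass per split pair:
#>     train ~ test: 40.64
```

Reading the numbers: the random split leaks 31% of the similarity mass
across the boundary and places a 94%-identical sequence pair on opposite
sides; the optimized split leaks 0.8% and its worst cross-split identity
is 3.7% — the clusters (here, exactly the five planted families) never
straddle the boundary, so only the weak cross-family similarity leaks.

The same workflows are available from the shell via the installed
`exec/leaksplit.R` script:

```sh
leaksplit=$(Rscript -e 'cat(system.file("exec", "leaksplit.R", package = "leakSplit"))')
Rscript "$leaksplit" simulate --what sequences --out fixtures --seed 1
Rscript "$leaksplit" split1d  --input fixtures/sequences.fasta --format fasta \
        --cluster-threshold 0.8 --splits train=0.8,test=0.2 --seed 1 --out run
Rscript "$leaksplit" score    --input fixtures/sequences.fasta \
        --assignment run/assignment.tsv --out scored
```

Exit codes: 0 success, 1 infeasible optimization problem, 2 input error.

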