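---
title: "kmerforest: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{kmerforest: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

kmerforest classifies genomic intervals as accessible (open) or
inaccessible (closed) chromatin from sequence alone, and then reuses the
trained classifier's feature importances to score single-nucleotide
variants (SNVs). The pipeline has two stages.

**Stage 1 — classification and k-mer importance.** Every interval of
length $L$ is converted into a k-mer count vector
$f^s = (x_1^s, \dots, x_n^s)^T$ with $n = 4^k$: a width-$k$ window slides
by one base, giving $L - k + 1$ windows, and each window increments its
k-mer's count (windows containing a non-ACGT base are skipped entirely, so
the counts always sum to the number of valid windows). A random forest of
full-depth, unpruned CART trees is trained on these vectors: each tree is
grown on a bootstrap resample of the full training-set size (so a sample
may be drawn more than once), with Gini impurity splits over
$\lfloor\sqrt{n}\rfloor$ randomly subsampled features per split. The
samples a tree did *not* draw — its out-of-bag (OOB) set — form a built-in
held-out set per tree.

The importance of k-mer $j$ is its **mean decrease accuracy (MDA)**:

$$\mathrm{MDA}_j = \frac{1}{B} \sum_{b=1}^{B}
  \left( \mathrm{acc}_b - \mathrm{acc}_{b,j} \right),$$

where $\mathrm{acc}_b$ is tree $b$'s accuracy on its own OOB samples and
$\mathrm{acc}_{b,j}$ its accuracy after the values of feature $j$ are
permuted among those OOB samples. Sorting all $4^k$ MDA scores
(descending, ties broken by ascending feature index, i.e. lexicographic
k-mer order) yields the k-mer importance ranking.

**Stage 2 — variant scoring.** A substitution at one position alters only
the at most $k$ windows that overlap it. For each aligned (ref, alt)
window pair the contribution is
$\delta_w = \mathrm{MDA}(\text{alt k-mer}) - \mathrm{MDA}(\text{ref k-mer})$,
and the variant is summarized by three aggregates: `score_abs`
$= \sum_w |\delta_w|$ (the default ranking key — disruption regardless of
direction, paralleling how SVM-weight-difference scores are used),
`score_signed` $= \sum_w \delta_w$ (retains effect direction), and
`score_mean_abs` (`score_abs` per contributing window, the "average score"
form). The text the method derives from defines the score only as the
accumulated change over affected k-mers and elsewhere plots an average
score, so all three are computed and the choice is a documented default
rather than a claim about the original; `score_signed` is the one that
exactly equals the full-sequence feature-difference
$\sum_j \mathrm{MDA}_j (x_j^{alt} - x_j^{ref})$, which the test suite
verifies by brute-force recounting.

**Conservation weighting (kmsa mode).** Functional sequence is under
purifying selection, so a per-base conservation frequency
$fre \in [0,1]$ (how often the human base appears at the aligned position
across species) can refine the counts. Each occurrence of k-mer $i$
contributes the mean conservation of its $k$ bases instead of 1:

$$x_i^{s*} = \frac{1}{k} \sum_{j=1}^{x_i^s} \sum_{q=1}^{k} fre_{q,j},$$

so $0 \le x_i^{s*} \le x_i^s$ with equality iff every touched $fre$ is 1.
Uncovered track positions default to $fre = 1$, which makes missing
conservation data degrade conservation mode exactly to count mode (the
default is configurable).

## Tunable parameters

| parameter | default | notes |
|---|---|---|
| `k` | 6 | word length; the feature space is $4^k$ (dimension exceeds one million at $k = 10$), and a sensible working range for DNA is roughly 4–10. 6 balances expressiveness against sparsity at benchmark sample sizes. |
| `rc_collapse` | `FALSE` | whether a k-mer and its reverse complement share one feature. Off by default so the dimension is exactly $4^k$; the flag exists because accessibility peaks are strandless, and whether the original counted both strands is not determinable. Collapsed dimension: $4^k/2 + 4^{k/2}/2$ for even $k$ (the second term counts reverse-complement palindromes), $4^k/2$ for odd. |
| `n_trees` | 500 | forest size for real use; the benchmark and tests use 5–100, which is already stable for these sample sizes. |
| `features_per_split` | $\lfloor\sqrt{n}\rfloor$ | canonical classification default. |
| `n_repeats` | 1 | permutations averaged per (tree, feature); raise to reduce MDA variance. |
| `conservation_default` | 1.0 | track value at uncovered positions (see above). |
| `score_mode` | `abs` | variant ranking aggregate. |
| `clamp_negative` | `FALSE` | MDA estimates can be slightly negative from permutation noise; they are used as-is so the exact oracle identities hold, with an opt-in floor at 0. |

## Numerical and algorithmic choices

- **Indexing.** Bases map to base-4 digits A=0, C=1, G=2, T=3, so a k-mer
  is a $k$-digit base-4 integer; this is pure index arithmetic, invisible
  to users.
- **Permutation substreams.** The permutation for tree $b$, feature $j$,
  repeat $r$ is drawn after seeding with
  $(\text{perm\_seed} + 100003\,b + 7\,j + 15485863\,(r-1)) \bmod (2^{31}-1)$.
  Per-(tree, feature) substreams make the result independent of the order
  trees are processed in and of which features are skipped, so per-tree
  work may run concurrently with bit-identical results, and the exactness
  shortcut below stays exact.
- **Provably-zero shortcuts.** A feature never used in any split of a tree
  cannot change that tree's predictions when permuted, and a feature
  constant across the matrix yields an identity permutation of values;
  both are skipped without permutation and scored 0 for that tree —
  identical to running the permutation, as the brute-force oracle test
  confirms.
- **Tie rules.** Forest vote ties (score exactly 0.5) map to label 0;
  MDA ranking ties break by ascending feature index. Both arbitrary,
  both fixed and documented.
- **ROC/PR.** The ROC sweep groups tied scores at one threshold and
  integrates by trapezoid, which equals the rank-sum
  probability-of-correct-ordering with ties counted one half. auPR uses
  interpolation-free step-wise summation
  $\sum_i (R_i - R_{i-1}) P_i$, because linearly interpolated PR curves
  overestimate.
- **Degenerate inputs.** Sequences shorter than $k$ are errors
  (intervals shorter than $k$ are dropped with a count); ref $=$ alt
  variants score exactly 0 with zero contributions; windows whose
  reference version contains a non-ACGT base are excluded from both the
  ref and alt side of variant scoring to avoid asymmetric phantom
  contributions; indels and symbolic alleles are excluded at VCF reading
  (the window-substitution model is only valid for substitutions).
- **Coordinates.** BED is 0-based half-open, VCF is 1-based; all internal
  arithmetic is 0-based half-open with a single conversion at each reader.

The forest itself (bagging, Gini splits, feature subsampling) is grown by
`ranger` with per-sample inbag counts retained; the trees are then
extracted into flat arrays and everything built *on* them — per-tree OOB
prediction, OOB accuracy, permutation MDA, vote aggregation — is computed
by this package (with a small C++ traversal kernel), which is what makes
the deterministic permutation contract and the exact oracle equalities
possible. Training is bit-identical across thread counts, so the
reproducibility contract is: (training seed, permutation seed) fully
determine the model, the MDA table, and every downstream score.

## The synthetic benchmark

Real experiments behind this method class use DNase-seq peak sequences as
positives, random genomic sequences as negatives, curated
pathogenic-versus-common SNV panels, and alignment-derived conservation.
None of that is redistributable at desk scale, so the package ships a
seed-deterministic generator whose defaults define the benchmark used by
the tests and the acceptance script:

- 200 kb uniform-composition background genome; 300 positive and 300
  negative intervals of 150–300 bp;
- the 6-mer word `GATAAG` (a pioneer-factor-like consensus, kept as an
  exact word rather than a position-weight matrix so ground truth is
  crisp) planted in each positive interval with probability 0.9 at a
  uniform offset;
- a conservation track with mean 0.95 over planted motif spans and 0.55
  elsewhere (sd 0.05, clipped to $[0,1]$) — signal that is measurable but
  not degenerate;
- 200 "pathogenic-like" SNVs placed uniformly inside planted motif
  occurrences and 200 "normal-like" SNVs at background positions at least
  $k$ bases from any motif occurrence, alt alleles uniform over the three
  non-reference bases.

Positive intervals are placed mutually non-overlapping, and the negative
sampler likewise rejects self-overlap by default: negatives emulate draws
from a genome so large that overlap is negligible, and at the benchmark's
packing density (~2/3 genome coverage) overlapping negatives would share
sequence across cross-validation folds, letting trees memorize fixture
geography rather than learn sequence signal. Chance background
occurrences of the motif are logged as "incidental" rather than scrubbed
— real peak sets carry the same ambiguity. The SNV panels draw from a
stream seeded at the config seed plus a fixed constant, so panel
generation does not depend on how much of the genome stream was consumed.

**What passing these tests does and does not show.** The generator plants
exact words in uniform background; real accessible chromatin has degenerate
motifs, GC and repeat structure, dinucleotide composition biases, and
shared motifs between open regions and the genomic background. Recovering
`GATAAG` at MDA rank 1 with held-out AUC above 0.9 demonstrates the
machinery is correct and sensitive, not that comparable accuracy would be
reached on real peak sets; the no-motif null (AUC ~0.5, motif rank
uniform) demonstrates the pipeline does not manufacture signal. Problem
sizes (600 samples, $4^6 = 4096$ features, 100 trees, three simulation
replicates) were chosen as the smallest at which these behaviours are
stable across seeds.

## Known limitations

- SNVs only: insertions and deletions shift the window frame and are not
  modelled; they are filtered out at input.
- Each variant is scored independently; epistasis between nearby variants
  and spatial interaction between k-mers are out of scope.
- MDA is the only importance measure (no Gini/impurity importance, no
  class-weighted forests, no probability calibration).
- Conservation must be supplied as a per-base track in $[0,1]$; computing
  it from raw multiple alignments (and deciding what $fre$ means at gap or
  N columns) is upstream of this package.
- Feature matrices are sparse in memory and on disk (SVMlight text), but
  tree training densifies them; beyond $k \approx 8$ or very large peak
  sets, memory becomes the binding constraint.
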