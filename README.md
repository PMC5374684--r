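# kmerforest

Sequence-only modelling of chromatin accessibility, and variant effect
scoring built on it. `kmerforest` turns genomic intervals into k-mer count
vectors ($n = 4^k$ features; a length-$L$ sequence has $L-k+1$ windows),
trains a random forest of full-depth unpruned trees to separate accessible
(e.g. DNase-seq peak) sequences from genomic background, and computes each
k-mer's **mean decrease accuracy (MDA)** by out-of-bag permutation:

$$\mathrm{MDA}_j = \frac{1}{B}\sum_{b=1}^{B}\big(\mathrm{acc}_b - \mathrm{acc}_{b,j}\big)$$

where $\mathrm{acc}_b$ is tree $b$'s accuracy on its out-of-bag samples and
$\mathrm{acc}_{b,j}$ the same after permuting feature $j$ among them. The
sorted MDA table is then used to score a single-nucleotide variant by the
accumulated MDA change over the (up to) $k$ k-mer windows the substitution
alters — a sequence-level estimate of regulatory disruption. A
conservation-weighted feature mode down-weights each k-mer occurrence by
the mean per-base cross-species conservation frequency,
$x_i^{s*} = \frac{1}{k}\sum_{j=1}^{x_i^s}\sum_{q=1}^{k} fre_{q,j}$, so that
$x_i^{s*} \le x_i^s$ with equality iff every touched frequency is 1.

It is aimed at regulatory-genomics analysts who want an interpretable,
alignment-free baseline for open-chromatin classification and for
prioritizing noncoding SNVs (pathogenic-versus-common panels, GWAS
linked-SNP sets) without any chromatin data at scoring time.

Standard formats in, plain tables out: FASTA, BED3+label, VCF (SNVs),
bedGraph conservation tracks; feature matrices in SVMlight sparse text;
ranked k-mer and variant tables as TSV. A seed-deterministic synthetic
generator (planted-motif positives, background negatives, conservation
track, SNV panels with truth records) makes the whole pipeline testable
offline.

## Worked example

```r
library(kmerforest)

# synthetic benchmark: 200 kb genome, 300 + 300 intervals, motif GATAAG
# planted in positives at probability 0.9
sim   <- simulate_genome(sim_config(seed = 1))
vocab <- kmer_vocabulary(k = 6)
fm    <- build_feature_matrix(sim$genome, sim$intervals, vocab)
fm
#> FeatureMatrix: 600 samples x 4096 features (count mode), 300 positive / 300 negative

model <- train_forest(fm, forest_config(n_trees = 100, seed = 1))
oob_accuracy(model, fm)
#> [1] 0.875

mda <- compute_mda(model, fm, permutation_seed = 1)
head(rank_kmers(mda, vocab, top = 3))
#>     kmer index         mda rank
#> 1 GATAAG  2243 0.074894141    1
#> 2 TGATAA  3633 0.010287802    2
#> 3 ATAAGC   778 0.008302851    3

panels <- simulate_snp_panels(sim, k = 6)
scored <- score_variant_set(sim$genome,
                            rbind(panels$pathogenic, panels$normal),
                            mda, vocab, primary = "abs")
compare_score_distributions(
  scored$score_abs[match(panels$pathogenic$id, scored$id)],
  scored$score_abs[match(panels$normal$id, scored$id)])$separation_auc
#> [1] 1
```

The planted word is recovered as the top-ranked k-mer of all 4096, the
out-of-bag accuracy estimates held-out classification performance, and the
motif-disrupting SNVs separate perfectly from background SNVs by their
absolute MDA-change score. `cross_validated_auc(fm, ...)` gives the
stratified held-out AUC/auPR (about 0.94 / 0.93 at these settings), and
passing `track = sim$track` to `build_feature_matrix()` enables the
conservation-weighted mode (about +2 AUC points here).

A shell entry point wrapping the same functions ships at
`inst/cli/kmerforest.R` with `simulate`, `train`, `score` and `evaluate`
subcommands; every output directory contains the fully-resolved
`run_config.yaml`, and results are bit-identical for fixed seeds at any
thread count.

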