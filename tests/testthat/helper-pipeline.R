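# Full benchmark pipeline at the standard study conditions (200 kb genome,
# 300+300 intervals of 150-300 bp, GATAAG at probability 0.9, k = 6,
# 100 trees, 5-fold CV), cached per seed so several test files can share
# one run.

.pipeline_cache <- new.env(parent = emptyenv())

run_benchmark_pipeline <- function(seed, motif_prob = 0.9) {
  key <- sprintf("s%d_p%g", seed, motif_prob)
  if (!is.null(.pipeline_cache[[key]])) return(.pipeline_cache[[key]])
  sim <- simulate_genome(sim_config(seed = seed, motif_prob = motif_prob))
  vocab <- kmer_vocabulary(6)
  fm <- build_feature_matrix(sim$genome, sim$intervals, vocab)
  cfg <- forest_config(n_trees = 100, seed = seed)
  cv <- cross_validated_auc(fm, cfg, n_folds = 5)
  model <- train_forest(fm, cfg)
  mda <- compute_mda(model, fm, permutation_seed = seed)
  out <- list(sim = sim, vocab = vocab, fm = fm, model = model, mda = mda,
              cv = cv, motif_rank = kmer_rank("GATAAG", mda, vocab))
  .pipeline_cache[[key]] <- out
  out
}
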