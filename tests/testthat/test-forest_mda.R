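test_that("a perfectly separable planted feature yields near-perfect OOB accuracy", {
  vocab <- kmer_vocabulary(2)
  fm <- separable_matrix(n = 200, p = 16, planted = 3, vocab, seed = 1)
  model <- train_forest(fm, forest_config(n_trees = 50, seed = 7))
  expect_gte(oob_accuracy(model, fm), 0.95)
  # bootstrap bookkeeping: inbag multiset and OOB set partition the samples
  for (b in c(1, 25, 50)) {
    inbag <- model$inbag[[b]]
    expect_equal(sum(inbag), model$n_samples)        # bootstrap size = n, with repeats
    expect_true(max(inbag) > 1)                      # some sample drawn twice
    expect_equal(sort(union(which(inbag > 0), model$oob[[b]])), 1:200)
    expect_length(intersect(which(inbag > 0), model$oob[[b]]), 0)
  }
})

test_that("training is deterministic given the seed and independent of thread count", {
  vocab <- kmer_vocabulary(2)
  fm <- separable_matrix(n = 100, p = 16, planted = 5, vocab, seed = 2)
  m1 <- train_forest(fm, forest_config(n_trees = 20, seed = 9, n_threads = 1))
  m2 <- train_forest(fm, forest_config(n_trees = 20, seed = 9, n_threads = 2))
  expect_identical(m1$trees, m2$trees)
  expect_identical(m1$oob, m2$oob)
  expect_identical(predict_forest(m1, fm), predict_forest(m2, fm))
  t1 <- compute_mda(m1, fm, permutation_seed = 4)
  t2 <- compute_mda(m2, fm, permutation_seed = 4)
  expect_identical(t1$mda, t2$mda)
})

test_that("single-class training data is rejected", {
  vocab <- kmer_vocabulary(2)
  fm <- toy_feature_matrix(matrix(rpois(80, 1), 5, 16), rep(1L, 5), vocab)
  expect_error(train_forest(fm), "single class")
})

test_that("label-free data gives chance-level OOB accuracy", {
  vocab <- kmer_vocabulary(2)
  accs <- vapply(1:3, function(s) {
    set.seed(s)
    X <- matrix(rpois(200 * 16, 0.5), 200, 16)
    fm <- toy_feature_matrix(X, rep(0:1, each = 100), vocab)
    model <- train_forest(fm, forest_config(n_trees = 50, seed = s))
    oob_accuracy(model, fm)
  }, numeric(1))
  expect_gt(mean(accs), 0.4)
  expect_lt(mean(accs), 0.6)
})

test_that("a single tree leaves about 1/e of the samples out-of-bag", {
  vocab <- kmer_vocabulary(2)
  fm <- separable_matrix(n = 300, p = 16, planted = 3, vocab, seed = 3)
  model <- train_forest(fm, forest_config(n_trees = 1, seed = 12))
  frac_oob <- length(model$oob[[1]]) / 300
  # each sample is OOB with probability (1 - 1/n)^n ~ e^-1 = 0.368;
  # binomial sd at n = 300 is ~0.028, allow 4 sd
  expect_gt(frac_oob, exp(-1) - 0.112)
  expect_lt(frac_oob, exp(-1) + 0.112)
})

test_that("MDA equals the brute-force permutation oracle and zeroes constant features", {
  vocab <- kmer_vocabulary(2)
  set.seed(13)
  X <- matrix(rpois(16 * 16, 0.8), 16, 16)
  y <- rep(0:1, each = 8)
  X[, 4] <- y * 2 + rpois(16, 0.2)   # informative feature
  X[, 7] <- 3                        # constant, nonzero
  X[, 9] <- 0                        # constant, zero
  fm <- toy_feature_matrix(X, y, vocab)
  model <- train_forest(fm, forest_config(n_trees = 5, seed = 17))
  table <- compute_mda(model, fm, permutation_seed = 23)
  oracle <- mda_oracle(model, as.matrix(fm$X), y, permutation_seed = 23)
  expect_identical(table$mda, oracle)
  expect_identical(table$mda[7], 0)
  expect_identical(table$mda[9], 0)
  expect_gt(table$mda[4], 0)
  # repeated permutations also match the oracle
  cfg <- forest_config(n_trees = 5, seed = 17, n_repeats = 3)
  model3 <- train_forest(fm, cfg)
  t3 <- compute_mda(model3, fm, permutation_seed = 23)
  o3 <- mda_oracle(model3, as.matrix(fm$X), y, permutation_seed = 23, n_repeats = 3)
  expect_identical(t3$mda, o3)
})

test_that("with labels shuffled the planted feature loses its MDA standing", {
  vocab <- kmer_vocabulary(2)
  ranks <- integer(5); means <- numeric(5)
  for (s in 1:5) {
    set.seed(100 + s)
    X <- matrix(rpois(120 * 16, 0.5), 120, 16)
    y <- rep(0:1, each = 60)
    X[, 4] <- y * 3
    y_null <- sample(y)                       # destroy the signal
    fm <- toy_feature_matrix(X, y_null, vocab)
    model <- train_forest(fm, forest_config(n_trees = 40, seed = s))
    tab <- compute_mda(model, fm, permutation_seed = s)
    ranks[s] <- match(4, tab$ranking)
    means[s] <- mean(tab$mda)
  }
  expect_lt(abs(mean(means)), 0.02)           # mean MDA ~ 0 under the null
  expect_gt(median(ranks), 16 / 10)           # planted feature not in the top decile
})

test_that("scaling all features by a positive constant leaves predictions unchanged", {
  vocab <- kmer_vocabulary(2)
  fm <- separable_matrix(n = 150, p = 16, planted = 6, vocab, seed = 4)
  fm_scaled <- fm; fm_scaled$X <- fm$X * 3.7
  m1 <- train_forest(fm, forest_config(n_trees = 30, seed = 5))
  m2 <- train_forest(fm_scaled, forest_config(n_trees = 30, seed = 5))
  expect_identical(predict_forest(m1, fm)$score, predict_forest(m2, fm_scaled)$score)
  # split thresholds scale; the split variables and topology do not
  expect_identical(lapply(m1$trees, `[[`, "splitvar"),
                   lapply(m2$trees, `[[`, "splitvar"))
})

test_that("ranking sorts by score with ascending-index tie-breaks", {
  vocab <- kmer_vocabulary(2)
  mda <- numeric(16)
  mda[kmer_index(c("AA", "AC", "AG"), vocab)] <- c(0.3, 0.1, 0.3)
  tab <- toy_mda_table(mda, vocab)
  top <- rank_kmers(tab, vocab, top = 3)
  expect_equal(top$kmer, c("AA", "AG", "AC"))
  expect_equal(top$rank, 1:3)
  expect_error(rank_kmers(tab, vocab, top = 0), "positive")
  expect_error(rank_kmers(tab, vocab, top = 17), "exceeds")
  # all-zero scores fall back to lexicographic k-mer order
  zero <- rank_kmers(toy_mda_table(numeric(16), vocab), vocab, 16)
  expect_equal(zero$kmer, index_kmer(1:16, vocab))
  # full ranking is a permutation
  full <- rank_kmers(tab, vocab, 16)
  expect_setequal(full$index, 1:16)
})

test_that("prediction scores are tree-vote fractions with ties mapping to label 0", {
  stump <- function(var, thr, pl, pr) list(left = c(1L, -1L, -1L),
                                           right = c(2L, -1L, -1L),
                                           splitvar = c(var, -1L, -1L),
                                           splitval = c(thr, 0, 0),
                                           pred = c(-1L, pl, pr))
  model <- structure(list(trees = list(stump(0L, 0.5, 0L, 1L),
                                       stump(0L, 0.5, 1L, 0L)),
                          n_samples = 0L, n_features = 4L,
                          config = forest_config(n_trees = 2),
                          vocab_checksum = "toy"),
                     class = "ForestModel")
  X <- matrix(c(0, 1, 0, 0, 0, 0, 0, 0), 2, 4)   # rows: x1 = 0 and x1 = 1
  pred <- predict_forest(model, X)
  expect_equal(pred$score, c(0.5, 0.5))           # trees disagree either way
  expect_equal(pred$label, c(0L, 0L))             # exact tie -> 0
  expect_error(predict_forest(model, X[, 1:3]), "dimension mismatch")
})

test_that("MDA tables round-trip through the TSV export", {
  vocab <- kmer_vocabulary(2)
  fm <- separable_matrix(n = 60, p = 16, planted = 2, vocab, seed = 6)
  model <- train_forest(fm, forest_config(n_trees = 10, seed = 3))
  tab <- compute_mda(model, fm, permutation_seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mda_table(tab, vocab, path)
  back <- read_mda_table(path, vocab)
  expect_equal(back$mda, tab$mda)
  expect_equal(back$ranking, tab$ranking)
})
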