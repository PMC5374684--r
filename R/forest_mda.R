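# Random-forest training with per-tree out-of-bag bookkeeping, and the
# mean-decrease-accuracy (MDA) importance of every k-mer computed by OOB
# permutation:
#   MDA_j = (1/B) * sum_b [ acc_b - acc_{b,j} ]
# where acc_b is tree b's accuracy on its own OOB samples and acc_{b,j} its
# accuracy after the values of feature j are permuted among those OOB
# samples. Tree growing (bagging, Gini splits, sqrt feature subsampling,
# unpruned full-depth trees) is delegated to ranger; everything the trees
# are *used* for afterwards (per-tree prediction, OOB accuracy, permutation
# importance) is computed here from the extracted tree structures.

#' Random-forest configuration
#'
#' @param n_trees number of trees (bootstrap size = training size, sampled
#'   with replacement, so one sample may be drawn more than once).
#' @param features_per_split `"sqrt"` (floor of sqrt(n features)) or a count.
#' @param seed training seed; together with the permutation seed it fully
#'   determines the model and the MDA table, independently of `n_threads`.
#' @param n_threads threads used for tree growing (wall time only).
#' @param n_repeats permutations averaged per (tree, feature) in
#'   [compute_mda()]; 1 reproduces the plain single-permutation estimate.
#' @return a `ForestConfig` list.
#' @export
forest_config <- function(n_trees = 500L, features_per_split = "sqrt",
                          seed = 1L, n_threads = 1L, n_repeats = 1L) {
  stopifnot(n_trees >= 1, n_repeats >= 1)
  structure(list(n_trees = as.integer(n_trees),
                 features_per_split = features_per_split,
                 seed = as.integer(seed), n_threads = as.integer(n_threads),
                 n_repeats = as.integer(n_repeats)),
            class = "ForestConfig")
}

.dense_features <- function(X) {
  Xd <- as.matrix(X)
  colnames(Xd) <- paste0("f", seq_len(ncol(Xd)))
  Xd
}

#' Train the random forest with OOB bookkeeping
#'
#' Trees are grown to purity (no pruning, minimum node size 1) on bootstrap
#' resamples of the full training-set size; each tree's out-of-bag sample
#' set (the complement of its bootstrap multiset) is recorded for OOB
#' accuracy and permutation importance.
#'
#' @param fm a [build_feature_matrix()] result with both classes present.
#' @param config a [forest_config()].
#' @return a `ForestModel` holding the extracted tree structures, per-tree
#'   bootstrap counts and OOB index sets, the config, and the vocabulary
#'   checksum.
#' @export
train_forest <- function(fm, config = forest_config()) {
  y <- fm$labels
  if (length(unique(y)) < 2L) stop("training data contains a single class")
  if (min(table(y)) < 2L) stop("need at least 2 samples of each label")
  Xd <- .dense_features(fm$X)
  p <- ncol(Xd)
  mtry <- if (identical(config$features_per_split, "sqrt"))
    max(1L, floor(sqrt(p))) else as.integer(config$features_per_split)
  rf <- ranger::ranger(x = Xd, y = factor(y, levels = c(0, 1)),
                       num.trees = config$n_trees, mtry = mtry,
                       min.node.size = 1, replace = TRUE, sample.fraction = 1,
                       splitrule = "gini", keep.inbag = TRUE,
                       seed = config$seed, num.threads = config$n_threads)
  trees <- lapply(seq_len(config$n_trees), function(b) {
    ti <- ranger::treeInfo(rf, b)
    leaf <- ti$terminal
    list(left = ifelse(leaf, -1L, ti$leftChild),
         right = ifelse(leaf, -1L, ti$rightChild),
         splitvar = ifelse(leaf, -1L, ti$splitvarID),
         splitval = ifelse(leaf, 0, ti$splitval),
         pred = ifelse(leaf, as.integer(as.character(ti$prediction)), -1L))
  })
  inbag <- lapply(rf$inbag.counts, as.integer)
  oob <- lapply(inbag, function(cnt) which(cnt == 0L))
  structure(list(trees = trees, inbag = inbag, oob = oob,
                 n_samples = nrow(Xd), n_features = p,
                 config = config, mtry = mtry,
                 vocab_checksum = .vocab_checksum(fm$vocab)),
            class = "ForestModel")
}

#' @export
print.ForestModel <- function(x, ...) {
  cat(sprintf("ForestModel: %d trees, %d training samples, %d features, mtry %d, seed %d\n",
              length(x$trees), x$n_samples, x$n_features, x$mtry,
              x$config$seed))
  invisible(x)
}

.tree_predict <- function(tree, Xd) {
  .tree_predict_cpp(Xd, tree$left, tree$right, tree$splitvar, tree$splitval,
                    tree$pred)
}

#' Out-of-bag accuracy of a trained forest
#'
#' Each training sample is predicted by majority vote of only the trees for
#' which it is out-of-bag (ties vote label 0); samples that are in-bag for
#' every tree are excluded from the denominator.
#'
#' @param model a [train_forest()] result.
#' @param fm the training `FeatureMatrix`.
#' @return fraction of OOB-predictable samples predicted correctly.
#' @export
oob_accuracy <- function(model, fm) {
  if (nrow(fm$X) != model$n_samples || ncol(fm$X) != model$n_features)
    stop("matrix does not match the model's training dimensions")
  Xd <- .dense_features(fm$X)
  votes1 <- integer(model$n_samples)
  ntrees <- integer(model$n_samples)
  for (b in seq_along(model$trees)) {
    o <- model$oob[[b]]
    if (length(o) == 0L) next
    pr <- .tree_predict(model$trees[[b]], Xd[o, , drop = FALSE])
    votes1[o] <- votes1[o] + pr
    ntrees[o] <- ntrees[o] + 1L
  }
  usable <- ntrees > 0L
  pred <- as.integer(votes1[usable] > ntrees[usable] / 2)  # tie -> 0
  mean(pred == fm$labels[usable])
}

# deterministic per-(tree, feature, repeat) permutation substream; makes the
# result independent of which features are skipped and of per-tree work order
.perm_seed <- function(perm_seed, b, j, r = 1L) {
  as.integer((perm_seed + 100003 * b + 7 * j + 15485863 * (r - 1)) %% 2147483647)
}

#' Per-k-mer mean decrease accuracy by OOB permutation
#'
#' For each tree b the baseline accuracy on its OOB samples is computed;
#' then, for each candidate feature j, the values of j among those OOB
#' samples are permuted (seeded), the tree re-predicts them, and the
#' accuracy drop is recorded. `MDA_j` is the drop averaged over all trees.
#' Features never used in any split of a tree, and features constant across
#' the matrix, contribute exactly zero for that tree (a permutation cannot
#' change any prediction), so they are skipped without being permuted; the
#' result is identical to permuting them.
#'
#' @param model a [train_forest()] result.
#' @param fm the training `FeatureMatrix`.
#' @param features integer vector of feature indices to score, or `NULL`
#'   for all features.
#' @param permutation_seed seed for the permutation substreams.
#' @return an `MdaTable`: `mda` (length-n score vector, zero at unscored
#'   features), `ranking` (feature indices by descending score, ties broken
#'   by ascending index), `base_acc` (per-tree baseline OOB accuracies).
#' @export
compute_mda <- function(model, fm, features = NULL, permutation_seed = 1L) {
  n <- model$n_features
  if (nrow(fm$X) != model$n_samples || ncol(fm$X) != n)
    stop("matrix does not match the model's training dimensions")
  if (is.null(features)) features <- seq_len(n)
  features <- as.integer(features)
  if (any(features < 1L | features > n)) stop("feature index out of range")
  Xd <- .dense_features(fm$X)
  y <- fm$labels
  # constant-across-matrix columns can never change a prediction when permuted
  nonconst <- which(apply(Xd, 2, function(col) any(col != col[1L])))
  candidate <- intersect(features, nonconst)
  B <- length(model$trees)
  n_repeats <- model$config$n_repeats
  mda <- numeric(n)
  base_acc <- numeric(B)
  old <- .save_rng(); on.exit(.restore_rng(old))
  for (b in seq_len(B)) {
    o <- model$oob[[b]]
    if (length(o) == 0L) { base_acc[b] <- NA_real_; next }
    tree <- model$trees[[b]]
    Xo <- Xd[o, , drop = FALSE]
    yo <- y[o]
    base_pred <- .tree_predict(tree, Xo)
    acc_b <- mean(base_pred == yo)
    base_acc[b] <- acc_b
    used <- unique(tree$splitvar[tree$splitvar >= 0L]) + 1L
    for (j in sort(intersect(used, candidate))) {
      drop_sum <- 0
      for (r in seq_len(n_repeats)) {
        set.seed(.perm_seed(permutation_seed, b, j, r))
        perm <- sample.int(length(o))
        pr <- .tree_predict_replace_cpp(Xo, tree$left, tree$right,
                                        tree$splitvar, tree$splitval,
                                        tree$pred, j - 1L, Xo[perm, j])
        drop_sum <- drop_sum + (acc_b - mean(pr == yo))
      }
      mda[j] <- mda[j] + drop_sum / n_repeats
    }
  }
  mda <- mda / B
  structure(list(mda = mda, ranking = order(-mda, seq_len(n)),
                 base_acc = base_acc, n = n,
                 vocab_checksum = model$vocab_checksum,
                 permutation_seed = as.integer(permutation_seed)),
            class = "MdaTable")
}

#' @export
print.MdaTable <- function(x, ...) {
  cat(sprintf("MdaTable: %d features, mean baseline OOB accuracy %.3f, max MDA %.4g\n",
              x$n, mean(x$base_acc, na.rm = TRUE), max(x$mda)))
  invisible(x)
}

#' Ranked k-mer importance table
#'
#' @param table an [compute_mda()] result.
#' @param vocab the [kmer_vocabulary()] the model was trained with.
#' @param top number of top-ranked k-mers to return (<= number of features).
#' @return `data.frame` with columns kmer, index, mda, rank (1-based,
#'   descending score, ties broken by ascending feature index, i.e.
#'   lexicographic k-mer order).
#' @export
rank_kmers <- function(table, vocab, top = table$n) {
  if (!is.numeric(top) || top <= 0) stop("top must be positive")
  if (top > table$n) stop("top exceeds the number of features")
  if (!identical(.vocab_checksum(vocab), table$vocab_checksum))
    stop("vocabulary does not match the one the MDA table was built with")
  idx <- table$ranking[seq_len(top)]
  data.frame(kmer = index_kmer(idx, vocab), index = idx,
             mda = table$mda[idx], rank = seq_len(top),
             stringsAsFactors = FALSE)
}

#' Rank of one k-mer in the MDA ordering
#'
#' @param kmer k-mer string.
#' @param table an `MdaTable`.
#' @param vocab the matching vocabulary.
#' @return 1-based rank (1 = most important).
#' @export
kmer_rank <- function(kmer, table, vocab) {
  j <- kmer_index(kmer, vocab)
  if (is.na(j)) stop("'", kmer, "' is not a valid k-mer")
  match(j, table$ranking)
}

#' Predict accessibility scores for new samples
#'
#' @param model a [train_forest()] result.
#' @param newdata a `FeatureMatrix`, a sparse/dense matrix with the model's
#'   feature dimension, or a list of `SparseKmerVector`s.
#' @return `data.frame` with `score` (fraction of trees voting accessible)
#'   and `label` (`score > 0.5`; an exact tie maps to 0).
#' @export
predict_forest <- function(model, newdata) {
  X <- if (inherits(newdata, "FeatureMatrix")) newdata$X
  else if (is.list(newdata) && all(vapply(newdata, inherits, logical(1), "SparseKmerVector"))) {
    Matrix::sparseMatrix(
      i = rep(seq_along(newdata), vapply(newdata, function(v) length(v$i), integer(1))),
      j = unlist(lapply(newdata, `[[`, "i")),
      x = unlist(lapply(newdata, `[[`, "x")),
      dims = c(length(newdata), model$n_features))
  } else newdata
  if (ncol(X) != model$n_features)
    stop("feature dimension mismatch: ", ncol(X), " vs ", model$n_features)
  Xd <- .dense_features(X)
  votes <- .forest_votes_cpp(Xd, model$trees)
  score <- votes / length(model$trees)
  data.frame(score = score, label = as.integer(score > 0.5))
}

#' Write a ranked MDA table to TSV
#'
#' Columns: kmer, index, mda, rank — the full feature set in rank order.
#' @param table an `MdaTable`.
#' @param vocab the matching vocabulary.
#' @param path output path.
#' @export
write_mda_table <- function(table, vocab, path) {
  utils::write.table(rank_kmers(table, vocab, table$n), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an MDA table written by [write_mda_table()]
#'
#' @param path TSV path.
#' @param vocab the matching vocabulary.
#' @return an `MdaTable`.
#' @export
read_mda_table <- function(path, vocab) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "integer", "numeric",
                                         "integer"))
  if (nrow(df) != vocab$n)
    stop("MDA table has ", nrow(df), " rows but the vocabulary has ", vocab$n,
         " features")
  mda <- numeric(vocab$n)
  mda[df$index] <- df$mda
  structure(list(mda = mda, ranking = order(-mda, seq_len(vocab$n)),
                 base_acc = NA_real_, n = vocab$n,
                 vocab_checksum = .vocab_checksum(vocab),
                 permutation_seed = NA_integer_),
            class = "MdaTable")
}
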