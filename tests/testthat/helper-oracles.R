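# Independent oracles and fixture builders shared across the suite.

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# naive k-mer counting by substring enumeration (independent of the
# vectorized base-4 implementation)
naive_kmer_counts <- function(seq, k) {
  seq <- toupper(seq)
  words <- vapply(1:(nchar(seq) - k + 1), function(p) substr(seq, p, p + k - 1),
                  character(1))
  words <- words[!grepl("[^ACGT]", words)]
  if (length(words) == 0) return(numeric(0))
  tab <- table(words)
  setNames(as.numeric(tab), names(tab))
}

# sparse vector -> named numeric, keyed by k-mer string
sparse_to_named <- function(v, vocab) {
  setNames(v$x, index_kmer(v$i, vocab))
}

# wrap a plain matrix as a FeatureMatrix without going through intervals
toy_feature_matrix <- function(X, labels, vocab, mode = "count") {
  structure(list(X = Matrix::Matrix(X, sparse = TRUE), labels = as.integer(labels),
                 vocab = vocab, mode = mode),
            class = "FeatureMatrix")
}

# an MdaTable with given scores, bypassing the forest
toy_mda_table <- function(mda, vocab) {
  structure(list(mda = mda, ranking = order(-mda, seq_along(mda)),
                 base_acc = NA_real_, n = length(mda),
                 vocab_checksum = kmerforest:::.vocab_checksum(vocab),
                 permutation_seed = NA_integer_),
            class = "MdaTable")
}

# separable training data: one planted feature equals the label, the rest
# is sparse noise
separable_matrix <- function(n = 200, p = 16, planted = 3, vocab, seed = 1) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  X <- matrix(rpois(n * p, 0.3), n, p)
  X[, planted] <- y * 3
  toy_feature_matrix(X, y, vocab)
}

# brute-force OOB permutation importance: explicit per-sample tree walks
# in R, same per-(tree, feature, repeat) seed scheme as the package
# (perm_seed + 100003*b + 7*j + 15485863*(r-1) mod 2^31-1), permuting
# every requested feature whether or not the tree uses it.
walk_tree <- function(tree, x) {
  node <- 1L
  while (tree$splitvar[node] >= 0L) {
    v <- tree$splitvar[node] + 1L
    node <- if (x[v] <= tree$splitval[node]) tree$left[node] + 1L
            else tree$right[node] + 1L
  }
  tree$pred[node]
}

mda_oracle <- function(model, Xd, y, permutation_seed, features = NULL,
                       n_repeats = 1L) {
  n <- ncol(Xd)
  if (is.null(features)) features <- seq_len(n)
  B <- length(model$trees)
  mda <- numeric(n)
  for (b in seq_len(B)) {
    tree <- model$trees[[b]]
    o <- model$oob[[b]]
    if (length(o) == 0) next
    Xo <- Xd[o, , drop = FALSE]
    yo <- y[o]
    base <- vapply(seq_len(nrow(Xo)), function(i) walk_tree(tree, Xo[i, ]),
                   numeric(1))
    acc_b <- mean(base == yo)
    for (j in features) {
      drop_sum <- 0
      for (r in seq_len(n_repeats)) {
        set.seed(as.integer((permutation_seed + 100003 * b + 7 * j +
                             15485863 * (r - 1)) %% 2147483647))
        perm <- sample.int(length(o))
        Xp <- Xo
        Xp[, j] <- Xo[perm, j]
        pr <- vapply(seq_len(nrow(Xp)), function(i) walk_tree(tree, Xp[i, ]),
                     numeric(1))
        drop_sum <- drop_sum + (acc_b - mean(pr == yo))
      }
      mda[j] <- mda[j] + drop_sum / n_repeats
    }
  }
  mda / B
}

# brute-force interval overlap scan
any_overlap <- function(a, b) {
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] == b$chrom[j] && a$start[i] < b$end[j] && b$start[j] < a$end[i])
      return(TRUE)
  }
  FALSE
}

# rank-sum AUC (probability of correct ordering, ties one half) used as the
# independent check on the threshold-sweep ROC
rank_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}
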