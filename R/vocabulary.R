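# k-mer vocabulary: bijection between k-mer strings over {A,C,G,T} and
# integer feature indices. Bases map to base-4 digits A=0, C=1, G=2, T=3,
# so a k-mer is read as a k-digit base-4 number; feature indices are 1-based
# in R (internal raw index = base-4 value + 1). With rc_collapse a k-mer and
# its reverse complement share the canonical (smaller raw) index.

.BASES <- c("A", "C", "G", "T")

# char code -> digit lookup (NA for anything outside ACGT)
.base_digits <- local({
  d <- rep(NA_integer_, 256L)
  d[utf8ToInt("A")] <- 0L; d[utf8ToInt("C")] <- 1L
  d[utf8ToInt("G")] <- 2L; d[utf8ToInt("T")] <- 3L
  d
})

#' Number of k-mer features
#'
#' Dimension of the k-mer feature space: `4^k` without reverse-complement
#' collapsing, or the number of canonical reverse-complement classes with it
#' (`4^k/2 + 4^(k/2)/2` for even k, where the second term counts
#' reverse-complement palindromes; `4^k/2` for odd k, which has none).
#'
#' @param k word length, an integer in `[2, 12]`.
#' @param rc_collapse collapse each k-mer with its reverse complement?
#' @return integer-valued count of features.
#' @examples
#' vocabulary_dimension(10, FALSE)  # 1048576
#' vocabulary_dimension(2, TRUE)    # 10
#' @export
vocabulary_dimension <- function(k, rc_collapse = FALSE) {
  if (!is.numeric(k) || length(k) != 1L || k != round(k) || k < 2 || k > 12)
    stop("k must be a single integer in [2, 12]")
  if (!rc_collapse) return(4^k)
  if (k %% 2 == 0) 4^k / 2 + 4^(k / 2) / 2 else 4^k / 2
}

#' Create a k-mer vocabulary
#'
#' @param k word length (integer in `[2, 10]` for materialized vocabularies).
#' @param rc_collapse if `TRUE`, a k-mer and its reverse complement map to
#'   one canonical feature; default `FALSE` so the dimension is exactly `4^k`.
#' @return an object of class `KmerVocabulary` with fields `k`, `rc_collapse`,
#'   `n` (feature count) and, when collapsing, the raw-to-canonical index map.
#' @export
kmer_vocabulary <- function(k = 6L, rc_collapse = FALSE) {
  if (!is.numeric(k) || length(k) != 1L || k != round(k) || k < 2 || k > 10)
    stop("k must be a single integer in [2, 10]")
  k <- as.integer(k)
  n_raw <- as.integer(4^k)
  v <- list(k = k, rc_collapse = isTRUE(rc_collapse))
  if (v$rc_collapse) {
    raw <- 0:(n_raw - 1L)
    rc <- .revcomp_index(raw, k)
    canon_raw <- pmin(raw, rc)
    reps <- sort(unique(canon_raw))
    map <- integer(n_raw)
    map[reps + 1L] <- seq_along(reps)
    feat <- map[canon_raw + 1L]           # raw 0-based index -> 1-based feature
    v$n <- length(reps)
    v$feature_of_raw <- feat
    v$rep_raw <- reps                     # 0-based raw index of each feature's representative
  } else {
    v$n <- n_raw
  }
  class(v) <- "KmerVocabulary"
  v
}

# reverse-complement of 0-based base-4 k-mer indices, vectorized
.revcomp_index <- function(idx, k) {
  out <- numeric(length(idx))
  rest <- idx
  for (q in seq_len(k)) {          # peel digits from the low end, complement, push high
    digit <- rest %% 4
    rest <- rest %/% 4
    out <- out * 4 + (3 - digit)
  }
  out
}

#' @export
print.KmerVocabulary <- function(x, ...) {
  cat(sprintf("KmerVocabulary: k = %d, rc_collapse = %s, %d features\n",
              x$k, x$rc_collapse, x$n))
  invisible(x)
}

#' Map k-mer strings to feature indices
#'
#' @param kmers character vector of length-k words over `{A,C,G,T}`.
#' @param vocab a [kmer_vocabulary()].
#' @return 1-based feature indices; `NA` for words containing other letters.
#' @export
kmer_index <- function(kmers, vocab) {
  k <- vocab$k
  if (any(nchar(kmers) != k)) stop("all k-mers must have length k = ", k)
  idx <- vapply(kmers, function(s) {
    d <- .base_digits[utf8ToInt(s)]
    if (anyNA(d)) return(NA_real_)
    sum(d * 4^((k - 1):0))
  }, numeric(1), USE.NAMES = FALSE)
  .raw_to_feature(idx, vocab)
}

# 0-based raw base-4 index -> 1-based feature index under the vocabulary
.raw_to_feature <- function(raw0, vocab) {
  if (vocab$rc_collapse) {
    out <- rep(NA_integer_, length(raw0))
    ok <- !is.na(raw0)
    out[ok] <- vocab$feature_of_raw[raw0[ok] + 1L]
    out
  } else {
    as.integer(raw0 + 1L)
  }
}

#' Map feature indices back to k-mer strings
#'
#' With `rc_collapse` the canonical representative (the lexicographically
#' smaller of the pair) is returned.
#'
#' @param indices 1-based feature indices.
#' @param vocab a [kmer_vocabulary()].
#' @return character vector of k-mers.
#' @export
index_kmer <- function(indices, vocab) {
  if (any(indices < 1 | indices > vocab$n)) stop("feature index out of range")
  raw0 <- if (vocab$rc_collapse) vocab$rep_raw[indices] else indices - 1
  vapply(raw0, function(v) {
    d <- integer(vocab$k)
    for (q in vocab$k:1) { d[q] <- v %% 4; v <- v %/% 4 }
    paste(.BASES[d + 1L], collapse = "")
  }, character(1))
}

#' Reverse complement of DNA strings
#'
#' Non-ACGT characters map to `N`.
#' @param seqs character vector of DNA strings.
#' @return reverse-complemented strings.
#' @export
revcomp <- function(seqs) {
  comp <- setNames(c("T", "G", "C", "A"), .BASES)
  vapply(seqs, function(s) {
    ch <- rev(strsplit(s, "", fixed = TRUE)[[1]])
    out <- comp[ch]
    out[is.na(out)] <- "N"
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# fingerprint used to check that a model and an MDA table were built with
# the same vocabulary
.vocab_checksum <- function(vocab) {
  sprintf("k%drc%d n%d", vocab$k, as.integer(vocab$rc_collapse), vocab$n)
}
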