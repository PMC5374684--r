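# Sequence -> sparse k-mer feature vectors. A length-L sequence has L-k+1
# sliding windows; windows containing any non-ACGT character are skipped
# entirely. In count mode feature i holds the number of valid windows whose
# word is k-mer i. In conservation mode each occurrence contributes the mean
# per-base conservation frequency over its k positions instead of 1:
#   x_i* = (1/k) * sum over occurrences j of i, sum over the k positions q,
#          of fre[q, j]
# so 0 <= x_i* <= x_i, with equality iff every touched fre equals 1.

# 0-based raw base-4 index of every window; NA where the window has a
# non-ACGT base. Vectorized: k shifted adds in base 4.
.window_raw_indices <- function(seq, k) {
  codes <- .base_digits[utf8ToInt(seq)]
  L <- length(codes)
  nwin <- L - k + 1L
  idx <- numeric(nwin)
  for (q in 0:(k - 1L)) idx <- idx * 4 + codes[(1L + q):(nwin + q)]
  idx
}

.new_sparse_vector <- function(i, x, n, mode, seq_id = NA_character_, L = NA_integer_) {
  o <- order(i)
  structure(list(i = as.integer(i[o]), x = as.numeric(x[o]), n = n,
                 mode = mode, seq_id = seq_id, length = L),
            class = "SparseKmerVector")
}

#' @export
print.SparseKmerVector <- function(x, ...) {
  cat(sprintf("SparseKmerVector (%s mode): %d/%d nonzero, sum %.4g\n",
              x$mode, length(x$i), x$n, sum(x$x)))
  invisible(x)
}

#' Count k-mers in a sequence
#'
#' Slides a width-k window by one base over `seq`; each valid window (no
#' character outside `{A,C,G,T}`) increments its k-mer's count, so the counts
#' sum to the number of valid windows — `L - k + 1` on an unambiguous
#' sequence.
#'
#' @param seq DNA string (uppercased internally).
#' @param vocab a [kmer_vocabulary()].
#' @param seq_id optional identifier stored in the result.
#' @return a `SparseKmerVector` in count mode.
#' @export
count_kmers <- function(seq, vocab, seq_id = NA_character_) {
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L < vocab$k) stop("sequence shorter than k")
  raw <- .window_raw_indices(seq, vocab$k)
  raw <- raw[!is.na(raw)]
  feat <- .raw_to_feature(raw, vocab)
  if (length(feat) == 0L)
    return(.new_sparse_vector(integer(0), numeric(0), vocab$n, "count", seq_id, L))
  tab <- table(feat)
  .new_sparse_vector(as.integer(names(tab)), as.numeric(tab), vocab$n,
                     "count", seq_id, L)
}

#' Conservation-weighted k-mer features
#'
#' Each valid window occurrence contributes the mean conservation frequency
#' of its k bases, `(1/k) * sum(fre)`, instead of a unit count; summing over
#' occurrences gives the conservation-weighted feature value, which is
#' bounded above by the plain count and equals it iff every touched
#' frequency is 1.
#'
#' @param seq DNA string.
#' @param offset 0-based genomic start of `seq` on `chrom` (track addressing).
#' @param track a [conservation_track()].
#' @param vocab a [kmer_vocabulary()].
#' @param chrom record name used for track lookup.
#' @param seq_id optional identifier stored in the result.
#' @return a `SparseKmerVector` in conservation mode.
#' @export
weight_kmers_by_conservation <- function(seq, offset, track, vocab,
                                         chrom = names(track$values)[1],
                                         seq_id = NA_character_) {
  seq <- toupper(seq)
  L <- nchar(seq)
  k <- vocab$k
  if (L < k) stop("sequence shorter than k")
  raw <- .window_raw_indices(seq, k)
  fre <- track_values(track, chrom, offset + 0:(L - 1L))
  # per-window mean of fre over the k covered bases, via cumulative sums
  cs <- c(0, cumsum(fre))
  wmean <- (cs[(k + 1L):(L + 1L)] - cs[1:(L - k + 1L)]) / k
  ok <- !is.na(raw)
  raw <- raw[ok]; wmean <- wmean[ok]
  feat <- .raw_to_feature(raw, vocab)
  if (length(feat) == 0L)
    return(.new_sparse_vector(integer(0), numeric(0), vocab$n, "conservation",
                              seq_id, L))
  agg <- rowsum(wmean, feat)
  .new_sparse_vector(as.integer(rownames(agg)), as.numeric(agg), vocab$n,
                     "conservation", seq_id, L)
}

#' Build a feature matrix from genome intervals
#'
#' One feature vector per interval, in input order; conservation mode is
#' used iff `track` is supplied. Intervals shorter than k are dropped with a
#' warning; the drop count is attached as attribute `n_dropped`.
#'
#' @param genome a `GenomeSource`.
#' @param intervals an `IntervalSet` (labels `positive` -> 1, `negative` -> 0).
#' @param vocab a [kmer_vocabulary()].
#' @param track optional [conservation_track()] enabling conservation mode.
#' @return a `FeatureMatrix`: sparse `Matrix::dgCMatrix` `X` (samples x
#'   features), integer `labels`, the vocabulary and the mode.
#' @export
build_feature_matrix <- function(genome, intervals, vocab, track = NULL) {
  if (nrow(intervals) == 0L) stop("no intervals supplied")
  keep <- (intervals$end - intervals$start) >= vocab$k
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    warning(n_dropped, " interval(s) shorter than k dropped")
  intervals <- intervals[keep, , drop = FALSE]
  if (nrow(intervals) == 0L) stop("all intervals shorter than k")
  vecs <- lapply(seq_len(nrow(intervals)), function(r) {
    seq <- get_sequence(genome, intervals$chrom[r], intervals$start[r],
                        intervals$end[r])
    id <- sprintf("%s:%d-%d", intervals$chrom[r], intervals$start[r],
                  intervals$end[r])
    if (is.null(track)) count_kmers(seq, vocab, seq_id = id)
    else weight_kmers_by_conservation(seq, intervals$start[r], track, vocab,
                                      chrom = intervals$chrom[r], seq_id = id)
  })
  X <- Matrix::sparseMatrix(
    i = rep(seq_along(vecs), vapply(vecs, function(v) length(v$i), integer(1))),
    j = unlist(lapply(vecs, `[[`, "i")),
    x = unlist(lapply(vecs, `[[`, "x")),
    dims = c(length(vecs), vocab$n))
  rownames(X) <- vapply(vecs, `[[`, character(1), "seq_id")
  fm <- structure(list(X = X,
                       labels = as.integer(intervals$label == "positive"),
                       vocab = vocab,
                       mode = if (is.null(track)) "count" else "conservation"),
                  class = "FeatureMatrix")
  attr(fm, "n_dropped") <- n_dropped
  fm
}

#' @export
print.FeatureMatrix <- function(x, ...) {
  cat(sprintf("FeatureMatrix: %d samples x %d features (%s mode), %d positive / %d negative\n",
              nrow(x$X), ncol(x$X), x$mode, sum(x$labels == 1), sum(x$labels == 0)))
  invisible(x)
}

#' Subset a FeatureMatrix by sample
#'
#' @param fm a `FeatureMatrix`.
#' @param idx sample indices.
#' @return the subsetted `FeatureMatrix`.
#' @export
subset_samples <- function(fm, idx) {
  out <- fm
  out$X <- fm$X[idx, , drop = FALSE]
  out$labels <- fm$labels[idx]
  out
}

#' Write a FeatureMatrix in SVMlight/LIBSVM sparse text format
#'
#' One line per sample: `label index:value ...` with 1-based feature
#' indices in ascending order. A companion JSON header (`<path>.vocab.json`)
#' records k, rc_collapse and the dimension.
#'
#' @param fm a `FeatureMatrix`.
#' @param path output path.
#' @export
write_svmlight <- function(fm, path) {
  Xt <- Matrix::t(fm$X)           # column-per-sample for fast per-sample slices
  p <- Xt@p; i <- Xt@i; x <- Xt@x
  lines <- vapply(seq_len(ncol(Xt)), function(s) {
    r <- if (p[s + 1L] > p[s]) (p[s] + 1L):p[s + 1L] else integer(0)
    paste(c(fm$labels[s], sprintf("%d:%.10g", i[r] + 1L, x[r])), collapse = " ")
  }, character(1))
  writeLines(lines, path)
  jsonlite::write_json(list(k = fm$vocab$k, rc_collapse = fm$vocab$rc_collapse,
                            n = fm$vocab$n, mode = fm$mode,
                            checksum = .vocab_checksum(fm$vocab)),
                       paste0(path, ".vocab.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read an SVMlight/LIBSVM sparse text file
#'
#' @param path file written by [write_svmlight()] (the companion
#'   `.vocab.json` must be present).
#' @return a `FeatureMatrix`.
#' @export
read_svmlight <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".vocab.json"), simplifyVector = TRUE)
  vocab <- kmer_vocabulary(hdr$k, hdr$rc_collapse)
  lines <- readLines(path)
  toks <- strsplit(lines, " ", fixed = TRUE)
  labels <- as.integer(vapply(toks, `[`, character(1), 1L))
  ij <- lapply(seq_along(toks), function(s) {
    tt <- toks[[s]][-1L]
    tt <- tt[nzchar(tt)]
    if (length(tt) == 0L) return(NULL)
    parts <- strsplit(tt, ":", fixed = TRUE)
    data.frame(i = s, j = as.integer(vapply(parts, `[`, character(1), 1L)),
               x = as.numeric(vapply(parts, `[`, character(1), 2L)))
  })
  ij <- do.call(rbind, ij)
  X <- if (is.null(ij))
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(length(labels), vocab$n))
  else
    Matrix::sparseMatrix(i = ij$i, j = ij$j, x = ij$x,
                         dims = c(length(labels), vocab$n))
  structure(list(X = X, labels = labels, vocab = vocab,
                 mode = if (is.null(hdr$mode)) "count" else hdr$mode),
            class = "FeatureMatrix")
}
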