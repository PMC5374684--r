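# SNV impact scoring. A substitution at one position alters only the (up
# to) k k-mer windows that overlap it; the variant's impact is accumulated
# from the change in MDA importance between each window's reference and
# alternate k-mer. Three aggregates are reported: the sum of |delta| (the
# default ranking key — disruption regardless of direction), the signed sum,
# and the mean |delta| per contributing window.

#' Enumerate the k-mer window pairs a variant alters
#'
#' Windows start at offsets `-(k-1) .. 0` relative to the variant; windows
#' truncated by a sequence end, or whose reference version contains a
#' non-ACGT base, are dropped (both versions, to keep ref/alt symmetric).
#'
#' @param genome a `GenomeSource`.
#' @param variant one-row data.frame (or list) with chrom, pos (1-based),
#'   ref, alt.
#' @param k window width.
#' @return `data.frame` with columns offset, ref_kmer, alt_kmer; each
#'   ref/alt pair differs at exactly one position (the variant's).
#' @export
enumerate_affected_windows <- function(genome, variant, k) {
  chrom <- variant$chrom
  if (!chrom %in% names(genome$seqs)) stop("unknown record '", chrom, "'")
  pos0 <- variant$pos - 1L
  L <- genome$lengths[[chrom]]
  gbase <- get_sequence(genome, chrom, pos0, pos0 + 1L)
  if (gbase != toupper(variant$ref))
    stop(sprintf("variant %s:%d ref '%s' does not match genome base '%s'",
                 chrom, variant$pos, variant$ref, gbase))
  offs <- (-(k - 1L)):0L
  starts <- pos0 + offs
  keep <- starts >= 0L & (starts + k) <= L
  offs <- offs[keep]; starts <- starts[keep]
  ref_kmer <- vapply(starts, function(s) get_sequence(genome, chrom, s, s + k),
                     character(1))
  within <- pos0 - starts + 1L            # variant's 1-based position in window
  alt_kmer <- ref_kmer
  substr(alt_kmer, within, within) <- rep(toupper(variant$alt), length(alt_kmer))
  ok <- !grepl("[^ACGT]", ref_kmer)
  data.frame(offset = offs[ok], ref_kmer = ref_kmer[ok],
             alt_kmer = alt_kmer[ok], stringsAsFactors = FALSE)
}

#' Score one SNV from the MDA table
#'
#' Per affected window, `delta = MDA(alt k-mer) - MDA(ref k-mer)`;
#' aggregates: `score_abs` (sum of |delta|), `score_signed` (sum of delta),
#' `score_mean_abs` (`score_abs` / number of contributing windows). A
#' degenerate variant with `ref == alt` scores exactly 0 with no
#' contributions. MDA values are used as-is (permutation noise can make
#' them slightly negative); set `clamp_negative` to floor them at 0.
#'
#' @param genome a `GenomeSource`.
#' @param variant one-row data.frame (or list) with chrom, pos, ref, alt,
#'   optionally id.
#' @param table an [compute_mda()] result (or [read_mda_table()]).
#' @param vocab the matching [kmer_vocabulary()].
#' @param clamp_negative floor negative MDA values at 0 before scoring?
#' @return a `VariantScore` list: the variant, the per-window contribution
#'   table, the three aggregates and `n_contributions`.
#' @export
score_variant <- function(genome, variant, table, vocab,
                          clamp_negative = FALSE) {
  if (!identical(.vocab_checksum(vocab), table$vocab_checksum))
    stop("vocabulary does not match the MDA table")
  id <- if (!is.null(variant$id)) variant$id else "."
  vv <- list(chrom = variant$chrom, pos = as.integer(variant$pos),
             id = id, ref = toupper(variant$ref), alt = toupper(variant$alt))
  if (vv$ref == vv$alt) {
    contrib <- data.frame(offset = integer(0), ref_kmer = character(0),
                          alt_kmer = character(0), ref_mda = numeric(0),
                          alt_mda = numeric(0), delta = numeric(0))
    out <- list(variant = vv, contributions = contrib, score_abs = 0,
                score_signed = 0, score_mean_abs = 0, n_contributions = 0L)
    class(out) <- "VariantScore"
    return(out)
  }
  w <- enumerate_affected_windows(genome, vv, vocab$k)
  mda <- table$mda
  if (clamp_negative) mda <- pmax(mda, 0)
  ref_mda <- mda[kmer_index(w$ref_kmer, vocab)]
  alt_mda <- mda[kmer_index(w$alt_kmer, vocab)]
  contrib <- cbind(w, ref_mda = ref_mda, alt_mda = alt_mda,
                   delta = alt_mda - ref_mda)
  out <- list(variant = vv, contributions = contrib,
              score_abs = sum(abs(contrib$delta)),
              score_signed = sum(contrib$delta),
              score_mean_abs = sum(abs(contrib$delta)) / max(1L, nrow(contrib)),
              n_contributions = nrow(contrib))
  class(out) <- "VariantScore"
  out
}

#' @export
print.VariantScore <- function(x, ...) {
  cat(sprintf("VariantScore %s:%d %s>%s  |sum|=%.4g signed=%.4g windows=%d\n",
              x$variant$chrom, x$variant$pos, x$variant$ref, x$variant$alt,
              x$score_abs, x$score_signed, x$n_contributions))
  invisible(x)
}

#' Score and rank a set of SNVs
#'
#' Variants whose ref allele mismatches the genome are skipped and counted
#' (attribute `n_skipped`), not fatal; an error is raised only when every
#' variant is rejected.
#'
#' @param genome a `GenomeSource`.
#' @param variants data.frame with chrom, pos, id, ref, alt (e.g. from
#'   [read_vcf()]).
#' @param table an `MdaTable`.
#' @param vocab the matching vocabulary.
#' @param primary aggregate used for ranking: `"abs"`, `"signed"` or
#'   `"mean_abs"`.
#' @param clamp_negative see [score_variant()].
#' @return `data.frame` sorted descending by the primary score, with columns
#'   chrom, pos, id, ref, alt, n_windows, score_abs, score_signed,
#'   score_mean_abs, rank.
#' @export
score_variant_set <- function(genome, variants, table, vocab,
                              primary = c("abs", "signed", "mean_abs"),
                              clamp_negative = FALSE) {
  primary <- match.arg(primary)
  if (nrow(variants) == 0L) stop("no variants supplied")
  rows <- vector("list", nrow(variants))
  n_skipped <- 0L
  for (i in seq_len(nrow(variants))) {
    vs <- tryCatch(score_variant(genome, variants[i, ], table, vocab,
                                 clamp_negative = clamp_negative),
                   error = function(e) NULL)
    if (is.null(vs)) { n_skipped <- n_skipped + 1L; next }
    rows[[i]] <- data.frame(chrom = vs$variant$chrom, pos = vs$variant$pos,
                            id = vs$variant$id, ref = vs$variant$ref,
                            alt = vs$variant$alt,
                            n_windows = vs$n_contributions,
                            score_abs = vs$score_abs,
                            score_signed = vs$score_signed,
                            score_mean_abs = vs$score_mean_abs,
                            stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) stop("all variants rejected (ref mismatches?)")
  out <- do.call(rbind, rows)
  key <- switch(primary, abs = out$score_abs, signed = out$score_signed,
                mean_abs = out$score_mean_abs)
  out <- out[order(-key), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  attr(out, "primary") <- primary
  out
}

#' Compare the score distributions of two variant groups
#'
#' @param scores_a,scores_b numeric score vectors (e.g. `score_abs` of a
#'   pathogenic-like and a normal-like panel).
#' @return list with per-group mean/median, the two-sided Wilcoxon rank-sum
#'   test (statistic and p-value), and `separation_auc`: the probability
#'   that a random a-score exceeds a random b-score, ties counting one half.
#' @export
compare_score_distributions <- function(scores_a, scores_b) {
  if (length(scores_a) == 0L || length(scores_b) == 0L)
    stop("both groups must be non-empty")
  na <- length(scores_a); nb <- length(scores_b)
  r <- rank(c(scores_a, scores_b))           # midranks handle ties as 1/2
  auc <- (sum(r[seq_len(na)]) - na * (na + 1) / 2) / (na * nb)
  wt <- suppressWarnings(wilcox.test(scores_a, scores_b,
                                     alternative = "two.sided"))
  list(mean_a = mean(scores_a), mean_b = mean(scores_b),
       median_a = median(scores_a), median_b = median(scores_b),
       wilcoxon_statistic = unname(wt$statistic),
       wilcoxon_p = wt$p.value,
       separation_auc = auc)
}

#' Write a scored variant table to TSV
#'
#' @param scored result of [score_variant_set()].
#' @param path output path.
#' @export
write_variant_scores <- function(scored, path) {
  utils::write.table(scored, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
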