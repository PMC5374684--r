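test_that("affected-window enumeration yields k aligned pairs, truncated at sequence ends", {
  set.seed(51)
  g <- genome_source(c(chr1 = random_dna(40)))
  v <- list(chrom = "chr1", pos = 20L,
            ref = get_sequence(g, "chr1", 19, 20), alt = "X")
  v$alt <- setdiff(c("A", "C", "G", "T"), v$ref)[1]
  w <- enumerate_affected_windows(g, v, k = 3)
  expect_equal(nrow(w), 3L)                       # full flanks: exactly k pairs
  expect_equal(w$offset, -2:0)
  # each pair differs at exactly one position, the variant's
  for (i in seq_len(nrow(w))) {
    diffs <- which(strsplit(w$ref_kmer[i], "")[[1]] != strsplit(w$alt_kmer[i], "")[[1]])
    expect_equal(diffs, 1L - w$offset[i])
  }
  # near the left edge only the windows that fit remain
  v2 <- list(chrom = "chr1", pos = 2L, ref = get_sequence(g, "chr1", 1, 2), alt = v$alt)
  expect_equal(nrow(enumerate_affected_windows(g, v2, k = 3)), 2L)
  expect_error(enumerate_affected_windows(g, list(chrom = "chrZ", pos = 1, ref = "A", alt = "C"), 3),
               "unknown record")
})

test_that("the hand-enumerated window pairs for AACGTT match", {
  g <- genome_source(c(chr1 = "AACGTT"))
  v <- list(chrom = "chr1", pos = 3L, ref = "C", alt = "A")
  w <- enumerate_affected_windows(g, v, k = 2)
  expect_equal(w$ref_kmer, c("AC", "CG"))
  expect_equal(w$alt_kmer, c("AA", "AG"))
})

test_that("windows with ambiguous reference bases are dropped from both sides", {
  g <- genome_source(c(chr1 = "ANACGTA"))
  v <- list(chrom = "chr1", pos = 4L, ref = "C", alt = "T")
  w <- enumerate_affected_windows(g, v, k = 3)    # window starting at the N is dropped
  expect_equal(w$ref_kmer, c("ACG", "CGT"))
})

test_that("variant scores aggregate per-window MDA deltas", {
  vocab <- kmer_vocabulary(3)
  g <- genome_source(c(chr1 = "TTACGTT"))
  mda <- numeric(vocab$n)
  mda[kmer_index("ACG", vocab)] <- 1.0
  tab <- toy_mda_table(mda, vocab)
  # C>T at 1-based 4 destroys the only ACG occurrence and creates none
  v <- list(chrom = "chr1", pos = 4L, id = "toy", ref = "C", alt = "T")
  vs <- score_variant(g, v, tab, vocab)
  expect_equal(vs$score_abs, 1.0)
  expect_equal(vs$score_signed, -1.0)
  expect_equal(vs$n_contributions, 3L)
  expect_equal(vs$score_mean_abs, 1 / 3)

  # all-zero table scores zero; degenerate ref == alt scores exactly zero
  vs0 <- score_variant(g, v, toy_mda_table(numeric(vocab$n), vocab), vocab)
  expect_equal(vs0$score_abs, 0)
  vsd <- score_variant(g, list(chrom = "chr1", pos = 4L, ref = "C", alt = "C"),
                       tab, vocab)
  expect_identical(vsd$score_abs, 0)
  expect_identical(vsd$n_contributions, 0L)

  expect_error(score_variant(g, list(chrom = "chr1", pos = 4L, ref = "G", alt = "T"),
                             tab, vocab), "does not match genome")
})

test_that("the signed score equals the full-recount feature-difference oracle", {
  # recounting the entire ref and alt sequences and taking
  # sum_j MDA_j * (x_j^alt - x_j^ref) must reproduce score_signed exactly:
  # the window enumeration is just a sparse view of that difference
  vocab <- kmer_vocabulary(3)
  set.seed(61)
  mda <- rnorm(vocab$n, 0, 0.1)          # permutation noise can be negative; used as-is
  tab <- toy_mda_table(mda, vocab)
  for (rep in 1:10) {
    seq <- random_dna(30)
    pos0 <- sample(5:24, 1)              # full flanks, no truncation
    ref <- substr(seq, pos0 + 1, pos0 + 1)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    g <- genome_source(c(chr1 = seq))
    v <- list(chrom = "chr1", pos = pos0 + 1L, ref = ref, alt = alt)
    alt_seq <- seq; substr(alt_seq, pos0 + 1, pos0 + 1) <- alt
    x_ref <- numeric(vocab$n); x_alt <- numeric(vocab$n)
    vr <- count_kmers(seq, vocab); x_ref[vr$i] <- vr$x
    va <- count_kmers(alt_seq, vocab); x_alt[va$i] <- va$x
    vs <- score_variant(g, v, tab, vocab)
    expect_equal(vs$score_signed, sum(mda * (x_alt - x_ref)), tolerance = 1e-12)
    expect_gte(vs$score_abs, abs(vs$score_signed) - 1e-12)
  }
})

test_that("with a single changed window the absolute and feature-wise scores coincide", {
  vocab <- kmer_vocabulary(3)
  set.seed(62)
  mda <- rnorm(vocab$n, 0, 0.1)
  tab <- toy_mda_table(mda, vocab)
  for (rep in 1:5) {
    seq <- random_dna(20)
    pos0 <- 19L                          # last base: only one window fits
    ref <- substr(seq, 20, 20)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    g <- genome_source(c(chr1 = seq))
    vs <- score_variant(g, list(chrom = "chr1", pos = 20L, ref = ref, alt = alt),
                        tab, vocab)
    expect_equal(vs$n_contributions, 1L)
    expect_equal(vs$score_abs, abs(vs$score_signed), tolerance = 1e-12)
    w <- enumerate_affected_windows(g, list(chrom = "chr1", pos = 20L,
                                            ref = ref, alt = alt), 3)
    expect_equal(vs$score_abs,
                 abs(mda[kmer_index(w$alt_kmer, vocab)] -
                     mda[kmer_index(w$ref_kmer, vocab)]),
                 tolerance = 1e-12)
  }
})

test_that("clamping floors negative MDA values before scoring", {
  vocab <- kmer_vocabulary(3)
  g <- genome_source(c(chr1 = "TTACGTT"))
  mda <- numeric(vocab$n)
  mda[kmer_index("ACG", vocab)] <- -0.5
  tab <- toy_mda_table(mda, vocab)
  v <- list(chrom = "chr1", pos = 4L, ref = "C", alt = "T")
  expect_equal(score_variant(g, v, tab, vocab)$score_abs, 0.5)
  expect_equal(score_variant(g, v, tab, vocab, clamp_negative = TRUE)$score_abs, 0)
})

test_that("variant sets are ranked, duplicates kept, and ref mismatches skipped", {
  vocab <- kmer_vocabulary(3)
  set.seed(71)
  g <- genome_source(c(chr1 = random_dna(60)))
  tab <- toy_mda_table(abs(rnorm(vocab$n, 0, 0.1)), vocab)
  mk <- function(pos, id) {
    ref <- get_sequence(g, "chr1", pos - 1, pos)
    data.frame(chrom = "chr1", pos = pos, id = id, ref = ref,
               alt = setdiff(c("A", "C", "G", "T"), ref)[1],
               stringsAsFactors = FALSE)
  }
  vars <- rbind(mk(10L, "a"), mk(20L, "b"), mk(10L, "a_dup"),
                data.frame(chrom = "chr1", pos = 30L, id = "bad", ref = "Z",
                           alt = "A", stringsAsFactors = FALSE))
  scored <- score_variant_set(g, vars, tab, vocab)
  expect_equal(nrow(scored), 3L)
  expect_equal(attr(scored, "n_skipped"), 1L)
  expect_equal(scored$rank, 1:3)
  expect_true(all(diff(scored$score_abs) <= 0))
  expect_equal(scored$score_abs[scored$id == "a"], scored$score_abs[scored$id == "a_dup"])
  expect_equal(nrow(score_variant_set(g, mk(15L, "solo"), tab, vocab)), 1L)
  expect_error(score_variant_set(g, vars[4, ], tab, vocab), "all variants rejected")
})

test_that("score distributions compare via rank-sum AUC with half-credit ties", {
  a <- c(1, 3); b <- c(2)
  expect_equal(compare_score_distributions(a, b)$separation_auc, 0.5)
  expect_equal(compare_score_distributions(c(1, 2), c(1, 2))$separation_auc, 0.5)
  expect_equal(compare_score_distributions(c(5, 6), c(1, 2))$separation_auc, 1.0)
  cmp <- compare_score_distributions(c(5, 6, 7), c(1, 2))
  expect_equal(cmp$mean_a, 6)
  expect_true(cmp$wilcoxon_p <= 1)
  expect_error(compare_score_distributions(numeric(0), 1), "non-empty")
})

test_that("reverse-complement-collapsed scoring is strand symmetric", {
  vocab <- kmer_vocabulary(3, rc_collapse = TRUE)
  set.seed(81)
  tab <- toy_mda_table(abs(rnorm(vocab$n, 0, 0.1)), vocab)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (rep in 1:10) {
    seq <- random_dna(30)
    pos0 <- sample(5:24, 1)
    ref <- substr(seq, pos0 + 1, pos0 + 1)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    fwd <- score_variant(genome_source(c(chr = seq)),
                         list(chrom = "chr", pos = pos0 + 1L, ref = ref, alt = alt),
                         tab, vocab)
    mirror_pos0 <- nchar(seq) - 1 - pos0
    rev <- score_variant(genome_source(c(chr = revcomp(seq))),
                         list(chrom = "chr", pos = mirror_pos0 + 1L,
                              ref = comp[[ref]], alt = comp[[alt]]),
                         tab, vocab)
    expect_equal(rev$score_abs, fwd$score_abs, tolerance = 1e-12)
  }
})
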