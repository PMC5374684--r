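# Seed-deterministic synthetic benchmark data: a random background genome,
# motif-enriched positive intervals versus background negatives, a
# conservation track elevated over planted motif spans, and
# pathogenic-like / normal-like SNV panels. Every planted motif occurrence
# is recorded in a truth table; chance background occurrences of the motif
# words are detected and logged as "incidental", not scrubbed — real peak
# sets carry the same ambiguity.

#' Simulation configuration
#'
#' Defaults describe the standard benchmark: a 200 kb background genome,
#' 300 positive and 300 negative intervals of 150-300 bp, one planted
#' 6-mer word ("GATAAG", a pioneer-factor-like consensus) inserted in each
#' positive interval with probability 0.9, conservation ~0.95 inside motif
#' spans vs ~0.55 in background (sd 0.05, clipped to `[0,1]`), and
#' 200 + 200 SNVs for the pathogenic-like / normal-like panels.
#'
#' @param seed master seed; all outputs are fully determined by it.
#' @param genome_length background genome length in bp.
#' @param chrom name of the single simulated chromosome.
#' @param n_pos,n_neg numbers of positive / negative intervals.
#' @param length_range min/max interval length in bp.
#' @param motifs character vector of planted words over `{A,C,G,T}`.
#' @param motif_prob per-positive-interval probability of inserting each word.
#' @param base_probs background composition for A, C, G, T.
#' @param cons_motif,cons_bg,cons_sd conservation-track means inside motif
#'   spans / in background, and the per-base jitter sd.
#' @param n_pathogenic,n_normal SNV panel sizes.
#' @return a `SimConfig` list.
#' @export
sim_config <- function(seed = 1L, genome_length = 200000L, chrom = "chrS",
                       n_pos = 300L, n_neg = 300L,
                       length_range = c(150L, 300L),
                       motifs = "GATAAG", motif_prob = 0.9,
                       base_probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       cons_motif = 0.95, cons_bg = 0.55, cons_sd = 0.05,
                       n_pathogenic = 200L, n_normal = 200L) {
  stopifnot(motif_prob >= 0, motif_prob <= 1,
            all(base_probs >= 0), abs(sum(base_probs) - 1) < 1e-8,
            length_range[1] <= length_range[2],
            all(grepl("^[ACGT]+$", motifs)))
  structure(list(seed = as.integer(seed),
                 genome_length = as.integer(genome_length), chrom = chrom,
                 n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 length_range = as.integer(length_range), motifs = motifs,
                 motif_prob = motif_prob, base_probs = base_probs,
                 cons_motif = cons_motif, cons_bg = cons_bg, cons_sd = cons_sd,
                 n_pathogenic = as.integer(n_pathogenic),
                 n_normal = as.integer(n_normal)),
            class = "SimConfig")
}

# all 0-based start positions of exact occurrences of `word` in `seq`
.find_occurrences <- function(seq, word) {
  out <- integer(0); from <- 1L
  repeat {
    hit <- regexpr(word, substr(seq, from, nchar(seq)), fixed = TRUE)
    if (hit < 0) break
    out <- c(out, from + hit - 2L)   # to 0-based
    from <- from + hit               # allow overlapping occurrences
  }
  out
}

#' Simulate a genome with planted motifs, labelled intervals and a
#' conservation track
#'
#' Positive intervals are placed without mutual overlap; each receives each
#' configured motif word with the configured probability at a uniform
#' offset. Negatives are drawn by [sample_negative_intervals()]. The truth
#' record lists every planted occurrence; background occurrences that arise
#' by chance are listed separately as `incidental`.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (`GenomeSource`), `intervals` (`IntervalSet`,
#'   positives then negatives), `track` (`ConservationTrack`), `truth`
#'   (data.frame chrom/start/word of planted occurrences), `incidental`
#'   (same columns, chance occurrences) and the `config`.
#' @export
simulate_genome <- function(config = sim_config()) {
  if (any(nchar(config$motifs) > config$length_range[1]))
    stop("motif longer than the minimum interval length")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)
  L <- config$genome_length
  bases <- sample(.BASES, L, replace = TRUE, prob = config$base_probs)

  # non-overlapping positive intervals, rejection-placed
  occupied <- logical(L)
  pos_start <- integer(config$n_pos); pos_end <- integer(config$n_pos)
  placed <- 0L; attempts <- 0L
  while (placed < config$n_pos) {
    if ((attempts <- attempts + 1L) > 1000L * config$n_pos)
      stop("could not place ", config$n_pos, " positive intervals")
    len <- sample(config$length_range[1]:config$length_range[2], 1L)
    s <- sample.int(L - len + 1L, 1L) - 1L
    if (any(occupied[(s + 1L):(s + len)])) next
    placed <- placed + 1L
    pos_start[placed] <- s; pos_end[placed] <- s + len
    occupied[(s + 1L):(s + len)] <- TRUE
  }
  o <- order(pos_start)
  pos_start <- pos_start[o]; pos_end <- pos_end[o]

  # plant motif words
  truth <- list()
  for (i in seq_len(config$n_pos)) {
    for (word in config$motifs) {
      if (runif(1) > config$motif_prob) next
      w <- nchar(word)
      off <- sample.int(pos_end[i] - pos_start[i] - w + 1L, 1L) - 1L
      at <- pos_start[i] + off
      bases[(at + 1L):(at + w)] <- strsplit(word, "")[[1]]
      truth[[length(truth) + 1L]] <- data.frame(chrom = config$chrom,
                                                start = at, word = word,
                                                stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(chrom = character(0), start = integer(0), word = character(0))
  seq <- paste(bases, collapse = "")
  genome <- genome_source(setNames(seq, config$chrom))

  positives <- interval_set(config$chrom, pos_start, pos_end, "positive")
  negatives <- sample_negative_intervals(genome, positives, config$n_neg,
                                         seed = config$seed + 1L)
  intervals <- rbind(positives, negatives)
  class(intervals) <- c("IntervalSet", "data.frame")

  # conservation: elevated over planted motif spans, background elsewhere
  vals <- rnorm(L, config$cons_bg, config$cons_sd)
  for (i in seq_len(nrow(truth))) {
    span <- (truth$start[i] + 1L):(truth$start[i] + nchar(truth$word[i]))
    vals[span] <- rnorm(length(span), config$cons_motif, config$cons_sd)
  }
  track <- conservation_track(setNames(list(pmin(1, pmax(0, vals))),
                                       config$chrom), default = 1.0)

  # chance occurrences not planted by us
  incidental <- list()
  for (word in unique(config$motifs)) {
    hits <- .find_occurrences(seq, word)
    planted <- truth$start[truth$word == word]
    extra <- setdiff(hits, planted)
    if (length(extra))
      incidental[[length(incidental) + 1L]] <-
        data.frame(chrom = config$chrom, start = extra, word = word,
                   stringsAsFactors = FALSE)
  }
  incidental <- if (length(incidental)) do.call(rbind, incidental) else
    data.frame(chrom = character(0), start = integer(0), word = character(0))

  list(genome = genome, intervals = intervals, track = track, truth = truth,
       incidental = incidental, config = config)
}

#' Simulate pathogenic-like and normal-like SNV panels
#'
#' Pathogenic-like SNVs fall uniformly inside planted motif occurrences;
#' normal-like SNVs fall at background positions at least `k` bases away
#' from any motif occurrence (planted or incidental), so none of their
#' affected k-mer windows can contain a motif word of length <= k. Alt
#' alleles are uniform over the three non-reference bases; the ref allele
#' always matches the genome. The panel stream is seeded from the config
#' seed (offset by a fixed constant), independent of the genome stream.
#'
#' @param sim a [simulate_genome()] result.
#' @param k window width used for the background-distance exclusion zone.
#' @return list with `pathogenic` and `normal` variant data.frames
#'   (chrom, pos, id, ref, alt) and `labels` (1 pathogenic-like, 0 normal).
#' @export
simulate_snp_panels <- function(sim, k = 6L) {
  config <- sim$config
  truth <- sim$truth
  if (nrow(truth) < 1L) stop("truth record has no planted motif occurrences")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed((config$seed + 1000003L) %% 2147483647L)
  seq <- sim$genome$seqs[[config$chrom]]
  L <- nchar(seq)

  motif_pos0 <- unlist(lapply(seq_len(nrow(truth)), function(i)
    truth$start[i] + 0:(nchar(truth$word[i]) - 1L)))
  motif_pos0 <- unique(motif_pos0)
  if (length(motif_pos0) < 1L) stop("no motif positions available")

  draw_snv <- function(pos0, prefix, i) {
    ref <- substr(seq, pos0 + 1L, pos0 + 1L)
    alt <- sample(setdiff(.BASES, ref), 1L)
    data.frame(chrom = config$chrom, pos = pos0 + 1L,
               id = sprintf("%s_%d", prefix, i), ref = ref, alt = alt,
               stringsAsFactors = FALSE)
  }
  path_sites <- sample(motif_pos0, config$n_pathogenic, replace = TRUE)
  pathogenic <- do.call(rbind, lapply(seq_len(config$n_pathogenic), function(i)
    draw_snv(path_sites[i], "path", i)))

  # exclusion zone: within k bases of any motif occurrence span
  all_occ <- rbind(truth, sim$incidental)
  excluded <- logical(L)
  for (i in seq_len(nrow(all_occ))) {
    w <- nchar(all_occ$word[i])
    lo <- max(0L, all_occ$start[i] - k); hi <- min(L - 1L, all_occ$start[i] + w - 1L + k)
    excluded[(lo + 1L):(hi + 1L)] <- TRUE
  }
  bg_pos0 <- which(!excluded) - 1L
  if (length(bg_pos0) < 1L) stop("no background positions available")
  norm_sites <- sample(bg_pos0, config$n_normal, replace = TRUE)
  normal <- do.call(rbind, lapply(seq_len(config$n_normal), function(i)
    draw_snv(norm_sites[i], "norm", i)))

  list(pathogenic = pathogenic, normal = normal,
       labels = c(rep(1L, nrow(pathogenic)), rep(0L, nrow(normal))))
}

#' Write a simulation to disk
#'
#' Writes `genome.fa`, `intervals.bed` (with label column), `conservation.
#' bedGraph`, `pathogenic.vcf`, `normal.vcf` and `truth.json`.
#'
#' @param sim a [simulate_genome()] result.
#' @param dir output directory (created if needed).
#' @param panels optional [simulate_snp_panels()] result.
#' @return named vector of written paths.
#' @export
write_simulation <- function(sim, dir, panels = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             intervals = file.path(dir, "intervals.bed"),
             track = file.path(dir, "conservation.bedGraph"),
             truth = file.path(dir, "truth.json"))
  seqs <- sim$genome$seqs
  writeLines(unlist(lapply(names(seqs), function(ch)
    c(paste0(">", ch),
      substring(seqs[[ch]], seq(1, nchar(seqs[[ch]]), 80),
                pmin(nchar(seqs[[ch]]), seq(80, nchar(seqs[[ch]]) + 79, 80)))))),
    paths["genome"])
  write_bed(sim$intervals, paths["intervals"])
  write_bedgraph(sim$track, paths["track"])
  jsonlite::write_json(list(planted = sim$truth, incidental = sim$incidental,
                            seed = sim$config$seed),
                       paths["truth"], auto_unbox = TRUE, digits = NA)
  if (!is.null(panels)) {
    paths <- c(paths, pathogenic = file.path(dir, "pathogenic.vcf"),
               normal = file.path(dir, "normal.vcf"))
    write_vcf(panels$pathogenic, paths["pathogenic"])
    write_vcf(panels$normal, paths["normal"])
  }
  paths
}
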