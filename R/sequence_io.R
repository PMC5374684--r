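# Readers/writers for the genomic formats the pipeline touches, with fixed
# coordinate conventions: BED is 0-based half-open, VCF is 1-based, and all
# internal arithmetic is 0-based half-open. Sequences are uppercased at load.

#' Build a genome source from named sequences
#'
#' @param seqs named character vector (chromosome id -> DNA string).
#' @return an object of class `GenomeSource`.
#' @export
genome_source <- function(seqs) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named")
  seqs <- toupper(unlist(seqs))
  structure(list(seqs = seqs, lengths = setNames(nchar(seqs), names(seqs))),
            class = "GenomeSource")
}

#' Read a FASTA file into a GenomeSource
#'
#' Sequences are uppercased; gzip input is handled transparently.
#'
#' @param path FASTA file.
#' @return a `GenomeSource`.
#' @export
read_genome_fasta <- function(path) {
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) stop("malformed FASTA '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  if (length(ss) == 0L) stop("FASTA '", path, "' contains no records")
  seqs <- as.character(ss)
  # FASTA headers may carry descriptions; record ids are the first word
  names(seqs) <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L)
  genome_source(seqs)
}

#' @export
print.GenomeSource <- function(x, ...) {
  cat(sprintf("GenomeSource: %d record(s), %s bp total\n",
              length(x$seqs), format(sum(x$lengths), big.mark = ",")))
  invisible(x)
}

#' Extract a genome slice
#'
#' @param genome a `GenomeSource`.
#' @param chrom record name.
#' @param start,end 0-based half-open coordinates; exactly `end - start`
#'   characters are returned.
#' @return uppercase DNA string.
#' @export
get_sequence <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome$seqs)) stop("unknown record '", chrom, "'")
  L <- genome$lengths[[chrom]]
  if (start < 0 || end > L || start >= end)
    stop(sprintf("invalid slice [%d, %d) on '%s' (length %d)", start, end, chrom, L))
  substr(genome$seqs[[chrom]], start + 1L, end)
}

#' Build an interval set
#'
#' @param chrom,start,end parallel vectors; 0-based half-open coordinates.
#' @param label per-interval label, `"positive"` or `"negative"`.
#' @return a `data.frame` with class `IntervalSet`.
#' @export
interval_set <- function(chrom, start, end, label = "positive") {
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), label = as.character(label),
                   stringsAsFactors = FALSE)
  if (any(df$start >= df$end)) stop("intervals must satisfy start < end")
  if (!all(df$label %in% c("positive", "negative")))
    stop("labels must be 'positive' or 'negative'")
  class(df) <- c("IntervalSet", "data.frame")
  df
}

#' Read a BED3+ file of intervals
#'
#' Columns: chrom, start, end and an optional 4th label column
#' (`positive`/`negative`; anything else, or its absence, defaults to
#' `positive`). Coordinates are 0-based half-open per the BED standard.
#' Intervals outside the genome bounds are rejected; their count is attached
#' as attribute `n_rejected` and reported in a warning.
#'
#' @param path BED file (plain or gzip).
#' @param genome `GenomeSource` used for bounds validation.
#' @return an `IntervalSet`.
#' @export
read_bed <- function(path, genome) {
  con <- gzfile(path, "rt"); on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                 !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (length(lines) == 0L) {
    warning("BED file '", path, "' contains no intervals")
    out <- interval_set(character(0), integer(0), integer(0), character(0))
    attr(out, "n_rejected") <- 0L
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  parse_row <- function(i) {
    f <- fields[[i]]
    if (length(f) < 3L)
      stop("BED line ", i, ": fewer than 3 columns", call. = FALSE)
    s <- suppressWarnings(as.integer(f[2])); e <- suppressWarnings(as.integer(f[3]))
    if (is.na(s) || is.na(e) || f[2] != as.character(s) || f[3] != as.character(e))
      stop("BED line ", i, ": non-integer coordinates '", f[2], "', '", f[3], "'",
           call. = FALSE)
    lab <- if (length(f) >= 4L && f[4] %in% c("positive", "negative")) f[4] else "positive"
    list(chrom = f[1], start = s, end = e, label = lab)
  }
  rows <- lapply(seq_along(fields), parse_row)
  df <- data.frame(chrom = vapply(rows, `[[`, character(1), "chrom"),
                   start = vapply(rows, `[[`, integer(1), "start"),
                   end = vapply(rows, `[[`, integer(1), "end"),
                   label = vapply(rows, `[[`, character(1), "label"),
                   stringsAsFactors = FALSE)
  lens <- genome$lengths[df$chrom]
  ok <- !is.na(lens) & df$start >= 0 & df$start < df$end & df$end <= lens
  n_rej <- sum(!ok)
  if (n_rej > 0)
    warning(n_rej, " interval(s) rejected (unknown record or out of bounds)")
  out <- df[ok, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("IntervalSet", "data.frame")
  attr(out, "n_rejected") <- n_rej
  out
}

#' Write an IntervalSet to BED (chrom, start, end, label)
#'
#' @param intervals an `IntervalSet`.
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s", intervals$chrom, intervals$start,
                     intervals$end, intervals$label), path)
  invisible(path)
}

#' Read SNVs from a VCF
#'
#' Multi-allelic records are split into one variant per alternate allele.
#' Records are excluded (and counted) when the ref or alt allele is not a
#' single `A/C/G/T` base (indels, symbolic alleles) or when the ref base does
#' not match the genome. Exclusion counts are attached as attributes
#' `n_not_snv` and `n_ref_mismatch`.
#'
#' @param path VCF file (plain or gzip).
#' @param genome `GenomeSource` for the ref-allele check.
#' @return `data.frame` with columns chrom, pos (1-based), id, ref, alt.
#' @export
read_vcf <- function(path, genome) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("unreadable VCF '", path, "': ",
                                         conditionMessage(e), call. = FALSE))
  fix <- vcfR::getFIX(v)
  if (!is.matrix(fix)) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    out <- data.frame(chrom = character(0), pos = integer(0), id = character(0),
                      ref = character(0), alt = character(0))
    attr(out, "n_not_snv") <- 0L; attr(out, "n_ref_mismatch") <- 0L
    return(out)
  }
  alts <- strsplit(ifelse(is.na(fix$ALT), "", fix$ALT), ",", fixed = TRUE)
  rep_i <- rep(seq_len(nrow(fix)), lengths(alts))
  df <- data.frame(chrom = fix$CHROM[rep_i],
                   pos = as.integer(fix$POS[rep_i]),
                   id = ifelse(is.na(fix$ID[rep_i]), ".", fix$ID[rep_i]),
                   ref = toupper(fix$REF[rep_i]),
                   alt = toupper(unlist(alts)),
                   stringsAsFactors = FALSE)
  is_snv <- df$ref %in% .BASES & df$alt %in% .BASES
  n_not_snv <- sum(!is_snv)
  df <- df[is_snv, , drop = FALSE]
  gbase <- vapply(seq_len(nrow(df)), function(i) {
    if (!df$chrom[i] %in% names(genome$seqs)) return(NA_character_)
    if (df$pos[i] < 1 || df$pos[i] > genome$lengths[[df$chrom[i]]]) return(NA_character_)
    get_sequence(genome, df$chrom[i], df$pos[i] - 1L, df$pos[i])
  }, character(1))
  ok <- !is.na(gbase) & gbase == df$ref
  n_mismatch <- sum(!ok)
  out <- df[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_not_snv") <- n_not_snv
  attr(out, "n_ref_mismatch") <- n_mismatch
  out
}

#' Write SNVs to a minimal VCF 4.2 file
#'
#' @param variants data.frame with chrom, pos, id, ref, alt.
#' @param path output path.
#' @export
write_vcf <- function(variants, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.", variants$chrom,
                  as.integer(variants$pos), variants$id, variants$ref,
                  variants$alt)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Build a conservation track from per-chromosome value vectors
#'
#' Values are per-base conservation frequencies in `[0,1]` (the frequency
#' with which the human base is seen at the aligned position across species).
#' Positions not covered by `values` return `default`; with the default of 1
#' the conservation-weighted features reduce to plain counts wherever the
#' track is missing.
#'
#' @param values named list of numeric vectors; element i of a chromosome's
#'   vector is the value at 0-based position i-1.
#' @param default value for uncovered positions.
#' @return an object of class `ConservationTrack`.
#' @export
conservation_track <- function(values = list(), default = 1.0) {
  stopifnot(default >= 0, default <= 1)
  values <- lapply(values, as.numeric)
  bad <- vapply(values, function(v) any(v < 0 | v > 1, na.rm = TRUE), logical(1))
  if (any(bad)) {
    warning("conservation values outside [0,1] clipped")
    values <- lapply(values, function(v) pmin(1, pmax(0, v)))
  }
  structure(list(values = values, default = default), class = "ConservationTrack")
}

#' Read a bedGraph conservation track
#'
#' @param path bedGraph file (plain or gzip); column 4 holds the per-base
#'   value over the 0-based half-open interval of columns 2-3.
#' @param default value returned for uncovered positions (see
#'   [conservation_track()]).
#' @return a `ConservationTrack`.
#' @export
read_conservation <- function(path, default = 1.0) {
  gr <- tryCatch(rtracklayer::import(path, format = "bedGraph"),
                 error = function(e) stop("malformed bedGraph '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  values <- list()
  if (length(gr) > 0) {
    grdf <- as.data.frame(gr)
    df <- data.frame(chrom = as.character(grdf$seqnames),
                     start = grdf$start - 1L,  # GRanges is 1-based; back to 0-based
                     end = grdf$end,
                     score = grdf$score, stringsAsFactors = FALSE)
    for (ch in unique(df$chrom)) {
      sub <- df[df$chrom == ch, , drop = FALSE]
      vec <- rep(default, max(sub$end))
      for (i in seq_len(nrow(sub)))
        vec[(sub$start[i] + 1L):sub$end[i]] <- sub$score[i]
      values[[ch]] <- vec
    }
  }
  conservation_track(values, default = default)
}

#' Look up conservation values at 0-based positions
#'
#' @param track a `ConservationTrack`.
#' @param chrom record name.
#' @param positions 0-based positions.
#' @return numeric vector of values in `[0,1]`.
#' @export
track_values <- function(track, chrom, positions) {
  vec <- track$values[[chrom]]
  if (is.null(vec)) return(rep(track$default, length(positions)))
  out <- rep(track$default, length(positions))
  inside <- positions >= 0 & positions < length(vec)
  out[inside] <- vec[positions[inside] + 1L]
  out
}

#' Write a ConservationTrack to bedGraph
#'
#' Runs of equal values are merged into single lines.
#'
#' @param track a `ConservationTrack`.
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  lines <- character(0)
  for (ch in names(track$values)) {
    r <- rle(track$values[[ch]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    lines <- c(lines, sprintf("%s\t%d\t%d\t%.6g", ch, starts, ends, r$values))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Sample length-matched negative intervals from the genome background
#'
#' Interval lengths are drawn with replacement from the positive-interval
#' length distribution; candidate intervals overlapping any positive
#' interval, or containing more than 10% `N` bases, are rejected and
#' resampled. By default negatives are also mutually non-overlapping —
#' emulating draws from a genome large enough that self-overlap is
#' negligible, and mirroring how peak sets are disjoint; without this,
#' sequence shared between overlapping negatives leaks across
#' train/held-out splits and inflates apparent accuracy. Deterministic
#' given `seed`.
#'
#' @param genome a `GenomeSource`.
#' @param positives `IntervalSet` of positive intervals.
#' @param n number of negatives to draw (>= 1).
#' @param seed RNG seed.
#' @param allow_self_overlap permit negatives to overlap one another.
#' @param max_attempts bound on total draws before giving up.
#' @return an `IntervalSet` of `n` intervals labelled `"negative"`.
#' @export
sample_negative_intervals <- function(genome, positives, n, seed,
                                      allow_self_overlap = FALSE,
                                      max_attempts = 1000L * n) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  chroms <- names(genome$seqs)
  chrom_p <- genome$lengths / sum(genome$lengths)
  out_chrom <- character(n); out_start <- integer(n); out_end <- integer(n)
  placed <- 0L; attempts <- 0L
  while (placed < n) {
    if (attempts >= max_attempts)
      stop("could not place ", n, " negative intervals in ", attempts, " attempts")
    attempts <- attempts + 1L
    len <- sample(positives$end - positives$start, 1L)
    ch <- if (length(chroms) == 1L) chroms else sample(chroms, 1L, prob = chrom_p)
    Lc <- genome$lengths[[ch]]
    if (Lc < len) next
    s <- sample.int(Lc - len + 1L, 1L) - 1L
    e <- s + len
    pos_ch <- positives[positives$chrom == ch, , drop = FALSE]
    if (nrow(pos_ch) > 0 && any(pos_ch$start < e & s < pos_ch$end)) next
    if (!allow_self_overlap && placed > 0L) {
      prev <- seq_len(placed)
      same <- prev[out_chrom[prev] == ch]
      if (length(same) > 0 && any(out_start[same] < e & s < out_end[same])) next
    }
    seq <- get_sequence(genome, ch, s, e)
    n_count <- nchar(gsub("[ACGT]", "", seq))
    if (n_count > 0.10 * len) next
    placed <- placed + 1L
    out_chrom[placed] <- ch; out_start[placed] <- s; out_end[placed] <- e
  }
  interval_set(out_chrom, out_start, out_end, "negative")
}

# save/restore the global RNG state so seeded helpers do not perturb the
# caller's stream
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
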