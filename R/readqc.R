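# QC and profiling: metagenomic read filtering, locus pair filtering,
# strand-aware substitution-bias profile, and capture summary metrics.

#' Filter a metagenomic read pool
#'
#' Removes reads with mean Phred quality below `min_mean_q` (strict less-than,
#' arithmetic mean of scores), length below `min_len`, any non-ACGT base, or
#' that are exact sequence duplicates of an earlier retained read (first
#' occurrence kept). The report tallies every rule a read violates, so a read
#' can appear in several tallies but is removed (and counted in
#' `n_input - n_passed`) only once.
#'
#' @param reads a [seq_records()] frame with qualities.
#' @param min_mean_q mean-quality threshold (removed when mean < threshold).
#' @param min_len length threshold in bp (removed when length < threshold).
#' @return list with `reads` (the retained frame) and `report` (QC counts:
#'   `n_input`, `n_low_mean_quality`, `n_short`, `n_ambiguous`,
#'   `n_exact_duplicates`, `n_passed`).
#' @export
filter_metagenomic_reads <- function(reads, min_mean_q = 25, min_len = 50) {
  if (!"qualities" %in% names(reads))
    stop("reads must carry qualities")
  mean_q <- vapply(reads$qualities, mean, 0)
  low_q <- mean_q < min_mean_q
  short <- nchar(reads$sequence) < min_len
  ambig <- grepl("[^ACGT]", reads$sequence)
  pred_pass <- !(low_q | short | ambig)
  dup <- rep(FALSE, nrow(reads))
  dup[pred_pass] <- duplicated(reads$sequence[pred_pass])
  pass <- pred_pass & !dup
  report <- list(n_input = nrow(reads),
                 n_low_mean_quality = sum(low_q),
                 n_short = sum(short),
                 n_ambiguous = sum(ambig),
                 n_exact_duplicates = sum(dup),
                 n_passed = sum(pass))
  list(reads = reads[pass, , drop = FALSE], report = report)
}

#' Filter locus read pairs on low-quality base content
#'
#' A pair is removed when the number of bases with quality `<= q_threshold`,
#' summed over both mates, exceeds `max_bad_bases` (strictly more than).
#'
#' @param pairs a [read_pairs()] frame with qualities for both mates.
#' @param max_bad_bases maximum tolerated low-quality bases per pair.
#' @param q_threshold quality at or below which a base counts as bad.
#' @return list with `pairs` (retained frame) and `counts`
#'   (`n_input`, `n_removed`, `n_passed`).
#' @export
filter_locus_pairs <- function(pairs, max_bad_bases = 5, q_threshold = 3) {
  if (!all(c("qualities1", "qualities2") %in% names(pairs)))
    stop("pairs must carry qualities for both mates")
  bad <- vapply(seq_len(nrow(pairs)), function(i) {
    sum(pairs$qualities1[[i]] <= q_threshold) +
      sum(pairs$qualities2[[i]] <= q_threshold)
  }, 0)
  keep <- bad <= max_bad_bases
  list(pairs = pairs[keep, , drop = FALSE],
       counts = list(n_input = nrow(pairs), n_removed = sum(!keep),
                     n_passed = sum(keep)))
}

sub_types <- function() {
  bases <- c("A", "C", "G", "T")
  g <- expand.grid(to = bases, from = bases, stringsAsFactors = FALSE)
  g <- g[g$from != g$to, c("from", "to")]
  paste0(g$from, ">", g$to)
}

#' Strand-aware per-position substitution profile
#'
#' For every retained mapped read, each read-vs-reference mismatch increments
#' the (strand, read position, ref base > read base) counter; rates are
#' counts divided by the number of retained reads of that strand. Only reads
#' whose CIGAR is a single full-length match are used (no indels, no
#' clipping). Positions index the read as stored: reverse-strand reads are
#' stored reverse-complemented, so their 5' end appears at the right of the
#' profile; they are not re-oriented.
#'
#' @param mapped data.frame with columns `read` (read sequence as stored),
#'   `strand` (`"forward"`/`"reverse"`), `ref` (reference bases under the
#'   read, same orientation and length) and `cigar`.
#' @param read_length profile length L; reads of other lengths are excluded
#'   along with indel/clipped reads.
#' @return list of class `substitution_profile`: `counts` and `rates` arrays
#'   of dim (2 strands x L positions x 12 types), `n_reads` per strand,
#'   `read_length`.
#' @export
substitution_profile <- function(mapped, read_length) {
  stopifnot(all(c("read", "strand", "ref", "cigar") %in% names(mapped)))
  full <- sprintf("%dM", read_length)
  use <- mapped$cigar == full & nchar(mapped$read) == read_length
  mapped <- mapped[use, , drop = FALSE]
  if (nrow(mapped) && any(nchar(mapped$ref) != nchar(mapped$read)))
    stop("reference segment length does not match read length")
  strands <- c("forward", "reverse")
  types <- sub_types()
  counts <- array(0L, dim = c(2L, read_length, 12L),
                  dimnames = list(strand = strands,
                                  position = as.character(seq_len(read_length) - 1L),
                                  type = types))
  n_reads <- c(forward = sum(mapped$strand == "forward"),
               reverse = sum(mapped$strand == "reverse"))
  if (nrow(mapped)) {
    rm_ <- do.call(rbind, strsplit(mapped$read, "", fixed = TRUE))
    fm_ <- do.call(rbind, strsplit(mapped$ref, "", fixed = TRUE))
    mm <- which(rm_ != fm_, arr.ind = TRUE)
    if (nrow(mm)) {
      si <- ifelse(mapped$strand[mm[, 1]] == "forward", 1L, 2L)
      ty <- match(paste0(fm_[mm], ">", rm_[mm]), types)
      ok <- !is.na(ty) # ignore mismatches involving N
      idx <- cbind(si, mm[, 2], ty)[ok, , drop = FALSE]
      for (r in seq_len(nrow(idx)))
        counts[idx[r, 1], idx[r, 2], idx[r, 3]] <-
          counts[idx[r, 1], idx[r, 2], idx[r, 3]] + 1L
    }
  }
  rates <- counts
  for (s in 1:2)
    rates[s, , ] <- if (n_reads[s] > 0) counts[s, , ] / n_reads[s] else 0
  structure(list(counts = counts, rates = rates, n_reads = n_reads,
                 read_length = read_length),
            class = "substitution_profile")
}

profile_to_df <- function(profile) {
  stopifnot(inherits(profile, "substitution_profile"))
  d <- dim(profile$counts)
  g <- expand.grid(strand = dimnames(profile$counts)$strand,
                   position = seq_len(d[2]) - 1L,
                   type = dimnames(profile$counts)$type,
                   stringsAsFactors = FALSE)
  data.frame(strand = g$strand, position = g$position,
             from = substr(g$type, 1, 1), to = substr(g$type, 3, 3),
             count = as.vector(profile$counts),
             rate = as.vector(profile$rates), stringsAsFactors = FALSE)
}

#' Exome-capture summary metrics
#'
#' Per-sample capture statistics over a per-read summary table:
#' `pct_unmapped` = unmapped / total; `pct_duplicates` = duplicate-flagged /
#' mapped; `pct_on_target` = non-duplicate mapped reads on target / all
#' non-duplicate mapped reads; `median_target_coverage` = median per-base
#' depth over all target bases from non-duplicate mapped reads. All
#' percentages are on the 0-100 scale. On-target membership is configurable:
#' alignment midpoint in a target (default), any overlap, or full containment.
#'
#' @param read_summary data.frame with columns `mapped` (logical), `duplicate`
#'   (logical; only meaningful for mapped reads), `chrom`, `start`, `end`
#'   (0-based half-open alignment interval; NA when unmapped).
#' @param targets TargetInterval data.frame (`chrom`, `start`, `end`, 0-based
#'   half-open).
#' @param on_target_rule `"midpoint"`, `"any-overlap"` or `"full-containment"`.
#' @return list of class `capture_metrics`: `total_reads`, `pct_unmapped`,
#'   `pct_duplicates`, `pct_on_target`, `median_target_coverage`.
#' @export
capture_metrics <- function(read_summary, targets,
                            on_target_rule = c("midpoint", "any-overlap",
                                               "full-containment")) {
  on_target_rule <- match.arg(on_target_rule)
  if (is.null(targets) || nrow(targets) == 0) stop("empty target set")
  total <- nrow(read_summary)
  mapped <- read_summary[read_summary$mapped, , drop = FALSE]
  n_dup <- sum(mapped$duplicate)
  nd <- mapped[!mapped$duplicate, , drop = FALSE]
  on_target <- logical(nrow(nd))
  for (i in seq_len(nrow(targets))) {
    t <- targets[i, ]
    same <- nd$chrom == t$chrom
    on_target <- on_target | switch(
      on_target_rule,
      "midpoint" = same & floor((nd$start + nd$end) / 2) >= t$start &
        floor((nd$start + nd$end) / 2) < t$end,
      "any-overlap" = same & nd$start < t$end & nd$end > t$start,
      "full-containment" = same & nd$start >= t$start & nd$end <= t$end)
  }
  # per-base depth over target bases (non-duplicate mapped reads)
  depths <- numeric(0)
  for (ch in unique(targets$chrom)) {
    tch <- targets[targets$chrom == ch, , drop = FALSE]
    rch <- nd[nd$chrom == ch, , drop = FALSE]
    L <- max(tch$end, if (nrow(rch)) max(rch$end) else 0L)
    delta <- numeric(L + 1L)
    if (nrow(rch)) {
      s <- pmax(rch$start, 0L) + 1L
      e <- pmin(rch$end, L) + 1L
      for (j in seq_len(nrow(rch))) {
        delta[s[j]] <- delta[s[j]] + 1
        delta[e[j]] <- delta[e[j]] - 1
      }
    }
    cov <- cumsum(delta)[seq_len(L)]
    tbases <- unlist(lapply(seq_len(nrow(tch)),
                            function(j) (tch$start[j] + 1L):tch$end[j]))
    depths <- c(depths, cov[tbases])
  }
  structure(list(
    total_reads = total,
    pct_unmapped = 100 * (total - nrow(mapped)) / total,
    pct_duplicates = if (nrow(mapped)) 100 * n_dup / nrow(mapped) else 0,
    pct_on_target = if (nrow(nd)) 100 * sum(on_target) / nrow(nd) else 0,
    median_target_coverage = median(depths)), class = "capture_metrics")
}
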