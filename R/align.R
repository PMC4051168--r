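# Seed-and-extend local aligner emitting m8-compatible hits, so fragment
# recruitment can be exercised end-to-end without an external aligner.

#' Scoring scheme for local alignment and e-values
#'
#' Affine-gap nucleotide scoring plus the Karlin-Altschul parameters used to
#' convert raw scores into e-values. The defaults emulate blastn-like
#' behaviour (match +1, mismatch -3, gap open 5, gap extend 2, lambda 1.33,
#' K 0.621); the effective database size mirrors an aligner's `-z` option and
#' defaults, in [align_reads()], to the summed genome length.
#'
#' @param match positive match reward.
#' @param mismatch non-negative mismatch penalty.
#' @param gap_open,gap_extend non-negative affine gap penalties; a gap of
#'   length g costs `gap_open + g * gap_extend`.
#' @param lambda,K Karlin-Altschul parameters (both > 0).
#' @param effective_db_size effective search-space length n in bp.
#' @return a list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 1L, mismatch = 3L, gap_open = 5L,
                           gap_extend = 2L, lambda = 1.33, K = 0.621,
                           effective_db_size = 1e6) {
  stopifnot(match > 0, mismatch >= 0, gap_open >= 0, gap_extend >= 0,
            lambda > 0, K > 0, effective_db_size > 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 lambda = lambda, K = K,
                 effective_db_size = effective_db_size),
            class = "scoring_scheme")
}

#' Optimal local alignment (Smith-Waterman, affine gaps)
#'
#' Full dynamic-programming local alignment with deterministic traceback
#' (diagonal preferred over up over left on ties). Returns `NULL` when no cell
#' reaches at least one match's worth of score.
#'
#' @param query,subject single sequence strings, or one-row [seq_records()]
#'   frames.
#' @param scoring a [scoring_scheme()].
#' @return `NULL`, or a list with `score`, 1-based `q_start`/`q_end`/
#'   `s_start`/`s_end`, the two aligned rows (gap character `-`), `matches`,
#'   `mismatches`, `gap_opens`, `aln_length` and `percent_identity`.
#' @export
smith_waterman <- function(query, subject, scoring = scoring_scheme()) {
  q <- if (is.data.frame(query)) query$sequence[1] else query
  s <- if (is.data.frame(subject)) subject$sequence[1] else subject
  stopifnot(nzchar(q), nzchar(s))
  res <- .sw_align_cpp(toupper(q), toupper(s), scoring$match,
                       scoring$mismatch, scoring$gap_open,
                       scoring$gap_extend)
  if (is.null(res)) return(NULL)
  c(res, list(percent_identity = 100 * res$matches / res$aln_length))
}

#' Karlin-Altschul e-value
#'
#' `E = K * m * n * exp(-lambda * S)` with query length m, effective database
#' size n and raw score S: strictly decreasing in score, linear in both m and
#' n.
#'
#' @param score raw alignment score (>= 0).
#' @param query_len query length m in bp.
#' @param scoring a [scoring_scheme()] supplying lambda, K and n.
#' @return the e-value (float >= 0).
#' @export
evalue <- function(score, query_len, scoring = scoring_scheme()) {
  stopifnot(all(score >= 0), all(query_len > 0))
  scoring$K * query_len * scoring$effective_db_size *
    exp(-scoring$lambda * score)
}

#' Bit score from a raw score
#'
#' `S' = (lambda * S - ln K) / ln 2`.
#'
#' @inheritParams evalue
#' @return bit score.
#' @export
bit_score <- function(score, scoring = scoring_scheme()) {
  (scoring$lambda * score - log(scoring$K)) / log(2)
}

#' Align reads to genomes by seed-and-extend
#'
#' Indexes the genomes by exact k-mers, extends every shared seed with
#' [smith_waterman()] on a window around the seed diagonal, tries both read
#' strands, and reports the best-scoring alignment per read x genome in m8
#' convention: query coordinates ascending on the read as sequenced, and
#' `s_start > s_end` encoding a reverse-strand hit. Hits scoring below
#' `min_score` or with e-value above `max_evalue` are suppressed, mirroring an
#' external aligner's reporting cutoff (`-e 0.01`).
#'
#' @param reads a [seq_records()] frame of reads.
#' @param genomes a [seq_records()] frame of reference genomes.
#' @param scoring a [scoring_scheme()]; when `effective_db_size` is `NULL` the
#'   summed genome length is used.
#' @param k exact seed length (>= 8).
#' @param min_score minimum raw score to report.
#' @param max_evalue reporting e-value cutoff.
#' @param seed_step distance between successive seed offsets along the read.
#' @return an AlignmentHit data.frame (see [read_m8()]).
#' @export
align_reads <- function(reads, genomes, scoring = scoring_scheme(),
                        k = 11L, min_score = 20L, max_evalue = 0.01,
                        seed_step = 10L) {
  stopifnot(k >= 8L, k <= 31L)
  if (any(nchar(reads$sequence) < k))
    stop("seed length k exceeds the shortest read length")
  scoring$effective_db_size <- if (is.null(scoring$effective_db_size))
    sum(nchar(genomes$sequence)) else scoring$effective_db_size
  res <- .seed_extend_cpp(reads$id, reads$sequence, genomes$id,
                          genomes$sequence, as.integer(k),
                          as.integer(seed_step), scoring$match,
                          scoring$mismatch, scoring$gap_open,
                          scoring$gap_extend, scoring$lambda, scoring$K,
                          scoring$effective_db_size, as.integer(min_score),
                          max_evalue)
  hits <- as.data.frame(res, stringsAsFactors = FALSE)
  if (!nrow(hits)) {
    hits <- empty_hits()
    hits$raw_score <- numeric(0)
  }
  validate_hits(hits)
  hits
}
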