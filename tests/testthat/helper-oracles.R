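# Independent oracles and fixture builders used across the suite.

# Full-matrix affine-gap local alignment score, written independently of the
# package's aligner (plain R, score only). Gap of length g costs
# gap_open + g * gap_extend.
sw_oracle_score <- function(q, s, match = 1, mismatch = 3, gap_open = 5,
                            gap_extend = 2) {
  qv <- strsplit(q, "")[[1]]
  sv <- strsplit(s, "")[[1]]
  m <- length(qv); n <- length(sv)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F_ <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      F_[i, j] <- max(H[i - 1, j] - gap_open - gap_extend,
                      F_[i - 1, j] - gap_extend)
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_extend,
                     E[i, j - 1] - gap_extend)
      sub <- if (qv[i - 1] == sv[j - 1]) match else -mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + sub, E[i, j], F_[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# Brute-force classification: filter, argmax on bit score, lexicographic tie.
classify_oracle <- function(hits, tier) {
  cov <- (hits$q_end - hits$q_start + 1) / hits$query_length
  ok <- hits$percent_identity >= tier$min_identity &
    hits$evalue <= tier$max_evalue
  if (!is.na(tier$min_read_coverage)) ok <- ok & cov >= tier$min_read_coverage
  p <- hits[ok, , drop = FALSE]
  if (!nrow(p)) return(list(genome = NA_character_, ambiguous = FALSE))
  b <- max(p$bit_score)
  top <- sort(p$subject_id[p$bit_score == b])
  list(genome = top[1], ambiguous = length(top) > 1)
}

# One read's worth of random alignment hits.
random_hits <- function(n, read_id = "r1", query_length = 75L,
                        genomes = sprintf("G%02d", 1:8)) {
  qs <- sample.int(20L, n, replace = TRUE)
  span <- sample.int(query_length - 20L, n, replace = TRUE) + 15L
  qe <- pmin(qs + span, query_length)
  data.frame(query_id = read_id,
             subject_id = sample(genomes, n, replace = TRUE),
             percent_identity = round(runif(n, 40, 100), 1),
             aln_length = qe - qs + 1L, mismatches = 0L, gap_opens = 0L,
             q_start = qs, q_end = qe, s_start = 1000L,
             s_end = 1000L + qe - qs,
             evalue = 10^runif(n, -12, 0),
             bit_score = sample(seq(30, 80, by = 5), n, replace = TRUE),
             query_length = query_length, stringsAsFactors = FALSE)
}

# Uniform random DNA (independent of the package's generator).
random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

reads_with_quals <- function(seqs, q = 40L) {
  seq_records(sprintf("r%03d", seq_along(seqs)), seqs,
              lapply(nchar(seqs), function(l) rep.int(q, l)))
}

# A small community simulation shared by recruitment tests.
toy_community <- function(n_genomes = 3, n_reads = 600, error_rate = 0.01,
                          weights = NULL, seed = 42,
                          length_range = c(8000, 12000)) {
  sim <- simulate_genomes(n_genomes, length_range, seed = seed)
  if (is.null(weights)) weights <- rep(1, n_genomes)
  cs <- community_spec(sim$genomes, sim$meta, weights,
                       error_rate = error_rate, seed = seed + 1)
  rr <- simulate_reads(cs, n_reads)
  list(sim = sim, spec = cs, reads = rr$reads, truth = rr$truth)
}
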