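mkread <- function(seq, quals) seq_records("r", seq, list(quals))

test_that("metagenomic QC removes each violation with exact counts", {
  L <- 60L
  ok1 <- strrep("ACGT", 15)
  ok2 <- strrep("TGCA", 15)
  short <- strrep("A", 49)             # length 49 < 50
  ambig <- paste0(strrep("ACGT", 14), "ACGN")  # one N
  lowq <- strrep("GATC", 15)           # mean quality 24.9 < 25
  reads <- seq_records(
    sprintf("r%d", 1:6),
    c(ok1, short, ambig, lowq, ok2, ok1), # r6 duplicates r1
    list(rep(40L, L), rep(40L, 49L), rep(40L, L),
         c(rep(25L, 54L), rep(24L, 6L)), # mean 24.9
         rep(40L, L), rep(40L, L)))
  res <- filter_metagenomic_reads(reads)
  expect_equal(res$report$n_input, 6L)
  expect_equal(res$report$n_short, 1L)
  expect_equal(res$report$n_ambiguous, 1L)
  expect_equal(res$report$n_low_mean_quality, 1L)
  expect_equal(res$report$n_exact_duplicates, 1L)
  expect_equal(res$report$n_passed, 2L)
  expect_equal(res$reads$id, c("r1", "r5"))
})

test_that("mean quality exactly at the threshold is retained (strict <)", {
  r <- mkread(strrep("ACGT", 15), rep(25L, 60L))
  expect_equal(filter_metagenomic_reads(r)$report$n_passed, 1L)
  r2 <- mkread(strrep("ACGT", 15), c(rep(25L, 59L), 24L))
  expect_equal(filter_metagenomic_reads(r2)$report$n_low_mean_quality, 1L)
  # length exactly 50 is retained
  r3 <- mkread(strrep("AC", 25), rep(40L, 50L))
  expect_equal(filter_metagenomic_reads(r3)$report$n_passed, 1L)
  expect_error(filter_metagenomic_reads(seq_records("x", "ACGT")),
               "qualities")
})

test_that("the passed set is invariant to rule evaluation order", {
  set.seed(81)
  n <- 200
  seqs <- vapply(seq_len(n), function(i)
    random_dna(sample(c(45, 55, 75), 1)), "")
  seqs[sample.int(n, 20)] <- seqs[sample.int(n, 20)] # plant duplicates
  seqs[sample.int(n, 10)] <- vapply(seqs[sample.int(n, 10)], function(s) {
    substr(s, 3, 3) <- "N"; s
  }, "")
  quals <- lapply(nchar(seqs), function(l)
    rep.int(sample(c(20L, 30L, 40L), 1), l))
  reads <- seq_records(sprintf("r%03d", seq_len(n)), seqs, quals)
  res <- filter_metagenomic_reads(reads)
  # independent re-derivation: predicates in a different order, then
  # first-kept dedup over predicate survivors
  mean_q <- vapply(quals, mean, 0)
  pred <- !grepl("[^ACGT]", reads$sequence) & nchar(reads$sequence) >= 50 &
    mean_q >= 25
  keep <- pred & !duplicated(ifelse(pred, reads$sequence, NA))
  expect_equal(res$reads$id, reads$id[keep])
})

test_that("pair filter applies the strict more-than-five rule over both mates", {
  q_ok <- rep(40L, 50L)
  mk <- function(n_bad1, n_bad2) {
    q1 <- q_ok; q2 <- q_ok
    if (n_bad1) q1[seq_len(n_bad1)] <- 3L
    if (n_bad2) q2[seq_len(n_bad2)] <- 2L
    read_pairs("p", strrep("A", 50), strrep("C", 50), list(q1), list(q2))
  }
  expect_equal(filter_locus_pairs(mk(3, 3))$counts$n_removed, 1L) # 6 > 5
  expect_equal(filter_locus_pairs(mk(3, 2))$counts$n_passed, 1L)  # 5 kept
  expect_equal(filter_locus_pairs(mk(0, 0))$counts$n_passed, 1L)
  # quality 4 does not count as bad (threshold is <= 3)
  q4 <- q_ok; q4[1:10] <- 4L
  p <- read_pairs("p", strrep("A", 50), strrep("C", 50), list(q4), list(q_ok))
  expect_equal(filter_locus_pairs(p)$counts$n_passed, 1L)
  expect_error(filter_locus_pairs(read_pairs("p", "AC", "GT")), "qualities")
})

test_that("substitution profile is all zero on error-free reads", {
  tc <- toy_community(n_reads = 200, error_rate = 0, seed = 91)
  mapped <- data.frame(read = tc$reads$sequence, strand = tc$truth$strand,
                       ref = tc$reads$sequence,
                       cigar = sprintf("%dM", tc$spec$read_length),
                       stringsAsFactors = FALSE)
  prof <- substitution_profile(mapped, tc$spec$read_length)
  expect_true(all(prof$rates == 0))
  expect_equal(sum(prof$n_reads), 200L)
})

test_that("indel and clipped reads are excluded from the profile", {
  mapped <- data.frame(
    read = c(strrep("A", 75), strrep("A", 75), strrep("A", 75)),
    strand = "forward",
    ref = c(strrep("A", 75), paste0("C", strrep("A", 74)),
            paste0("G", strrep("A", 74))),
    cigar = c("75M", "30M1I44M", "5S70M"), stringsAsFactors = FALSE)
  prof <- substitution_profile(mapped, 75L)
  expect_equal(unname(prof$n_reads["forward"]), 1L)
  expect_true(all(prof$counts == 0)) # the mismatching reads were excluded
})

test_that("profile recovers planted damage on the right strand only", {
  tc <- toy_community(n_reads = 10000, error_rate = 0, seed = 92,
                      n_genomes = 2)
  dmg <- damage_spec(0L, "A", "G", 0.10, "forward")
  damaged <- inject_positional_substitutions(tc$reads, dmg, tc$truth$strand,
                                             seed = 93)
  # reference = pre-damage sequence (error-free sim)
  mapped <- data.frame(read = damaged$sequence, strand = tc$truth$strand,
                       ref = tc$reads$sequence,
                       cigar = sprintf("%dM", tc$spec$read_length),
                       stringsAsFactors = FALSE)
  prof <- substitution_profile(mapped, tc$spec$read_length)
  fwd <- tc$truth$strand == "forward"
  n_a <- sum(fwd & substr(tc$reads$sequence, 1, 1) == "A")
  got <- prof$counts["forward", "0", "A>G"]
  expect_lt(abs(got - 0.1 * n_a), 3 * sqrt(n_a * 0.1 * 0.9))
  expect_true(all(prof$counts["reverse", , ] == 0))
  # and the rate is count over forward reads
  expect_equal(unname(prof$rates["forward", "0", "A>G"]),
               unname(got / prof$n_reads["forward"]))
})

test_that("capture metrics compute the stated ratios", {
  targets <- data.frame(chrom = "c1", start = 1000L, end = 2000L)
  rs <- data.frame(mapped = c(rep(TRUE, 90), rep(FALSE, 10)),
                   duplicate = FALSE,
                   chrom = "c1", start = 1200L, end = 1300L,
                   stringsAsFactors = FALSE)
  rs$chrom[!rs$mapped] <- NA
  m <- capture_metrics(rs, targets)
  expect_equal(m$pct_unmapped, 10)
  expect_equal(m$pct_on_target, 100)
  expect_error(capture_metrics(rs, targets[0, ]), "empty target")
})

test_that("uniform tiling gives the constant median target coverage", {
  targets <- data.frame(chrom = "c1", start = 0L, end = 1000L)
  # 120 reads of 100 bp tiling the 1 kb target uniformly: depth 12 everywhere
  starts <- rep(seq(0, 900, by = 100), 12)
  rs <- data.frame(mapped = TRUE, duplicate = FALSE, chrom = "c1",
                   start = starts, end = starts + 100L)
  m <- capture_metrics(rs, targets)
  expect_equal(m$median_target_coverage, 12)
  expect_equal(m$pct_on_target, 100)
  expect_equal(m$pct_duplicates, 0)
})

test_that("on-target fraction equals a brute-force midpoint oracle", {
  set.seed(94)
  targets <- data.frame(chrom = "c1", start = c(100L, 500L),
                        end = c(200L, 800L))
  starts <- sample.int(900, 300)
  rs <- data.frame(mapped = TRUE, duplicate = runif(300) < 0.1,
                   chrom = "c1", start = starts, end = starts + 76L)
  m <- capture_metrics(rs, targets)
  nd <- rs[!rs$duplicate, ]
  mid <- floor((nd$start + nd$end) / 2)
  oracle <- mean((mid >= 100 & mid < 200) | (mid >= 500 & mid < 800)) * 100
  expect_equal(m$pct_on_target, oracle)
  expect_equal(m$pct_duplicates, 100 * sum(rs$duplicate) / 300)
})

test_that("pct_duplicates recovers the planted duplicate fraction", {
  tc0 <- toy_community(seed = 95)
  rr <- simulate_reads(tc0$spec, 2000, duplicate_fraction = 0.15)
  rs <- data.frame(mapped = TRUE, duplicate = rr$truth$is_duplicate,
                   chrom = "c1", start = 0L, end = 75L)
  m <- capture_metrics(rs, data.frame(chrom = "c1", start = 0L, end = 100L))
  expect_equal(m$pct_duplicates, 15)
})
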