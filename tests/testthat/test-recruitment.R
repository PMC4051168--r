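mkhit <- function(subject = "G1", identity = 96, cov = 0.8, ev = 1e-6,
                  bs = 100, qlen = 100L, qid = "r1") {
  span <- round(cov * qlen)
  data.frame(query_id = qid, subject_id = subject,
             percent_identity = identity, aln_length = span,
             mismatches = 0L, gap_opens = 0L, q_start = 1L, q_end = span,
             s_start = 500L, s_end = 500L + span - 1L, evalue = ev,
             bit_score = bs, query_length = qlen, stringsAsFactors = FALSE)
}

test_that("tier defaults match the recruitment stringency levels", {
  expect_equal(tier_thresholds("lenient")$min_identity, 50)
  expect_true(is.na(tier_thresholds("lenient")$min_read_coverage))
  expect_equal(tier_thresholds("stringent")$min_identity, 80)
  expect_equal(tier_thresholds("stringent")$min_read_coverage, 0.75)
  expect_equal(tier_thresholds("species")$min_identity, 95)
  expect_equal(tier_thresholds("species")$max_evalue, 1e-3)
})

test_that("classify_read applies thresholds, best score and tie rule", {
  sp <- tier_thresholds("species")
  expect_equal(classify_read(mkhit(identity = 96), sp)$genome_id, "G1")
  expect_true(is.na(classify_read(mkhit(identity = 94.9), sp)$genome_id))
  expect_true(is.na(classify_read(mkhit(cov = 0.74), sp)$genome_id))
  expect_true(is.na(classify_read(mkhit(ev = 0.01), sp)$genome_id))
  two <- rbind(mkhit("GA", bs = 100), mkhit("GB", bs = 90))
  expect_equal(classify_read(two, sp)$genome_id, "GA")
  tie <- rbind(mkhit("GB", bs = 100), mkhit("GA", bs = 100))
  res <- classify_read(tie, sp)
  expect_equal(res$genome_id, "GA")
  expect_true(res$ambiguous)
  expect_error(classify_read(rbind(mkhit(qid = "a"), mkhit(qid = "b")), sp),
               "single read")
})

test_that("classify_read equals the brute-force oracle on random hit sets", {
  set.seed(101)
  tiers <- default_tiers()
  for (i in 1:1000) {
    hits <- random_hits(sample.int(6, 1))
    tier <- tiers[[sample.int(3, 1)]]
    got <- classify_read(hits, tier)
    want <- classify_oracle(hits, tier)
    expect_identical(got$genome_id, want$genome)
    expect_identical(got$ambiguous, want$ambiguous)
  }
})

test_that("recruit_all matches read-by-read classification", {
  tc <- toy_community(n_reads = 1000, error_rate = 0.05, seed = 102)
  hits <- align_reads(tc$reads, tc$sim$genomes)
  rec <- recruit_all(hits, genomes = tc$sim$meta)
  for (tn in names(rec)) {
    tier <- default_tiers()[[tn]]
    per_read <- lapply(split(hits, hits$query_id), classify_read, tier = tier)
    per_read <- do.call(rbind, per_read)
    counts <- table(per_read$genome_id[!is.na(per_read$genome_id)])
    expect_equal(rec[[tn]]$counts[names(counts)],
                 setNames(as.integer(counts), names(counts)))
    got <- rec[[tn]]$assignments
    m <- match(per_read$read_id, got$read_id)
    expect_identical(got$genome_id[m], per_read$genome_id)
    expect_identical(got$ambiguous[m], per_read$ambiguous)
  }
})

test_that("tier assignments are nested species within stringent within lenient", {
  tc <- toy_community(n_reads = 1500, error_rate = 0.04, seed = 103)
  hits <- align_reads(tc$reads, tc$sim$genomes)
  rec <- recruit_all(hits, genomes = tc$sim$meta)
  assigned <- function(tn)
    rec[[tn]]$assignments$read_id[!is.na(rec[[tn]]$assignments$genome_id)]
  expect_true(all(assigned("species") %in% assigned("stringent")))
  expect_true(all(assigned("stringent") %in% assigned("lenient")))
})

test_that("recruit_all rejects unknown genomes and handles no passing hits", {
  gm <- genome_meta("G1", 1e4, "s", "g", "p")
  expect_error(recruit_all(mkhit("G9"), genomes = gm), "G9")
  weak <- mkhit(identity = 30) # fails every tier
  rec <- recruit_all(weak, genomes = gm)
  expect_equal(sum(rec$lenient$counts), 0L)
  expect_equal(rec$lenient$n_unassigned, 1L)
})

test_that("length normalization follows the stated formula", {
  gm <- genome_meta(c("A", "B"), c(1e6, 2e6), c("s1", "s2"), c("g1", "g2"),
                    c("p", "p"))
  ab <- normalize_abundance(c(A = 100L, B = 100L), gm)
  expect_equal(setNames(ab$abundance, ab$taxon), c(A = 2 / 3, B = 1 / 3))
  one <- normalize_abundance(c(A = 57L), gm)
  expect_equal(one$abundance, 1)
  empty <- normalize_abundance(integer(0), gm)
  expect_equal(nrow(empty), 0L)
  expect_error(normalize_abundance(c(Z = 5L), gm), "missing")
})

test_that("abundances sum to one and rollup conserves totals", {
  tc <- toy_community(n_genomes = 6, n_reads = 2000, error_rate = 0.01,
                      seed = 104, weights = c(3, 2, 1, 1, 2, 3))
  hits <- align_reads(tc$reads, tc$sim$genomes)
  rec <- recruit_all(hits, genomes = tc$sim$meta)
  ab <- normalize_abundance(rec$species$counts, tc$sim$meta)
  expect_equal(sum(ab$abundance), 1, tolerance = 1e-9)
  gen <- rollup(ab, tc$sim$meta, "genus")
  phy <- rollup(ab, tc$sim$meta, "phylum")
  expect_equal(sum(gen$abundance), 1, tolerance = 1e-12)
  expect_equal(sum(phy$abundance), 1, tolerance = 1e-12)
  # group-by oracle
  want <- tapply(ab$abundance,
                 tc$sim$meta$genus[match(ab$taxon, tc$sim$meta$genome_id)],
                 sum)
  expect_equal(setNames(gen$abundance, gen$taxon),
               setNames(as.vector(want[gen$taxon]), gen$taxon))
  # two species in one genus: additivity
  gm <- genome_meta(c("A", "B"), c(1e6, 1e6), c("s1", "s2"), c("g1", "g1"),
                    c("p", "p"))
  ab2 <- normalize_abundance(c(A = 3L, B = 2L), gm)
  expect_equal(rollup(ab2, gm, "genus")$abundance, 1)
})

test_that("normalized abundance recovers the community weights", {
  w <- c(4, 3, 2, 2, 1)
  tc <- toy_community(n_genomes = 5, n_reads = 8000, error_rate = 0.01,
                      seed = 105, weights = w)
  hits <- align_reads(tc$reads, tc$sim$genomes)
  rec <- recruit_all(hits, genomes = tc$sim$meta)
  ab <- normalize_abundance(rec$species$counts, tc$sim$meta)
  est <- setNames(ab$abundance, ab$taxon)[tc$sim$meta$genome_id]
  truth <- w / sum(w)
  # multinomial sd on each component
  for (i in seq_along(w))
    expect_lt(abs(est[i] - truth[i]),
              3 * sqrt(truth[i] * (1 - truth[i]) / 8000) + 0.01)
})

test_that("coverage track flags localized recruitment", {
  gm <- genome_meta("G1", 100000, "s", "g", "p")
  tile <- function(starts, width = 100L) {
    n <- length(starts)
    data.frame(query_id = sprintf("r%04d", seq_len(n)), subject_id = "G1",
               percent_identity = 100, aln_length = width, mismatches = 0L,
               gap_opens = 0L, q_start = 1L, q_end = width,
               s_start = starts, s_end = starts + width - 1L,
               evalue = 1e-30, bit_score = 100, query_length = width,
               stringsAsFactors = FALSE)
  }
  full <- tile(seq(1L, 99901L, by = 100L))
  asn <- data.frame(read_id = full$query_id, tier = "species",
                    genome_id = "G1", best_bit_score = 100,
                    ambiguous = FALSE, stringsAsFactors = FALSE)
  tr <- coverage_track(asn, full, gm)
  expect_equal(tr$fraction_covered, 1)
  expect_false(tr$localized)

  loc <- tile(sample(900L, 400L, replace = TRUE)) # all hits in 1 kb of 100 kb
  asn2 <- asn[seq_len(nrow(loc)), ]
  asn2$read_id <- loc$query_id
  tr2 <- coverage_track(asn2, loc, gm)
  expect_lt(tr2$fraction_covered, 0.011)
  expect_true(tr2$localized)

  none <- coverage_track(asn[0, ], full[0, ], gm)
  expect_equal(none$fraction_covered, 0)
  expect_false(none$localized)
  bad <- tile(99999L)
  asn3 <- asn[1, ]; asn3$read_id <- bad$query_id
  expect_error(coverage_track(asn3, bad, gm), "outside genome")
})
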