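fake_pileup <- function(...) {
  # build a 4 x L count matrix from per-position named count vectors
  cols <- list(...)
  counts <- matrix(0L, 4L, length(cols),
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (p in seq_along(cols))
    counts[names(cols[[p]]), p] <- as.integer(cols[[p]])
  list(counts = counts)
}

test_that("positive filter keeps target-matching pairs and drops noise", {
  set.seed(301)
  target <- random_dna(1000)
  panel <- locus_panel(seq_records("GENE1", target),
                       seq_records("HOM1", random_dna(1000)),
                       low_stringency = 3)
  mate <- substr(target, 301, 400) # identical 100 bp window
  good <- read_pairs("p1", mate, random_dna(100))
  noise <- read_pairs("p2", random_dna(100), random_dna(100))
  expect_equal(positive_filter(rbind(good, noise), panel, "GENE1")$pair_id,
               "p1")
  expect_error(positive_filter(good, panel, "GENE9"), "absent from panel")
  # reverse-complement mate is also harvested
  rc <- read_pairs("p3", revcomp(mate), random_dna(100))
  expect_equal(nrow(positive_filter(rc, panel, "GENE1")), 1L)
})

test_that("homologue-derived pairs escape only at inflated stringency", {
  set.seed(302)
  target <- random_dna(1000)
  hom <- target
  # 10% divergence: exactly 10 divergent sites inside each 100 bp mate span
  flips <- c(seq(205, 295, by = 10), seq(405, 495, by = 10))
  for (p in flips)
    substr(hom, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(hom, p, p)), 1)
  mate <- substr(hom, 201, 300)
  pair <- read_pairs("p1", mate, revcomp(substr(hom, 401, 500)))
  strict <- locus_panel(seq_records("GENE1", target),
                        seq_records("HOM1", hom), low_stringency = 3)
  loose <- locus_panel(seq_records("GENE1", target),
                       seq_records("HOM1", hom), low_stringency = 12)
  expect_equal(nrow(positive_filter(pair, strict, "GENE1")), 0L)
  expect_equal(nrow(positive_filter(pair, loose, "GENE1")), 1L)
})

test_that("negative filter removes any pair with homologue evidence", {
  set.seed(303)
  target <- random_dna(800)
  hom <- random_dna(800)
  panel <- locus_panel(seq_records("GENE1", target),
                       seq_records("HOM1", hom), low_stringency = 3)
  only_target <- read_pairs("t", substr(target, 101, 200),
                            substr(target, 301, 400))
  hom_mate <- read_pairs("h", substr(target, 101, 200),
                         substr(hom, 301, 400))
  kept <- negative_filter(rbind(only_target, hom_mate), panel)
  expect_equal(kept$pair_id, "t")
  empty <- locus_panel(seq_records("GENE1", target),
                       seq_records(character(), character()))
  expect_warning(out <- negative_filter(only_target, empty), "pass-through")
  expect_equal(nrow(out), 1L)
})

test_that("homologue-origin pairs surviving the positive filter are removed", {
  sim <- simulate_paralogous_locus(locus_spec(seed = 304))
  panel <- locus_panel(sim$targets, sim$homologues)
  hom_pairs <- sim$pairs[sim$truth$origin$source == "homologue" &
                           sim$truth$origin$gene == "GENE1", ]
  cand <- positive_filter(hom_pairs, panel, "GENE1")
  retained <- negative_filter(cand, panel)
  expect_equal(nrow(retained), 0L)
})

test_that("genotype calls respect the 20/10 depth thresholds exactly", {
  ref <- "A"
  hom25 <- call_genotypes(fake_pileup(c(G = 25L)), ref)
  expect_equal(hom25$genotype, "hom")
  expect_equal(hom25$allele1, "G")
  hom20 <- call_genotypes(fake_pileup(c(G = 20L)), ref)
  expect_equal(hom20$genotype, "hom")
  hom19 <- call_genotypes(fake_pileup(c(G = 19L)), ref)
  expect_equal(hom19$genotype, "no_call")
  expect_equal(hom19$reason, "low_depth")
  het12 <- call_genotypes(fake_pileup(c(A = 6L, G = 6L)), ref)
  expect_equal(het12$genotype, "het")
  expect_equal(c(het12$allele1, het12$allele2), c("A", "G"))
  het10 <- call_genotypes(fake_pileup(c(A = 5L, G = 5L)), ref)
  expect_equal(het10$genotype, "het")
  het9 <- call_genotypes(fake_pileup(c(A = 5L, G = 4L)), ref)
  expect_equal(het9$genotype, "no_call")
  expect_equal(het9$reason, "low_depth")
})

test_that("allele fraction and multi-allelic guards hold", {
  ref <- "A"
  # one error base at depth 21 stays hom (4.8% < 20% allele fraction)
  g <- call_genotypes(fake_pileup(c(G = 20L, T = 1L)), ref)
  expect_equal(g$genotype, "hom")
  expect_equal(g$allele1, "G")
  tri <- call_genotypes(fake_pileup(c(A = 10L, G = 10L, T = 10L)), ref)
  expect_equal(tri$genotype, "no_call")
  expect_equal(tri$reason, "multi_allelic")
  zero <- call_genotypes(fake_pileup(c(A = 0L)), ref)
  expect_equal(zero$genotype, "no_call")
})

test_that("gene presence uses the >= depth rule", {
  pres <- gene_presence(c(g1 = 0, g2 = 30, g3 = 5, g4 = 4.9),
                        presence_min_depth = 5)
  expect_equal(pres$present, c(FALSE, TRUE, TRUE, FALSE))
})

test_that("phasing joins consistently bridged sites and flags conflicts", {
  calls <- call_genotypes(
    do.call(fake_pileup, c(list(c(A = 10L, G = 10L)),
                           rep(list(c(A = 25L)), 48),
                           list(c(C = 10L, T = 10L)))),
    paste(rep("A", 50), collapse = ""), gene = "g")
  mkplace <- function(id, base1, base50) {
    s <- strrep("A", 50)
    substr(s, 1, 1) <- base1
    substr(s, 50, 50) <- base50
    data.frame(pair_id = id, mate = 1L, offset = 0L, strand = "forward",
               placed_seq = s, stringsAsFactors = FALSE)
  }
  consistent <- rbind(mkplace("p1", "A", "C"), mkplace("p2", "A", "C"),
                      mkplace("p3", "G", "T"))
  ph <- phase_local(calls, consistent)
  het <- ph$calls[ph$calls$genotype == "het", ]
  expect_equal(length(unique(het$phase_set)), 1L)
  expect_false(any(het$phase_conflict))
  expect_equal(ph$edges$orientation, "cis")

  conflicted <- rbind(consistent, mkplace("p4", "A", "T"))
  ph2 <- phase_local(calls, conflicted)
  het2 <- ph2$calls[ph2$calls$genotype == "het", ]
  expect_true(all(is.na(het2$phase_set)))
  expect_true(all(het2$phase_conflict))

  # sites not bridged by any pair stay in separate (absent) phase sets
  lonely <- rbind(mkplace("p5", "A", "A")[, ],
                  data.frame(pair_id = "p6", mate = 1L, offset = 30L,
                             strand = "forward", placed_seq = strrep("A", 20),
                             stringsAsFactors = FALSE))
  ph3 <- phase_local(calls, lonely)
  expect_true(all(is.na(ph3$calls$phase_set)))
})

test_that("concordance counts and the non-reference restriction are right", {
  calls <- data.frame(gene = "g", pos = 0:3, ref = "A",
                      genotype = c("hom", "het", "hom", "no_call"),
                      allele1 = c("G", "A", "A", NA),
                      allele2 = c("G", "C", "A", NA),
                      stringsAsFactors = FALSE)
  truth <- data.frame(gene = "g", pos = c(0L, 1L, 3L), ref = "A",
                      allele1 = c("G", "A", "T"), allele2 = c("G", "C", "T"),
                      stringsAsFactors = FALSE)
  co <- concordance(calls, truth, non_ref_only = TRUE)
  expect_equal(co$n_compared, 2L)
  expect_equal(co$n_concordant, 2L)
  expect_equal(co$rate, 1)
  expect_equal(co$n_no_call, 1L)
  # a call at a truth hom-ref site is excluded under non_ref_only ...
  calls2 <- calls
  calls2$genotype[3] <- "hom"; calls2$allele1[3] <- "C"; calls2$allele2[3] <- "C"
  co2 <- concordance(calls2, truth, non_ref_only = TRUE)
  expect_equal(co2$n_compared, 2L)
  # ... but counted (as discordant) when hom-ref sites are included
  co3 <- concordance(calls2, truth, non_ref_only = FALSE)
  expect_equal(co3$n_concordant, 2L)
  expect_gt(co3$n_compared, co2$n_compared)
  expect_error(concordance(calls[0, ], truth[0, ]), "empty comparison")
})

test_that("filter chain is monotone and end-to-end recovery is clean", {
  n_called <- 0L; n_truth_total <- 0L
  for (seed in c(311, 312, 313)) {
    sim <- simulate_paralogous_locus(locus_spec(
      seed = seed, paralogue_divergence = 0.08 + 0.02 * (seed - 311)))
    panel <- locus_panel(sim$targets, sim$homologues)
    qc <- filter_locus_pairs(sim$pairs)
    cand <- positive_filter(qc$pairs, panel, "GENE1")
    ret <- negative_filter(cand, panel)
    expect_lte(nrow(cand), nrow(qc$pairs))
    expect_lte(nrow(ret), nrow(cand))
    expect_true(all(ret$pair_id %in% cand$pair_id))

    res <- genotype_locus(qc$pairs, panel)
    co <- concordance(res$calls, sim$truth$genotypes, non_ref_only = TRUE)
    expect_equal(co$rate, 1) # every called truth site is correct
    n_called <- n_called + co$n_compared
    n_truth_total <- n_truth_total + nrow(sim$truth$genotypes)
    expect_true(all(res$presence$present))
    # no non-reference call at homologue-only variant positions
    hs <- sim$truth$homologue_sites
    tg <- sim$truth$genotypes
    hs_only <- hs[!paste(hs$gene, hs$pos) %in% paste(tg$gene, tg$pos), ]
    m <- merge(res$calls, unique(hs_only[, c("gene", "pos")]),
               by = c("gene", "pos"))
    bad <- m[m$genotype != "no_call" &
               !(m$genotype == "hom" & m$allele1 == m$ref), ]
    expect_equal(nrow(bad), 0L)
  }
  # call rate is an aggregate property across the simulated loci
  expect_gte(n_called / n_truth_total, 0.9)
})

test_that("low depth drives het sites to no_call, never to wrong homs", {
  sim <- simulate_paralogous_locus(locus_spec(depth = 8, seed = 314))
  panel <- locus_panel(sim$targets, sim$homologues)
  res <- genotype_locus(sim$pairs, panel)
  tg <- sim$truth$genotypes[sim$truth$genotypes$zygosity == "het", ]
  m <- merge(res$calls, tg, by = c("gene", "pos"))
  expect_true(all(m$genotype %in% c("het", "no_call")))
})

test_that("planted phasing is recovered for well-bridged site pairs", {
  sim <- simulate_paralogous_locus(locus_spec(het_sites = 6, seed = 315))
  panel <- locus_panel(sim$targets, sim$homologues)
  res <- genotype_locus(sim$pairs, panel)
  tg <- sim$truth$genotypes
  for (g in names(res$phasing)) {
    ed <- res$phasing[[g]]
    if (!nrow(ed)) next
    well <- ed[(ed$n_cis + ed$n_trans) >= 3 & !ed$conflict, , drop = FALSE]
    for (r in seq_len(nrow(well))) {
      ti <- tg[tg$gene == g & tg$pos == well$pos_i[r], ]
      tj <- tg[tg$gene == g & tg$pos == well$pos_j[r], ]
      if (ti$zygosity != "het" || tj$zygosity != "het") next
      # calls order alleles alphabetically; truth hap1/hap2 define cis
      ci <- res$calls[res$calls$gene == g & res$calls$pos == well$pos_i[r], ]
      cj <- res$calls[res$calls$gene == g & res$calls$pos == well$pos_j[r], ]
      truth_cis <- (ti$hap1 == ci$allele1) == (tj$hap1 == cj$allele1)
      expect_equal(well$orientation[r], if (truth_cis) "cis" else "trans")
    }
  }
})
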