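# Generators for every pipeline input, with known truth: microbial genome
# sets, community read pools with sequencing error / positional damage /
# exact duplicates, genus abundance tables, and diploid paralogous loci.
#
# All generators take an explicit seed and are deterministic under it.

rand_dna <- function(n, gc = 0.5) {
  stopifnot(gc >= 0, gc <= 1)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

mutate_positions <- function(seqs, idx_read, idx_pos) {
  # substitute a random different base at (read, position) pairs
  if (!length(idx_read)) return(seqs)
  for (i in seq_along(idx_read)) {
    r <- idx_read[i]; p <- idx_pos[i]
    old <- substr(seqs[r], p, p)
    alt <- setdiff(c("A", "C", "G", "T"), old)
    substr(seqs[r], p, p) <- sample(alt, 1L)
  }
  seqs
}

#' Simulate a set of reference genomes with nested taxonomy
#'
#' Generates i.i.d. genome sequences with a given GC content and assigns a
#' nested species < genus < phylum taxonomy (one genome per species, as a
#' recruitment database keeps a single representative genome per species
#' group).
#'
#' @param n number of genomes (>= 1).
#' @param length_range integer vector `c(min, max)` of genome lengths in bp.
#' @param gc GC content in `[0, 1]`.
#' @param seed integer RNG seed.
#' @param species_per_genus,genera_per_phylum taxonomy tree shape.
#' @return list with `genomes` (a [seq_records()] frame) and `meta`
#'   (a [genome_meta()] table).
#' @export
simulate_genomes <- function(n, length_range = c(30000L, 60000L), gc = 0.5,
                             seed = 1L, species_per_genus = 2L,
                             genera_per_phylum = 2L) {
  stopifnot(n >= 1)
  if (gc < 0 || gc > 1) stop("gc must be in [0, 1]")
  set.seed(seed)
  lens <- if (length_range[1] == length_range[2]) rep(length_range[1], n)
          else sample(length_range[1]:length_range[2], n, replace = TRUE)
  seqs <- vapply(lens, rand_dna, "", gc = gc)
  ids <- sprintf("G%03d", seq_len(n))
  genus_idx <- (seq_len(n) - 1L) %/% species_per_genus + 1L
  phylum_idx <- (genus_idx - 1L) %/% genera_per_phylum + 1L
  meta <- genome_meta(ids, lens,
                      species = sprintf("species_%03d", seq_len(n)),
                      genus = sprintf("genus_%02d", genus_idx),
                      phylum = sprintf("phylum_%d", phylum_idx))
  list(genomes = seq_records(ids, seqs), meta = meta)
}

#' Describe a synthetic microbial community
#'
#' Bundles the genomes, their metadata and the community composition. Weights
#' are cell abundances: the chance a read originates from a genome is
#' proportional to `weight * genome length`, so that genome-length
#' normalization downstream recovers the weights.
#'
#' @param genomes a [seq_records()] frame of genome sequences.
#' @param meta the matching [genome_meta()] table (one genome per species).
#' @param weights non-negative cell-abundance weights, one per genome.
#' @param read_length read length in bp.
#' @param error_rate per-base substitution error rate in `[0, 1)`.
#' @param seed integer RNG seed.
#' @return a list of class `community_spec`.
#' @export
community_spec <- function(genomes, meta, weights, read_length = 75L,
                           error_rate = 0.01, seed = 1L) {
  stopifnot(nrow(genomes) == nrow(meta), length(weights) == nrow(meta),
            all(weights >= 0), sum(weights) > 0,
            error_rate >= 0, error_rate < 1)
  if (anyDuplicated(meta$species))
    stop("at most one genome per species in a community")
  structure(list(genomes = genomes, meta = meta, weights = weights,
                 read_length = as.integer(read_length),
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "community_spec")
}

#' Simulate a community read pool with known origins
#'
#' Draws read origins from a multinomial with probability proportional to
#' `weight * genome length`, uniform start positions and random strand,
#' applies uniform per-base substitution error, and emits a chosen fraction of
#' reads as exact copies of already-emitted reads. Qualities are constant
#' `quality` (default Q40).
#'
#' @param spec a [community_spec()].
#' @param n_reads number of reads to emit (> 0).
#' @param duplicate_fraction fraction of emitted reads that are exact
#'   duplicates of earlier reads.
#' @param quality constant Phred quality for all bases.
#' @return list with `reads` (a [seq_records()] frame with qualities) and
#'   `truth` (data.frame: `read_id`, `genome_id`, `start` 1-based on the
#'   genome, `strand`, `is_duplicate`, `duplicate_of`).
#' @export
simulate_reads <- function(spec, n_reads, duplicate_fraction = 0,
                           quality = 40L) {
  stopifnot(inherits(spec, "community_spec"))
  if (n_reads <= 0) stop("n_reads must be positive")
  rl <- spec$read_length
  if (rl > min(spec$meta$length_bp))
    stop("read_length exceeds the shortest genome")
  set.seed(spec$seed)
  n_dup <- round(duplicate_fraction * n_reads)
  n_orig <- n_reads - n_dup
  prob <- spec$weights * spec$meta$length_bp
  gidx <- sample.int(nrow(spec$meta), n_orig, replace = TRUE, prob = prob)
  starts <- 1L + floor(runif(n_orig) * (spec$meta$length_bp[gidx] - rl + 1))
  strand <- sample(c("forward", "reverse"), n_orig, replace = TRUE)
  seqs <- substring(spec$genomes$sequence[gidx], starts, starts + rl - 1L)
  is_rev <- strand == "reverse"
  seqs[is_rev] <- revcomp(seqs[is_rev])
  if (spec$error_rate > 0) {
    hit <- which(runif(n_orig * rl) < spec$error_rate)
    seqs <- mutate_positions(seqs, (hit - 1L) %/% rl + 1L,
                             (hit - 1L) %% rl + 1L)
  }
  ids <- sprintf("read%06d", seq_len(n_reads))
  truth <- data.frame(read_id = ids,
                      genome_id = c(spec$meta$genome_id[gidx],
                                    character(n_dup)),
                      start = c(starts, integer(n_dup)),
                      strand = c(strand, character(n_dup)),
                      is_duplicate = c(rep(FALSE, n_orig), rep(TRUE, n_dup)),
                      duplicate_of = NA_character_,
                      stringsAsFactors = FALSE)
  if (n_dup > 0) {
    src <- sample.int(n_orig, n_dup, replace = TRUE)
    seqs <- c(seqs, seqs[src])
    truth$genome_id[n_orig + seq_len(n_dup)] <- spec$meta$genome_id[gidx[src]]
    truth$start[n_orig + seq_len(n_dup)] <- starts[src]
    truth$strand[n_orig + seq_len(n_dup)] <- strand[src]
    truth$duplicate_of[n_orig + seq_len(n_dup)] <- ids[src]
  }
  quals <- rep(list(rep.int(as.integer(quality), rl)), n_reads)
  list(reads = seq_records(ids, seqs, quals), truth = truth)
}

#' Positional substitution ("damage") specification
#'
#' @param position 0-based position along the read.
#' @param from,to single upper-case bases.
#' @param rate substitution probability in `[0, 1]`.
#' @param strand `"forward"` or `"reverse"`: which mapping strand's reads are
#'   affected.
#' @return data.frame of class `damage_spec`.
#' @export
damage_spec <- function(position, from, to, rate, strand = "forward") {
  stopifnot(all(rate >= 0), all(rate <= 1), all(position >= 0))
  structure(data.frame(position = as.integer(position), from = from, to = to,
                       rate = rate, strand = strand,
                       stringsAsFactors = FALSE),
            class = c("damage_spec", "data.frame"))
}

#' Inject position-dependent substitutions into reads
#'
#' For each damage row, flips `from -> to` at the given read position with the
#' given rate, on reads of the matching strand only. Emulates the
#' degradation-like excess of specific substitution types at read starts that
#' the substitution-bias profile is designed to detect.
#'
#' @param reads a [seq_records()] frame.
#' @param damage a [damage_spec()].
#' @param strand per-read mapping strand (`"forward"`/`"reverse"`), e.g. from
#'   the truth table of [simulate_reads()].
#' @param seed integer RNG seed.
#' @return the modified reads frame.
#' @export
inject_positional_substitutions <- function(reads, damage, strand, seed = 1L) {
  stopifnot(length(strand) == nrow(reads))
  if (nrow(damage) && any(damage$position >= min(nchar(reads$sequence))))
    stop("damage position beyond read length")
  set.seed(seed)
  seqs <- reads$sequence
  for (i in seq_len(nrow(damage))) {
    p <- damage$position[i] + 1L
    cand <- which(strand == damage$strand[i] &
                    substr(seqs, p, p) == damage$from[i])
    sel <- cand[runif(length(cand)) < damage$rate[i]]
    if (length(sel)) substr(seqs[sel], p, p) <- damage$to[i]
  }
  reads$sequence <- seqs
  reads
}

#' Simulate genus-level abundance tables
#'
#' Per-sample relative abundances drawn around a population profile with
#' lognormal sample-to-sample noise, then renormalized to sum to 1. Used to
#' emulate the pre-annotated genus tables entering the cross-population
#' comparison.
#'
#' @param n_samples samples to draw.
#' @param profile named non-negative vector of population-mean abundances
#'   (taxa as names).
#' @param overdispersion sd of the lognormal per-sample noise.
#' @param sample_prefix prefix for sample names.
#' @param seed integer RNG seed.
#' @return samples x taxa matrix; rows sum to 1.
#' @export
simulate_genus_table <- function(n_samples, profile, overdispersion = 0.3,
                                 sample_prefix = "S", seed = 1L) {
  stopifnot(n_samples >= 1, all(profile >= 0), sum(profile) > 0)
  set.seed(seed)
  m <- matrix(rep(profile, each = n_samples), nrow = n_samples,
              dimnames = list(sprintf("%s%02d", sample_prefix,
                                      seq_len(n_samples)),
                              names(profile)))
  noise <- matrix(exp(rnorm(length(m), 0, overdispersion)), nrow = n_samples)
  m <- m * noise
  m / rowSums(m)
}

#' Describe a diploid paralogous locus
#'
#' A family of target genes, each diploid with known heterozygous (and
#' optionally homozygous non-reference) sites, shadowed by homologous
#' pseudogene-like sequences at a given divergence -- the situation that makes
#' mapping-based genotyping of HLA/KIR-like loci error-prone without
#' paralogue filtering.
#'
#' @param n_target_genes number of target genes.
#' @param n_homologues number of homologue/pseudogene sequences, each derived
#'   from one of the targets.
#' @param gene_length gene length in bp.
#' @param paralogue_divergence expected fraction of sites differing between a
#'   homologue and its source target, in `(0, 0.3]`.
#' @param het_sites heterozygous sites per gene.
#' @param hom_sites homozygous non-reference sites per gene.
#' @param depth mean read-pair depth over a gene (> 0).
#' @param read_length read length in bp.
#' @param insert_mean,insert_sd insert-size distribution (bp).
#' @param base_error per-base sequencing error rate.
#' @param absent_genes indices of target genes emitted at zero depth
#'   (variable-content genes absent from the simulated diplotype).
#' @param seed integer RNG seed.
#' @return a list of class `locus_spec`.
#' @export
locus_spec <- function(n_target_genes = 3L, n_homologues = 3L,
                       gene_length = 1000L, paralogue_divergence = 0.10,
                       het_sites = 5L, hom_sites = 2L, depth = 40,
                       read_length = 100L, insert_mean = 250, insert_sd = 25,
                       base_error = 0.001, absent_genes = integer(0),
                       seed = 1L) {
  stopifnot(paralogue_divergence > 0, paralogue_divergence <= 0.3, depth > 0,
            n_target_genes >= 1, gene_length > 2 * read_length)
  if (het_sites + hom_sites > gene_length)
    stop("more variant sites than gene positions")
  structure(as.list(environment()), class = "locus_spec")
}

#' Construct a read-pair table
#'
#' @param pair_id pair identifiers.
#' @param sequence1,sequence2 mate sequences.
#' @param qualities1,qualities2 optional per-mate integer quality lists.
#' @return data.frame with one row per pair.
#' @export
read_pairs <- function(pair_id, sequence1, sequence2, qualities1 = NULL,
                       qualities2 = NULL) {
  stopifnot(all(nzchar(sequence1)), all(nzchar(sequence2)))
  out <- data.frame(pair_id = as.character(pair_id), sequence1 = sequence1,
                    sequence2 = sequence2, stringsAsFactors = FALSE)
  if (!is.null(qualities1)) out$qualities1 <- I(lapply(qualities1, as.integer))
  if (!is.null(qualities2)) out$qualities2 <- I(lapply(qualities2, as.integer))
  out
}

#' Simulate a diploid paralogous locus with known genotypes
#'
#' Builds target gene references, derives homologues from them by random
#' substitution at the paralogue divergence, plants two haplotypes per target
#' (heterozygous at `het_sites` positions, both-alt at `hom_sites` positions),
#' and samples read pairs from the haplotypes of present genes and from every
#' homologue at the stated depth. The truth records genotype and phase at
#' every variant site, presence/absence per gene, and the homologue-only
#' variant positions where a correct caller must make no call.
#'
#' @param spec a [locus_spec()].
#' @return list with `targets` and `homologues` ([seq_records()] frames, one
#'   target per gene), `pairs` (a [read_pairs()] frame, constant Q40),
#'   `truth`: list of `genotypes` (gene, pos 0-based, ref, allele1, allele2,
#'   zygosity, hap1, hap2), `presence` (gene, present), `homologue_sites`
#'   (gene, pos, target_base, homologue_base), and `origin` (pair_id, source,
#'   gene, hap).
#' @export
simulate_paralogous_locus <- function(spec) {
  stopifnot(inherits(spec, "locus_spec"))
  set.seed(spec$seed)
  gl <- spec$gene_length; rl <- spec$read_length
  genes <- sprintf("GENE%d", seq_len(spec$n_target_genes))
  refs <- vapply(seq_len(spec$n_target_genes), function(i) rand_dna(gl), "")
  # plant haplotypes
  geno <- list(); hap1 <- refs; hap2 <- refs
  # read-pair depth ramps over the first/last insert length of an isolated
  # locus reference; variant sites are planted in the uniformly covered
  # interior (the exon-like core of the locus)
  margin <- min(spec$insert_mean, floor(gl / 3))
  interior <- seq(margin + 1L, gl - margin)
  for (i in seq_along(genes)) {
    nvar <- spec$het_sites + spec$hom_sites
    pos <- sort(sample(interior, nvar))
    kind <- c(rep("het", spec$het_sites), rep("hom", spec$hom_sites))
    kind <- kind[sample.int(nvar)]
    for (j in seq_len(nvar)) {
      p <- pos[j]
      ref_b <- substr(refs[i], p, p)
      alt_b <- sample(setdiff(c("A", "C", "G", "T"), ref_b), 1L)
      if (kind[j] == "het") {
        substr(hap2[i], p, p) <- alt_b
        geno[[length(geno) + 1L]] <- data.frame(
          gene = genes[i], pos = p - 1L, ref = ref_b, allele1 = ref_b,
          allele2 = alt_b, zygosity = "het", hap1 = ref_b, hap2 = alt_b,
          stringsAsFactors = FALSE)
      } else {
        substr(hap1[i], p, p) <- alt_b
        substr(hap2[i], p, p) <- alt_b
        geno[[length(geno) + 1L]] <- data.frame(
          gene = genes[i], pos = p - 1L, ref = ref_b, allele1 = alt_b,
          allele2 = alt_b, zygosity = "hom", hap1 = alt_b, hap2 = alt_b,
          stringsAsFactors = FALSE)
      }
    }
  }
  genotypes <- do.call(rbind, geno)
  # homologues derived from targets
  hom_ids <- sprintf("HOM%d", seq_len(spec$n_homologues))
  hom_src <- (seq_len(spec$n_homologues) - 1L) %% spec$n_target_genes + 1L
  hom_seqs <- character(spec$n_homologues)
  hom_sites <- list()
  for (h in seq_len(spec$n_homologues)) {
    s <- refs[hom_src[h]]
    flips <- which(runif(gl) < spec$paralogue_divergence)
    for (p in flips) {
      old <- substr(s, p, p)
      substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
    }
    hom_seqs[h] <- s
    if (length(flips))
      hom_sites[[h]] <- data.frame(
        gene = genes[hom_src[h]], homologue = hom_ids[h], pos = flips - 1L,
        target_base = substring(refs[hom_src[h]], flips, flips),
        homologue_base = substring(s, flips, flips),
        stringsAsFactors = FALSE)
  }
  homologue_sites <- do.call(rbind, hom_sites)
  present <- !(seq_along(genes) %in% spec$absent_genes)
  # read pairs
  n_pairs_per_seq <- max(1L, round(spec$depth * gl / (2 * rl)))
  src_seqs <- c(hap1[present], hap2[present], hom_seqs)
  src_label <- c(rep("target", 2 * sum(present)), rep("homologue",
                                                      spec$n_homologues))
  src_gene <- c(genes[present], genes[present], genes[hom_src])
  src_hap <- c(rep(1L, sum(present)), rep(2L, sum(present)),
               rep(NA_integer_, spec$n_homologues))
  # haplotypes each at half the gene depth; homologues at full depth
  n_per <- c(rep(ceiling(n_pairs_per_seq / 2), 2 * sum(present)),
             rep(n_pairs_per_seq, spec$n_homologues))
  tot <- sum(n_per)
  s1 <- character(tot); s2 <- character(tot)
  origin <- data.frame(pair_id = sprintf("pair%06d", seq_len(tot)),
                       source = rep(src_label, n_per),
                       gene = rep(src_gene, n_per),
                       hap = rep(src_hap, n_per), stringsAsFactors = FALSE)
  k <- 0L
  for (si in seq_along(src_seqs)) {
    for (r in seq_len(n_per[si])) {
      k <- k + 1L
      ins <- round(rnorm(1, spec$insert_mean, spec$insert_sd))
      ins <- max(2L * rl, min(gl, ins))
      st <- sample.int(gl - ins + 1L, 1L)
      s1[k] <- substr(src_seqs[si], st, st + rl - 1L)
      s2[k] <- revcomp(substr(src_seqs[si], st + ins - rl, st + ins - 1L))
    }
  }
  if (spec$base_error > 0) {
    for (nm in c("s1", "s2")) {
      v <- get(nm)
      hit <- which(runif(tot * rl) < spec$base_error)
      v <- mutate_positions(v, (hit - 1L) %/% rl + 1L, (hit - 1L) %% rl + 1L)
      assign(nm, v)
    }
  }
  q <- rep(list(rep.int(40L, rl)), tot)
  pairs <- read_pairs(origin$pair_id, s1, s2, q, q)
  list(targets = seq_records(genes, refs),
       homologues = seq_records(hom_ids, hom_seqs),
       pairs = pairs,
       truth = list(genotypes = genotypes,
                    presence = data.frame(gene = genes, present = present,
                                          stringsAsFactors = FALSE),
                    homologue_sites = homologue_sites,
                    origin = origin,
                    haplotypes = list(hap1 = setNames(hap1, genes),
                                      hap2 = setNames(hap2, genes))))
}
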