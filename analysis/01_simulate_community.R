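#!/usr/bin/env Rscript

# Stage 1: build the synthetic study inputs.
#
# Emulates the off-target read pool of saliva-derived exome capture: a
# 12-genome mock oral community (weights spanning two orders of magnitude,
# as in real saliva communities), 75 bp reads at 1% sequencing error, 15%
# exact duplicates, and degradation-like positional damage (excess
# purine substitutions at the start of the read) planted on the forward
# strand. Large intermediates go to scratch/, small tables to results/.

suppressPackageStartupMessages(library(oralcap))
dir.create("scratch", showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

SEED <- 20260921L
n_genomes <- 12L
n_reads <- 20000L

sim <- simulate_genomes(n_genomes, c(30000, 60000), gc = 0.45, seed = SEED)
weights <- c(20, 12, 8, 6, 5, 4, 3, 2, 1.5, 1, 0.7, 0.3)
cs <- community_spec(sim$genomes, sim$meta, weights, read_length = 75L,
                     error_rate = 0.01, seed = SEED + 1L)
rr <- simulate_reads(cs, n_reads, duplicate_fraction = 0.15)

# degradation-like damage: elevated substitutions toward purines at the
# first positions of forward-strand reads
dmg <- damage_spec(position = c(0L, 0L, 1L, 1L),
                   from = c("A", "C", "A", "T"),
                   to = c("G", "A", "G", "A"),
                   rate = c(0.10, 0.06, 0.05, 0.03),
                   strand = "forward")
damaged <- inject_positional_substitutions(rr$reads, dmg, rr$truth$strand,
                                           seed = SEED + 2L)

write_fasta(sim$genomes, "scratch/genomes.fa")
write_fastq(damaged, "scratch/reads.fq")
write.table(rr$truth, "scratch/read_truth.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(sim$meta, "results/genome_taxonomy.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
saveRDS(list(weights = weights, damage = dmg, seed = SEED,
             read_length = cs$read_length),
        "scratch/community_truth.rds")

cat(sprintf("simulated %d genomes (%.0f-%.0f kb) and %d reads (%d duplicates)\n",
            n_genomes, min(sim$meta$length_bp) / 1e3,
            max(sim$meta$length_bp) / 1e3, n_reads,
            sum(rr$truth$is_duplicate)))
cat("wrote scratch/genomes.fa, scratch/reads.fq, scratch/read_truth.tsv\n")
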