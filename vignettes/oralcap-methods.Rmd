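---
title: "Methods: off-target metagenomics and paralogue-aware locus genotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: off-target metagenomics and paralogue-aware locus genotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oralcap)
```

# Scope

Exome capture of saliva-derived DNA leaves a large off-target read pool that
is rich in oral microbial sequence, and captures enough on-target sequence to
genotype even the most paralogue-confounded human loci. `oralcap` implements
the computational procedures this situation calls for, in three strands:

1. **Fragment-recruitment metagenomics** — quality filtering of the unmapped
   pool, local alignment of every read against a reference genome set, tiered
   identity/coverage/e-value classification, genome-length-normalized
   relative abundance, and taxonomic rollup.
2. **Read substitution-bias profiling** — strand-separated per-position rates
   of all twelve substitution types, used to distinguish DNA-degradation
   signatures (excess substitutions toward purines at read starts) from
   ordinary cycle-dependent sequencing error.
3. **Paralogue-aware locus genotyping** — positive/negative read-pair
   filtering against target and homologue references, depth-thresholded
   genotype calls, variable-content gene presence, and local read-backed
   phasing for HLA/KIR-like multigene families.

Everything runs on synthetic inputs with known truth, produced by the
package's own generators, so every stage is testable without downloads.

# The recruitment model

## Alignment and e-values

Reads are aligned by seed-and-extend: genomes are indexed by exact k-mers
(default k = 11), each shared seed is extended with a full Smith–Waterman
local alignment (affine gaps; a gap of length g costs
`gap_open + g * gap_extend`) on a window around the seed diagonal wide enough
to contain any local alignment of the read passing through that seed, and the
best extension per read x genome is reported in BLAST m8 convention
(`s_start > s_end` marking reverse-strand hits). Traceback ties prefer
diagonal over up over left, so output is deterministic.

Raw scores map to e-values by the Karlin–Altschul form
`E = K * m * n * exp(-lambda * S)` with query length m and effective database
size n. The original study used an external nucleotide aligner whose exact
scoring constants are not printed; they are therefore configuration, not
constants. Defaults emulate blastn-like behaviour: match +1, mismatch −3,
gap open 5, gap extend 2, lambda 1.33, K 0.621, n defaulting to the summed
genome length, and a reporting cutoff of e ≤ 0.01 mirroring a conventional
`-e 0.01` invocation. The test suite pins the aligner to an independent
full-matrix dynamic-programming oracle (score equality on random pairs) and
to exhaustive alignment over whole genomes (seed-and-extend completeness).

## QC rules

The metagenomic pool is filtered by four independent rules: mean Phred
quality below 25 (arithmetic mean of scores, matching the behaviour of the
standard preprocessing tool the field uses), length below 50 bp, any
ambiguous base, and exact sequence duplication (first occurrence kept).
All thresholds are strict inequalities, and the boundary cases (mean quality
exactly 25, length exactly 50) are asserted in the tests. The rules commute:
the retained set does not depend on evaluation order. Whether mean quality
is assessed before or after trimming is ambiguous in the source pipelines;
here reads are filtered as given (post-trim semantics).

Locus read pairs use a different rule: a pair is removed when more than five
bases across both mates have quality ≤ 3.

Two distinct duplicate notions coexist deliberately: the metagenomic filter
removes *exact sequence* duplicates, while the capture metrics consume
coordinate-based duplicate *flags* computed upstream — the two pipelines the
package mirrors used different definitions, and conflating them would change
the counts.

## Tier classification

Each read's hits are filtered by the tier thresholds and the read adopts the
taxonomy of the genome with the best alignment score among survivors:

| tier      | min identity | min read coverage | max e-value |
|-----------|--------------|-------------------|-------------|
| lenient   | 50%          | none              | 1e-3        |
| stringent | 80%          | 0.75              | 1e-3        |
| species   | 95%          | 0.75              | 1e-3        |

Read coverage is `(q_end - q_start + 1) / read length` — a statement about
the read, so subject-side gaps cannot inflate it. The species tier's 95%
identity corresponds to the conventional average-nucleotide-identity species
boundary. Because thresholds are nested, assignments are nested
(species ⊆ stringent ⊆ lenient), which the suite asserts on every
simulation. Score ties are assigned to the lexicographically smallest genome
id and flagged `ambiguous` — assignment keeps abundances deterministic while
the flag keeps ties auditable; discarding ties instead would silently bias
abundance against genomes with close relatives. Reads passing no tier are
discarded from that tier's diversity summaries, not re-binned. Identity is
consumed from the m8 field as produced by the aligner (matches over alignment
columns); any upstream aligner with a compatible m8 dialect can be swapped in
through `read_m8()`.

## Length normalization and rollup

Recruited counts are converted to relative abundance by
`abundance(g) = (count_g / length_g) / sum_h (count_h / length_h)`, so that
abundance estimates organism (cell) frequency rather than genome size. The
synthetic community generator draws read origins with probability
proportional to `weight * genome length` — the cell-abundance convention —
precisely so that this normalization must recover the input weights; that
recovery (rank correlation and total variation distance against truth) is
the pipeline's headline acceptance property. Rollup sums abundances within
genus or phylum and conserves the total exactly.

Per-genome coverage tracks guard against recruitment artifacts: a genome
whose recruited bases concentrate in a tiny subregion is likely recruiting
via one shared locus rather than genuine presence. The localization flag
raises when ≥ 50% of recruited bases fall in ≤ 1% of the genome.

# Substitution-bias profiling

Only reads whose CIGAR is a single full-length match enter the profile — any
indel or clip shifts the read/reference correspondence and would smear the
positional signal. For each retained read, every read-vs-reference mismatch
increments a (strand, read position, ref>read type) counter; rates divide by
the number of retained reads of that strand, matching the convention of
"observed changes of a type over total reads". Reads are profiled in storage
orientation: reverse-strand reads are stored reverse-complemented, so their
5' ends appear at the right edge of the profile — they are deliberately not
re-oriented, and the two strands are reported separately.

The damage generator plants position-specific `from>to` flips at a stated
rate on one strand. Note the unit difference: a planted rate of 0.10 flips
10% of reads carrying the `from` base at that position, while the profile
reports counts per read, so the recovered per-read rate is 0.10 times the
base frequency. Tests compare on the count scale with binomial error bounds.

# Capture metrics

`capture_metrics()` summarizes a per-read table into percent unmapped
(of all reads), percent duplicates (of mapped), percent on target (of
non-duplicate mapped) and the median per-base depth over target bases.
Read-level on-target membership is not defined in the source pipelines; the
default rule — alignment midpoint inside a target — is exposed as
configuration alongside any-overlap and full-containment.

# Community statistics

Clustering uses partition around medoids on Bray–Curtis dissimilarity by
default (both configurable): the standard choice for compositional
microbiome data, scanned over k and scored by average silhouette width. The
scan reports widths without declaring a verdict; a moderate maximum width is
read as a gradient rather than discrete clusters, and the package leaves
that interpretation to the analyst. PCA is run on column-centered
abundances with a fixed sign convention (the largest-|loading| taxon of each
component is positive) so loadings are reproducible.

Cross-population comparison runs a two-sided Wilcoxon rank-sum test per
taxon over the union of taxa (absent = 0 — true zeros, no pseudocounts,
because "effectively undetected" is part of the signal), Bonferroni-corrects
over the number of taxa tested, and reports each population's median
abundance and the median/max normalized value used for plotting. With
within-group ties the standard exact rank-sum distribution is unavailable
and the implementation would normally fall back to a normal approximation;
for *completely separated* samples, however, the exact permutation p-value
is still well defined — exactly one of the `choose(n+m, n)` group splits
attains the observed extreme rank sum regardless of within-group ties — so
that case returns `2 / choose(n+m, n)` exactly. This matters because a taxon
present in one population and entirely absent (all zeros) in the other is
precisely the complete-separation case.

Spearman correlations use average ranks; the p-value is the exact
permutation value for n ≤ 10 without ties, the large-sample approximation
otherwise.

# Paralogue-aware genotyping

## Filters

The positive filter harvests pairs where at least one mate matches the
gene's target reference within `low_stringency` mismatches (ungapped scan,
both strands, all offsets; default 5 per 100 bp read). The negative filter
then removes any pair in which either mate matches *any* homologue within
the same bound, leaving pairs with target-exclusive evidence. The ungapped
≤k-mismatch formulation was chosen over a full mapper because the filter's
job is a decision, not an alignment: it is simple, fast and auditable, and
its behaviour under divergence is exactly binomial. Pairs harvested by two
or more different target genes have ambiguous gene of origin and are dropped
and counted (`n_multi_gene`) — a documented local rule, not a claim about
the original pipeline's behaviour.

Matched-reference selection is deliberately simplified from the original
two-stage design (which picked final references from externally determined
genotypes): retained reads are aligned to every allele of the gene and the
allele with the maximum mean identity wins. This keeps the pipeline
self-contained at the cost of the external calibration step.

## Calls and the dropout guard

Per pileup column, alleles at ≥ `min_allele_fraction` (default 0.2) of depth
are retained; one allele at depth ≥ 20 calls homozygous, two alleles at
depth ≥ 10 call heterozygous, anything else is a `no_call` with its reason
(`low_depth`, `multi_allelic`, or `allele_dropout`, below). All-reference
columns are emitted as hom-ref only at depth ≥ 20. The allele-fraction floor
is this package's addition — the depth thresholds alone would let a single
error base at depth 20 manufacture a heterozygote.

The negative filter has a structural side effect that the thresholds alone
cannot see: wherever one haplotype locally resembles a homologue within the
filter's mismatch bound, *that haplotype's* pairs are removed, and the
column presents as a clean single-allele pileup at roughly half the gene's
typical depth — a confident, wrong homozygous call. The source study saw the
same phenomenon from the other side: its discordant genotypes clustered in
low-depth regions where only one or neither allele was represented. The
`dropout_guard` therefore declines a would-be homozygous column when either
signature of a suppressed allele is present: depth below 0.6 of the gene's
typical covered depth (its 75th percentile, robust to edge ramps), or a
sub-threshold second allele backed by at least two reads at ≥ 5% of depth
(a lone error base never triggers it). The guard trades a small amount of
call rate for the elimination of wrong calls; disabling it
(`dropout_guard = 0`) restores the plain 20/10 behaviour.

Gene presence for variable-content genes is mean post-filter depth ≥ 5. The
source states the principle (post-filter depth determines presence) but not
a number; 5x is this package's default and is configuration.

## Phasing

Two heterozygous sites share a phase set when connected (transitively) by
read pairs observing both sites with a consistent allele pairing; edges with
both pairings observed are conflicts that join nothing and flag both ends.
Orientation bookkeeping uses the alphabetically ordered call alleles, and
the per-edge support counts are returned so downstream analysis can require
a minimum number of concordant bridging pairs.

## Concordance

Non-reference concordance excludes truth hom-ref sites, excludes `no_call`s
from numerator and denominator (counting them separately), and compares
unordered genotypes. This matches the convention of evaluating genotype
agreement only at heterozygous or homozygous non-reference sites.

# The synthetic-data generators

The generators define the study conditions for every test:

* **Community**: genomes of 30–60 kb (desk-scale stand-ins for full
  microbial genomes; all downstream statistics are per-base or relative, so
  genome scale cancels), GC 0.45–0.5, taxonomy nested two species per genus
  and two genera per phylum; 75 bp reads (the platform read length the
  profiling figures assume) at 1% uniform substitution error; duplicates as
  exact copies of already-emitted reads; constant Q40 qualities with knobs
  for planting low-quality bases.
* **Damage**: position/strand/type-specific substitution rates layered on
  top of error-free or noisy reads.
* **Genus tables**: population profiles with lognormal per-sample noise,
  renormalized to compositions — continuous values, so rank tests see no
  spurious ties.
* **Locus**: three 1 kb target genes, two haplotypes each (five het sites,
  two hom-alt sites), three homologues derived from the targets at 8–12%
  divergence, 2 x 100 bp pairs at insert 250 ± 25 and mean pair depth 40
  (a typical exome target coverage), per-base error 0.001 (Q30-ish),
  optional absent genes at zero depth. Variant sites are planted in the
  uniformly covered interior of the gene: an isolated locus reference has a
  depth ramp over the first and last insert length (pairs must fit inside
  it), which is a property of simulating a locus without flanking sequence,
  not of the caller.

What the generators do **not** emulate — and hence what passing tests do not
establish about real data: pangenome structure and shared genes between
community members (reads here have a unique true source; real oral genera
share operons), GC- and insert-size biases of capture chemistry, indel
sequencing errors (configurable but off by default; the tier rules are
identity/coverage-based and substitutions exercise them directly), quality
score miscalibration, and real HLA/KIR allelic architecture (IPD-style
allele databases, exon/intron structure, structural variation). Conclusions
about threshold *behaviour* transfer; absolute recovery numbers do not.

# Numerical and implementation choices

* Alignment kernels (Smith–Waterman, ungapped mismatch scans, seed-and-
  extend) are compiled code; all bookkeeping stays in R. An independent
  plain-R dynamic-programming oracle lives in the test helpers, not in the
  package, so the checked path and the checking path cannot collapse into
  one.
* Intervals are 0-based half-open internally (BED convention); m8
  coordinates are 1-based inclusive and converted at the boundary; hit
  tables keep m8 convention because that is the type's contract.
* Sequences are uppercased on read; soft-masking carries no meaning here.
* Floats round-trip through the TSV writers at 6 significant digits.
* All generators take explicit integer seeds; the pipeline itself has no
  hidden randomness (pam on a fixed dissimilarity is deterministic; the
  seed argument guards degenerate-tie medoid choices).
* Problem sizes in the shipped analyses and acceptance checks — 20k reads
  over 5–12 genomes, 1000-case classification oracles, 20-seed locus grids —
  were chosen as the smallest sizes at which the binomial/multinomial error
  bounds in the tests are comfortably separated from their thresholds.

# Known limitations

* The seed-and-extend aligner requires an exact shared k-mer; at very high
  divergence (lenient-tier territory) it can miss alignments an exhaustive
  search would find. The oracle-equivalence tests run at error rates where
  seeds are essentially guaranteed.
* The positive/negative filters are ungapped; an indel inside a mate would
  fail the mismatch scan and lose the pair (conservative, never unsound).
* `classify_read`'s lexicographic tie rule is a determinism device, not a
  biological claim.
* The genus-table comparison consumes pre-annotated abundance tables; 16S
  processing, bootstrap filtering and classifier behaviour are upstream of
  this package and out of scope.
* Phasing is local and read-backed only: sites never bridged by a pair stay
  unphased, by design.
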