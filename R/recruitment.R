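# Tiered fragment recruitment: per-read genome assignment under nested
# identity/coverage/e-value thresholds, genome-length-normalized abundance,
# taxonomic rollup, and per-genome coverage tracks.

#' Tier thresholds for fragment recruitment
#'
#' The three nested stringency levels: lenient (distant homology, >= 50%
#' identity, no read-coverage floor), stringent (recent homology, >= 80%
#' identity and the alignment covering >= 75% of the read) and species
#' (species binning, >= 95% identity with the same 75% coverage floor). All
#' tiers apply an e-value ceiling of 1e-3.
#'
#' @param name `"lenient"`, `"stringent"` or `"species"`, or `"custom"` with
#'   explicit thresholds.
#' @param min_identity minimum percent identity.
#' @param min_read_coverage minimum `(q_end - q_start + 1) / query_length`, or
#'   `NA` for no floor.
#' @param max_evalue e-value ceiling.
#' @return list of class `tier_thresholds`.
#' @export
tier_thresholds <- function(name = c("lenient", "stringent", "species",
                                     "custom"),
                            min_identity = NULL, min_read_coverage = NULL,
                            max_evalue = NULL) {
  name <- match.arg(name)
  def <- switch(name,
                lenient = list(50, NA_real_, 1e-3),
                stringent = list(80, 0.75, 1e-3),
                species = list(95, 0.75, 1e-3),
                custom = list(min_identity, min_read_coverage, max_evalue))
  structure(list(name = name,
                 min_identity = if (is.null(min_identity) || name != "custom")
                   def[[1]] else min_identity,
                 min_read_coverage = if (is.null(min_read_coverage) ||
                                         name != "custom")
                   def[[2]] else min_read_coverage,
                 max_evalue = if (is.null(max_evalue) || name != "custom")
                   def[[3]] else max_evalue),
            class = "tier_thresholds")
}

#' Default tier set
#' @return named list of the lenient, stringent and species
#'   [tier_thresholds()].
#' @export
default_tiers <- function() {
  list(lenient = tier_thresholds("lenient"),
       stringent = tier_thresholds("stringent"),
       species = tier_thresholds("species"))
}

tier_pass <- function(hits, tier) {
  cov <- (hits$q_end - hits$q_start + 1) / hits$query_length
  ok <- hits$percent_identity >= tier$min_identity &
    hits$evalue <= tier$max_evalue
  if (!is.na(tier$min_read_coverage))
    ok <- ok & cov >= tier$min_read_coverage
  ok
}

#' Classify one read against one tier
#'
#' Filters the read's hits by the tier thresholds and transfers the taxonomy
#' of the genome producing the best alignment (bit) score among the passing
#' hits. Score ties are assigned to the lexicographically smallest genome id
#' and flagged ambiguous; a read with no passing hit is unassigned.
#'
#' @param hits AlignmentHit data.frame, all rows sharing one `query_id`.
#' @param tier a [tier_thresholds()].
#' @return one-row data.frame: `read_id`, `tier`, `genome_id` (NA when
#'   unassigned), `best_bit_score`, `ambiguous`.
#' @export
classify_read <- function(hits, tier) {
  if (length(unique(hits$query_id)) > 1)
    stop("classify_read expects hits for a single read")
  read_id <- if (nrow(hits)) hits$query_id[1] else NA_character_
  pass <- hits[tier_pass(hits, tier), , drop = FALSE]
  if (!nrow(pass))
    return(data.frame(read_id = read_id, tier = tier$name,
                      genome_id = NA_character_, best_bit_score = NA_real_,
                      ambiguous = FALSE, stringsAsFactors = FALSE))
  best <- max(pass$bit_score)
  top <- pass[pass$bit_score == best, , drop = FALSE]
  data.frame(read_id = read_id, tier = tier$name,
             genome_id = min(top$subject_id), best_bit_score = best,
             ambiguous = nrow(top) > 1, stringsAsFactors = FALSE)
}

#' Recruit all reads at every tier
#'
#' Vectorized equivalent of applying [classify_read()] to every read at every
#' tier: per-genome read counts plus the per-read assignments. Reads whose
#' hits all fail a tier are counted as unassigned at that tier and take no
#' further part in that tier's abundances (they are discarded from the
#' diversity analysis, not re-binned).
#'
#' @param hits AlignmentHit data.frame over many reads.
#' @param tiers named list of [tier_thresholds()] (default [default_tiers()]).
#' @param genomes a [genome_meta()] table covering every `subject_id`.
#' @return named list per tier: `counts` (named integer vector per genome),
#'   `assignments` (data.frame as in [classify_read()]), `n_unassigned`.
#' @export
recruit_all <- function(hits, tiers = default_tiers(), genomes) {
  unknown <- setdiff(unique(hits$subject_id), genomes$genome_id)
  if (length(unknown))
    stop("subject id(s) missing from genome table: ",
         paste(unknown, collapse = ", "))
  all_reads <- unique(hits$query_id)
  out <- list()
  for (tn in names(tiers)) {
    tier <- tiers[[tn]]
    pass <- hits[tier_pass(hits, tier), , drop = FALSE]
    if (nrow(pass)) {
      # per read: max bit score, tie -> lexicographically smallest genome id
      o <- order(pass$query_id, -pass$bit_score, pass$subject_id)
      pass <- pass[o, , drop = FALSE]
      first <- !duplicated(pass$query_id)
      top <- pass[first, , drop = FALSE]
      # ambiguity: more than one genome at the top score
      key <- paste(pass$query_id, pass$bit_score)
      top_key <- paste(top$query_id, top$bit_score)
      n_at_top <- table(key)[top_key]
      assignments <- data.frame(read_id = top$query_id, tier = tn,
                                genome_id = top$subject_id,
                                best_bit_score = top$bit_score,
                                ambiguous = as.vector(n_at_top) > 1,
                                stringsAsFactors = FALSE)
    } else {
      assignments <- data.frame(read_id = character(), tier = character(),
                                genome_id = character(),
                                best_bit_score = numeric(),
                                ambiguous = logical(),
                                stringsAsFactors = FALSE)
    }
    unassigned <- setdiff(all_reads, assignments$read_id)
    if (length(unassigned))
      assignments <- rbind(assignments,
                           data.frame(read_id = unassigned, tier = tn,
                                      genome_id = NA_character_,
                                      best_bit_score = NA_real_,
                                      ambiguous = FALSE,
                                      stringsAsFactors = FALSE))
    cnt <- table(factor(assignments$genome_id[!is.na(assignments$genome_id)],
                        levels = genomes$genome_id))
    out[[tn]] <- list(counts = setNames(as.integer(cnt), names(cnt)),
                      assignments = assignments,
                      n_unassigned = length(unassigned))
  }
  out
}

#' Genome-length-normalized relative abundance
#'
#' Divides each genome's recruited read count by its genome length and
#' renormalizes, so abundance reflects organism (cell) frequency rather than
#' genome size: `abundance(g) = (count_g / length_g) / sum_h (count_h /
#' length_h)`.
#'
#' @param counts named integer vector of per-genome read counts.
#' @param genomes a [genome_meta()] table.
#' @param sample_id,tier labels attached to the result.
#' @return an abundance table: data.frame (`taxon`, `abundance`) with
#'   attributes `level = "genome"`, `sample_id`, `tier`; empty when no read is
#'   assigned.
#' @export
normalize_abundance <- function(counts, genomes, sample_id = "sample",
                                tier = "species") {
  counts <- counts[counts > 0]
  if (!length(counts)) {
    out <- data.frame(taxon = character(), abundance = numeric(),
                      stringsAsFactors = FALSE)
  } else {
    len <- genomes$length_bp[match(names(counts), genomes$genome_id)]
    if (any(is.na(len)))
      stop("counted genome(s) missing from genome table: ",
           paste(names(counts)[is.na(len)], collapse = ", "))
    if (any(len <= 0)) stop("zero-length genome")
    dens <- counts / len
    out <- data.frame(taxon = names(counts), abundance = dens / sum(dens),
                      stringsAsFactors = FALSE)
    out <- out[order(out$taxon), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "level") <- "genome"
  attr(out, "sample_id") <- sample_id
  attr(out, "tier") <- tier
  class(out) <- c("abundance_table", "data.frame")
  out
}

abundance_to_df <- function(tab) {
  n <- nrow(tab)
  data.frame(taxon = tab$taxon,
             sample = rep(attr(tab, "sample_id") %||% "sample", n),
             level = rep(attr(tab, "level") %||% "genome", n),
             tier = rep(attr(tab, "tier") %||% NA_character_, n),
             abundance = tab$abundance, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Roll an abundance table up a taxonomic rank
#'
#' Sums genome-level abundances within species, genus or phylum; total
#' abundance is conserved exactly.
#'
#' @param table a genome-level abundance table from [normalize_abundance()].
#' @param genomes a [genome_meta()] table supplying the taxonomy.
#' @param level `"species"`, `"genus"` or `"phylum"`.
#' @return an abundance table at the requested level.
#' @export
rollup <- function(table, genomes, level = c("species", "genus", "phylum")) {
  level <- match.arg(level)
  if (attr(table, "level") != "genome")
    stop("rollup starts from a genome-level table")
  idx <- match(table$taxon, genomes$genome_id)
  if (any(is.na(idx)))
    stop("taxonomy missing for: ",
         paste(table$taxon[is.na(idx)], collapse = ", "))
  tax <- genomes[[level]][idx]
  if (any(is.na(tax) | !nzchar(tax))) stop("incomplete taxonomy at ", level)
  agg <- tapply(table$abundance, tax, sum)
  out <- data.frame(taxon = names(agg), abundance = as.vector(agg),
                    stringsAsFactors = FALSE)
  out <- out[order(out$taxon), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "level") <- level
  attr(out, "sample_id") <- attr(table, "sample_id")
  attr(out, "tier") <- attr(table, "tier")
  class(out) <- c("abundance_table", "data.frame")
  out
}

#' Per-genome coverage track from recruited reads
#'
#' Accumulates depth over the subject intervals of the hits backing the reads
#' assigned to one genome (strand-normalized: `s_start > s_end` intervals are
#' flipped), reports the fraction of the genome covered, and raises a
#' localization flag when at least half of the recruited bases fall into at
#' most 1% of the genome -- the signature of recruitment driven by a short
#' shared subsequence rather than genuine presence.
#'
#' @param assignments assignment frame (one tier) from [recruit_all()].
#' @param hits the AlignmentHit frame the assignments were derived from.
#' @param genome one row of a [genome_meta()] table.
#' @return list of class `coverage_track`: `genome_id`, `depth_rle`
#'   (run-length encoded per-position depth), `fraction_covered`,
#'   `localized` flag plus `localized_fraction` and `window_fraction` used by
#'   the heuristic.
#' @export
coverage_track <- function(assignments, hits, genome) {
  gid <- genome$genome_id[1]
  L <- genome$length_bp[1]
  reads <- assignments$read_id[!is.na(assignments$genome_id) &
                                 assignments$genome_id == gid]
  h <- hits[hits$query_id %in% reads & hits$subject_id == gid, , drop = FALSE]
  # one interval per assigned read: its best-scoring hit on this genome
  if (nrow(h)) {
    h <- h[order(h$query_id, -h$bit_score), , drop = FALSE]
    h <- h[!duplicated(h$query_id), , drop = FALSE]
  }
  delta <- numeric(L + 1L)
  for (i in seq_len(nrow(h))) {
    s <- min(h$s_start[i], h$s_end[i])
    e <- max(h$s_start[i], h$s_end[i])
    if (s < 1 || e > L) stop("hit interval outside genome ", gid)
    delta[s] <- delta[s] + 1
    delta[e + 1L] <- delta[e + 1L] - 1
  }
  depth <- cumsum(delta)[seq_len(L)]
  total <- sum(depth)
  win <- max(1L, floor(0.01 * L))
  top <- sum(sort(depth, decreasing = TRUE)[seq_len(win)])
  localized <- total > 0 && top >= 0.5 * total
  structure(list(genome_id = gid, depth_rle = rle(depth),
                 fraction_covered = sum(depth > 0) / L,
                 localized = localized,
                 localized_fraction = if (total > 0) top / total else 0,
                 window_fraction = win / L),
            class = "coverage_track")
}
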