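# Paralogue-aware genotyping of polymorphic multigene loci: positive/negative
# read-pair filters, depth-thresholded genotype calls, variable-content gene
# presence, local phasing, and concordance.

#' Build a locus panel
#'
#' The mapping references for a polymorphic multigene locus: per-gene target
#' sequences (one or more alleles per gene) and the homologous genes /
#' pseudogenes whose reads must be excluded. The positive/negative filters use
#' ungapped matching with at most `low_stringency` mismatches (the
#' low-stringency mapping that harvests candidate read pairs).
#'
#' @param targets a [seq_records()] frame of target references; an optional
#'   `gene` column groups alleles by gene (default: the record id).
#' @param homologues a [seq_records()] frame of homologue/pseudogene
#'   references; may be empty.
#' @param low_stringency maximum mismatches per read for both filters
#'   (default 5 per 100 bp read).
#' @return list of class `locus_panel`.
#' @export
locus_panel <- function(targets, homologues, low_stringency = 5L) {
  if (!"gene" %in% names(targets)) targets$gene <- targets$id
  if (length(intersect(targets$id, homologues$id)))
    stop("target and homologue namespaces must be disjoint")
  structure(list(targets = targets, homologues = homologues,
                 low_stringency = as.integer(low_stringency)),
            class = "locus_panel")
}

mate_matches <- function(seqs, ref, max_mm) {
  vapply(seqs, function(s) .min_mismatch_cpp(s, ref, max_mm) <= max_mm, TRUE,
         USE.NAMES = FALSE)
}

#' Positive filter: harvest candidate read pairs for one gene
#'
#' Keeps a pair iff at least one mate matches one of the gene's target
#' references with at most `low_stringency` mismatches (ungapped scan over all
#' offsets and both strands).
#'
#' @param pairs a [read_pairs()] frame (already quality-filtered, see
#'   [filter_locus_pairs()]).
#' @param panel a [locus_panel()].
#' @param gene gene name present in the panel.
#' @return the candidate subset of `pairs`.
#' @export
positive_filter <- function(pairs, panel, gene) {
  refs <- panel$targets$sequence[panel$targets$gene == gene]
  if (!length(refs)) stop("gene '", gene, "' absent from panel")
  keep <- rep(FALSE, nrow(pairs))
  for (ref in refs) {
    todo <- which(!keep)
    if (!length(todo)) break
    keep[todo] <- mate_matches(pairs$sequence1[todo], ref,
                               panel$low_stringency) |
      mate_matches(pairs$sequence2[todo], ref, panel$low_stringency)
  }
  pairs[keep, , drop = FALSE]
}

#' Negative filter: remove pairs with homologue evidence
#'
#' Removes a candidate pair iff either mate matches ANY homologue/pseudogene
#' reference with at most `low_stringency` mismatches; what survives has
#' target-exclusive evidence.
#'
#' @param candidates output of [positive_filter()].
#' @param panel a [locus_panel()].
#' @return the retained subset of `candidates`; with an empty homologue set,
#'   candidates pass through with a warning.
#' @export
negative_filter <- function(candidates, panel) {
  if (!nrow(panel$homologues)) {
    warning("empty homologue set: negative filter is a pass-through")
    return(candidates)
  }
  drop <- rep(FALSE, nrow(candidates))
  for (ref in panel$homologues$sequence) {
    todo <- which(!drop)
    if (!length(todo)) break
    drop[todo] <- mate_matches(candidates$sequence1[todo], ref,
                               panel$low_stringency) |
      mate_matches(candidates$sequence2[todo], ref, panel$low_stringency)
  }
  candidates[!drop, , drop = FALSE]
}

#' Pick the matched reference allele for a gene
#'
#' Aligns the retained mates to every allele of the gene (ungapped best
#' placement) and picks the allele with the maximum mean identity.
#'
#' @param pairs retained pairs for this gene (post negative filter).
#' @param panel a [locus_panel()].
#' @param gene gene name.
#' @return the id of the chosen allele.
#' @export
select_matched_reference <- function(pairs, panel, gene) {
  alleles <- panel$targets[panel$targets$gene == gene, , drop = FALSE]
  if (!nrow(alleles)) stop("gene '", gene, "' absent from panel")
  if (nrow(alleles) == 1L || !nrow(pairs)) return(alleles$id[1])
  mean_ident <- vapply(alleles$sequence, function(ref) {
    mm <- vapply(c(pairs$sequence1, pairs$sequence2), function(s) {
      .best_placement_cpp(s, ref)$mismatches / nchar(s)
    }, 0)
    1 - mean(mm)
  }, 0)
  alleles$id[which.max(mean_ident)]
}

#' Pile up read pairs on a reference
#'
#' Places every mate at its best ungapped position (both strands) on the
#' reference and accumulates per-position base counts. Placements are recorded
#' in reference orientation for downstream phasing.
#'
#' @param pairs a [read_pairs()] frame.
#' @param ref reference sequence string.
#' @return list: `counts` (4 x L matrix, rows A/C/G/T), `placements`
#'   (data.frame: `pair_id`, `mate`, `offset` 0-based, `strand`,
#'   `placed_seq`).
#' @export
pileup_pairs <- function(pairs, ref) {
  L <- nchar(ref)
  bases <- c("A", "C", "G", "T")
  n <- nrow(pairs)
  pid <- character(0); mate <- integer(0); off <- integer(0)
  strand <- character(0); placed <- character(0)
  for (m in 1:2) {
    seqs <- pairs[[paste0("sequence", m)]]
    bp <- lapply(seqs, .best_placement_cpp, ref = ref)
    offs <- vapply(bp, `[[`, 0L, "offset")
    str_ <- vapply(bp, `[[`, "", "strand")
    ok <- offs >= 0
    pseq <- seqs
    rev <- ok & str_ == "reverse"
    pseq[rev] <- revcomp(pseq[rev])
    pid <- c(pid, pairs$pair_id[ok]); mate <- c(mate, rep(m, sum(ok)))
    off <- c(off, offs[ok]); strand <- c(strand, str_[ok])
    placed <- c(placed, pseq[ok])
  }
  # base counts via one tabulate over encoded (position, base) indices
  enc <- integer(0)
  if (length(placed)) {
    chars <- strsplit(placed, "", fixed = TRUE)
    lens <- lengths(chars)
    posv <- unlist(lapply(seq_along(chars),
                          function(i) off[i] + seq_len(lens[i])))
    bidx <- match(unlist(chars), bases)
    keep <- !is.na(bidx) & posv >= 1 & posv <= L
    enc <- (posv[keep] - 1L) * 4L + bidx[keep]
  }
  counts <- matrix(tabulate(enc, nbins = 4L * L), nrow = 4L,
                   dimnames = list(bases, NULL))
  list(counts = counts,
       placements = data.frame(pair_id = pid, mate = mate, offset = off,
                               strand = strand, placed_seq = placed,
                               stringsAsFactors = FALSE))
}

#' Depth-thresholded genotype calls from a pileup
#'
#' Per column: alleles with `count / depth >= min_allele_fraction` are
#' retained; a single allele with depth `>= hom_min` is called homozygous, two
#' alleles with depth `>= het_min` heterozygous; anything else is a `no_call`
#' with reason `low_depth` or `multi_allelic` (never a forced diploid call).
#' All-reference columns are emitted as homozygous-reference only when depth
#' reaches `hom_min`.
#'
#' @param pileup output of [pileup_pairs()].
#' @param ref reference sequence string.
#' @param gene gene label for the output.
#' @param hom_min minimum depth for homozygous calls.
#' @param het_min minimum depth for heterozygous calls.
#' @param min_allele_fraction allele-balance floor (guards against a single
#'   error base creating a spurious het).
#' @param dropout_guard single-allele columns whose depth is below
#'   `dropout_guard` times the gene's typical covered depth (its 75th
#'   percentile over covered columns) are declined (`no_call`, reason
#'   `allele_dropout`): the negative filter
#'   removes target-origin pairs wherever a haplotype locally resembles a
#'   homologue, and the resulting one-allele, half-depth columns would
#'   otherwise surface as confident wrong homozygous calls. Set to 0 to
#'   disable.
#' @return data.frame of calls: `gene`, `pos` (0-based), `ref`, `genotype`
#'   (`hom`/`het`/`no_call`), `allele1`, `allele2`, `reason`, `depth`,
#'   `count1`, `count2`, `phase_set`.
#' @export
call_genotypes <- function(pileup, ref, gene = "gene", hom_min = 20L,
                           het_min = 10L, min_allele_fraction = 0.2,
                           dropout_guard = 0.6) {
  counts <- pileup$counts
  L <- ncol(counts)
  bases <- rownames(counts)
  refb <- strsplit(toupper(ref), "", fixed = TRUE)[[1]]
  if (length(refb) != L) stop("reference length does not match pileup")
  depth <- colSums(counts)
  retained <- counts > 0 &
    sweep(counts, 2, pmax(depth, 1L), "/") >= min_allele_fraction
  n_alleles <- colSums(retained)
  genotype <- rep("no_call", L)
  reason <- rep("low_depth", L)
  a1 <- rep(NA_character_, L); a2 <- rep(NA_character_, L)
  c1 <- rep(NA_integer_, L); c2 <- rep(NA_integer_, L)
  # typical on-gene depth, robust to edge ramps and to the dips the guard
  # is looking for
  baseline <- if (any(depth > 0))
    quantile(depth[depth > 0], 0.75, names = FALSE) else 0
  # dropout signatures for a would-be hom column: depth well below the
  # gene's typical depth, or a sub-threshold second allele backed by more
  # than one read (a lone error base never triggers it)
  second <- apply(counts, 2, function(cc) sort(cc, decreasing = TRUE)[2])
  dropout <- n_alleles == 1L & depth >= hom_min & dropout_guard > 0 &
    (depth < dropout_guard * baseline |
       (second >= 2L & second / pmax(depth, 1L) >= 0.05))
  reason[dropout] <- "allele_dropout"
  hom <- n_alleles == 1L & depth >= hom_min & !dropout
  if (any(hom)) {
    bi <- apply(retained[, hom, drop = FALSE], 2, which)
    genotype[hom] <- "hom"; reason[hom] <- NA
    a1[hom] <- bases[bi]; a2[hom] <- bases[bi]
    c1[hom] <- counts[cbind(bi, which(hom))]; c2[hom] <- c1[hom]
  }
  het <- n_alleles == 2L & depth >= het_min
  for (p in which(het)) {
    bi <- which(retained[, p]) # base order is alphabetical already
    genotype[p] <- "het"; reason[p] <- NA
    a1[p] <- bases[bi[1]]; a2[p] <- bases[bi[2]]
    c1[p] <- counts[bi[1], p]; c2[p] <- counts[bi[2], p]
  }
  reason[n_alleles > 2L] <- "multi_allelic"
  data.frame(gene = gene, pos = seq_len(L) - 1L, ref = refb,
             genotype = genotype, allele1 = a1, allele2 = a2,
             reason = reason, depth = unname(depth), count1 = c1,
             count2 = c2, phase_set = NA_character_,
             stringsAsFactors = FALSE)
}

#' Variable-content gene presence from post-filter depth
#'
#' @param mean_depths named numeric vector: mean post-filter depth per gene
#'   (summed placed bases / gene length, computed from negative-filter output
#'   only).
#' @param presence_min_depth minimum mean depth to call a gene present
#'   (present iff depth >= threshold).
#' @return data.frame: `gene`, `mean_depth`, `present`.
#' @export
gene_presence <- function(mean_depths, presence_min_depth = 5) {
  data.frame(gene = names(mean_depths), mean_depth = unname(mean_depths),
             present = unname(mean_depths) >= presence_min_depth,
             stringsAsFactors = FALSE)
}

#' Phase heterozygous calls with read-pair evidence
#'
#' Two het sites share a phase set iff they are connected (transitively) by at
#' least one read pair observing both sites with a consistent allele pairing.
#' Edges where both pairings are observed are conflicts: they do not join
#' sites and both ends are flagged.
#'
#' @param calls output of [call_genotypes()] for one gene.
#' @param placements the `placements` frame from [pileup_pairs()] for the same
#'   retained pairs.
#' @return list: `calls` (with `phase_set` filled for phased het sites and a
#'   `phase_conflict` logical column), `edges` (data.frame: `pos_i`, `pos_j`,
#'   `n_cis`, `n_trans`, `orientation`, `conflict`).
#' @export
phase_local <- function(calls, placements) {
  het <- calls[calls$genotype == "het", , drop = FALSE]
  calls$phase_conflict <- FALSE
  empty_edges <- data.frame(pos_i = integer(), pos_j = integer(),
                            n_cis = integer(), n_trans = integer(),
                            orientation = character(), conflict = logical(),
                            stringsAsFactors = FALSE)
  if (nrow(het) < 2 || !nrow(placements))
    return(list(calls = calls, edges = empty_edges))
  # per pair, the base observed at each het site
  obs <- list()
  for (r in seq_len(nrow(placements))) {
    off <- placements$offset[r]
    len <- nchar(placements$placed_seq[r])
    cover <- het$pos >= off & het$pos < off + len
    if (!any(cover)) next
    idx <- which(cover)
    base <- substring(placements$placed_seq[r], het$pos[idx] - off + 1L,
                      het$pos[idx] - off + 1L)
    valid <- base == het$allele1[idx] | base == het$allele2[idx]
    if (!any(valid)) next
    pid <- placements$pair_id[r]
    prev <- obs[[pid]]
    add <- setNames(base[valid], het$pos[idx[valid]])
    obs[[pid]] <- c(prev, add[setdiff(names(add), names(prev))])
  }
  # orientation tallies per site pair
  tal <- new.env(parent = emptyenv())
  for (o in obs) {
    if (length(o) < 2) next
    ps <- sort(as.integer(names(o)))
    for (a in seq_len(length(ps) - 1L)) {
      for (b in (a + 1L):length(ps)) {
        i <- ps[a]; j <- ps[b]
        hi <- het[het$pos == i, ]; hj <- het[het$pos == j, ]
        cis <- (o[[as.character(i)]] == hi$allele1) ==
          (o[[as.character(j)]] == hj$allele1)
        key <- paste(i, j)
        cur <- if (exists(key, envir = tal)) get(key, envir = tal)
               else c(cis = 0L, trans = 0L)
        cur[if (cis) "cis" else "trans"] <- cur[if (cis) "cis" else "trans"] + 1L
        assign(key, cur, envir = tal)
      }
    }
  }
  keys <- ls(tal)
  if (!length(keys)) return(list(calls = calls, edges = empty_edges))
  edges <- do.call(rbind, lapply(keys, function(k) {
    v <- get(k, envir = tal)
    ij <- as.integer(strsplit(k, " ")[[1]])
    data.frame(pos_i = ij[1], pos_j = ij[2], n_cis = v[["cis"]],
               n_trans = v[["trans"]],
               orientation = if (v[["cis"]] > 0 && v[["trans"]] == 0) "cis"
                             else if (v[["trans"]] > 0 && v[["cis"]] == 0)
                               "trans" else "conflict",
               conflict = v[["cis"]] > 0 && v[["trans"]] > 0,
               stringsAsFactors = FALSE)
  }))
  # union-find over consistent edges
  parent <- setNames(het$pos, as.character(het$pos))
  find <- function(x) {
    while (parent[[as.character(x)]] != x) x <- parent[[as.character(x)]]
    x
  }
  for (r in seq_len(nrow(edges))) {
    if (edges$conflict[r]) next
    ri <- find(edges$pos_i[r]); rj <- find(edges$pos_j[r])
    if (ri != rj) parent[[as.character(max(ri, rj))]] <- min(ri, rj)
  }
  roots <- vapply(het$pos, find, 0L)
  comp_size <- table(roots)
  phased <- comp_size[as.character(roots)] >= 2
  ps_id <- ifelse(phased, sprintf("%s_ps%d", het$gene, roots), NA_character_)
  calls$phase_set[match(het$pos, calls$pos)] <- ps_id
  confl <- unique(c(edges$pos_i[edges$conflict], edges$pos_j[edges$conflict]))
  calls$phase_conflict[calls$pos %in% confl & calls$genotype == "het"] <- TRUE
  list(calls = calls, edges = edges)
}

#' Genotype concordance against truth
#'
#' Compares calls with truth genotypes on a shared gene/position space. With
#' `non_ref_only` (non-reference concordance), sites where the truth is
#' homozygous reference are excluded. `no_call` rows are excluded from both
#' numerator and denominator and counted separately; truth variant sites with
#' no emitted call count as no_calls.
#'
#' @param calls data.frame from [call_genotypes()] (possibly several genes).
#' @param truth data.frame with `gene`, `pos`, `ref`, `allele1`, `allele2`
#'   (positions absent from `truth` are homozygous reference).
#' @param non_ref_only restrict to truth-het / truth-hom-non-ref sites.
#' @return list: `n_compared`, `n_concordant`, `rate`, `n_no_call`.
#' @export
concordance <- function(calls, truth, non_ref_only = TRUE) {
  key <- function(g, p) paste(g, p)
  tkey <- key(truth$gene, truth$pos)
  truth_ref <- truth$allele1 == truth$ref & truth$allele2 == truth$ref
  cmp_keys <- if (non_ref_only) tkey[!truth_ref]
              else union(tkey, key(calls$gene, calls$pos))
  if (!length(cmp_keys)) stop("empty comparison set")
  ckey <- key(calls$gene, calls$pos)
  n_comp <- 0L; n_conc <- 0L; n_nc <- 0L
  for (kk in cmp_keys) {
    ci <- match(kk, ckey)
    if (is.na(ci) || calls$genotype[ci] == "no_call") {
      n_nc <- n_nc + 1L
      next
    }
    ti <- match(kk, tkey)
    if (is.na(ti)) {
      t_all <- rep(calls$ref[ci], 2) # hom-ref truth
    } else {
      t_all <- c(truth$allele1[ti], truth$allele2[ti])
    }
    c_all <- c(calls$allele1[ci], calls$allele2[ci])
    n_comp <- n_comp + 1L
    if (setequal(sort(t_all), sort(c_all)) &&
        identical(sort(t_all), sort(c_all)))
      n_conc <- n_conc + 1L
  }
  list(n_compared = n_comp, n_concordant = n_conc,
       rate = if (n_comp) n_conc / n_comp else NA_real_, n_no_call = n_nc)
}

#' End-to-end genotyping of a locus panel
#'
#' For each gene: positive filter, negative filter, matched-reference
#' selection, pileup, depth-thresholded calls and local phasing; plus
#' variable-content presence calls from post-filter mean depth. Pairs
#' harvested by two or more different target genes are dropped and counted
#' (`n_multi_gene`), since their gene of origin is ambiguous.
#'
#' @param pairs a quality-filtered [read_pairs()] frame.
#' @param panel a [locus_panel()].
#' @param hom_min,het_min,min_allele_fraction see [call_genotypes()].
#' @param presence_min_depth see [gene_presence()].
#' @return list: `calls` (all genes), `presence`, `phasing` (per-gene edge
#'   tables), `n_multi_gene`, `retained` (per-gene retained pair counts).
#' @export
genotype_locus <- function(pairs, panel, hom_min = 20L, het_min = 10L,
                           min_allele_fraction = 0.2, dropout_guard = 0.6,
                           presence_min_depth = 5) {
  genes <- unique(panel$targets$gene)
  cand <- lapply(genes, function(g) positive_filter(pairs, panel, g))
  names(cand) <- genes
  # ambiguous-gene pairs: harvested by >= 2 target genes
  all_ids <- unlist(lapply(cand, function(x) x$pair_id))
  multi <- unique(all_ids[duplicated(all_ids)])
  calls <- list(); edges <- list(); mean_depth <- numeric(); retained <- integer()
  for (g in genes) {
    cg <- cand[[g]]
    cg <- cg[!cg$pair_id %in% multi, , drop = FALSE]
    ret <- if (nrow(panel$homologues)) negative_filter(cg, panel) else cg
    retained[g] <- nrow(ret)
    ref_id <- select_matched_reference(ret, panel, g)
    ref <- panel$targets$sequence[panel$targets$id == ref_id]
    pu <- pileup_pairs(ret, ref)
    mean_depth[g] <- sum(pu$counts) / nchar(ref)
    cl <- call_genotypes(pu, ref, gene = g, hom_min = hom_min,
                         het_min = het_min,
                         min_allele_fraction = min_allele_fraction,
                         dropout_guard = dropout_guard)
    ph <- phase_local(cl, pu$placements)
    calls[[g]] <- ph$calls
    edges[[g]] <- ph$edges
  }
  list(calls = do.call(rbind, calls), presence = gene_presence(mean_depth,
                                                               presence_min_depth),
       phasing = edges, n_multi_gene = length(multi), retained = retained)
}
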