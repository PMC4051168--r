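# Community-structure statistics: silhouette cluster scan, PCA loadings,
# cross-population comparison, and abundance concordance.

check_abundance_matrix <- function(m) {
  if (!is.matrix(m)) m <- as.matrix(m)
  if (any(m < 0)) stop("abundances must be non-negative")
  if (any(abs(rowSums(m) - 1) > 1e-6))
    stop("abundance matrix rows must sum to 1")
  m
}

#' Silhouette scan over cluster numbers
#'
#' Partition-around-medoids clustering of samples on their relative-abundance
#' profiles for each k in `k_range`, scored by average silhouette width. A low
#' best width (the study's reading of 0.46 as only moderate) indicates a
#' gradient rather than discrete clusters; the scan reports widths without a
#' verdict.
#'
#' @param matrix samples x taxa relative-abundance matrix (rows sum to 1).
#' @param k_range integer vector of cluster numbers (each >= 2, <= n-1).
#' @param distance `"bray-curtis"` (default) or `"euclidean"`.
#' @param seed integer RNG seed (clustering of degenerate ties).
#' @return list of class `cluster_scan`: `widths` (named per k), `best_k`,
#'   `best_width`. All-identical samples yield NA widths with a warning.
#' @export
silhouette_scan <- function(matrix, k_range = 2:6,
                            distance = c("bray-curtis", "euclidean"),
                            seed = 1L) {
  distance <- match.arg(distance)
  m <- check_abundance_matrix(matrix)
  n <- nrow(m)
  if (any(k_range < 2)) stop("k must be >= 2")
  if (max(k_range) > n - 1)
    stop("k_range exceeds n - 1 (", n - 1, ")")
  d <- if (distance == "bray-curtis") vegan::vegdist(m, method = "bray")
       else stats::dist(m)
  widths <- setNames(rep(NA_real_, length(k_range)), k_range)
  if (all(d == 0)) {
    warning("all samples identical: silhouette widths undefined")
    return(structure(list(widths = widths, best_k = NA_integer_,
                          best_width = NA_real_), class = "cluster_scan"))
  }
  set.seed(seed)
  for (i in seq_along(k_range)) {
    fit <- cluster::pam(d, k = k_range[i], diss = TRUE)
    widths[i] <- fit$silinfo$avg.width
  }
  best <- which.max(widths)
  structure(list(widths = widths, best_k = k_range[best],
                 best_width = widths[[best]]), class = "cluster_scan")
}

#' PCA scores and loadings of an abundance matrix
#'
#' Principal components of the column-centered abundances. The sign of each
#' component is fixed so that its largest-|loading| taxon has a positive
#' loading, and taxa are ranked by absolute loading to identify those that
#' most strongly differentiate samples along the leading gradient.
#'
#' @param matrix samples x taxa relative-abundance matrix.
#' @param top_m how many top taxa to report per component.
#' @return list: `scores` (samples x PCs), `loadings` (taxa x PCs),
#'   `top_taxa` (list per PC of the top-m taxa by |loading|), `sdev`.
#' @export
pca_loadings <- function(matrix, top_m = 5L) {
  m <- check_abundance_matrix(matrix)
  if (nrow(m) < 3) stop("need at least 3 samples")
  if (all(apply(m, 2, function(x) max(x) - min(x)) < 1e-12))
    stop("constant abundance matrix: PCA undefined")
  pr <- prcomp(m, center = TRUE, scale. = FALSE)
  load <- pr$rotation
  scores <- pr$x
  for (j in seq_len(ncol(load))) {
    lead <- which.max(abs(load[, j]))
    if (load[lead, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  top <- lapply(seq_len(ncol(load)), function(j) {
    o <- order(abs(load[, j]), decreasing = TRUE)
    rownames(load)[head(o, top_m)]
  })
  names(top) <- colnames(load)
  list(scores = scores, loadings = load, top_taxa = top, sdev = pr$sdev,
       center = pr$center)
}

#' Cross-population differential-abundance comparison
#'
#' For every taxon in the union of the two populations' taxa (absent = 0): a
#' two-sided Wilcoxon rank-sum test on per-sample abundances, Bonferroni
#' correction over the number of taxa tested, a differential flag at
#' `adjusted p < alpha`, each population's median abundance, and the
#' median/max normalized value (a taxon's median relative abundance within a
#' population divided by that population's maximum for the taxon) used for
#' plotting. Also reports the cross-population Spearman correlation of median
#' abundances.
#'
#' @param matrixA,matrixB samples x taxa abundance matrices (each >= 2
#'   samples).
#' @param alpha significance level on the adjusted p-value.
#' @return list of class `population_comparison`: `table` (per-taxon
#'   data.frame: `taxon`, `median_A`, `median_B`, `normalized_A`,
#'   `normalized_B`, `p`, `p_adjusted`, `differential`), `spearman_rho`,
#'   `n_taxa`, `alpha`.
#' @export
compare_populations <- function(matrixA, matrixB, alpha = 0.01) {
  a <- check_abundance_matrix(matrixA)
  b <- check_abundance_matrix(matrixB)
  if (nrow(a) < 2 || nrow(b) < 2)
    stop("each population needs at least 2 samples")
  taxa <- sort(union(colnames(a), colnames(b)))
  pad <- function(m) {
    out <- matrix(0, nrow(m), length(taxa), dimnames = list(rownames(m), taxa))
    out[, colnames(m)] <- m
    out
  }
  a <- pad(a); b <- pad(b)
  p <- vapply(taxa, function(t) {
    x <- a[, t]; y <- b[, t]
    if (all(x == y[1]) && all(y == y[1])) return(1)
    if (min(x) > max(y) || min(y) > max(x)) {
      # complete separation: exactly one of the choose(n+m, n) group splits
      # attains the observed extreme rank sum (within-group ties included),
      # so the exact two-sided p is available even where the standard test
      # falls back to a normal approximation
      return(min(1, 2 / choose(length(x) + length(y), length(x))))
    }
    suppressWarnings(wilcox.test(x, y, alternative = "two.sided")$p.value)
  }, 0)
  p_adj <- p.adjust(p, method = "bonferroni")
  med_a <- apply(a, 2, median); med_b <- apply(b, 2, median)
  max_a <- apply(a, 2, max); max_b <- apply(b, 2, max)
  norm_a <- ifelse(max_a > 0, med_a / max_a, 0)
  norm_b <- ifelse(max_b > 0, med_b / max_b, 0)
  tab <- data.frame(taxon = taxa, median_A = med_a, median_B = med_b,
                    normalized_A = norm_a, normalized_B = norm_b, p = p,
                    p_adjusted = p_adj, differential = p_adj < alpha,
                    row.names = NULL, stringsAsFactors = FALSE)
  rho <- suppressWarnings(cor(med_a, med_b, method = "spearman"))
  structure(list(table = tab, spearman_rho = rho, n_taxa = length(taxa),
                 alpha = alpha), class = "population_comparison")
}

#' Spearman correlation of two abundance vectors
#'
#' Rank correlation with average ranks for ties; the p-value is exact (by
#' enumeration of the permutation distribution) for n <= 10 without ties and a
#' large-sample approximation otherwise.
#'
#' @param vectorA,vectorB equal-length numeric vectors over matched
#'   taxa/genomes (length >= 3).
#' @return list: `rho`, `p_value`, `n`.
#' @export
abundance_correlation <- function(vectorA, vectorB) {
  if (length(vectorA) != length(vectorB))
    stop("vectors must have equal length")
  n <- length(vectorA)
  if (n < 3) stop("need at least 3 paired values")
  ties <- anyDuplicated(vectorA) || anyDuplicated(vectorB)
  ct <- suppressWarnings(
    cor.test(vectorA, vectorB, method = "spearman",
             exact = (n <= 10 && !ties)))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n)
}
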