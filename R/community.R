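# Community structure: relative abundance at a rank, alpha diversity,
# Bray-Curtis beta diversity, PCoA ordination, and ANOSIM.

#' Aggregate counts to relative abundance at a taxonomic rank
#'
#' Counts are summed within each taxon of the requested rank and divided by
#' the sample total, so every column sums to 1.
#'
#' @param tab An [otu_table()].
#' @param rank One of kingdom/phylum/class/order/family/genus, or `"otu"`
#'   for no aggregation.
#' @return An object of class `abundance_table`: list with `proportions`
#'   (rank-taxa x samples), `rank`, and the sample `metadata`.
#' @export
aggregate_relative_abundance <- function(tab, rank = "phylum") {
  stopifnot(inherits(tab, "otu_table"))
  totals <- colSums(tab$counts)
  if (any(totals == 0)) {
    af_stop("degenerate", "all-zero sample(s): %s",
            paste(colnames(tab$counts)[totals == 0], collapse = ", "))
  }
  if (rank == "otu") {
    agg <- tab$counts
  } else {
    if (!rank %in% names(tab$taxonomy)) af_stop("usage", "unknown rank '%s'", rank)
    lineage <- tab$taxonomy[[rank]]
    agg <- rowsum(tab$counts, group = lineage)
  }
  props <- sweep(agg, 2, totals, "/")
  structure(list(proportions = props, rank = rank, metadata = tab$metadata),
            class = "abundance_table")
}

#' Group-mean relative abundances
#'
#' Averages the per-sample proportions of an [aggregate_relative_abundance()]
#' result over the member samples of each group.
#'
#' @param ab An `abundance_table`.
#' @return Matrix, rank-taxa x groups.
#' @export
group_mean_abundance <- function(ab) {
  stopifnot(inherits(ab, "abundance_table"))
  groups <- ab$metadata$group
  sapply(sort(unique(groups)), function(g) {
    rowMeans(ab$proportions[, groups == g, drop = FALSE])
  })
}

#' Alpha diversity indices per sample
#'
#' Chao1 (bias-corrected, `S_obs + F1(F1-1)/(2(F2+1))`) and ACE (rare-taxon
#' cutoff 10) come from [vegan::estimateR()]; Shannon is `-sum(p log p)`
#' (natural log) and Simpson is `1 - sum(p^2)` via [vegan::diversity()].
#' Chao1 and ACE need integer counts: with non-integer counts and the
#' default `indices`, this is a usage error; request only
#' `c("shannon", "simpson")` to proceed.
#'
#' @param tab An [otu_table()] or a taxa x samples count matrix.
#' @param indices Subset of `c("chao1", "ace", "shannon", "simpson")`.
#' @return Data frame with one row per sample.
#' @export
alpha_diversity <- function(tab, indices = c("chao1", "ace", "shannon", "simpson")) {
  counts <- if (inherits(tab, "otu_table")) tab$counts else tab
  indices <- match.arg(indices, several.ok = TRUE)
  needs_int <- any(c("chao1", "ace") %in% indices)
  if (needs_int && any(counts != round(counts))) {
    af_stop("usage",
            "Chao1/ACE need integer counts; request only shannon/simpson for non-integer data")
  }
  comm <- t(counts)  # vegan convention: samples x taxa
  out <- data.frame(sample_id = rownames(comm))
  if (needs_int) {
    est <- vegan::estimateR(round(comm))
    if ("chao1" %in% indices) out$chao1 <- unname(est["S.chao1", ])
    if ("ace" %in% indices) out$ace <- unname(est["S.ACE", ])
  }
  if ("shannon" %in% indices) out$shannon <- unname(vegan::diversity(comm, "shannon"))
  if ("simpson" %in% indices) out$simpson <- unname(vegan::diversity(comm, "simpson"))
  rownames(out) <- out$sample_id
  out
}

#' Bray-Curtis distance matrix between samples
#'
#' d(i, j) = sum |x_i - x_j| / sum (x_i + x_j) over taxa, computed with
#' [vegan::vegdist()].
#'
#' @param x An [otu_table()], `abundance_table`, or taxa x samples matrix.
#' @return Square symmetric matrix with sample ids as dimnames, entries in
#'   \[0, 1\].
#' @export
bray_curtis <- function(x) {
  m <- if (inherits(x, "otu_table")) x$counts
       else if (inherits(x, "abundance_table")) x$proportions
       else x
  if (ncol(m) < 2) af_stop("usage", "need >= 2 samples for a distance matrix")
  if (any(colSums(m) == 0)) {
    af_stop("degenerate", "Bray-Curtis undefined for all-zero sample(s): %s",
            paste(colnames(m)[colSums(m) == 0], collapse = ", "))
  }
  as.matrix(vegan::vegdist(t(m), method = "bray"))
}

#' Principal coordinates analysis (PCoA)
#'
#' Classical metric scaling of a distance matrix (Gower double-centering and
#' eigen-decomposition). Negative eigenvalues are retained in the report but
#' excluded from the coordinates; the proportion explained per axis uses the
#' sum of positive eigenvalues.
#'
#' @param d Square symmetric distance matrix or `dist`.
#' @param n_axes Number of axes to keep.
#' @return List of class `pcoa_ordination`: `coordinates` (samples x axes),
#'   `eigenvalues` (all), `prop_explained` (per kept axis),
#'   `negative_eigenvalues`.
#' @export
pcoa <- function(d, n_axes = 2) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) af_stop("usage", "distance matrix must be symmetric")
  n <- nrow(d)
  k <- min(n_axes, n - 1)
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = k, eig = TRUE))
  eig <- fit$eig
  pos <- eig[eig > 1e-12]
  keep <- min(k, length(pos))
  coords <- fit$points[, seq_len(keep), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(keep))
  structure(list(
    coordinates = coords,
    eigenvalues = eig,
    prop_explained = pos[seq_len(keep)] / sum(pos),
    negative_eigenvalues = eig[eig < -1e-12]
  ), class = "pcoa_ordination")
}

#' Analysis of similarities (ANOSIM)
#'
#' Clarke's rank-based test of between-group differences on a distance
#' matrix: with midranks r of all pairwise distances,
#' R = (mean rank between - mean rank within) / (n(n-1)/4), and the p-value
#' is the permutation tail probability
#' p = (1 + #\{R_perm >= R_obs\}) / (1 + n_permutations) under random
#' reassignment of group labels.
#'
#' @param d Square symmetric distance matrix or `dist`.
#' @param groups Group label per sample (in the order of `d`).
#' @param n_permutations Number of label permutations (>= 99).
#' @param seed Optional seed for the permutation stream.
#' @return List with `R`, `p`, `n_permutations`, and the permuted statistics
#'   `perm_R`.
#' @export
anosim_test <- function(d, groups, n_permutations = 999, seed = NULL) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  n <- nrow(d)
  groups <- as.character(groups)
  if (length(groups) != n) af_stop("usage", "groups must have one label per sample")
  if (length(unique(groups)) < 2) af_stop("usage", "need >= 2 groups")
  check_group_sizes(groups)
  if (n_permutations < 99) af_stop("usage", "n_permutations must be >= 99")

  lower <- lower.tri(d)
  r <- rank(d[lower])                     # midranks for ties
  denom <- n * (n - 1) / 4
  pair_i <- row(d)[lower]
  pair_j <- col(d)[lower]
  stat <- function(g) {
    within <- g[pair_i] == g[pair_j]
    (mean(r[!within]) - mean(r[within])) / denom
  }
  R_obs <- stat(groups)
  perm_R <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) stat(sample(groups)), numeric(1))
  })
  p <- (1 + sum(perm_R >= R_obs)) / (1 + n_permutations)
  list(R = R_obs, p = p, n_permutations = n_permutations, perm_R = perm_R)
}
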