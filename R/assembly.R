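# Null-model partitioning of community assembly into five ecological
# processes: the two-step betaNTI + Raup-Crick(Bray) framework.
#
# Step 1 (phylogenetic): betaMNTD between each sample pair is compared with
# a null distribution obtained by shuffling taxon labels across the tips of
# the phylogeny; the standardized deviation is betaNTI. |betaNTI| > 2 marks
# deterministic selection (heterogeneous if > +2, homogeneous if < -2).
# Step 2 (taxonomic): pairs not assigned to selection are classified by the
# Raup-Crick metric on Bray-Curtis against a richness- and
# abundance-preserving null. RC > 0.95 marks dispersal limitation,
# RC < -0.95 homogenizing dispersal, and the residual pairs are drift and
# other processes.

#' Between-community mean nearest taxon distance (betaMNTD)
#'
#' For each sample pair, the (abundance-weighted) mean over the taxa of one
#' sample of the phylogenetic distance to the nearest taxon present in the
#' other sample, averaged over both directions. A taxon shared by both
#' samples has nearest-taxon distance 0.
#'
#' @param tab An [otu_table()] or taxa x samples count matrix.
#' @param tree An [ape::phylo] tree whose tips cover all taxa with nonzero
#'   counts.
#' @param weighted Use relative abundances as weights (default); otherwise
#'   presence/absence, where the pair value is the pooled mean of the
#'   nearest-taxon distances of both samples' taxa (the picante convention).
#' @return Square symmetric matrix of betaMNTD values with zero diagonal.
#' @export
beta_mntd <- function(tab, tree, weighted = TRUE) {
  counts <- if (inherits(tab, "otu_table")) tab$counts else tab
  present_taxa <- rownames(counts)[rowSums(counts) > 0]
  missing <- setdiff(present_taxa, tree$tip.label)
  if (length(missing)) {
    af_stop("input", "taxa absent from the tree: %s",
            paste(utils::head(missing, 10), collapse = ", "))
  }
  counts <- counts[intersect(tree$tip.label, rownames(counts)), , drop = FALSE]
  D <- stats::cophenetic(tree)[rownames(counts), rownames(counts)]
  bm <- beta_mntd_engine(counts, D, weighted)
  bm$value
}

# Shared core for observed and null betaMNTD, all integer-indexed so a
# row/column-permuted distance matrix (the tip-shuffling null) is honored.
# A taxon present in both samples has nearest-taxon distance 0, so only
# taxa exclusive to one side contribute.
beta_mntd_engine <- function(counts, D, weighted = TRUE, prep = NULL) {
  n <- ncol(counts)
  n_taxa <- nrow(counts)
  if (is.null(prep)) prep <- beta_mntd_prep(counts, weighted)
  dmin <- vector("list", n)  # per sample: minima over its taxa, full-length
  for (j in seq_len(n)) {
    dvec <- numeric(n_taxa)
    abs_j <- prep$absent[[j]]
    if (length(abs_j)) {
      dvec[abs_j] <- row_mins(D[abs_j, prep$present[[j]], drop = FALSE])
    }
    dmin[[j]] <- dvec
  }
  val <- matrix(0, n, n, dimnames = list(colnames(counts), colnames(counts)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      only_i <- prep$only[[i]][[j]]
      only_j <- prep$only[[j]][[i]]
      v <- if (weighted) {
        0.5 * (sum(prep$w[only_i, i] * dmin[[j]][only_i]) +
               sum(prep$w[only_j, j] * dmin[[i]][only_j]))
      } else {
        (sum(dmin[[j]][only_i]) + sum(dmin[[i]][only_j])) /
          (prep$richness[i] + prep$richness[j])
      }
      val[i, j] <- val[j, i] <- v
    }
  }
  list(value = val, prep = prep)
}

beta_mntd_prep <- function(counts, weighted) {
  n <- ncol(counts)
  pa <- counts > 0
  present <- lapply(seq_len(n), function(j) which(pa[, j]))
  absent <- lapply(seq_len(n), function(j) which(!pa[, j]))
  only <- lapply(seq_len(n), function(i) {
    lapply(seq_len(n), function(j) which(pa[, i] & !pa[, j]))
  })
  w <- if (weighted) sweep(counts, 2, colSums(counts), "/") else pa * 1
  list(present = present, absent = absent, only = only, w = w,
       richness = colSums(pa))
}

#' Beta nearest taxon index (betaNTI)
#'
#' Standardized deviation of observed betaMNTD from a null distribution in
#' which taxon labels are shuffled across the tree tips (`n_nulls` draws):
#' betaNTI = (obs - mean_null) / sd_null per sample pair. Pairs whose null
#' standard deviation is 0 (e.g. a star phylogeny) are flagged `NA` with a
#' warning and excluded from downstream process fractions.
#'
#' @inheritParams beta_mntd
#' @param n_nulls Number of tip-shuffling null draws (>= 99).
#' @param seed Seed for the null stream.
#' @return Square matrix of betaNTI values (`NA` where undefined), with the
#'   observed betaMNTD attached as attribute `obs`.
#' @export
beta_nti <- function(tab, tree, n_nulls = 999, seed = NULL, weighted = TRUE) {
  if (n_nulls < 99) af_stop("usage", "n_nulls must be >= 99")
  counts <- if (inherits(tab, "otu_table")) tab$counts else tab
  present_taxa <- rownames(counts)[rowSums(counts) > 0]
  missing <- setdiff(present_taxa, tree$tip.label)
  if (length(missing)) {
    af_stop("input", "taxa absent from the tree: %s",
            paste(utils::head(missing, 10), collapse = ", "))
  }
  counts <- counts[intersect(tree$tip.label, rownames(counts)), , drop = FALSE]
  D <- stats::cophenetic(tree)[rownames(counts), rownames(counts)]
  n_taxa <- nrow(counts)

  obs <- beta_mntd_engine(counts, D, weighted)
  prep <- obs$prep
  lower <- lower.tri(obs$value)
  null_sum <- 0
  null_sq <- 0
  with_seed(seed, {
    for (b in seq_len(n_nulls)) {
      perm <- sample.int(n_taxa)
      v <- beta_mntd_engine(counts, D[perm, perm, drop = FALSE], weighted,
                            prep = prep)$value[lower]
      null_sum <- null_sum + v
      null_sq <- null_sq + v^2
    }
  })
  mu <- null_sum / n_nulls
  sd_null <- sqrt(pmax(0, null_sq / n_nulls - mu^2) * n_nulls / (n_nulls - 1))
  z <- (obs$value[lower] - mu) / sd_null
  undef <- sd_null < 1e-12
  if (any(undef)) {
    af_warn("%d pair(s) with zero null variance flagged as undefined betaNTI", sum(undef))
    z[undef] <- NA_real_
  }
  out <- matrix(0, ncol(counts), ncol(counts),
                dimnames = dimnames(obs$value))
  out[lower] <- z
  out <- out + t(out)
  diag(out) <- NA_real_
  attr(out, "obs") <- obs$value
  out
}

#' Raup-Crick metric on Bray-Curtis dissimilarity
#'
#' Each null community preserves the observed sample's richness and total
#' abundance: taxa are drawn without replacement with probability
#' proportional to their occurrence frequency across samples, seeded with
#' one individual each, and the remaining individuals are assigned
#' multinomially in proportion to the regional relative abundances of the
#' chosen taxa. For each pair, RC = 2 * (P(null < obs) + 0.5 P(null = obs)) - 1
#' on the Bray-Curtis scale, so RC is in \[-1, 1\].
#'
#' @param tab An [otu_table()] or taxa x samples count matrix.
#' @param n_nulls Number of null community draws (>= 99).
#' @param seed Seed for the null stream.
#' @return Square matrix of RC values; pairs involving a sample with fewer
#'   than 2 taxa are `NA`.
#' @export
raup_crick_bray <- function(tab, n_nulls = 999, seed = NULL) {
  if (n_nulls < 99) af_stop("usage", "n_nulls must be >= 99")
  counts <- if (inherits(tab, "otu_table")) tab$counts else tab
  n <- ncol(counts)
  n_taxa <- nrow(counts)
  occ <- rowSums(counts > 0)                 # occurrence frequency
  regional <- rowSums(counts)                # regional abundances
  richness <- colSums(counts > 0)
  depth <- colSums(counts)
  flagged <- richness < 2
  if (any(flagged)) {
    af_warn("%d sample(s) with < 2 taxa: their pairs are flagged NA", sum(flagged))
  }
  obs_d <- as.matrix(vegan::vegdist(t(counts), method = "bray"))
  lower <- lower.tri(obs_d)
  obs_v <- obs_d[lower]
  n_less <- numeric(length(obs_v))
  n_equal <- numeric(length(obs_v))
  with_seed(seed, {
    for (b in seq_len(n_nulls)) {
      nullc <- matrix(0, n_taxa, n)
      for (j in seq_len(n)) {
        if (flagged[j]) next
        pick <- sample.int(n_taxa, richness[j], prob = occ)
        fill <- depth[j] - richness[j]
        ab <- rep(1, richness[j])
        if (fill > 0) {
          ab <- ab + as.vector(stats::rmultinom(1, fill, prob = regional[pick]))
        }
        nullc[pick, j] <- ab
      }
      nd <- as.matrix(vegan::vegdist(t(nullc), method = "bray"))[lower]
      n_less <- n_less + (nd < obs_v - 1e-12)
      n_equal <- n_equal + (abs(nd - obs_v) <= 1e-12)
    }
  })
  rc_v <- 2 * ((n_less + 0.5 * n_equal) / n_nulls) - 1
  rc <- matrix(0, n, n, dimnames = dimnames(obs_d))
  rc[lower] <- rc_v
  rc <- rc + t(rc)
  diag(rc) <- NA_real_
  if (any(flagged)) {
    rc[flagged, ] <- NA_real_
    rc[, flagged] <- NA_real_
  }
  attr(rc, "obs_bray") <- obs_d
  rc
}

PROCESSES <- c("heterogeneous_selection", "homogeneous_selection",
               "dispersal_limitation", "homogenizing_dispersal",
               "drift_and_others")

#' Partition community assembly into five ecological processes
#'
#' Classifies each sample pair: heterogeneous selection if betaNTI >
#' `bnti_cut`; homogeneous selection if betaNTI < -`bnti_cut`; otherwise
#' dispersal limitation if RC > `rc_cut`; homogenizing dispersal if RC <
#' -`rc_cut`; else drift and other processes. Per-group fractions are
#' computed over within-group pairs; a group is deterministic-dominated when
#' its two selection fractions sum above 0.5, stochastic otherwise.
#'
#' @param bnti betaNTI matrix from [beta_nti()].
#' @param rc Raup-Crick matrix from [raup_crick_bray()].
#' @param groups Named group labels per sample, or `NULL` for a single group.
#' @param bnti_cut,rc_cut Classification thresholds (defaults 2 and 0.95).
#' @return Object of class `assembly_result`: list with `classification`
#'   (character matrix), `fractions` (group x process data frame),
#'   `dominant` (per-group "deterministic"/"stochastic"), plus the inputs
#'   and thresholds.
#' @export
partition_processes <- function(bnti, rc, groups = NULL,
                                bnti_cut = 2, rc_cut = 0.95) {
  if (!all(dim(bnti) == dim(rc))) af_stop("usage", "betaNTI and RC matrices must match")
  if (!is.null(colnames(bnti)) && !is.null(colnames(rc)) &&
      !identical(colnames(bnti), colnames(rc))) {
    af_stop("usage", "betaNTI and RC sample ids differ")
  }
  n <- ncol(bnti)
  cls <- matrix(NA_character_, n, n, dimnames = dimnames(bnti))
  lower <- which(lower.tri(cls))
  b <- bnti[lower]
  r <- rc[lower]
  k <- ifelse(is.na(b), NA_character_,
       ifelse(b > bnti_cut, "heterogeneous_selection",
       ifelse(b < -bnti_cut, "homogeneous_selection",
       ifelse(is.na(r), NA_character_,
       ifelse(r > rc_cut, "dispersal_limitation",
       ifelse(r < -rc_cut, "homogenizing_dispersal", "drift_and_others"))))))
  if (all(is.na(k))) af_stop("degenerate", "all sample pairs are undefined; cannot partition")
  if (anyNA(k)) af_warn("%d undefined pair(s) excluded from process fractions", sum(is.na(k)))
  cls[lower] <- k
  cls <- t(cls); cls[lower] <- k; cls <- t(cls)  # symmetrize

  if (is.null(groups)) groups <- rep("all", n)
  groups <- as.character(groups)
  gnames <- sort(unique(groups))
  frac <- matrix(0, length(gnames), length(PROCESSES),
                 dimnames = list(gnames, PROCESSES))
  for (g in gnames) {
    idx <- which(groups == g)
    if (length(idx) < 2) af_stop("usage", "group '%s' has fewer than 2 samples", g)
    sub <- cls[idx, idx][lower.tri(diag(length(idx)))]
    sub <- sub[!is.na(sub)]
    if (!length(sub)) af_stop("degenerate", "group '%s' has no defined pairs", g)
    frac[g, ] <- tabulate(factor(sub, levels = PROCESSES), length(PROCESSES)) / length(sub)
  }
  fractions <- as.data.frame(frac)
  selection <- fractions$heterogeneous_selection + fractions$homogeneous_selection
  dominant <- stats::setNames(ifelse(selection > 0.5, "deterministic", "stochastic"), gnames)
  structure(list(classification = cls, fractions = fractions, dominant = dominant,
                 bnti = bnti, rc = rc,
                 thresholds = c(bnti_cut = bnti_cut, rc_cut = rc_cut)),
            class = "assembly_result")
}

#' @export
print.assembly_result <- function(x, ...) {
  cat("Assembly process fractions (within-group pairs):\n")
  print(round(x$fractions, 3))
  cat("Dominant regime:", paste(names(x$dominant), x$dominant, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
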