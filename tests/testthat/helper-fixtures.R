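# Fixture builders and independent brute-force oracles shared by the tests.

make_tab <- function(counts, groups = NULL, taxonomy = NULL) {
  if (is.null(colnames(counts))) colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  if (is.null(rownames(counts))) rownames(counts) <- paste0("t", seq_len(nrow(counts)))
  if (is.null(groups)) groups <- rep("G1", ncol(counts))
  otu_table(counts,
            metadata = data.frame(sample_id = colnames(counts), group = groups),
            taxonomy = taxonomy)
}

rand_tab <- function(n_taxa, n_samples, groups = NULL, seed = 1, lambda = 30) {
  set.seed(seed)
  counts <- matrix(stats::rpois(n_taxa * n_samples, lambda), n_taxa, n_samples)
  make_tab(counts, groups = groups)
}

# All set partitions of n elements (restricted-growth strings).
set_partitions <- function(n) {
  out <- list()
  recurse <- function(assign, k) {
    i <- length(assign) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- assign
      return(invisible())
    }
    for (b in seq_len(k + 1)) recurse(c(assign, b), max(k, b))
  }
  recurse(integer(0), 0)
  out
}

# Independent ANOSIM R: mean-rank formula written from scratch.
brute_anosim_R <- function(d, g) {
  n <- nrow(d)
  lower <- lower.tri(d)
  r <- rank(d[lower])
  same <- outer(g, g, "==")[lower]
  (mean(r[!same]) - mean(r[same])) / (n * (n - 1) / 4)
}

# All permutations of seq_len(n) (n small).
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_perms(n - 1)
  out <- vector("list", n * length(sub))
  k <- 0
  for (p in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1
      out[[k]] <- append(p, n, after = pos - 1)
    }
  }
  out
}
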