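# Signed co-occurrence networks at a taxonomic rank and their topology
# report (nodes, links, signed-edge percentages, degree, density,
# modularity).

#' Build a signed co-occurrence network
#'
#' Taxa are aggregated to `rank` as relative abundances, filtered by
#' prevalence, and correlated pairwise (Spearman). An edge is kept iff
#' |rho| >= `r_cut` and the BH-adjusted p-value <= `p_cut`; its sign is the
#' sign of rho and its weight |rho|. Isolated nodes are dropped from the
#' graph; the pre-filter taxon count is kept in the result.
#'
#' @param tab An [otu_table()].
#' @param rank Taxonomic rank for aggregation (default genus).
#' @param method Correlation method; only `"spearman"` is supported.
#' @param r_cut Minimum absolute correlation.
#' @param p_cut Maximum adjusted p-value.
#' @param mtc Multiple-testing correction, passed to [stats::p.adjust()]
#'   (default `"BH"`).
#' @param min_prevalence Minimum fraction of samples in which a taxon must
#'   be present (count > 0) to enter the correlation.
#' @return Object of class `conetwork`: list with `graph` (igraph, with
#'   vertex attributes `phylum` and `degree`, edge attributes `rho`, `sign`,
#'   `weight`), `params`, `n_taxa_prefilter`, `n_taxa_tested`, `rank`.
#' @export
build_conetwork <- function(tab, rank = "genus", method = "spearman",
                            r_cut = 0.6, p_cut = 0.05, mtc = "BH",
                            min_prevalence = 1 / 3) {
  stopifnot(inherits(tab, "otu_table"))
  if (!identical(method, "spearman")) af_stop("usage", "only method = 'spearman' is supported")
  n_samples <- ncol(tab$counts)
  if (n_samples < 4) {
    af_stop("usage", "co-occurrence networks need >= 4 samples (correlation p-values are meaningless below)")
  }
  ab <- aggregate_relative_abundance(tab, rank)
  props <- ab$proportions
  props <- props[rownames(props) != "Unclassified", , drop = FALSE]
  n_prefilter <- nrow(props)
  prevalence <- rowMeans(props > 0)
  props <- props[prevalence >= min_prevalence, , drop = FALSE]
  taxa <- rownames(props)
  n_taxa <- length(taxa)

  edges <- NULL
  if (n_taxa >= 2) {
    pairs <- utils::combn(n_taxa, 2)
    rho <- numeric(ncol(pairs))
    pval <- numeric(ncol(pairs))
    for (k in seq_len(ncol(pairs))) {
      ct <- suppressWarnings(stats::cor.test(props[pairs[1, k], ], props[pairs[2, k], ],
                                             method = "spearman", exact = FALSE))
      rho[k] <- unname(ct$estimate)
      pval[k] <- ct$p.value
    }
    padj <- stats::p.adjust(pval, method = mtc)
    keep <- !is.na(rho) & abs(rho) >= r_cut & padj <= p_cut
    edges <- data.frame(from = taxa[pairs[1, keep]], to = taxa[pairs[2, keep]],
                        rho = rho[keep], padj = padj[keep])
  }

  g <- igraph::make_empty_graph(directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0) {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
    igraph::E(g)$sign <- ifelse(igraph::E(g)$rho > 0, 1L, -1L)
    igraph::E(g)$weight <- abs(igraph::E(g)$rho)
    phy <- rank_phylum_map(tab, rank)
    igraph::V(g)$phylum <- unname(phy[igraph::V(g)$name])
    igraph::V(g)$degree <- igraph::degree(g)
  }
  structure(list(graph = g,
                 params = list(method = method, r_cut = r_cut, p_cut = p_cut,
                               mtc = mtc, min_prevalence = min_prevalence),
                 n_taxa_prefilter = n_prefilter, n_taxa_tested = n_taxa,
                 rank = rank),
            class = "conetwork")
}

# Map each rank-level taxon to the (modal) phylum of its member OTUs.
rank_phylum_map <- function(tab, rank) {
  if (rank == "phylum") {
    phyla <- unique(tab$taxonomy$phylum)
    return(stats::setNames(phyla, phyla))
  }
  key <- if (rank == "otu") tab$taxonomy$taxon_id else tab$taxonomy[[rank]]
  tapply(tab$taxonomy$phylum, key, function(v) names(sort(table(v), decreasing = TRUE))[1])
}

#' @export
print.conetwork <- function(x, ...) {
  cat(sprintf("conetwork (%s rank): %d nodes, %d edges (|rho| >= %s, %s p <= %s)\n",
              x$rank, igraph::vcount(x$graph), igraph::ecount(x$graph),
              x$params$r_cut, x$params$mtc, x$params$p_cut))
  invisible(x)
}

#' Topology report of a co-occurrence network
#'
#' Closed-form descriptors plus modularity: with N nodes and L links,
#' average degree is 2L/N, graph density 2L/(N(N-1)), average weighted
#' degree 2*sum(weights)/N, and the positive/negative link percentages
#' partition 100. Modularity is the best of `n_restarts` seeded Louvain
#' runs on the absolute-correlation weights, ignoring edge signs.
#'
#' @param net A `conetwork` or an igraph graph (edge attribute `sign`
#'   optional, `weight` defaulting to 1).
#' @param seed Seed for the Louvain restarts.
#' @param n_restarts Number of community-detection restarts.
#' @return Data frame of class `topology_report` with one row:
#'   `n_nodes`, `n_links`, `positive_links_pct`, `negative_links_pct`,
#'   `average_degree`, `average_weighted_degree`, `graph_density`,
#'   `modularity`.
#' @export
topology <- function(net, seed = 1, n_restarts = 10) {
  g <- if (inherits(net, "conetwork")) net$graph else net
  n <- igraph::vcount(g)
  l <- igraph::ecount(g)
  if (n == 0 || l == 0) {
    af_warn("empty network: modularity undefined")
    out <- data.frame(n_nodes = n, n_links = l, positive_links_pct = NA_real_,
                      negative_links_pct = NA_real_, average_degree = 0,
                      average_weighted_degree = 0, graph_density = 0,
                      modularity = NA_real_)
    class(out) <- c("topology_report", "data.frame")
    return(out)
  }
  sgn <- igraph::edge_attr(g, "sign") %||% rep(1L, l)
  w <- igraph::edge_attr(g, "weight") %||% rep(1, l)
  pos_pct <- 100 * sum(sgn > 0) / l
  best_mod <- -Inf
  for (i in seq_len(n_restarts)) {
    cl <- with_seed(seed + i - 1, igraph::cluster_louvain(g, weights = w))
    m <- igraph::modularity(g, igraph::membership(cl), weights = w)
    if (m > best_mod) best_mod <- m
  }
  out <- data.frame(
    n_nodes = n, n_links = l,
    positive_links_pct = pos_pct,
    negative_links_pct = 100 - pos_pct,
    average_degree = 2 * l / n,
    average_weighted_degree = 2 * sum(w) / n,
    graph_density = 2 * l / (n * (n - 1)),
    modularity = best_mod
  )
  class(out) <- c("topology_report", "data.frame")
  out
}

#' @export
print.topology_report <- function(x, ...) {
  y <- as.data.frame(x)
  y$positive_links_pct <- round(y$positive_links_pct, 2)
  y$negative_links_pct <- round(y$negative_links_pct, 2)
  for (col in c("average_degree", "average_weighted_degree", "graph_density", "modularity")) {
    y[[col]] <- round(y[[col]], 3)
  }
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
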