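# Readers and writers for the plain-text interchange formats: counts TSV,
# taxonomy TSV, metadata CSV, function-panel CSV, newick trees, GraphML/GEXF
# networks, YAML run configuration. Readers validate and reject; they never
# silently repair.

#' Read an OTU table from TSV counts plus taxonomy and metadata files
#'
#' The counts file is tab-separated with taxon ids in the first column and
#' sample ids in the header. Taxonomy is a TSV with a `taxon_id` column and
#' ranked lineage columns; metadata is a CSV with `sample_id` and `group`
#' columns.
#'
#' @param path Path to the counts TSV.
#' @param metadata_path Path to the sample metadata CSV.
#' @param taxonomy_path Optional path to the taxonomy TSV.
#' @return An [otu_table()].
#' @export
read_otu_table <- function(path, metadata_path, taxonomy_path = NULL) {
  for (p in c(path, metadata_path, taxonomy_path)) {
    if (!file.exists(p)) af_stop("format", "file not found: %s", p)
  }
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(header[-1])) af_stop("format", "duplicated sample column in %s", path)
  raw <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "", comment.char = "")
  if (anyDuplicated(raw[[1]])) af_stop("format", "duplicated taxon id in %s", path)
  counts <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(counts)) af_stop("format", "non-numeric counts in %s", path)
  rownames(counts) <- as.character(raw[[1]])

  metadata <- utils::read.csv(metadata_path, stringsAsFactors = FALSE)
  taxonomy <- if (!is.null(taxonomy_path)) {
    utils::read.table(taxonomy_path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, quote = "", comment.char = "")
  }
  otu_table(counts, metadata = metadata, taxonomy = taxonomy)
}

#' Write an OTU table to counts TSV, taxonomy TSV and metadata CSV
#'
#' @param tab An [otu_table()].
#' @param dir Output directory (created if absent).
#' @param prefix File-name prefix.
#' @return Invisibly, a named vector of the three file paths.
#' @export
write_otu_table <- function(tab, dir, prefix = "otu") {
  stopifnot(inherits(tab, "otu_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    counts   = file.path(dir, paste0(prefix, "_counts.tsv")),
    taxonomy = file.path(dir, paste0(prefix, "_taxonomy.tsv")),
    metadata = file.path(dir, paste0(prefix, "_metadata.csv"))
  )
  df <- data.frame(taxon_id = rownames(tab$counts), tab$counts, check.names = FALSE)
  utils::write.table(df, paths["counts"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(tab$taxonomy, paths["taxonomy"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(tab$metadata, paths["metadata"], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Read an OTU table from a BIOM-format JSON file
#'
#' Accepts the JSON (format 1.0) flavour of the BIOM standard, read-only;
#' the canonical interchange format of this package remains plain TSV.
#' Requires the `biomformat` package.
#'
#' @param path Path to a `.biom` JSON file.
#' @param metadata_path Sample metadata CSV (used if the BIOM file carries
#'   no group metadata).
#' @return An [otu_table()].
#' @export
read_otu_biom <- function(path, metadata_path = NULL) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    af_stop("usage", "reading BIOM files requires the 'biomformat' package")
  }
  b <- biomformat::read_biom(path)
  counts <- as.matrix(biomformat::biom_data(b))
  md <- if (!is.null(metadata_path)) {
    utils::read.csv(metadata_path, stringsAsFactors = FALSE)
  } else {
    sm <- biomformat::sample_metadata(b)
    if (is.null(sm) || !"group" %in% names(sm)) {
      af_stop("metadata", "BIOM file has no group metadata; supply metadata_path")
    }
    data.frame(sample_id = rownames(sm), sm, stringsAsFactors = FALSE)
  }
  otu_table(counts, metadata = md)
}

#' Read a rooted phylogeny from a newick file
#'
#' Wraps [ape::read.tree()] with validation: tips must be uniquely labeled,
#' and missing branch lengths are set to 0 with a warning.
#'
#' @param path Path to a newick file (or a newick string via `text`).
#' @param text Optional newick string, bypassing `path`.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tr <- tryCatch(
    suppressWarnings(
      if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
    ),
    error = function(e) NULL
  )
  if (is.null(tr) || !inherits(tr, "phylo")) {
    af_stop("format", "could not parse newick input%s",
            if (is.null(text)) sprintf(" (%s)", path) else "")
  }
  if (anyNA(tr$tip.label) || any(tr$tip.label == "") || anyDuplicated(tr$tip.label)) {
    af_stop("format", "tree has unlabeled or duplicated tips")
  }
  if (is.null(tr$edge.length)) {
    af_warn("tree has no branch lengths; defaulting all to 0")
    tr$edge.length <- rep(0, nrow(tr$edge))
  } else if (anyNA(tr$edge.length)) {
    af_warn("%d missing branch lengths set to 0", sum(is.na(tr$edge.length)))
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  if (any(tr$edge.length < 0)) af_stop("format", "negative branch lengths")
  tr
}

#' Export a co-occurrence network to GraphML or GEXF
#'
#' Nodes carry their taxon id, phylum and degree; edges carry the
#' correlation, its sign and the absolute-correlation weight, so the file
#' loads directly into Gephi or igraph.
#'
#' @param net A `conetwork` (see [build_conetwork()]) or an igraph graph.
#' @param path Output file path.
#' @param format `"graphml"` or `"gexf"`.
#' @return Invisibly, `path`.
#' @export
write_network <- function(net, path, format = c("graphml", "gexf")) {
  if (!is.character(format) || !all(format %in% c("graphml", "gexf"))) {
    af_stop("usage", "unsupported network format; use 'graphml' or 'gexf'")
  }
  format <- match.arg(format)
  g <- if (inherits(net, "conetwork")) net$graph else net
  if (!inherits(g, "igraph")) af_stop("usage", "net must be a conetwork or igraph graph")
  if (igraph::vcount(g) > 0 && is.null(igraph::vertex_attr(g, "degree"))) {
    g <- igraph::set_vertex_attr(g, "degree", value = igraph::degree(g))
  }
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    write_gexf(g, path)
  }
  invisible(path)
}

# Minimal GEXF 1.2 writer (igraph has no GEXF support).
write_gexf <- function(g, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  n <- igraph::vcount(g)
  ids <- igraph::vertex_attr(g, "name") %||% as.character(seq_len(n))
  phylum <- igraph::vertex_attr(g, "phylum") %||% rep("", n)
  degree <- igraph::vertex_attr(g, "degree") %||% igraph::degree(g)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">',
    '  <graph defaultedgetype="undirected">',
    '    <attributes class="node">',
    '      <attribute id="phylum" title="phylum" type="string"/>',
    '      <attribute id="degree" title="degree" type="double"/>',
    '    </attributes>',
    '    <attributes class="edge">',
    '      <attribute id="sign" title="sign" type="integer"/>',
    '      <attribute id="rho" title="rho" type="double"/>',
    '    </attributes>',
    '    <nodes>'
  )
  if (n > 0) {
    lines <- c(lines, sprintf(
      '      <node id="%s" label="%s"><attvalues><attvalue for="phylum" value="%s"/><attvalue for="degree" value="%s"/></attvalues></node>',
      esc(ids), esc(ids), esc(phylum), degree))
  }
  lines <- c(lines, "    </nodes>", "    <edges>")
  m <- igraph::ecount(g)
  if (m > 0) {
    el <- igraph::as_edgelist(g, names = TRUE)
    sign <- igraph::edge_attr(g, "sign") %||% rep(1L, m)
    rho <- igraph::edge_attr(g, "rho") %||% rep(NA_real_, m)
    weight <- igraph::edge_attr(g, "weight") %||% abs(rho)
    lines <- c(lines, sprintf(
      '      <edge id="%d" source="%s" target="%s" weight="%s"><attvalues><attvalue for="sign" value="%d"/><attvalue for="rho" value="%s"/></attvalues></edge>',
      seq_len(m), esc(el[, 1]), esc(el[, 2]), weight, sign, rho))
  }
  lines <- c(lines, "    </edges>", "  </graph>", "</gexf>")
  writeLines(lines, path)
  invisible(path)
}

#' Read a GraphML network back into an igraph graph
#'
#' @param path Path to a GraphML file written by [write_network()].
#' @return An igraph graph.
#' @export
read_network_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

#' Read a function-indicator panel from CSV
#'
#' The values CSV has plot ids in the first column and one column per
#' indicator; the groups CSV maps `indicator` to one of the EF groups.
#'
#' @param path Values CSV (plot x indicator).
#' @param groups_path CSV with columns `indicator`, `group`.
#' @param metadata_path Optional plot metadata CSV (`sample_id`, `group`).
#' @return A [function_matrix()].
#' @export
read_function_matrix <- function(path, groups_path, metadata_path = NULL) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(raw[, -1, drop = FALSE])
  rownames(vals) <- as.character(raw[[1]])
  gr <- utils::read.csv(groups_path, stringsAsFactors = FALSE)
  groups <- stats::setNames(gr$group, gr$indicator)
  meta <- if (!is.null(metadata_path)) utils::read.csv(metadata_path, stringsAsFactors = FALSE)
  function_matrix(vals, indicator_groups = groups, plot_meta = meta)
}

#' Write a function-indicator panel to CSV
#'
#' @param fm A [function_matrix()].
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Invisibly, the file paths.
#' @export
write_function_matrix <- function(fm, dir, prefix = "functions") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(values = file.path(dir, paste0(prefix, ".csv")),
             groups = file.path(dir, paste0(prefix, "_groups.csv")))
  utils::write.csv(data.frame(plot_id = rownames(fm$values), fm$values,
                              check.names = FALSE),
                   paths["values"], row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(indicator = names(fm$indicator_groups),
                              group = unname(fm$indicator_groups)),
                   paths["groups"], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Run configuration for a full study analysis
#'
#' Collects the master seed, permutation/null/bootstrap counts and the
#' thresholds used by the network and assembly stages. All stochastic
#' operations derive their seeds from `seed` via [substream()].
#'
#' @param seed Master integer seed.
#' @param n_permutations Permutations for ANOSIM.
#' @param n_nulls Null draws for betaNTI and Raup-Crick.
#' @param n_bootstrap Bootstrap resamples for PLS-PM path p-values.
#' @param r_cut Minimum absolute correlation for a network edge.
#' @param p_cut Maximum BH-adjusted p for a network edge.
#' @param min_prevalence Minimum fraction of samples a taxon must occupy
#'   before entering the correlation network.
#' @param bnti_cut betaNTI magnitude separating selection from stochasticity.
#' @param rc_cut Raup-Crick magnitude separating dispersal processes from drift.
#' @param va_convention Enzyme vector-angle convention: `"spreadsheet"`,
#'   `"math"` or `"both"`.
#' @param network_rank,abundance_rank Taxonomic ranks for the network and
#'   relative-abundance stages.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 42, n_permutations = 999, n_nulls = 999,
                       n_bootstrap = 200, r_cut = 0.6, p_cut = 0.05,
                       min_prevalence = 1 / 3, bnti_cut = 2, rc_cut = 0.95,
                       va_convention = "spreadsheet",
                       network_rank = "genus", abundance_rank = "phylum") {
  cfg <- list(seed = as.integer(seed), n_permutations = as.integer(n_permutations),
              n_nulls = as.integer(n_nulls), n_bootstrap = as.integer(n_bootstrap),
              r_cut = r_cut, p_cut = p_cut, min_prevalence = min_prevalence,
              bnti_cut = bnti_cut, rc_cut = rc_cut,
              va_convention = va_convention,
              network_rank = network_rank, abundance_rank = abundance_rank)
  if (cfg$n_permutations < 1 || cfg$n_nulls < 1 || cfg$n_bootstrap < 0) {
    af_stop("usage", "permutation/null/bootstrap counts must be positive")
  }
  if (r_cut < 0 || r_cut > 1 || p_cut <= 0 || p_cut > 1) {
    af_stop("usage", "network thresholds out of range: need 0 <= r_cut <= 1, 0 < p_cut <= 1")
  }
  if (bnti_cut <= 0 || rc_cut <= 0 || rc_cut > 1) {
    af_stop("usage", "assembly thresholds out of range")
  }
  if (!va_convention %in% c("spreadsheet", "math", "both")) {
    af_stop("usage", "unknown va_convention '%s'", va_convention)
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path Path to a YAML file whose keys match [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) af_stop("usage", "unknown config keys: %s", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}
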