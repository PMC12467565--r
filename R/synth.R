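# Synthetic-data generators. Every generator is a pure function of its
# parameters and seed, and produces objects that pass the package's type
# invariants. The defaults mirror the supported study design: 4 altitude
# groups x 5 replicate plots, 300 taxa, sequencing depth 10,000.

ASSEMBLY_REGIMES <- c("heterogeneous_selection", "homogeneous_selection",
                      "dispersal_limitation", "homogenizing_dispersal", "drift")

#' Simulate an ultrametric pure-birth phylogeny
#'
#' @param n_tips Number of tips (>= 3).
#' @param seed Integer seed.
#' @return An [ape::phylo] rooted ultrametric tree with positive branch
#'   lengths and tips labeled `t1..tn`.
#' @export
simulate_tree <- function(n_tips, seed = NULL) {
  if (n_tips < 3) af_stop("usage", "n_tips must be >= 3")
  tr <- with_seed(seed, ape::rphylo(n_tips, birth = 1, death = 0))
  tr$edge.length <- pmax(tr$edge.length, 1e-8)
  tr
}

# Brownian-motion trait on the tree, standardized to unit variance, so
# phylogenetic signal (niche conservatism) exists for the selection regimes.
simulate_trait <- function(tree, seed = NULL) {
  tr <- with_seed(seed, ape::rTraitCont(tree, model = "BM", sigma = 1))
  stats::setNames(as.vector(scale(tr)), names(tr))
}

# Clade-based synthetic taxonomy: phyla are deep clades of the tree.
synthetic_taxonomy <- function(tree, n_phyla = 6) {
  D <- stats::cophenetic(tree)
  cl <- stats::cutree(stats::hclust(stats::as.dist(D), method = "average"),
                      k = min(n_phyla, length(tree$tip.label)))
  data.frame(
    taxon_id = tree$tip.label,
    kingdom = "Bacteria",
    phylum = paste0("Phylum", cl[tree$tip.label]),
    class = paste0("Class", cl[tree$tip.label]),
    order = paste0("Order", cl[tree$tip.label]),
    family = paste0("Family", cl[tree$tip.label]),
    genus = paste0("g_", tree$tip.label),
    stringsAsFactors = FALSE
  )
}

#' Simulate communities under a known assembly regime
#'
#' Counts are multinomial draws of `depth` individuals per sample with
#' regime-dependent sampling probabilities over a lognormal metacommunity:
#' * `heterogeneous_selection` / `homogeneous_selection`: log-abundance
#'   proportional to Gaussian fitness of a Brownian-motion (phylogenetically
#'   conserved) trait against the sample's environment; heterogeneous uses
#'   divergent environments across samples, homogeneous a common one.
#' * `drift`: neutral multinomial resampling from the shared metacommunity.
#' * `dispersal_limitation`: disjoint regional taxon pools per sample
#'   cluster.
#' * `homogenizing_dispersal`: heavy migrant exchange (migration rate `m`)
#'   toward the common metacommunity pool.
#'
#' @param tree Phylogeny from [simulate_tree()]; its tips are the taxa.
#' @param regime One of the five-process vocabulary (see above).
#' @param n_samples Number of replicate samples.
#' @param depth Sequencing depth per sample (>= 1000).
#' @param env_values Sample environments for the selection regimes; defaults
#'   to trait quantiles 0.05..0.95 (heterogeneous) or the trait median
#'   (homogeneous).
#' @param seed Integer seed.
#' @param group Group label written into the sample metadata.
#' @param altitude_m Altitude recorded in the metadata.
#' @param meta_sdlog Lognormal spread of the metacommunity abundances.
#' @param sel_width Gaussian niche width of the selection filter, in trait
#'   standard deviations (smaller = stronger selection).
#' @param migration Migrant fraction toward the common pool under
#'   homogenizing dispersal.
#' @param n_pools Number of disjoint regional pools under dispersal
#'   limitation.
#' @param meta_log_abundance,trait Optional shared metacommunity
#'   log-abundances and trait (drawn from `seed` when `NULL`), so several
#'   groups can share one regional species pool.
#' @return An [otu_table()] with the regime recorded as attribute `regime`.
#' @export
simulate_communities <- function(tree, regime, n_samples, depth = 10000,
                                 env_values = NULL, seed = NULL,
                                 group = "G1", altitude_m = NA_real_,
                                 meta_sdlog = 2, sel_width = 0.3,
                                 migration = 0.9, n_pools = 2,
                                 meta_log_abundance = NULL, trait = NULL) {
  if (!regime %in% ASSEMBLY_REGIMES) {
    af_stop("usage", "unknown regime '%s'; use one of: %s", regime,
            paste(ASSEMBLY_REGIMES, collapse = ", "))
  }
  if (depth < 1000) af_stop("usage", "depth must be >= 1000")
  taxa <- tree$tip.label
  n_taxa <- length(taxa)
  counts <- with_seed(seed, {
    base <- meta_log_abundance %||% stats::rnorm(n_taxa, 0, meta_sdlog)
    tr <- trait %||% simulate_trait(tree)
    meta_p <- exp(base - max(base))
    meta_p <- meta_p / sum(meta_p)
    probs <- switch(regime,
      drift = matrix(meta_p, n_taxa, n_samples),
      heterogeneous_selection = ,
      homogeneous_selection = {
        env <- env_values %||% if (regime == "heterogeneous_selection") {
          stats::quantile(tr, seq(0.05, 0.95, length.out = n_samples), names = FALSE)
        } else {
          rep(stats::median(tr), n_samples)
        }
        if (length(env) != n_samples) af_stop("usage", "env_values must have one value per sample")
        sapply(env, function(e) {
          lp <- base - (tr - e)^2 / (2 * sel_width^2)
          p <- exp(lp - max(lp)); p / sum(p)
        })
      },
      dispersal_limitation = {
        pool_of_taxon <- sample(rep_len(seq_len(n_pools), n_taxa))
        cluster_of_sample <- rep_len(seq_len(n_pools), n_samples)
        sapply(cluster_of_sample, function(cl) {
          p <- ifelse(pool_of_taxon == cl, exp(base - max(base)), 0)
          p / sum(p)
        })
      },
      homogenizing_dispersal = {
        sapply(seq_len(n_samples), function(j) {
          local <- exp(base + stats::rnorm(n_taxa, 0, 1))
          local <- local / sum(local)
          migration * meta_p + (1 - migration) * local
        })
      }
    )
    m <- sapply(seq_len(n_samples), function(j) stats::rmultinom(1, depth, probs[, j]))
    dimnames(m) <- list(taxa, paste0(group, "_s", seq_len(n_samples)))
    m
  })
  meta <- data.frame(sample_id = colnames(counts), group = group,
                     altitude_m = altitude_m, replicate = seq_len(n_samples),
                     stringsAsFactors = FALSE)
  out <- otu_table(counts, metadata = meta, taxonomy = synthetic_taxonomy(tree))
  attr(out, "regime") <- regime
  out
}

#' Simulate an OTU table with planted co-occurrence modules
#'
#' Taxa within a module share a latent per-sample log-abundance factor;
#' the sign of each taxon's loading sets the sign of its correlations.
#' Counts are Poisson-lognormal, so module members co-vary strongly while
#' background taxa are independent noise.
#'
#' Module members ride a shared factor on the log scale; background taxa are
#' more abundant and stable (offset `background_log_offset`), which keeps the
#' table's compositional closure from leaking module signal into spurious
#' cross-module correlations.
#'
#' @param module_sizes Integer vector of module sizes.
#' @param n_background Number of unstructured background taxa.
#' @param n_samples Number of samples (one group).
#' @param loading Latent-factor loading magnitude (log scale).
#' @param frac_negative Fraction of each module's taxa loading negatively.
#' @param base_log_mean Baseline log mean count of module taxa.
#' @param background_log_offset Extra log abundance of background taxa.
#' @param noise_sd Taxon-level residual log noise.
#' @param seed Integer seed.
#' @return An [otu_table()] with attribute `modules` (module index per
#'   taxon, 0 = background) and `loading_sign`.
#' @export
simulate_module_table <- function(module_sizes = c(8, 8), n_background = 34,
                                  n_samples = 30, loading = 1.2,
                                  frac_negative = 0, base_log_mean = 3,
                                  background_log_offset = 3,
                                  noise_sd = 0.3, seed = NULL) {
  n_taxa <- sum(module_sizes) + n_background
  module <- c(rep(seq_along(module_sizes), module_sizes), rep(0L, n_background))
  sign_v <- rep(1, n_taxa)
  for (m in seq_along(module_sizes)) {
    idx <- which(module == m)
    n_neg <- floor(frac_negative * length(idx))
    if (n_neg > 0) sign_v[idx[seq_len(n_neg)]] <- -1
  }
  counts <- with_seed(seed, {
    z <- matrix(stats::rnorm(length(module_sizes) * n_samples), length(module_sizes))
    loglam <- matrix(base_log_mean, n_taxa, n_samples) +
      ifelse(module == 0, background_log_offset, 0)
    for (t in seq_len(n_taxa)) {
      if (module[t] > 0) {
        loglam[t, ] <- loglam[t, ] + sign_v[t] * loading * z[module[t], ]
      }
      loglam[t, ] <- loglam[t, ] + stats::rnorm(n_samples, 0, noise_sd)
    }
    m <- matrix(stats::rpois(n_taxa * n_samples, exp(loglam)), n_taxa, n_samples)
    dimnames(m) <- list(paste0("t", seq_len(n_taxa)), paste0("s", seq_len(n_samples)))
    m
  })
  taxonomy <- data.frame(taxon_id = rownames(counts), kingdom = "Bacteria",
                         phylum = paste0("Phylum", pmax(module, 1)),
                         genus = paste0("g_", rownames(counts)))
  meta <- data.frame(sample_id = colnames(counts), group = "G1",
                     replicate = seq_len(n_samples))
  out <- otu_table(counts, metadata = meta, taxonomy = taxonomy)
  attr(out, "modules") <- stats::setNames(module, rownames(counts))
  attr(out, "loading_sign") <- stats::setNames(sign_v, rownames(counts))
  out
}

#' Default latent blocks and manifest indicators of the function panel
#' @return Named list: block name -> manifest indicator names.
#' @export
default_panel_blocks <- function() {
  list(
    altitude = "altitude_m",
    ph = "ph",
    bacteria = c("bact_pco1", "bact_pco2"),
    fungi = c("fung_pco1", "fung_pco2"),
    EF_C = c("soil_tc", "stem_tc", "leaf_tc", "sucrase"),
    EF_N = c("soil_tn", "stem_tn", "leaf_tn", "urease"),
    EF_P = c("soil_tp", "stem_tp", "leaf_tp", "alkaline_phosphatase",
             "acid_phosphatase"),
    EF_Prod = c("plant_height", "stem_biomass", "leaf_biomass", "crown_width"),
    EMF = "emf"
  )
}

#' Default true inner path matrix for the synthetic function panel
#'
#' Lower-triangular over the block order of [default_panel_blocks()]:
#' altitude drives pH, the microbial axes and the N/P nutrient functions;
#' pH and the microbial communities drive the nutrient functions; the three
#' nutrient functions (and the fungal community, negatively) drive EMF.
#'
#' @return Square numeric matrix (to x from layout: entry \[j, k\] is the
#'   path k -> j).
#' @export
default_true_paths <- function() {
  b <- names(default_panel_blocks())
  p <- matrix(0, length(b), length(b), dimnames = list(b, b))
  p["ph", "altitude"] <- -0.4
  p["bacteria", "altitude"] <- 0.45
  p["fungi", "altitude"] <- 0.5
  p["EF_C", "ph"] <- -0.4
  p["EF_C", "bacteria"] <- 0.45
  p["EF_C", "fungi"] <- -0.3
  p["EF_N", "altitude"] <- 0.5
  p["EF_N", "ph"] <- 0.4
  p["EF_N", "fungi"] <- -0.3
  p["EF_P", "altitude"] <- 0.4
  p["EF_P", "fungi"] <- -0.35
  p["EF_Prod", "altitude"] <- 0.3
  p["EMF", "EF_C"] <- 0.45
  p["EMF", "EF_N"] <- 0.25
  p["EMF", "EF_P"] <- 0.35
  p["EMF", "fungi"] <- -0.2
  p
}

#' Simulate a function-indicator panel with known path structure
#'
#' Latent block scores are generated in topological order with unit
#' variance: each endogenous block is the linear combination of its
#' predecessors given by `true_paths` plus a Gaussian structural residual
#' sized so the latent variance stays 1 (so the entries of `true_paths` ARE
#' the standardized path coefficients). Manifest indicators equal their
#' block score plus `N(0, noise_sd)` measurement noise; with `noise_sd = 0`
#' they reproduce the linear structure exactly. The altitude score is the
#' standardized group altitude, so group means of downstream indicators are
#' ordered as the paths dictate.
#'
#' @param n_plots_per_group Replicate plots per altitude group.
#' @param true_paths Square lower-triangular path matrix over the block
#'   order (entry \[j, k\] = path from block k to block j, |path| <= 1);
#'   default [default_true_paths()].
#' @param noise_sd Manifest measurement noise standard deviation.
#' @param seed Integer seed.
#' @param blocks Block -> manifest map; default [default_panel_blocks()].
#' @param altitudes Named altitudes (m) defining the groups.
#' @return List: `functions` (a [function_matrix()] of the 17 EF
#'   indicators), `covariates` (data frame with altitude, pH, microbial
#'   axes, emf indicator), `latents` (plot x block scores), `truth`
#'   (`synth_truth`: the path matrix and blocks).
#' @export
simulate_function_panel <- function(n_plots_per_group = 5,
                                    true_paths = default_true_paths(),
                                    noise_sd = 0.1, seed = NULL,
                                    blocks = default_panel_blocks(),
                                    altitudes = c(HB1 = 896, HB2 = 1407,
                                                  HB3 = 1597, HB4 = 1805)) {
  bn <- names(blocks)
  if (is.null(dimnames(true_paths)) || !identical(rownames(true_paths), colnames(true_paths))) {
    af_stop("usage", "true_paths needs matching row/column block names")
  }
  if (!all(rownames(true_paths) %in% bn)) af_stop("usage", "true_paths blocks not in `blocks`")
  ord <- match(rownames(true_paths), bn)
  if (any(true_paths[order(ord), order(ord)][upper.tri(true_paths)] != 0)) {
    af_stop("usage", "true_paths must be acyclic (lower-triangular in block order)")
  }
  if (any(abs(true_paths) > 1)) af_stop("usage", "|true path coefficients| must be <= 1")

  n_groups <- length(altitudes)
  n <- n_groups * n_plots_per_group
  group <- rep(names(altitudes), each = n_plots_per_group)
  alt_m <- rep(unname(altitudes), each = n_plots_per_group)

  # Implied latent covariance, filled in topological order, keeps every
  # latent at unit variance; residual variance must stay positive.
  sigma <- diag(length(bn)); dimnames(sigma) <- list(bn, bn)
  resid_sd <- stats::setNames(numeric(length(bn)), bn)
  for (j in bn) {
    b <- true_paths[j, ]
    preds <- names(b)[b != 0]
    if (!length(preds)) { resid_sd[j] <- 1; next }
    expl <- as.numeric(t(b[preds]) %*% sigma[preds, preds] %*% b[preds])
    if (expl >= 1) af_stop("usage", "block '%s' over-determined: explained variance %.2f >= 1", j, expl)
    resid_sd[j] <- sqrt(1 - expl)
    for (k in bn) {
      if (k == j) next
      sigma[j, k] <- sigma[k, j] <- sum(b[preds] * sigma[preds, k])
    }
  }

  out <- with_seed(seed, {
    lat <- matrix(0, n, length(bn), dimnames = list(NULL, bn))
    for (j in bn) {
      b <- true_paths[j, ]
      preds <- names(b)[b != 0]
      struct <- if (length(preds)) as.vector(lat[, preds, drop = FALSE] %*% b[preds]) else 0
      lat[, j] <- if (j == "altitude" || identical(j, bn[1])) {
        as.vector(scale(alt_m))
      } else {
        struct + stats::rnorm(n, 0, resid_sd[j])
      }
    }
    man <- do.call(cbind, lapply(bn, function(j) {
      m <- sapply(blocks[[j]], function(nm) lat[, j] + stats::rnorm(n, 0, noise_sd))
      colnames(m) <- blocks[[j]]
      m
    }))
    list(lat = lat, man = man)
  })
  plot_ids <- paste0(group, "_p", rep(seq_len(n_plots_per_group), n_groups))
  rownames(out$lat) <- rownames(out$man) <- plot_ids

  ef_cols <- names(default_indicator_groups())
  groups_map <- default_indicator_groups()
  plot_meta <- data.frame(sample_id = plot_ids, group = group, altitude_m = alt_m)
  fm <- function_matrix(out$man[, ef_cols], indicator_groups = groups_map,
                        plot_meta = plot_meta)
  covariates <- data.frame(sample_id = plot_ids, group = group,
                           altitude_m = alt_m,
                           out$man[, setdiff(colnames(out$man), ef_cols), drop = FALSE])
  covariates$altitude_score <- out$lat[, "altitude"]
  truth <- structure(list(true_paths = true_paths, blocks = blocks,
                          resid_sd = resid_sd), class = "synth_truth")
  list(functions = fm, covariates = covariates, latents = out$lat, truth = truth)
}

#' Simulate a full study input bundle
#'
#' One shared phylogeny and regional species pool; per-group communities
#' under the requested assembly regimes; a function panel with known path
#' structure; and positive enzyme activities (exponentiated panel
#' indicators) for the stoichiometry stage. Optionally writes the bundle as
#' plain-text files (TSV/CSV/newick + truth JSON).
#'
#' @param regimes Named character vector: group -> assembly regime.
#' @param n_reps Replicates per group.
#' @param n_taxa Number of taxa (tree tips).
#' @param depth Sequencing depth per sample.
#' @param seed Master seed; stage seeds are derived via [substream()].
#' @param altitudes Named altitudes (m), same names as `regimes`.
#' @param noise_sd Manifest noise of the function panel.
#' @param dir Optional output directory for the file bundle.
#' @return List: `otu`, `tree`, `functions`, `covariates`, `enzymes`,
#'   `truth`, and `paths` (when written).
#' @export
simulate_study_bundle <- function(regimes = c(HB1 = "drift", HB2 = "drift",
                                              HB3 = "drift",
                                              HB4 = "heterogeneous_selection"),
                                  n_reps = 5, n_taxa = 300, depth = 10000,
                                  seed = 42,
                                  altitudes = c(HB1 = 896, HB2 = 1407,
                                                HB3 = 1597, HB4 = 1805),
                                  noise_sd = 0.1, dir = NULL) {
  if (!all(names(regimes) %in% names(altitudes))) {
    af_stop("usage", "regimes and altitudes must share group names")
  }
  tree <- simulate_tree(n_taxa, seed = substream(seed, "tree"))
  base <- with_seed(substream(seed, "metacommunity"), stats::rnorm(n_taxa, 0, 2))
  trait <- simulate_trait(tree, seed = substream(seed, "trait"))
  tabs <- lapply(names(regimes), function(g) {
    simulate_communities(tree, regimes[[g]], n_samples = n_reps, depth = depth,
                         seed = substream(seed, paste0("community_", g)),
                         group = g, altitude_m = altitudes[[g]],
                         meta_log_abundance = base, trait = trait)
  })
  counts <- do.call(cbind, lapply(tabs, function(t) t$counts))
  meta <- do.call(rbind, lapply(tabs, function(t) t$metadata))
  otu <- otu_table(counts, metadata = meta, taxonomy = tabs[[1]]$taxonomy)

  panel <- simulate_function_panel(n_plots_per_group = n_reps,
                                   noise_sd = noise_sd,
                                   seed = substream(seed, "panel"),
                                   altitudes = altitudes)
  # the same physical plots yield the communities and the function panel
  stopifnot(identical(panel$functions$plot_meta$group, meta$group))
  plot_ids <- meta$sample_id
  rownames(panel$functions$values) <- plot_ids
  panel$functions$plot_meta$sample_id <- plot_ids
  rownames(panel$functions$plot_meta) <- plot_ids
  panel$covariates$sample_id <- plot_ids
  rownames(panel$covariates) <- plot_ids
  rownames(panel$latents) <- plot_ids
  vals <- panel$functions$values
  enzymes <- data.frame(
    sample_id = rownames(vals),
    group = panel$functions$plot_meta$group,
    ces = exp(vals[, "sucrase"]),
    nes = exp(vals[, "urease"]),
    pes = exp(vals[, "alkaline_phosphatase"]) + exp(vals[, "acid_phosphatase"])
  )
  truth <- structure(list(regimes = regimes, true_paths = panel$truth$true_paths,
                          blocks = panel$truth$blocks, seed = seed),
                     class = "synth_truth")
  out <- list(otu = otu, tree = tree, functions = panel$functions,
              covariates = panel$covariates, enzymes = enzymes, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- write_otu_table(otu, dir)
    ape::write.tree(tree, file.path(dir, "tree.nwk"))
    fp <- write_function_matrix(panel$functions, dir)
    utils::write.csv(panel$covariates, file.path(dir, "covariates.csv"), row.names = FALSE)
    utils::write.csv(enzymes, file.path(dir, "enzymes.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(regimes = as.list(regimes),
           true_paths = as.data.frame(panel$truth$true_paths), seed = seed),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
    out$paths <- c(paths, tree = file.path(dir, "tree.nwk"), fp,
                   covariates = file.path(dir, "covariates.csv"),
                   enzymes = file.path(dir, "enzymes.csv"),
                   truth = file.path(dir, "truth.json"))
  }
  out
}
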