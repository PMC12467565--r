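# End-to-end orchestration: run every analysis stage on a validated input
# bundle and emit the study's result surfaces as machine-readable tables.

#' Run the full study workflow
#'
#' Executes, in dependency order: relative abundance and group means; alpha
#' diversity with ANOVA letters; Bray-Curtis, PCoA and ANOSIM; the
#' co-occurrence network and its topology report; assembly-process
#' partitioning (needs the tree); enzyme stoichiometry (needs enzyme
#' activities); EF/EMF indices with ANOVA letters and EMF correlations;
#' PLS-PM (needs covariates); and RDA of the community on the function
#' indices. Optional stages with missing inputs are marked `"skipped"`
#' rather than failing the run.
#'
#' @param inputs List with `otu` (an [otu_table()], mandatory) and
#'   optionally `tree` ([ape::phylo]), `functions` ([function_matrix()]),
#'   `enzymes` (data frame with `ces`, `nes`, `pes`), `covariates` (data
#'   frame with `ph` and microbial axes for PLS-PM).
#' @param config A [run_config()].
#' @return Object of class `study_report`: a named list of per-stage
#'   results, each stage a list or `"skipped"`, plus the `config` echo.
#' @export
run_study <- function(inputs, config = run_config()) {
  if (is.null(inputs$otu) || !inherits(inputs$otu, "otu_table")) {
    af_stop("usage", "inputs$otu (an otu_table) is mandatory")
  }
  otu <- inputs$otu
  groups <- sample_groups(otu)
  check_group_sizes(groups)
  seed <- config$seed
  report <- list(config = unclass(config))

  ab <- aggregate_relative_abundance(otu, config$abundance_rank)
  report$abundance <- list(rank = config$abundance_rank,
                           proportions = ab$proportions,
                           group_means = group_mean_abundance(ab))

  alpha <- alpha_diversity(otu)
  letters <- lapply(c("chao1", "ace", "shannon", "simpson"), function(idx) {
    anova_lsd(alpha[[idx]], groups)
  })
  names(letters) <- c("chao1", "ace", "shannon", "simpson")
  report$alpha <- list(indices = alpha, anova = letters)

  d <- bray_curtis(otu)
  ord <- pcoa(d, n_axes = 2)
  an <- anosim_test(d, groups, n_permutations = config$n_permutations,
                    seed = substream(seed, "anosim"))
  report$beta <- list(bray_curtis = d, pcoa = ord,
                      anosim = an[c("R", "p", "n_permutations")])

  report$network <- tryCatch({
    net <- build_conetwork(otu, rank = config$network_rank,
                           r_cut = config$r_cut, p_cut = config$p_cut,
                           min_prevalence = config$min_prevalence)
    list(network = net,
         topology = topology(net, seed = substream(seed, "modularity")))
  }, altifun_usage_error = function(e) "skipped")

  report$assembly <- if (is.null(inputs$tree)) {
    "skipped"
  } else {
    bnti <- beta_nti(otu, inputs$tree, n_nulls = config$n_nulls,
                     seed = substream(seed, "bnti"))
    rc <- raup_crick_bray(otu, n_nulls = config$n_nulls,
                          seed = substream(seed, "rc"))
    partition_processes(bnti, rc, groups = groups,
                        bnti_cut = config$bnti_cut, rc_cut = config$rc_cut)
  }

  report$stoichiometry <- if (is.null(inputs$enzymes)) {
    "skipped"
  } else {
    ez <- inputs$enzymes
    conv <- if (config$va_convention == "both") "both" else config$va_convention
    vec <- enzyme_vector(ez$ces, ez$nes, ez$pes, convention = conv)
    vec$sample_id <- ez$sample_id %||% rownames(ez)
    vec
  }

  report$multifunctionality <- if (is.null(inputs$functions)) {
    "skipped"
  } else {
    fm <- inputs$functions
    std <- minmax_standardize(fm)
    emf <- emf_index(std)
    fgroups <- fm$plot_meta$group %||% groups
    efa <- lapply(colnames(emf$ef), function(g) anova_lsd(emf$ef[, g], fgroups))
    names(efa) <- colnames(emf$ef)
    list(standardized = std, emf = emf$emf, ef = emf$ef,
         correlations = emf$correlations,
         anova = c(efa, list(EMF = anova_lsd(emf$emf, fgroups))))
  }

  report$plspm <- if (is.null(inputs$functions) || is.null(inputs$covariates)) {
    "skipped"
  } else {
    std <- minmax_standardize(inputs$functions)
    emf <- emf_index(std)
    dat <- data.frame(inputs$covariates,
                      EF_C = emf$ef[, "EF-C"], EF_N = emf$ef[, "EF-N"],
                      EF_P = emf$ef[, "EF-P"], EMF = emf$emf,
                      check.names = FALSE)
    blocks <- list(altitude = "altitude_m", ph = "ph",
                   bacteria = grep("^bact_", names(dat), value = TRUE),
                   fungi = grep("^fung_", names(dat), value = TRUE),
                   EF_C = "EF_C", EF_N = "EF_N", EF_P = "EF_P", EMF = "EMF")
    blocks <- blocks[vapply(blocks, length, 1L) > 0]
    pm <- default_true_paths()
    pm <- (pm != 0) * 1
    pm <- pm[names(blocks), names(blocks)]
    plspm_fit(dat, blocks, pm, n_bootstrap = config$n_bootstrap,
              seed = substream(seed, "plspm"))
  }

  report$rda <- if (is.null(inputs$functions)) {
    "skipped"
  } else {
    std <- minmax_standardize(inputs$functions)
    emf <- emf_index(std)
    X <- data.frame(EF_C = emf$ef[, "EF-C"], EF_N = emf$ef[, "EF-N"],
                    EF_P = emf$ef[, "EF-P"], EMF = emf$emf)
    if (!is.null(inputs$covariates$ph)) X$pH <- inputs$covariates$ph
    Y <- t(ab$proportions)
    if (nrow(Y) == nrow(X)) rda_fit(Y, X) else "skipped"
  }

  structure(report, class = "study_report")
}

#' Write a study report as CSV/JSON tables
#'
#' @param report A `study_report` from [run_study()].
#' @param dir Output directory.
#' @return Invisibly, the vector of files written.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  put_csv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    written <<- c(written, p)
  }
  jsonlite::write_json(report$config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  written <- c(written, file.path(dir, "config.json"))

  gm <- report$abundance$group_means
  put_csv(data.frame(taxon = rownames(gm), round(100 * gm, 4), check.names = FALSE),
          "abundance_group_means_pct.csv")
  put_csv(report$alpha$indices, "alpha_diversity.csv")
  alpha_letters <- do.call(rbind, lapply(names(report$alpha$anova), function(i) {
    m <- report$alpha$anova[[i]]$means
    data.frame(index = i, m)
  }))
  put_csv(alpha_letters, "alpha_anova_letters.csv")
  ord <- report$beta$pcoa
  put_csv(data.frame(sample_id = rownames(ord$coordinates), ord$coordinates),
          "pcoa_coordinates.csv")
  jsonlite::write_json(c(report$beta$anosim, seed = report$config$seed),
                       file.path(dir, "anosim.json"), auto_unbox = TRUE, digits = NA)
  written <- c(written, file.path(dir, "anosim.json"))
  if (!identical(report$network, "skipped")) {
    put_csv(as.data.frame(report$network$topology), "network_topology.csv")
  }
  if (!identical(report$assembly, "skipped")) {
    fr <- report$assembly$fractions
    put_csv(data.frame(group = rownames(fr), fr,
                       dominant = report$assembly$dominant[rownames(fr)]),
            "assembly_fractions.csv")
  }
  if (!identical(report$stoichiometry, "skipped")) {
    put_csv(report$stoichiometry, "enzyme_stoichiometry.csv")
  }
  if (!identical(report$multifunctionality, "skipped")) {
    mf <- report$multifunctionality
    put_csv(data.frame(sample_id = names(mf$emf), mf$ef, EMF = mf$emf,
                       check.names = FALSE), "ef_emf.csv")
    mf_letters <- do.call(rbind, lapply(names(mf$anova), function(i) {
      data.frame(index = i, mf$anova[[i]]$means)
    }))
    put_csv(mf_letters, "ef_emf_anova_letters.csv")
  }
  if (!identical(report$plspm, "skipped")) {
    put_csv(report$plspm$paths, "plspm_paths.csv")
  }
  if (!identical(report$rda, "skipped")) {
    r <- report$rda
    put_csv(data.frame(axis = names(r$prop_per_axis),
                       eigenvalue = r$constrained_eig,
                       prop_explained = r$prop_per_axis,
                       total_explained = r$prop_explained),
            "rda_summary.csv")
  }
  invisible(written)
}
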