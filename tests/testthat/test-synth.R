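test_that("simulate_tree yields seeded, ultrametric pure-birth trees", {
  expect_error(simulate_tree(2), class = "altifun_usage_error")
  tr3 <- simulate_tree(3, seed = 1)
  expect_equal(ape::Ntip(tr3), 3)
  expect_equal(tr3$Nnode, 2)
  expect_identical(ape::write.tree(simulate_tree(20, seed = 9)),
                   ape::write.tree(simulate_tree(20, seed = 9)))
  tr <- simulate_tree(100, seed = 2)
  depths <- ape::node.depth.edgelength(tr)[seq_len(100)]
  expect_lt(diff(range(depths)), 1e-9)
  expect_true(all(tr$edge.length > 0))
})

test_that("simulate_communities is deterministic and conserves depth", {
  tr <- simulate_tree(30, seed = 3)
  for (regime in c("drift", "heterogeneous_selection", "homogeneous_selection",
                   "dispersal_limitation", "homogenizing_dispersal")) {
    a <- simulate_communities(tr, regime, n_samples = 4, depth = 2000, seed = 11)
    b <- simulate_communities(tr, regime, n_samples = 4, depth = 2000, seed = 11)
    expect_identical(a$counts, b$counts)
    expect_true(all(colSums(a$counts) == 2000))
    expect_s3_class(a, "otu_table")
  }
  expect_error(simulate_communities(tr, "teleportation", 4, 2000),
               class = "altifun_usage_error")
  expect_error(simulate_communities(tr, "drift", 4, depth = 10),
               class = "altifun_usage_error")
})

test_that("divergent selection produces more dissimilar communities than homogenizing dispersal", {
  tr <- simulate_tree(40, seed = 4)
  mean_bray <- function(regime, s) {
    tab <- simulate_communities(tr, regime, n_samples = 2, depth = 2000, seed = s)
    bray_curtis(tab)[1, 2]
  }
  het <- vapply(1:20, function(s) mean_bray("heterogeneous_selection", s), numeric(1))
  hom <- vapply(1:20, function(s) mean_bray("homogenizing_dispersal", s), numeric(1))
  expect_gt(mean(het), mean(hom))
})

test_that("function panel reproduces the linear structure exactly at zero noise", {
  panel <- simulate_function_panel(n_plots_per_group = 5, noise_sd = 0, seed = 6)
  lat <- panel$latents
  blocks <- default_panel_blocks()
  for (b in names(blocks)) {
    for (m in blocks[[b]]) {
      col <- if (m %in% colnames(panel$functions$values)) {
        panel$functions$values[, m]
      } else if (m == "altitude_m") {
        panel$covariates$altitude_score
      } else {
        panel$covariates[[m]]
      }
      expect_equal(unname(col), unname(lat[, b]), tolerance = 1e-12)
    }
  }
  again <- simulate_function_panel(n_plots_per_group = 5, noise_sd = 0, seed = 6)
  expect_identical(panel$functions$values, again$functions$values)
})

test_that("panel generation rejects cyclic or overloaded path matrices", {
  tp <- default_true_paths()
  tp["altitude", "EMF"] <- 0.5  # upper-triangular entry = cycle
  expect_error(simulate_function_panel(true_paths = tp, seed = 1),
               class = "altifun_usage_error")
  tp2 <- default_true_paths()
  tp2["EMF", c("EF_C", "EF_N", "EF_P")] <- 0.9
  expect_error(simulate_function_panel(true_paths = tp2, seed = 1),
               class = "altifun_usage_error")
})

test_that("fitted PLS paths recover a planted altitude effect", {
  tp <- default_true_paths()
  tp["EF_N", "altitude"] <- 0.6
  ests <- vapply(1:10, function(s) {
    panel <- simulate_function_panel(n_plots_per_group = 50, true_paths = tp,
                                     noise_sd = 0.3, seed = 200 + s)
    dat <- data.frame(panel$covariates, panel$functions$values)
    blocks <- default_panel_blocks()
    blocks$EMF <- "emf"
    fit <- plspm_fit(dat, blocks, (tp != 0) * 1)
    fit$path_matrix["EF_N", "altitude"]
  }, numeric(1))
  expect_lt(abs(mean(ests) - 0.6), 0.1)
})

test_that("study bundle writes a complete, re-readable input set", {
  dir <- withr::local_tempdir()
  bundle <- simulate_study_bundle(seed = 5, n_taxa = 40, depth = 1500, dir = dir)
  expect_true(all(file.exists(bundle$paths)))
  back <- read_otu_table(bundle$paths["counts"], bundle$paths["metadata"],
                         bundle$paths["taxonomy"])
  expect_identical(back$counts, bundle$otu$counts)
  truth <- jsonlite::read_json(bundle$paths[["truth"]])
  expect_equal(unlist(truth$regimes), unlist(as.list(bundle$truth$regimes)))
  expect_true(all(bundle$enzymes$ces > 0))
})
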