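toy_tree <- function() read_newick(text = "(A:1,(B:1,C:1):1);")

test_that("betaMNTD matches hand computation on a 3-tip tree", {
  cts <- matrix(c(5, 0, 0,
                  0, 7, 0), nrow = 3,
                dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  tab <- make_tab(cts)
  bm <- beta_mntd(tab, toy_tree())
  expect_equal(bm["s1", "s2"], 3)  # d(A,B) = 3 averaged over both directions
  expect_equal(unname(diag(bm)), c(0, 0))

  ident <- matrix(c(3, 4, 0, 3, 4, 0), nrow = 3,
                  dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  expect_equal(beta_mntd(make_tab(ident), toy_tree())["s1", "s2"], 0)

  perm <- cts[c(3, 1, 2), ]
  expect_equal(beta_mntd(make_tab(perm), toy_tree()), bm)

  bad <- matrix(c(1, 1), 2, 1, dimnames = list(c("A", "Z"), "s1"))
  expect_error(beta_mntd(make_tab(bad), toy_tree()), class = "altifun_input_error")
})

test_that("betaMNTD agrees with picante on random communities", {
  skip_if_not_installed("picante")
  tr <- simulate_tree(40, seed = 5)
  for (s in 1:3) {
    tab <- simulate_communities(tr, "drift", n_samples = 5, depth = 2000, seed = s)
    mine <- beta_mntd(tab, tr)
    ref <- as.matrix(picante::comdistnt(t(tab$counts), stats::cophenetic(tr),
                                        abundance.weighted = TRUE))
    expect_equal(mine, ref[rownames(mine), colnames(mine)], tolerance = 1e-10)
    unw <- beta_mntd(tab, tr, weighted = FALSE)
    refu <- as.matrix(picante::comdistnt(t(tab$counts), stats::cophenetic(tr),
                                         abundance.weighted = FALSE))
    expect_equal(unw, refu[rownames(unw), colnames(unw)], tolerance = 1e-10)
  }
})

test_that("betaNTI flags degenerate trees and is scale- and seed-stable", {
  # star tree: all pairwise tip distances equal -> every null equals obs
  star <- read_newick(text = "(A:1,B:1,C:1,D:1);")
  cts <- matrix(c(5, 3, 0, 0,
                  0, 0, 4, 6), nrow = 4,
                dimnames = list(LETTERS[1:4], c("s1", "s2")))
  expect_warning(z <- beta_nti(make_tab(cts), star, n_nulls = 99, seed = 1),
                 "zero null variance")
  expect_true(is.na(z["s1", "s2"]))

  tr <- simulate_tree(16, seed = 6)
  tab <- simulate_communities(tr, "drift", n_samples = 4, depth = 1000, seed = 7)
  z1 <- suppressWarnings(beta_nti(tab, tr, n_nulls = 199, seed = 8))
  tr2 <- tr
  tr2$edge.length <- tr2$edge.length * 7.3
  z2 <- suppressWarnings(beta_nti(tab, tr2, n_nulls = 199, seed = 8))
  # obs and null betaMNTD scale together, so the z-score is scale-invariant
  expect_equal(as.vector(z1), as.vector(z2), tolerance = 1e-9)
  expect_equal(attr(z2, "obs"), attr(z1, "obs") * 7.3, tolerance = 1e-9)
  expect_identical(suppressWarnings(beta_nti(tab, tr, n_nulls = 199, seed = 8)), z1)
})

test_that("drift communities are betaNTI-calibrated and selection is recovered", {
  tr <- simulate_tree(64, seed = 10)
  fracs <- vapply(1:5, function(s) {
    tab <- simulate_communities(tr, "drift", n_samples = 5, depth = 10000, seed = s)
    z <- suppressWarnings(beta_nti(tab, tr, n_nulls = 199, seed = 100 + s))
    mean(abs(z[lower.tri(z)]) > 2, na.rm = TRUE)
  }, numeric(1))
  expect_lte(mean(fracs), 0.10)

  tr300 <- simulate_tree(300, seed = 11)
  med <- vapply(1:5, function(s) {
    tab <- simulate_communities(tr300, "heterogeneous_selection", n_samples = 5,
                                depth = 10000, seed = s)
    z <- suppressWarnings(beta_nti(tab, tr300, n_nulls = 199, seed = 300 + s))
    median(z[lower.tri(z)], na.rm = TRUE)
  }, numeric(1))
  expect_gte(sum(med > 2), 4)
  expect_gt(median(med), 2)
})

test_that("Raup-Crick is bounded, detects identity, and recovers dispersal limitation", {
  tr <- simulate_tree(40, seed = 12)
  tab <- simulate_communities(tr, "drift", n_samples = 4, depth = 2000, seed = 13)
  rc <- raup_crick_bray(tab, n_nulls = 199, seed = 14)
  off <- rc[lower.tri(rc)]
  expect_true(all(off >= -1 & off <= 1))

  ident <- tab$counts[, c(1, 1, 2)]
  colnames(ident) <- c("s1", "s2", "s3")
  rci <- raup_crick_bray(make_tab(ident), n_nulls = 199, seed = 15)
  expect_lte(rci["s1", "s2"], -0.99)

  fracs <- vapply(1:5, function(s) {
    tabd <- simulate_communities(tr, "dispersal_limitation", n_samples = 6,
                                 depth = 2000, seed = s)
    r <- raup_crick_bray(tabd, n_nulls = 199, seed = 400 + s)
    mean(r[lower.tri(r)] > 0.95)
  }, numeric(1))
  expect_gte(mean(fracs >= 0.5), 0.8)
})

test_that("process partition is exhaustive, normalized, and threshold-driven", {
  n <- 6
  ids <- paste0("s", 1:n)
  m3 <- matrix(3, n, n, dimnames = list(ids, ids)); diag(m3) <- NA
  m0 <- matrix(0, n, n, dimnames = list(ids, ids)); diag(m0) <- NA
  res <- partition_processes(m3, m0)
  expect_equal(res$fractions$heterogeneous_selection, 1)
  expect_equal(unname(res$dominant), "deterministic")

  res0 <- partition_processes(m0, m0)
  expect_equal(res0$fractions$drift_and_others, 1)
  expect_equal(unname(res0$dominant), "stochastic")

  mixed_rc <- m0; mixed_rc[] <- 0.99; diag(mixed_rc) <- NA
  res_disp <- partition_processes(m0, mixed_rc)
  expect_equal(res_disp$fractions$dispersal_limitation, 1)
  res_wide <- partition_processes(m0, mixed_rc, rc_cut = 0.995)
  expect_equal(res_wide$fractions$drift_and_others, 1)

  groups <- rep(c("g1", "g2"), each = 3)
  resg <- partition_processes(m3, m0, groups = groups)
  expect_equal(rowSums(resg$fractions), c(g1 = 1, g2 = 1), tolerance = 1e-9)

  all_na <- m0; all_na[] <- NA
  expect_error(partition_processes(all_na, all_na), class = "altifun_degenerate_error")
})

test_that("the full assembly pipeline is bit-reproducible under a fixed seed", {
  bundle <- simulate_study_bundle(seed = 3, n_taxa = 60, depth = 1500,
                                  regimes = c(A = "drift", B = "drift"),
                                  altitudes = c(A = 900, B = 1800), n_reps = 3)
  run <- function() {
    z <- suppressWarnings(beta_nti(bundle$otu, bundle$tree, n_nulls = 99, seed = 17))
    r <- raup_crick_bray(bundle$otu, n_nulls = 99, seed = 18)
    partition_processes(z, r, groups = bundle$otu$metadata$group)
  }
  a <- run(); b <- run()
  expect_identical(a$fractions, b$fractions)
  expect_identical(a$bnti, b$bnti)
  expect_identical(a$rc, b$rc)
})
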