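test_that("relative abundance aggregation sums to one and averages by group", {
  tax <- data.frame(taxon_id = paste0("t", 1:4),
                    phylum = c("A", "A", "B", "B"))
  cts <- matrix(c(10, 10, 20, 60,
                  5, 5, 45, 45), ncol = 2,
                dimnames = list(paste0("t", 1:4), c("s1", "s2")))
  tab <- make_tab(cts, groups = c("G1", "G1"), taxonomy = tax)
  ab <- aggregate_relative_abundance(tab, "phylum")
  expect_equal(colSums(ab$proportions), c(s1 = 1, s2 = 1))
  expect_equal(ab$proportions["A", "s1"], 0.2)
  gm <- group_mean_abundance(ab)
  expect_equal(gm["A", "G1"], mean(c(0.2, 0.1)))

  single <- make_tab(matrix(c(3, 8), 1, 2))
  expect_equal(unname(aggregate_relative_abundance(single, "otu")$proportions[1, ]),
               c(1, 1))
  zero <- matrix(c(1, 0), 1, 2, dimnames = list("t1", c("s1", "s2")))
  expect_error(aggregate_relative_abundance(make_tab(zero), "otu"),
               class = "altifun_degenerate_error")

  tab10 <- rand_tab(10, 4, seed = 8)
  expect_equal(unname(colSums(aggregate_relative_abundance(tab10, "otu")$proportions)),
               rep(1, 4), tolerance = 1e-12)
})

test_that("alpha diversity matches closed forms and hand computation", {
  uni <- make_tab(matrix(c(5, 5, 5, 5), 4, 1))
  a <- alpha_diversity(uni)
  expect_equal(a$shannon, log(4), tolerance = 1e-12)
  expect_equal(a$simpson, 0.75, tolerance = 1e-12)
  expect_equal(a$chao1, 4)  # no singletons -> S_obs

  mixed <- make_tab(matrix(c(5, 3, 1, 1), 4, 1))
  b <- alpha_diversity(mixed)
  p <- c(5, 3, 1, 1) / 10
  expect_equal(b$shannon, -sum(p * log(p)), tolerance = 1e-12)
  expect_equal(b$chao1, 4 + 2 * 1 / (2 * (0 + 1)), tolerance = 1e-12)
  expect_equal(b$ace, 6.111111, tolerance = 1e-6)  # hand-evaluated ACE, cutoff 10

  expect_error(alpha_diversity(matrix(c(0.5, 1.5), 2, 1, dimnames = list(c("a", "b"), "s"))),
               class = "altifun_usage_error")
  ok <- alpha_diversity(matrix(c(0.5, 1.5), 2, 1, dimnames = list(c("a", "b"), "s")),
                        indices = c("shannon", "simpson"))
  expect_equal(ok$shannon, -sum(c(0.25, 0.75) * log(c(0.25, 0.75))))
})

test_that("Shannon is maximal iff uniform and ignores empty taxa", {
  set.seed(21)
  for (i in 1:10) {
    cts <- matrix(rpois(8, 20) + 1, 8, 1, dimnames = list(paste0("t", 1:8), "s"))
    sh <- alpha_diversity(cts, indices = "shannon")$shannon
    expect_lte(sh, log(8) + 1e-12)
    if (length(unique(cts)) > 1) expect_lt(sh, log(8))
    with_zero <- rbind(cts, t9 = 0)
    expect_equal(alpha_diversity(with_zero, indices = "shannon")$shannon, sh)
  }
})

test_that("Bray-Curtis matches hand computation and its invariants", {
  m <- matrix(c(1, 2, 3, 2, 2, 0), 3, 2,
              dimnames = list(paste0("t", 1:3), c("s1", "s2")))
  expect_equal(bray_curtis(m)["s1", "s2"], (1 + 0 + 3) / (3 + 4 + 3))
  ident <- cbind(s1 = c(1, 2, 3), s2 = c(1, 2, 3))
  rownames(ident) <- paste0("t", 1:3)
  expect_equal(bray_curtis(ident)["s1", "s2"], 0)
  disjoint <- cbind(s1 = c(5, 0), s2 = c(0, 7))
  rownames(disjoint) <- c("a", "b")
  expect_equal(bray_curtis(disjoint)["s1", "s2"], 1)

  set.seed(5)
  r <- matrix(rpois(40, 10), 10, 4, dimnames = list(paste0("t", 1:10), paste0("s", 1:4)))
  d <- bray_curtis(r)
  expect_true(isSymmetric(d))
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(unname(diag(d)), rep(0, 4))
  shuffled <- r[sample(10), ]
  expect_equal(bray_curtis(shuffled), d)

  allzero <- cbind(s1 = c(0, 0), s2 = c(1, 2))
  rownames(allzero) <- c("a", "b")
  expect_error(bray_curtis(allzero), class = "altifun_degenerate_error")
})

test_that("PCoA embeds Euclidean configurations exactly", {
  x <- c(0, 1, 3, 7)
  d <- as.matrix(dist(x))
  ord <- pcoa(d, n_axes = 3)
  ax1 <- ord$coordinates[, 1]
  expect_equal(abs(cor(ax1, x)), 1, tolerance = 1e-10)
  expect_equal(max(abs(as.matrix(dist(ax1)) - d)), 0, tolerance = 1e-8)

  two <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  o2 <- pcoa(two)
  expect_equal(ncol(o2$coordinates), 1)
  expect_equal(unname(o2$prop_explained), 1)

  set.seed(14)
  pts <- matrix(rnorm(18), 6, 3)
  de <- as.matrix(dist(pts))
  full <- pcoa(de, n_axes = 5)
  rec <- as.matrix(dist(full$coordinates))
  expect_equal(max(abs(rec - de)), 0, tolerance = 1e-8)
  expect_true(all(diff(full$prop_explained) <= 1e-12))

  asym <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(pcoa(asym), class = "altifun_usage_error")
})

test_that("ANOSIM matches vegan, attains R = 1 at perfect separation, and is seeded", {
  set.seed(30)
  m <- matrix(rpois(15 * 12, 25), 15, 12,
              dimnames = list(paste0("t", 1:15), paste0("s", 1:12)))
  g <- rep(c("a", "b", "c"), each = 4)
  d <- bray_curtis(m)
  mine <- anosim_test(d, g, n_permutations = 999, seed = 3)
  set.seed(3)
  ref <- vegan::anosim(as.dist(d), g, permutations = 999)
  expect_equal(mine$R, unname(ref$statistic), tolerance = 1e-12)

  sep <- matrix(0, 6, 6, dimnames = list(paste0("s", 1:6), paste0("s", 1:6)))
  sep[1:3, 4:6] <- 0.9
  sep[4:6, 1:3] <- 0.9
  sep[1:3, 1:3][lower.tri(diag(3))] <- 0.1
  sep[4:6, 4:6][lower.tri(diag(3))] <- 0.1
  sep <- pmax(sep, t(sep))
  res <- anosim_test(sep, rep(c("x", "y"), each = 3), 99, seed = 1)
  expect_equal(res$R, 1)

  expect_identical(anosim_test(d, g, 199, seed = 5)$p,
                   anosim_test(d, g, 199, seed = 5)$p)
  expect_error(anosim_test(d, c(rep("a", 11), "b"), 199),
               class = "altifun_usage_error")
  expect_true(mine$R >= -1 && mine$R <= 1 && mine$p > 0 && mine$p <= 1)
})
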