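test_that("one-way ANOVA reduces to the squared t statistic for two groups", {
  set.seed(2)
  x <- rnorm(12)
  g <- rep(c("a", "b"), each = 6)
  fit <- anova_lsd(x, g)
  tt <- t.test(x ~ g, var.equal = TRUE)
  expect_equal(fit$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(fit$p, tt$p.value, tolerance = 1e-10)
})

test_that("LSD letters separate clearly different groups and respect the p matrix", {
  set.seed(3)
  x <- c(rnorm(5, 1, 0.05), rnorm(5, 1, 0.05), rnorm(5, 10, 0.05))
  g <- rep(c("g1", "g2", "g3"), each = 5)
  fit <- anova_lsd(x, g)
  lt <- fit$means$letters
  names(lt) <- fit$means$group
  expect_identical(unname(lt["g3"] == lt["g1"]), FALSE)
  expect_identical(lt[["g1"]], lt[["g2"]])

  # letter-sharing must equal non-significance closed under greedy insertion
  set.seed(8)
  for (i in 1:10) {
    y <- rnorm(20, mean = rep(sample(1:3, 4, replace = TRUE), each = 5))
    gr <- rep(paste0("h", 1:4), each = 5)
    f <- anova_lsd(y, gr)
    share <- outer(f$means$letters, f$means$letters,
                   Vectorize(function(a, b) any(strsplit(a, "")[[1]] %in% strsplit(b, "")[[1]])))
    dimnames(share) <- list(f$means$group, f$means$group)
    for (a in f$means$group) for (b in f$means$group) {
      if (a == b) next
      if (share[a, b]) expect_gt(f$pairwise_p[a, b], f$alpha)
      if (f$pairwise_p[a, b] > f$alpha) expect_true(share[a, b])
    }
  }

  expect_error(suppressWarnings(anova_lsd(rep(1, 10), rep(c("a", "b"), 5))),
               class = "altifun_degenerate_error")
  expect_error(anova_lsd(rnorm(3), c("a", "a", "b")), class = "altifun_usage_error")
})

test_that("RDA recovers perfect constraints and rejects collinear predictors", {
  set.seed(5)
  X <- data.frame(x1 = rnorm(30), x2 = rnorm(30))
  B <- matrix(rnorm(2 * 6), 2, 6)
  Y <- as.matrix(X) %*% B  # exactly linear, no noise
  fit <- suppressWarnings(rda_fit(Y, X, hellinger = FALSE))
  expect_equal(fit$prop_explained, 1, tolerance = 1e-9)

  # Y variation orthogonal to X by construction
  set.seed(6)
  X2 <- data.frame(x = rnorm(100))
  Y2 <- apply(matrix(rnorm(100 * 5), 100, 5), 2,
              function(v) resid(lm(v ~ X2$x)))
  fit2 <- rda_fit(Y2, X2, hellinger = FALSE)
  expect_lt(fit2$prop_explained, 0.05)

  # single predictor: constrained axis equals the fitted regression direction
  set.seed(7)
  x <- rnorm(40)
  Y3 <- outer(x, c(1, -2, 0.5)) + matrix(rnorm(120, sd = 0.3), 40, 3)
  fit3 <- rda_fit(Y3, data.frame(x = x), hellinger = FALSE)
  fitted_dir <- coef(lm(Y3 ~ x))["x", ]
  cosine <- abs(sum(fit3$species_scores[, 1] * fitted_dir)) /
    sqrt(sum(fit3$species_scores[, 1]^2) * sum(fitted_dir^2))
  expect_gt(cosine, 0.999)

  Xbad <- data.frame(a = x, b = 2 * x)
  expect_error(rda_fit(Y3, Xbad), class = "altifun_usage_error")
})

test_that("RDA explained proportion is monotone in added predictors", {
  set.seed(9)
  Y <- matrix(rpois(40 * 8, 20), 40, 8)
  X <- data.frame(a = rnorm(40), b = rnorm(40), c = rnorm(40))
  p1 <- rda_fit(Y, X[, "a", drop = FALSE])$prop_explained
  p2 <- rda_fit(Y, X[, c("a", "b")])$prop_explained
  p3 <- rda_fit(Y, X)$prop_explained
  expect_true(p1 <= p2 + 1e-12 && p2 <= p3 + 1e-12)
})

test_that("PLS-PM solves a noiseless chain exactly and ignores row order", {
  blocks <- list(altitude = "a", EF_N = "b", EMF = "c")
  pm <- matrix(0, 3, 3, dimnames = list(names(blocks), names(blocks)))
  pm["EF_N", "altitude"] <- 1
  pm["EMF", "EF_N"] <- 1
  set.seed(11)
  a <- rnorm(40)
  dat <- data.frame(a = a, b = 2 * a, c = -0.5 * a)
  fit <- plspm_fit(dat, blocks, pm)
  expect_equal(fit$path_matrix["EF_N", "altitude"], 1, tolerance = 1e-6)
  expect_equal(abs(fit$path_matrix["EMF", "EF_N"]), 1, tolerance = 1e-6)

  panel <- simulate_function_panel(n_plots_per_group = 10, noise_sd = 0.2, seed = 12)
  dat2 <- data.frame(panel$covariates, panel$functions$values)
  blocks2 <- default_panel_blocks(); blocks2$EMF <- "emf"
  pm2 <- (default_true_paths() != 0) * 1
  f1 <- plspm_fit(dat2, blocks2, pm2)
  f2 <- plspm_fit(dat2[sample(nrow(dat2)), ], blocks2, pm2)
  expect_equal(f1$path_matrix, f2$path_matrix, tolerance = 1e-8)
  expect_true(all(abs(colMeans(f1$scores)) < 1e-10))
  expect_equal(unname(apply(f1$scores, 2, sd)), rep(1, ncol(f1$scores)))

  pm_bad <- pm; pm_bad["altitude", "EMF"] <- 1
  expect_error(plspm_fit(dat, blocks, pm_bad), class = "altifun_usage_error")
})

test_that("PLS-PM path signs match partial correlations under strong effects", {
  panel <- simulate_function_panel(n_plots_per_group = 50, noise_sd = 0.1, seed = 13)
  dat <- data.frame(panel$covariates, panel$functions$values)
  blocks <- default_panel_blocks(); blocks$EMF <- "emf"
  pm <- (default_true_paths() != 0) * 1
  fit <- plspm_fit(dat, blocks, pm, n_bootstrap = 100, seed = 14)
  truth <- default_true_paths()
  est <- fit$path_matrix[truth != 0]
  expect_identical(sign(est), sign(truth[truth != 0]))
  expect_true(all(fit$paths$p >= 0 & fit$paths$p <= 1))
  expect_gt(fit$gof, 0.5)
})
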