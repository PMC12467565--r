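panel_17 <- function(n_plots = 8, seed = 1) {
  set.seed(seed)
  vals <- matrix(rnorm(n_plots * 17), n_plots, 17,
                 dimnames = list(paste0("p", seq_len(n_plots)),
                                 names(default_indicator_groups())))
  function_matrix(vals)
}

test_that("min-max standardization pins extremes and is affine-invariant", {
  fm <- panel_17()
  std <- minmax_standardize(fm)
  expect_true(all(std >= 0 & std <= 1))
  expect_equal(unname(apply(std, 2, max)), rep(1, 17))
  expect_equal(unname(apply(std, 2, min)), rep(0, 17))

  col <- matrix(c(2, 4, 6, 10), 4, 1, dimnames = list(NULL, "x"))
  expect_equal(unname(minmax_standardize(col)[, 1]), c(0, 0.25, 0.5, 1))

  shifted <- fm
  shifted$values[, "soil_tc"] <- 3.7 * shifted$values[, "soil_tc"] + 11
  expect_equal(minmax_standardize(shifted), std, tolerance = 1e-12)

  const <- fm
  const$values[, "urease"] <- 5
  expect_warning(stdc <- minmax_standardize(const), "constant")
  expect_equal(unname(stdc[, "urease"]), rep(0.5, nrow(stdc)))
})

test_that("EF and EMF indices follow the averaging definitions", {
  fm <- panel_17()
  std <- minmax_standardize(fm)
  efc <- ef_index(std, "EF-C")
  expect_equal(efc, rowMeans(std[, c("soil_tc", "stem_tc", "leaf_tc", "sucrase")]))
  expect_equal(ef_index(std, "sucrase"), std[, "sucrase"])  # single indicator
  expect_error(ef_index(std, "EF-K"), class = "altifun_usage_error")

  hand <- matrix(c(0, 0.2, 0.9, 1), 1, 4,
                 dimnames = list("p1", c("soil_tc", "stem_tc", "leaf_tc", "sucrase")))
  expect_equal(unname(ef_index(hand, c("soil_tc", "stem_tc", "leaf_tc", "sucrase"))),
               0.525)

  res <- emf_index(std)
  expect_equal(res$emf, rowMeans(std))
  # EMF is the n_g/N-weighted mean of the four EF group indices
  ng <- table(fm$indicator_groups)[colnames(res$ef)]
  expect_equal(unname(res$emf), as.vector(res$ef %*% (as.numeric(ng) / 17)),
               tolerance = 1e-12)

  top <- std
  top[1, ] <- 1
  expect_equal(unname(emf_index(top)$emf[1]), 1)
  nas <- std; nas[2, 3] <- NA
  expect_error(emf_index(nas), class = "altifun_format_error")
})

test_that("EMF correlates most with the EF group that varies most", {
  set.seed(9)
  vals <- matrix(rnorm(40 * 17, sd = 0.2), 40, 17,
                 dimnames = list(paste0("p", 1:40), names(default_indicator_groups())))
  driver <- rnorm(40, sd = 3)
  efc_cols <- names(default_indicator_groups())[default_indicator_groups() == "EF-C"]
  vals[, efc_cols] <- vals[, efc_cols] + driver
  res <- emf_index(minmax_standardize(function_matrix(vals)))
  expect_gt(res$correlations["EF-C"], res$correlations["EF-N"])
})

test_that("element ratios are consistent and flag bad denominators", {
  r <- element_ratios(tc = 20, tn = 2, tp = 1)
  expect_equal(unlist(r), c(c_n = 10, c_p = 20, n_p = 2))
  set.seed(4)
  tc <- runif(20, 5, 40); tn <- runif(20, 0.5, 4); tp <- runif(20, 0.2, 2)
  rr <- element_ratios(tc, tn, tp)
  expect_equal(rr$c_n, tc / tn)
  expect_equal(rr$c_p, rr$c_n * rr$n_p, tolerance = 1e-12)
  expect_warning(bad <- element_ratios(c(1, 2), c(1, 0), c(1, 1)))
  expect_true(is.na(bad$c_n[2]))
})

test_that("enzyme vectors follow the closed forms and the 45-degree rule", {
  v <- enzyme_vector(1, 1, 1)
  expect_equal(v$va, 45)
  expect_equal(v$vl, sqrt(2), tolerance = 1e-12)
  expect_equal(v$limitation, "balanced")

  # x = CEs:PEs = 1, y = CEs:NEs = sqrt(3)
  both <- enzyme_vector(1, 1 / sqrt(3), 1, convention = "both")
  expect_equal(both$va_spreadsheet, 60, tolerance = 1e-12)
  expect_equal(both$va_math, 30, tolerance = 1e-12)
  expect_equal(both$vl, 2, tolerance = 1e-12)
  expect_equal(both$limitation, "phosphorus")

  set.seed(6)
  ces <- runif(25, 0.5, 5); nes <- runif(25, 0.5, 5); pes <- runif(25, 0.5, 5)
  bb <- enzyme_vector(ces, nes, pes, convention = "both")
  expect_equal(bb$va_spreadsheet + bb$va_math, rep(90, 25), tolerance = 1e-10)
  expect_true(all(bb$va_spreadsheet > 0 & bb$va_spreadsheet < 90))
  sp <- enzyme_vector(ces, nes, pes)
  expect_identical(sp$limitation, ifelse(sp$va < 45, "nitrogen",
                                  ifelse(sp$va > 45, "phosphorus", "balanced")))

  # VL strictly increases in carbon-acquiring activity
  grid <- seq(0.5, 5, length.out = 10)
  vls <- enzyme_vector(grid, rep(2, 10), rep(2, 10))$vl
  expect_true(all(diff(vls) > 0))

  expect_warning(flag <- enzyme_vector(c(1, 0), c(1, 1), c(1, 1)))
  expect_true(is.na(flag$vl[2]) && is.na(flag$limitation[2]))
})
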