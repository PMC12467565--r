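# Group inference and multivariate drivers: one-way ANOVA with LSD compact
# letter displays, redundancy analysis, and PLS path modeling.

#' One-way ANOVA with LSD multiple comparison and compact letters
#'
#' Fits a one-way ANOVA, then Fisher's least significant difference pairwise
#' t-tests with the pooled mean squared error (df = N - k), and assigns a
#' compact letter display by greedy insertion over groups sorted by
#' decreasing mean: groups sharing a letter are not significantly different
#' at `alpha`.
#'
#' @param values Numeric response, one value per plot.
#' @param groups Group label per plot (>= 2 groups, >= 2 replicates each).
#' @param alpha Significance level of the pairwise tests.
#' @return Object of class `anova_lsd`: list with `F`, `df`, `p`, `means`
#'   (per-group mean, n, letters), `pairwise_p` (matrix), `mse`, `alpha`.
#' @export
anova_lsd <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  check_group_sizes(groups)
  if (length(unique(groups)) < 2) af_stop("usage", "need >= 2 groups")
  fit <- stats::lm(values ~ factor(groups))
  aov_tab <- stats::anova(fit)
  mse <- aov_tab[["Mean Sq"]][2]
  df_resid <- aov_tab[["Df"]][2]
  if (!is.finite(mse) || mse <= 1e-14 * max(1, mean(values^2))) {
    af_stop("degenerate", "zero within-group variance everywhere: F undefined")
  }
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  g <- names(means)
  k <- length(g)
  pw <- matrix(NA_real_, k, k, dimnames = list(g, g))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      se <- sqrt(mse * (1 / ns[i] + 1 / ns[j]))
      t_stat <- (means[i] - means[j]) / se
      pw[i, j] <- pw[j, i] <- 2 * stats::pt(-abs(t_stat), df_resid)
    }
  }
  letters <- lsd_letters(means, pw, alpha)
  structure(list(
    F = aov_tab[["F value"]][1], df = aov_tab[["Df"]],
    p = aov_tab[["Pr(>F)"]][1],
    means = data.frame(group = g, mean = as.vector(means), n = as.vector(ns),
                       letters = letters[g], row.names = g),
    pairwise_p = pw, mse = mse, alpha = alpha
  ), class = "anova_lsd")
}

# Greedy insertion compact letter display: sort groups by decreasing mean,
# grow maximal runs of mutually non-significant groups, drop runs contained
# in an earlier one, and assign one letter per surviving run.
lsd_letters <- function(means, pairwise_p, alpha) {
  ord <- names(sort(means, decreasing = TRUE))
  k <- length(ord)
  nonsig <- function(a, b) pairwise_p[a, b] > alpha
  runs <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k) {
      cand <- ord[i:(j + 1)]
      ok <- all(utils::combn(cand, 2, function(p) nonsig(p[1], p[2])))
      if (!ok) break
      j <- j + 1
    }
    runs[[length(runs) + 1]] <- ord[i:j]
  }
  keep <- rep(TRUE, length(runs))
  for (a in seq_along(runs)) {
    for (b in seq_along(runs)) {
      if (a != b && keep[b] && all(runs[[a]] %in% runs[[b]]) &&
          length(runs[[a]]) < length(runs[[b]])) keep[a] <- FALSE
    }
  }
  runs <- unique(runs[keep])
  out <- stats::setNames(rep("", k), ord)
  for (r in seq_along(runs)) {
    out[runs[[r]]] <- paste0(out[runs[[r]]], letters[r])
  }
  out
}

#' @export
print.anova_lsd <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$df[1], x$df[2], x$F, x$p))
  print(x$means[order(-x$means$mean), c("group", "mean", "n", "letters")],
        row.names = FALSE)
  invisible(x)
}

#' Redundancy analysis of a community matrix on explanatory variables
#'
#' Constrained ordination: the (optionally Hellinger-transformed) community
#' matrix is regressed on the explanatory matrix and the fitted values are
#' eigen-decomposed. Wraps [vegan::rda()] after an explicit collinearity
#' check.
#'
#' @param Y Community matrix, plots x taxa (e.g. phylum relative
#'   abundances).
#' @param X Explanatory data frame or matrix, plots x variables (e.g. EF-C,
#'   EF-N, EF-P, EMF, pH).
#' @param hellinger Apply the Hellinger transform to `Y` (default TRUE).
#' @return Object of class `rda_result`: list with `model` (the vegan fit),
#'   `constrained_eig`, `prop_explained` (total), `prop_per_axis`,
#'   `site_scores`, `species_scores`, `biplot_scores`.
#' @export
rda_fit <- function(Y, X, hellinger = TRUE) {
  Y <- as.matrix(Y)
  X <- as.data.frame(X)
  if (nrow(Y) != nrow(X)) af_stop("usage", "Y and X must describe the same plots")
  qrX <- qr(cbind(1, scale(as.matrix(X), scale = FALSE)))
  if (qrX$rank < ncol(X) + 1) {
    aliased <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)] - 1]
    af_stop("usage", "explanatory matrix is rank deficient; collinear column(s): %s",
            paste(aliased, collapse = ", "))
  }
  if (hellinger) Y <- vegan::decostand(Y, method = "hellinger")
  fit <- vegan::rda(Y ~ ., data = X)
  eig <- fit$CCA$eig
  total <- fit$tot.chi
  # axes with numerically nonzero inertia (a near-orthogonal X can leave none)
  n_axes <- sum(eig > sqrt(.Machine$double.eps) * total)
  sc <- function(display) {
    if (n_axes == 0) return(NULL)
    vegan::scores(fit, display = display, choices = seq_len(n_axes))
  }
  structure(list(
    model = fit,
    constrained_eig = eig,
    prop_explained = sum(eig) / total,
    prop_per_axis = eig / total,
    site_scores = sc("sites"),
    species_scores = sc("species"),
    biplot_scores = sc("bp")
  ), class = "rda_result")
}

#' Partial least squares path modeling (PLS-PM)
#'
#' Mode-A outer estimation with the centroid inner scheme: manifest
#' variables are standardized; latent scores are iteratively re-estimated as
#' (sign-corrected) weighted sums of their manifests, with outer weights the
#' correlations between manifests and the inner estimate, until the largest
#' outer-weight change falls below `tol`. Path coefficients of each
#' endogenous block are the least-squares regression of its score on its
#' predecessors' scores. Goodness of fit is
#' sqrt(mean communality x mean R-squared). Bootstrap resampling of plots
#' (seeded) yields a two-sided normal-approximation p per path.
#'
#' @param data Plot x manifest data frame or matrix.
#' @param blocks Named list: block -> manifest column names.
#' @param path_matrix Square 0/1 (or named-coefficient) matrix over blocks;
#'   entry \[j, k\] nonzero means a path from k to j. Must be acyclic
#'   (lower-triangular in block order).
#' @param scheme Inner weighting scheme; only `"centroid"` is implemented.
#' @param tol Convergence tolerance on outer weights.
#' @param max_iter Maximum outer/inner iterations.
#' @param n_bootstrap Bootstrap resamples for path p-values (0 = skip).
#' @param seed Seed for the bootstrap.
#' @return Object of class `plspm_result`: list with `paths` (data frame:
#'   from, to, estimate, boot_se, p), `path_matrix` (estimated
#'   coefficients), `scores`, `outer` (weights and loadings), `r_squared`,
#'   `communality`, `gof`, `iterations`.
#' @export
plspm_fit <- function(data, blocks, path_matrix, scheme = "centroid",
                      tol = 1e-6, max_iter = 300, n_bootstrap = 0,
                      seed = NULL) {
  if (!identical(scheme, "centroid")) af_stop("usage", "only scheme = 'centroid' is implemented")
  data <- as.data.frame(data)
  bn <- names(blocks)
  if (is.null(dimnames(path_matrix))) dimnames(path_matrix) <- list(bn, bn)
  if (!identical(rownames(path_matrix), bn) || !identical(colnames(path_matrix), bn)) {
    af_stop("usage", "path_matrix dimnames must equal the block names")
  }
  if (any(path_matrix[upper.tri(path_matrix)] != 0)) {
    af_stop("usage", "path_matrix must be acyclic (lower-triangular over block order)")
  }
  for (j in bn) {
    if (!length(blocks[[j]])) af_stop("usage", "block '%s' has no manifest variables", j)
    miss <- setdiff(blocks[[j]], colnames(data))
    if (length(miss)) af_stop("usage", "manifests not in data: %s", paste(miss, collapse = ", "))
  }
  X <- lapply(blocks, function(v) scale(as.matrix(data[, v, drop = FALSE])))
  n <- nrow(data)
  core <- plspm_core(X, path_matrix, tol, max_iter)

  paths_df <- NULL
  coefs <- core$coefs
  est <- data.frame()
  for (j in bn) {
    preds <- bn[path_matrix[j, ] != 0]
    if (length(preds)) {
      est <- rbind(est, data.frame(from = preds, to = j,
                                   estimate = coefs[j, preds]))
    }
  }
  rownames(est) <- NULL

  if (n_bootstrap > 0 && nrow(est)) {
    boot <- with_seed(seed, {
      sapply(seq_len(n_bootstrap), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        Xb <- lapply(X, function(m) scale(m[idx, , drop = FALSE]))
        cb <- tryCatch(plspm_core(Xb, path_matrix, tol, max_iter)$coefs,
                       error = function(e) matrix(NA_real_, length(bn), length(bn),
                                                  dimnames = list(bn, bn)))
        mapply(function(f, t) cb[t, f], est$from, est$to)
      })
    })
    boot <- matrix(boot, nrow = nrow(est))
    est$boot_se <- apply(boot, 1, stats::sd, na.rm = TRUE)
    est$p <- 2 * stats::pnorm(-abs(est$estimate) / est$boot_se)
  }

  r2 <- core$r2[sapply(bn, function(j) any(path_matrix[j, ] != 0))]
  comm <- unlist(lapply(bn, function(j) core$loadings[[j]]^2))
  structure(list(paths = est, path_matrix = coefs, scores = core$scores,
                 outer = list(weights = core$weights, loadings = core$loadings),
                 r_squared = core$r2, communality = mean(comm),
                 gof = sqrt(mean(comm) * mean(r2)),
                 iterations = core$iterations), class = "plspm_result")
}

# Inner PLS-PM engine shared by the fit and its bootstrap.
plspm_core <- function(X, path_matrix, tol, max_iter) {
  bn <- names(X)
  n <- nrow(X[[1]])
  connected <- (path_matrix != 0) | t(path_matrix != 0)
  isolated <- bn[rowSums(connected) == 0]
  if (length(isolated)) {
    af_stop("usage", "block(s) disconnected from the inner model: %s",
            paste(isolated, collapse = ", "))
  }
  w <- lapply(X, function(m) rep(1 / sqrt(ncol(m)), ncol(m)))
  Y <- mapply(function(m, wj) as.vector(scale(m %*% wj)), X, w, SIMPLIFY = FALSE)
  it <- 0
  repeat {
    it <- it + 1
    Ymat <- do.call(cbind, Y)
    Z <- vector("list", length(bn)); names(Z) <- bn
    for (j in seq_along(bn)) {
      nb <- which(connected[j, ])
      e <- sign(stats::cor(Ymat[, j], Ymat[, nb, drop = FALSE]))
      e[e == 0] <- 1
      Z[[j]] <- as.vector(Ymat[, nb, drop = FALSE] %*% as.vector(e))
    }
    w_new <- vector("list", length(bn)); names(w_new) <- bn
    delta <- 0
    for (j in seq_along(bn)) {
      wj <- as.vector(stats::cor(X[[j]], Z[[j]]))
      wj <- wj / sqrt(sum(wj^2))
      yj <- as.vector(scale(X[[j]] %*% wj))
      if (stats::cor(yj, X[[j]][, 1]) < 0) { wj <- -wj; yj <- -yj }
      w_old <- w[[j]] / sqrt(sum(w[[j]]^2))
      delta <- max(delta, max(abs(abs(wj) - abs(w_old))))
      w_new[[j]] <- wj
      Y[[j]] <- yj
    }
    w <- w_new
    if (delta < tol) break
    if (it >= max_iter) {
      af_stop("degenerate",
              "PLS-PM did not converge in %d iterations (last weight change %.2e)",
              max_iter, delta)
    }
  }
  scores <- do.call(cbind, Y)
  colnames(scores) <- bn
  coefs <- matrix(0, length(bn), length(bn), dimnames = list(bn, bn))
  r2 <- stats::setNames(numeric(length(bn)), bn)
  for (j in bn) {
    preds <- bn[path_matrix[j, ] != 0]
    if (!length(preds)) next
    fit <- stats::lm.fit(cbind(Intercept = 1, scores[, preds, drop = FALSE]),
                         scores[, j])
    coefs[j, preds] <- fit$coefficients[preds]
    r2[j] <- 1 - sum(fit$residuals^2) / sum((scores[, j] - mean(scores[, j]))^2)
  }
  loadings <- lapply(bn, function(j) as.vector(stats::cor(X[[j]], scores[, j])))
  names(loadings) <- bn
  weights <- w
  list(scores = scores, coefs = coefs, r2 = r2, loadings = loadings,
       weights = weights, iterations = it)
}

#' @export
print.plspm_result <- function(x, ...) {
  cat(sprintf("PLS-PM (mode A, centroid scheme), converged in %d iterations; GoF = %.3f\n",
              x$iterations, x$gof))
  print(x$paths, row.names = FALSE)
  invisible(x)
}
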