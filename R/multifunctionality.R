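# Ecosystem function (EF) and multifunctionality (EMF) indices, soil element
# ratios, and ecoenzymatic stoichiometry vectors.
#
# The 17 default indicators and their grouping follow the study design this
# package supports: EF-C (total soil/stem/leaf carbon, sucrase), EF-N (total
# soil/stem/leaf nitrogen, urease), EF-P (total soil/stem/leaf phosphorus,
# alkaline and acid phosphatase), EF-Prod (plant height, stem biomass, leaf
# biomass, crown width). The group map is fully configurable.

#' Default 17-indicator grouping into the four EF groups
#' @return Named character vector mapping indicator name to EF group.
#' @export
default_indicator_groups <- function() {
  c(soil_tc = "EF-C", stem_tc = "EF-C", leaf_tc = "EF-C", sucrase = "EF-C",
    soil_tn = "EF-N", stem_tn = "EF-N", leaf_tn = "EF-N", urease = "EF-N",
    soil_tp = "EF-P", stem_tp = "EF-P", leaf_tp = "EF-P",
    alkaline_phosphatase = "EF-P", acid_phosphatase = "EF-P",
    plant_height = "EF-Prod", stem_biomass = "EF-Prod",
    leaf_biomass = "EF-Prod", crown_width = "EF-Prod")
}

#' Construct a plot x indicator function panel
#'
#' @param values Numeric matrix, plots in rows (named), indicators in
#'   columns (named).
#' @param indicator_groups Named character vector mapping each indicator to
#'   an EF group (defaults to [default_indicator_groups()] when the columns
#'   match it).
#' @param plot_meta Optional data frame with `sample_id` and `group` (the
#'   altitude group of each plot).
#' @param units Optional named character vector of indicator units.
#' @return An object of class `function_matrix`.
#' @export
function_matrix <- function(values, indicator_groups = NULL, plot_meta = NULL,
                            units = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    af_stop("format", "values must be a numeric plot x indicator matrix")
  }
  if (is.null(colnames(values))) af_stop("format", "indicator columns must be named")
  if (is.null(rownames(values))) rownames(values) <- paste0("plot", seq_len(nrow(values)))
  if (is.null(indicator_groups)) {
    dg <- default_indicator_groups()
    if (!all(colnames(values) %in% names(dg))) {
      af_stop("format", "indicator_groups must be supplied for non-default indicators")
    }
    indicator_groups <- dg[colnames(values)]
  }
  missing <- setdiff(colnames(values), names(indicator_groups))
  if (length(missing)) {
    af_stop("format", "indicators without a group: %s", paste(missing, collapse = ", "))
  }
  indicator_groups <- indicator_groups[colnames(values)]
  if (!is.null(plot_meta)) {
    plot_meta <- as.data.frame(plot_meta)
    if (!"sample_id" %in% names(plot_meta)) plot_meta$sample_id <- rownames(plot_meta)
    if (!all(rownames(values) %in% plot_meta$sample_id)) {
      af_stop("metadata", "plots missing from plot_meta")
    }
    plot_meta <- plot_meta[match(rownames(values), plot_meta$sample_id), , drop = FALSE]
    rownames(plot_meta) <- plot_meta$sample_id
  }
  structure(list(values = values, indicator_groups = indicator_groups,
                 plot_meta = plot_meta, units = units),
            class = "function_matrix")
}

#' @export
print.function_matrix <- function(x, ...) {
  cat(sprintf("function_matrix: %d plots x %d indicators (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s: %d", names(table(x$indicator_groups)),
                            table(x$indicator_groups)), collapse = ", ")))
  invisible(x)
}

#' Min-max standardize a function panel
#'
#' Each indicator j is rescaled across plots as
#' f_ij = (x_ij - min_j) / (max_j - min_j), so every indicator lies in
#' \[0, 1\] with the best plot at 1 and the worst at 0. A constant indicator
#' (max = min) is set to 0.5 for every plot, with a warning.
#'
#' @param fm A [function_matrix()] or a plain numeric plot x indicator matrix.
#' @return Numeric matrix of f_ij with the indicator group map attached as
#'   attribute `indicator_groups`.
#' @export
minmax_standardize <- function(fm) {
  vals <- if (inherits(fm, "function_matrix")) fm$values else fm
  if (nrow(vals) < 2) af_stop("usage", "min-max standardization needs >= 2 plots")
  lo <- apply(vals, 2, min)
  hi <- apply(vals, 2, max)
  rng <- hi - lo
  const <- rng == 0
  if (any(const)) {
    af_warn("constant indicator(s) set to 0.5: %s",
            paste(colnames(vals)[const], collapse = ", "))
    rng[const] <- 1
  }
  std <- sweep(sweep(vals, 2, lo, "-"), 2, rng, "/")
  std[, const] <- 0.5
  if (inherits(fm, "function_matrix")) {
    attr(std, "indicator_groups") <- fm$indicator_groups
  }
  std
}

#' Single-function (EF group) index
#'
#' The EF index of a group is the arithmetic mean, per plot, of the
#' standardized values of the group's member indicators.
#'
#' @param standardized Matrix from [minmax_standardize()].
#' @param group EF group name (e.g. `"EF-C"`), or a character vector of
#'   member indicator names.
#' @param indicator_groups Group map; defaults to the attribute carried by
#'   `standardized`.
#' @return Named numeric vector of per-plot EF values.
#' @export
ef_index <- function(standardized, group,
                     indicator_groups = attr(standardized, "indicator_groups")) {
  members <- if (length(group) == 1 && !group %in% colnames(standardized)) {
    if (is.null(indicator_groups)) af_stop("usage", "no indicator group map available")
    m <- names(indicator_groups)[indicator_groups == group]
    if (!length(m)) af_stop("usage", "unknown EF group '%s'", group)
    m
  } else {
    group
  }
  missing <- setdiff(members, colnames(standardized))
  if (length(missing)) af_stop("usage", "indicators not in panel: %s", paste(missing, collapse = ", "))
  rowMeans(standardized[, members, drop = FALSE])
}

#' Ecosystem multifunctionality index (averaging approach)
#'
#' EMF_i is the mean over all N indicators of the standardized values f_ij
#' of plot i. Also returns the per-group EF indices and the Pearson
#' correlation of EMF with each EF across plots.
#'
#' @param standardized Matrix from [minmax_standardize()].
#' @param indicator_groups Group map; defaults to the attached attribute.
#' @return List with `emf` (per-plot), `ef` (plot x group matrix), and
#'   `correlations` (Pearson r of EMF with each EF).
#' @export
emf_index <- function(standardized,
                      indicator_groups = attr(standardized, "indicator_groups")) {
  if (anyNA(standardized)) {
    idx <- which(is.na(standardized), arr.ind = TRUE)[1, ]
    af_stop("format", "missing standardized value for plot '%s', indicator '%s'",
            rownames(standardized)[idx[1]] %||% idx[1],
            colnames(standardized)[idx[2]] %||% idx[2])
  }
  emf <- rowMeans(standardized)
  ef <- NULL
  correlations <- NULL
  if (!is.null(indicator_groups)) {
    grps <- unique(unname(indicator_groups))
    ef <- sapply(grps, function(g) ef_index(standardized, g, indicator_groups))
    if (is.null(dim(ef))) ef <- matrix(ef, nrow = 1, dimnames = list(rownames(standardized), grps))
    correlations <- if (nrow(standardized) > 2) {
      apply(ef, 2, function(v) stats::cor(emf, v))
    }
  }
  list(emf = emf, ef = ef, correlations = correlations)
}

#' Soil element mass ratios
#'
#' @param tc,tn,tp Per-plot total carbon, nitrogen and phosphorus.
#' @return Data frame with columns `c_n`, `c_p`, `n_p`; plots with a zero or
#'   negative denominator get `NA` and a warning.
#' @export
element_ratios <- function(tc, tn, tp) {
  stopifnot(length(tc) == length(tn), length(tn) == length(tp))
  bad <- tn <= 0 | tp <= 0
  if (any(bad)) af_warn("%d plot(s) with non-positive TN or TP flagged as NA", sum(bad))
  out <- data.frame(c_n = tc / tn, c_p = tc / tp, n_p = tn / tp)
  out[bad, ] <- NA_real_
  rownames(out) <- names(tc) %||% NULL
  out
}

#' Ecoenzymatic stoichiometry vector length and angle
#'
#' From the carbon-, nitrogen- and phosphorus-acquiring enzyme activities
#' (C: sucrase; N: urease; P: alkaline plus acid phosphatase) the enzyme
#' ratios x = CEs:PEs and y = CEs:NEs define
#' VL = sqrt(x^2 + y^2) and VA = degrees(atan2(y, x)) under the default
#' spreadsheet ATAN2(x, y) argument convention. Longer VL means stronger
#' microbial carbon limitation; VA < 45 degrees indicates nitrogen
#' limitation and VA > 45 degrees phosphorus limitation. The `"math"`
#' convention swaps the two arguments; the two angles sum to 90 degrees.
#'
#' @param ces,nes,pes Per-plot enzyme activities (all positive). `pes`
#'   should already be the summed phosphatase activity.
#' @param convention `"spreadsheet"` (default), `"math"` or `"both"`.
#' @return Data frame with `ratio_cp`, `ratio_cn`, `vl`, the requested
#'   vector angle column(s) (`va`, or `va_spreadsheet` and `va_math`), and a
#'   `limitation` label ("nitrogen", "phosphorus" or "balanced" at exactly
#'   45 degrees), based on the default-convention angle.
#' @export
enzyme_vector <- function(ces, nes, pes,
                          convention = c("spreadsheet", "math", "both")) {
  convention <- match.arg(convention)
  stopifnot(length(ces) == length(nes), length(nes) == length(pes))
  bad <- !(ces > 0 & nes > 0 & pes > 0)
  if (any(bad)) af_warn("%d plot(s) with non-positive enzyme activity flagged as NA", sum(bad))
  x <- ces / pes   # CEs:PEs
  y <- ces / nes   # CEs:NEs
  vl <- sqrt(x^2 + y^2)
  va_spread <- atan2(y, x) * 180 / pi
  va_math <- atan2(x, y) * 180 / pi
  va <- if (convention == "math") va_math else va_spread
  lim <- ifelse(va < 45, "nitrogen", ifelse(va > 45, "phosphorus", "balanced"))
  out <- data.frame(ratio_cp = x, ratio_cn = y, vl = vl)
  if (convention == "both") {
    out$va_spreadsheet <- va_spread
    out$va_math <- va_math
  } else {
    out$va <- va
  }
  out$limitation <- lim
  out[bad, setdiff(names(out), "limitation")] <- NA_real_
  out$limitation[bad] <- NA_character_
  rownames(out) <- names(ces) %||% NULL
  out
}
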