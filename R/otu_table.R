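# The otu_table container: taxa x sample counts with taxonomy and metadata.

RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus")

#' Construct an OTU count table
#'
#' Bundles a non-negative integer count matrix (taxa in rows, samples in
#' columns) with a ranked taxonomy and per-sample metadata. All downstream
#' stages (diversity, networks, assembly nulls) consume this container.
#'
#' @param counts Numeric matrix of non-negative integers, taxa x samples,
#'   with unique row (taxon) and column (sample) names.
#' @param metadata Data frame with one row per sample; must contain a
#'   `sample_id` column (or row names) matching the count columns and a
#'   `group` column. Optional columns: `altitude_m`, `replicate`.
#' @param taxonomy Optional data frame with a `taxon_id` column (or row
#'   names) and any of the ranked lineage columns
#'   kingdom/phylum/class/order/family/genus. Taxa absent from it are
#'   assigned the lineage "Unclassified".
#' @return An object of class `otu_table`: a list with elements `counts`,
#'   `taxonomy`, `metadata`.
#' @export
otu_table <- function(counts, metadata, taxonomy = NULL) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    af_stop("format", "counts must be a numeric matrix (taxa x samples)")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    af_stop("format", "counts must carry taxon row names and sample column names")
  }
  if (anyDuplicated(rownames(counts))) af_stop("format", "duplicate taxon ids in counts")
  if (anyDuplicated(colnames(counts))) af_stop("format", "duplicate sample ids in counts")
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    af_stop("format", "counts must be non-negative integers with no missing values")
  }
  storage.mode(counts) <- "double"

  metadata <- as.data.frame(metadata)
  if (!"sample_id" %in% names(metadata)) {
    metadata$sample_id <- rownames(metadata)
  }
  metadata$sample_id <- as.character(metadata$sample_id)
  if (anyDuplicated(metadata$sample_id)) af_stop("metadata", "duplicate sample ids in metadata")
  missing <- setdiff(colnames(counts), metadata$sample_id)
  if (length(missing)) {
    af_stop("metadata", "samples missing from metadata: %s", paste(missing, collapse = ", "))
  }
  if (!"group" %in% names(metadata) || anyNA(metadata$group)) {
    af_stop("metadata", "every sample needs a group label in metadata$group")
  }
  metadata <- metadata[match(colnames(counts), metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- metadata$sample_id
  metadata$group <- as.character(metadata$group)

  tax <- data.frame(taxon_id = rownames(counts))
  for (r in RANKS) tax[[r]] <- "Unclassified"
  if (!is.null(taxonomy)) {
    taxonomy <- as.data.frame(taxonomy)
    if (!"taxon_id" %in% names(taxonomy)) taxonomy$taxon_id <- rownames(taxonomy)
    taxonomy$taxon_id <- as.character(taxonomy$taxon_id)
    if (anyDuplicated(taxonomy$taxon_id)) af_stop("format", "duplicate taxon ids in taxonomy")
    idx <- match(tax$taxon_id, taxonomy$taxon_id)
    for (r in intersect(RANKS, names(taxonomy))) {
      v <- as.character(taxonomy[[r]])[idx]
      v[is.na(v) | v == ""] <- "Unclassified"
      tax[[r]] <- v
    }
  }
  rownames(tax) <- tax$taxon_id

  structure(list(counts = counts, taxonomy = tax, metadata = metadata),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d taxa x %d samples, %d group(s): %s\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$metadata$group)),
              paste(sort(unique(x$metadata$group)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

sample_groups <- function(tab) {
  stats::setNames(tab$metadata$group, tab$metadata$sample_id)
}

# Require >= 2 samples per group before any between-group statistic.
check_group_sizes <- function(groups, min_size = 2) {
  sizes <- table(groups)
  bad <- names(sizes)[sizes < min_size]
  if (length(bad)) {
    af_stop("usage", "groups with fewer than %d samples: %s",
            min_size, paste(bad, collapse = ", "))
  }
  invisible(sizes)
}
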