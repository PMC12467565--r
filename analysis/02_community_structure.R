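#!/usr/bin/env Rscript
# Stage 2: community composition, alpha diversity, and beta diversity.
#
# Phylum-level relative abundance per altitude group; Chao1/ACE/Shannon/
# Simpson per sample with one-way ANOVA + LSD letters across groups; and
# Bray-Curtis -> PCoA + ANOSIM for between-group structure.

suppressPackageStartupMessages(library(altifun))

seed <- 42
data_dir <- "results/data"
out_dir <- "results/tables"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

otu <- read_otu_table(file.path(data_dir, "otu_counts.tsv"),
                      file.path(data_dir, "otu_metadata.csv"),
                      file.path(data_dir, "otu_taxonomy.tsv"))
groups <- otu$metadata$group

ab <- aggregate_relative_abundance(otu, "phylum")
gm <- group_mean_abundance(ab)
write.csv(data.frame(phylum = rownames(gm), round(100 * gm, 2), check.names = FALSE),
          file.path(out_dir, "phylum_group_means_pct.csv"), row.names = FALSE)
dom <- names(sort(rowMeans(gm), decreasing = TRUE))[1:3]
cat("Dominant phyla:", paste(dom, collapse = ", "), "\n")
cat("Their summed group means (%):",
    paste(colnames(gm), round(100 * colSums(gm[dom, , drop = FALSE]), 2),
          sep = "=", collapse = ", "), "\n")

alpha <- alpha_diversity(otu)
write.csv(alpha, file.path(out_dir, "alpha_diversity.csv"), row.names = FALSE)
letters_tab <- do.call(rbind, lapply(c("chao1", "ace", "shannon", "simpson"),
  function(i) data.frame(index = i, anova_lsd(alpha[[i]], groups)$means)))
write.csv(letters_tab, file.path(out_dir, "alpha_anova_letters.csv"),
          row.names = FALSE)
cat("\nAlpha diversity group letters:\n")
print(letters_tab[letters_tab$index == "shannon", ], row.names = FALSE)

d <- bray_curtis(otu)
ord <- pcoa(d, n_axes = 2)
write.csv(data.frame(sample_id = rownames(ord$coordinates), ord$coordinates,
                     group = groups),
          file.path(out_dir, "pcoa_coordinates.csv"), row.names = FALSE)
an <- anosim_test(d, groups, n_permutations = 999, seed = substream(seed, "anosim"))
cat(sprintf("\nPCoA axes 1-2 explain %.1f%% + %.1f%%; ANOSIM R = %.3f, p = %.3f\n",
            100 * ord$prop_explained[1], 100 * ord$prop_explained[2], an$R, an$p))
jsonlite::write_json(c(an[c("R", "p", "n_permutations")], seed = seed),
                     file.path(out_dir, "anosim.json"), auto_unbox = TRUE,
                     digits = NA)
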