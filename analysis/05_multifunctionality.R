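#!/usr/bin/env Rscript
# Stage 5: ecosystem function indices and enzyme stoichiometry.
#
# Min-max standardizes the 17-indicator panel, averages it into the EF-C /
# EF-N / EF-P / EF-Prod single-function indices and the EMF
# multifunctionality index, tests group differences (ANOVA + LSD letters),
# reports the Pearson correlation of EMF with each nutrient function, and
# computes the enzyme stoichiometry vectors (VL = carbon limitation
# strength; VA </> 45 degrees = nitrogen/phosphorus limitation).

suppressPackageStartupMessages(library(altifun))

data_dir <- "results/data"
out_dir <- "results/tables"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

fm <- read_function_matrix(file.path(data_dir, "functions.csv"),
                           file.path(data_dir, "functions_groups.csv"),
                           file.path(data_dir, "otu_metadata.csv"))
covars <- read.csv(file.path(data_dir, "covariates.csv"))
enzymes <- read.csv(file.path(data_dir, "enzymes.csv"))
groups <- covars$group[match(rownames(fm$values), covars$sample_id)]

std <- minmax_standardize(fm)
res <- emf_index(std)
write.csv(data.frame(sample_id = rownames(std), group = groups, res$ef,
                     EMF = res$emf, check.names = FALSE),
          file.path(out_dir, "ef_emf.csv"), row.names = FALSE)

letters_tab <- do.call(rbind, lapply(colnames(res$ef), function(g) {
  data.frame(index = g, anova_lsd(res$ef[, g], groups)$means)
}))
letters_tab <- rbind(letters_tab,
                     data.frame(index = "EMF", anova_lsd(res$emf, groups)$means))
write.csv(letters_tab, file.path(out_dir, "ef_emf_anova_letters.csv"),
          row.names = FALSE)
cat("EF/EMF group means and LSD letters:\n")
print(letters_tab, row.names = FALSE, digits = 3)
cat("\nPearson correlation of EMF with each single function:\n")
print(round(res$correlations, 2))

vec <- enzyme_vector(enzymes$ces, enzymes$nes, enzymes$pes)
vec <- data.frame(sample_id = enzymes$sample_id, group = enzymes$group, vec)
write.csv(vec, file.path(out_dir, "enzyme_stoichiometry.csv"), row.names = FALSE)
cat("\nEnzyme vectors: mean VL per group:",
    paste(names(tapply(vec$vl, vec$group, mean)),
          round(tapply(vec$vl, vec$group, mean), 3), sep = "=", collapse = ", "),
    "\n")
cat("Limitation labels:", paste(names(table(vec$limitation)),
                                table(vec$limitation), sep = ":", collapse = ", "), "\n")
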