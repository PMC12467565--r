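#!/usr/bin/env Rscript
# Stage 6: what drives community composition and multifunctionality.
#
# RDA of phylum-level (Hellinger-transformed) composition on the nutrient
# function indices and pH, and a PLS path model
# altitude -> pH / microbial axes -> EF-C/EF-N/EF-P -> EMF with bootstrap
# path p-values. The generator's true path matrix is the recovery target.

suppressPackageStartupMessages(library(altifun))

seed <- 42
data_dir <- "results/data"
out_dir <- "results/tables"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

otu <- read_otu_table(file.path(data_dir, "otu_counts.tsv"),
                      file.path(data_dir, "otu_metadata.csv"),
                      file.path(data_dir, "otu_taxonomy.tsv"))
fm <- read_function_matrix(file.path(data_dir, "functions.csv"),
                           file.path(data_dir, "functions_groups.csv"))
covars <- read.csv(file.path(data_dir, "covariates.csv"))

std <- minmax_standardize(fm)
res <- emf_index(std)

Y <- t(aggregate_relative_abundance(otu, "phylum")$proportions)
X <- data.frame(EF_C = res$ef[, "EF-C"], EF_N = res$ef[, "EF-N"],
                EF_P = res$ef[, "EF-P"], EMF = res$emf, pH = covars$ph)
rda <- rda_fit(Y, X, hellinger = TRUE)
write.csv(data.frame(axis = names(rda$prop_per_axis),
                     eigenvalue = rda$constrained_eig,
                     prop_explained = rda$prop_per_axis),
          file.path(out_dir, "rda_axes.csv"), row.names = FALSE)
write.csv(data.frame(variable = rownames(rda$biplot_scores), rda$biplot_scores),
          file.path(out_dir, "rda_biplot_scores.csv"), row.names = FALSE)
cat(sprintf("RDA: function indices + pH explain %.1f%% of phylum composition\n",
            100 * rda$prop_explained))

dat <- data.frame(covars, EF_C = res$ef[, "EF-C"], EF_N = res$ef[, "EF-N"],
                  EF_P = res$ef[, "EF-P"], EMF = res$emf)
blocks <- list(altitude = "altitude_m", ph = "ph",
               bacteria = c("bact_pco1", "bact_pco2"),
               fungi = c("fung_pco1", "fung_pco2"),
               EF_C = "EF_C", EF_N = "EF_N", EF_P = "EF_P", EMF = "EMF")
pm <- (default_true_paths() != 0) * 1
pm <- pm[names(blocks), names(blocks)]
fit <- plspm_fit(dat, blocks, pm, n_bootstrap = 500,
                 seed = substream(seed, "plspm"))
write.csv(fit$paths, file.path(out_dir, "plspm_paths.csv"), row.names = FALSE)
cat("\n")
print(fit)
cat("\nR-squared per endogenous block:\n")
print(round(fit$r_squared[fit$r_squared > 0], 3))
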