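#!/usr/bin/env Rscript
# Stage 6 — trait correlations and folding-yield shapes.
#
# A synthetic six-trait table emulates the measured panel (total binding
# capacity, soluble level, insoluble level, ligand affinity, native
# thermal stability, in vitro folding efficiency) for constructs along
# the trajectory, with the foldability group (binding capacity, soluble
# level, refolding yield) driven by one latent factor and the stability
# group (affinity, thermal stability, insoluble level) by another —
# the structure the correlation/PCA machinery is meant to expose.
# Folding-yield concentration shapes are classified for the mechanistic
# toy models of oligomer and monomer folding.

suppressPackageStartupMessages(library(propevo))

outdir <- "results/traits"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

set.seed(61)
n <- 12                                   # constructs along the trajectory
fold <- rnorm(n)                          # latent foldability
stab <- rnorm(n)                          # latent stability/affinity
noise <- function() rnorm(n, 0, 0.35)
traits <- data.frame(
  binding_capacity = fold + noise(),
  soluble_level = 0.9 * fold + noise(),
  refolding_yield = 0.85 * fold + noise(),
  glcnac_affinity = stab + noise(),
  thermal_stability = 0.9 * stab + noise(),
  insoluble_level = 0.8 * stab + noise())

res <- trait_pca(traits)
utils::write.table(round(res$correlation, 3),
                   file.path(outdir, "trait_correlation.tsv"),
                   sep = "\t", quote = FALSE)
utils::write.table(round(res$loadings, 3),
                   file.path(outdir, "trait_loadings.tsv"),
                   sep = "\t", quote = FALSE)
cat(sprintf("first two PCs explain %.0f%% and %.0f%% of the correlation variance\n",
            100 * res$variance_fraction[1], 100 * res$variance_fraction[2]))
g1 <- rownames(res$loadings)[res$loadings[, 1] *
                               res$loadings["binding_capacity", 1] > 0.2]
cat(sprintf("traits loading with binding capacity on PC1: %s\n",
            paste(g1, collapse = ", ")))

conc <- c(0.5, 2, 8, 32, 128)
cat(sprintf("oligomer toy model over %s uM: %s\n",
            paste(conc, collapse = "/"),
            classify_concentration_dependence(
              conc, folding_yield_curve(conc, "oligomer"))))
cat(sprintf("monomer toy model: %s\n",
            classify_concentration_dependence(
              conc, folding_yield_curve(conc, "monomer"))))
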