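#!/usr/bin/env Rscript
# Sudoku-style combinatorial pooling of the progenitor collection, naive
# address deconvolution, and curation of the condensed-collection picklist.

library(koscreen)
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(seed = seed)
genome <- if (file.exists("results/genome.fa")) {
  read_genome("results/genome.fa", "results/genome.gff3", "CDS")
} else generate_genome(cfg)$genome
pc <- generate_progenitor_catalog(genome, cfg)
utils::write.csv(pc$catalog, "results/progenitor_catalog.csv",
                 row.names = FALSE)

n_plates <- max(pc$catalog$plate)
design <- design_pools(n_plates)
cat(sprintf("pool design: %d plates on a %dx%d grid -> %d pools\n",
            n_plates, design$grid_rows, design$grid_cols, n_pools(design)))

pools <- simulate_pooling(pc$catalog, design)
dec <- deconvolve_naive(pools, design)
n_unique <- sum(table(dec$candidates$strain_id) == 1L)
cat(sprintf(
  "naive deconvolution: %d/%d strains resolve to a unique address;\n",
  n_unique, length(unique(pc$catalog$strain_id))))
cat(sprintf("%d unlocatable; multi-well (contaminated) strains yield candidate sets\n",
            length(dec$unlocatable)))

picks <- curate_condensed(pc$catalog, genome)
utils::write.csv(picks, "results/condensed_picklist.csv", row.names = FALSE)
cat(sprintf(
  "picklist: %d genes with a strain, %d with a backup, %d with a third\n",
  length(unique(picks$gene_id)), sum(picks$rank == 2L),
  sum(picks$rank == 3L)))
cat(sprintf("colonies to pick: %d total (2x predicted well occupancy, <= 10)\n",
            sum(picks$colonies_to_pick)))
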