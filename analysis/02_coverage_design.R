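#!/usr/bin/env Rscript
# Monte Carlo design of collection saturation: how many mutants must be
# picked for a target fraction of genes to carry at least one disruption.
# Requires results/genome.* from 01_genome_and_sites.R (regenerates if absent).

library(koscreen)
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
dir.create("results", showWarnings = FALSE)

if (file.exists("results/genome.fa")) {
  genome <- read_genome("results/genome.fa", "results/genome.gff3", "CDS")
} else {
  genome <- generate_genome(sim_config(seed = seed))$genome
}
idx <- index_insertion_sites(genome)
G <- nrow(genome$genes)

model <- pick_model("site-uniform", replicates = 1000L, seed = seed + 10L)
grid <- as.integer(seq(2500, 60000, by = 2500))
curve <- simulate_pick_curve(idx, genome, model, grid)
write_coverage_curve(curve, "results/coverage_curve.csv")

for (n in c(25000L, 50000L)) {
  cat(sprintf("at %d picks: %.1f%% of genes covered (+/- 2 sd: %.1f-%.1f%%)\n",
              n, curve$mean_unique[grid == n] / G * 100,
              (curve$mean_unique[grid == n] - 2 * curve$sd_unique[grid == n]) / G * 100,
              (curve$mean_unique[grid == n] + 2 * curve$sd_unique[grid == n]) / G * 100))
}
n99 <- min_picks_for_coverage(model, 0.99, idx, genome)
cat(sprintf("closed form: %d picks needed for 99%% expected coverage\n", n99))

# validation-style depletion curve from a sequenced progenitor catalog
pc <- generate_progenitor_catalog(genome, sim_config(seed = seed), idx)
strains <- pc$catalog[!duplicated(pc$catalog$strain_id), ]
dep_grid <- as.integer(seq(5000, nrow(strains), length.out = 10))
dep <- simulate_depletion_curve(strains, replicates = 200L,
                                seed = seed + 11L, n_grid = dep_grid)
write_coverage_curve(dep, "results/depletion_curve.csv")
cat(sprintf("progenitor catalog: %d strains disrupting %d genes\n",
            nrow(strains),
            length(setdiff(unique(strains$gene_id), "intergenic"))))
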