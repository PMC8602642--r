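# koscreen

Computational pipeline for genome-wide transposon knockout collections in
acid-producing bacteria, built around the chain of analyses used to mine
*Gluconobacter oxydans*-style collections for rare-earth-element (REE)
bioleaching genes:

1. **Insertion-site model** — index mariner TA/AT target sites from
   FASTA + GFF3, map insertions to genes, list undisrupted (candidate
   essential) genes.
2. **Saturation design** — Monte Carlo and closed-form estimates of unique
   genes disrupted versus mutants picked:
   `E[unique] = Σᵢ (1 − (1 − pᵢ)^N)` with `pᵢ = sᵢ/S` from per-gene site
   counts, plus without-replacement depletion curves from a sequenced
   catalog.
3. **Combinatorial pooling** — Sudoku-style 4-axis pool design over a
   20 × 27 plate grid, pooling simulation, naive address deconvolution, and
   curation of a condensed collection (rank by translation-start proximity,
   then address probability; 2× predicted well occupancy colonies, ≤ 10).
4. **Dye screens** — thymol blue endpoint ratio (A435/A545, linear in pH
   over 2.0–3.4) and bromophenol blue acidification rate (−slope of seven
   A600 reads, normalized by OD), with plate-wise IQR outlier calling
   (inclusive quartiles, 1.5 × IQR bounds, majority / 1-of-2 strain rule).
5. **Confirmation statistics** — batch-matched proxy-wild-type sets,
   two-tailed pooled-variance t-tests at Bonferroni `0.05/N`, growth
   filter, strain categories.
6. **GO enrichment** — one-sided Fisher's exact (hypergeometric upper
   tail) against the genome background.
7. **Bioleaching** — dilution-corrected 16-element REE panels, extraction
   efficiency, strain comparisons with percent change, spike recovery, and
   the pH–extraction regression.
8. **Synthetic data** — seeded generators for every input above, with
   ground truth, so the whole pipeline runs and is tested end to end with
   no external data.

The package is aimed at people building or mining arrayed transposon
collections: it turns the bookkeeping (sites, pools, plates, controls,
corrections) into tested functions.

## Worked example

Index a study-scale synthetic genome and size the collection:

```r
library(koscreen)
cfg <- sim_config(seed = 1)                 # 3283 genes, 62 contigs, GC 0.61
sim <- generate_genome(cfg)
idx <- index_insertion_sites(sim$genome)
idx
#> insertion_site_index: 303896 sites on 62 contig(s); 3283 gene(s)

model <- pick_model("site-uniform", replicates = 1000, seed = 11)
round(expected_unique_genes(model, c(25000, 50000), idx, sim$genome))
#> [1] 3201 3272                             # 97.5% and 99.7% of genes
min_picks_for_coverage(model, 0.99, idx, sim$genome)
#> [1] 35313                                 # picks for 99% expected coverage
```

Call a screen hit the way the plate assays do — a strain whose biolixiviant
ratio sits below the plate's lower IQR bound:

```r
plate <- data.frame(plate_id = 65, well = paste0("F", 1:8), row = "F",
                    col = 1:8, od590 = 1,
                    a435 = c(0.50, 0.49, 0.51, 0.50, 0.52, 0.48, 0.50, 0.23),
                    a545 = 0.8, occupied = TRUE, control = FALSE)
out <- call_plate_outliers(tb_score(plate))
round(unlist(out[c("q1", "q3", "lb", "ub")]), 4)
#>     q1     q3     lb     ub
#> 0.6094 0.6281 0.5812 0.6563
out$flags[out$flags$outlier != "none", ]
#>   plate_id well  value outlier
#> 8       65   F8 0.2875   below     # a much more acidic biolixiviant
```

Merge screen hit sets by inclusion–exclusion:

```r
m <- merge_screens(sprintf("g%03d", 1:282), sprintf("g%03d", c(1:60, 501:522)))
c(m$n_tb, m$n_bpb, m$n_both, m$n_union)
#> [1] 282  82  60 304
```

The `analysis/` directory holds numbered drivers
(`01_genome_and_sites.R` … `07_bioleaching.R`) that run the full chain at
collection scale and write tables under `results/`; each takes an optional
seed argument (`Rscript analysis/02_coverage_design.R 1`).

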