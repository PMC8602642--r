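small_cfg <- function(seed = 77, ...) {
  sim_config(seed = seed, n_genes = 40L, n_contigs = 4L,
             n_progenitor_picks = 800L, n_cc_plates = 4L, ...)
}

test_that("generated genomes are valid and every gene has at least seven sites", {
  sim <- generate_genome(small_cfg())
  expect_s3_class(sim$genome, "genome_annotation")
  expect_identical(nrow(sim$genome$genes), 40L)
  idx <- index_insertion_sites(sim$genome)
  expect_true(all(idx$per_gene_count >= 7L))
  expect_true(all(vapply(idx$sites, function(p) !is.unsorted(p, strictly = TRUE),
                         logical(1))))
})

test_that("a GC fraction incompatible with TA/AT sites is rejected", {
  expect_error(sim_config(seed = 1, gc = 1.0), "TA/AT")
  expect_error(sim_config(seed = 1, gc = 0.95), "TA/AT")
})

test_that("generators are pure functions of config and seed", {
  g1 <- generate_genome(small_cfg())
  g2 <- generate_genome(small_cfg())
  expect_identical(as.character(g1$genome$contigs), as.character(g2$genome$contigs))
  expect_identical(g1$genome$genes, g2$genome$genes)
  c1 <- generate_progenitor_catalog(g1$genome, small_cfg())
  c2 <- generate_progenitor_catalog(g2$genome, small_cfg())
  expect_identical(c1$catalog, c2$catalog)
  layout <- make_cc_layout(sprintf("s%02d", 1:50))
  r1 <- generate_plate_readouts(layout, small_cfg())
  r2 <- generate_plate_readouts(layout, small_cfg())
  expect_identical(r1$endpoint, r2$endpoint)
  expect_identical(r1$kinetics, r2$kinetics)
})

test_that("zero cross-contamination leaves every strain in one well", {
  sim <- generate_genome(small_cfg())
  pc <- generate_progenitor_catalog(sim$genome,
                                    small_cfg(cross_contamination = 0))
  expect_identical(anyDuplicated(pc$catalog$strain_id), 0L)
  expect_identical(nrow(pc$catalog), 800L)
  # wells fill in plate order, 94 usable wells per plate, B2/E7 never used
  expect_false(any(is_control_well(pc$catalog$row, pc$catalog$col)))
  expect_identical(max(pc$catalog$plate), 9L)   # ceiling(800 / 94)
})

test_that("cross-contamination adds duplicate wells at roughly the configured rate", {
  sim <- generate_genome(small_cfg())
  pc <- generate_progenitor_catalog(sim$genome,
                                    small_cfg(cross_contamination = 0.2))
  n_extra <- nrow(pc$catalog) - 800L
  expect_gt(n_extra, 800 * 0.2 - 3 * sqrt(800 * 0.2 * 0.8))
  expect_lt(n_extra, 800 * 0.2 + 3 * sqrt(800 * 0.2 * 0.8))
})

test_that("progenitor unique-gene yield falls inside the Monte Carlo prediction band", {
  cfg <- sim_config(seed = 31, n_genes = 200L, n_contigs = 4L,
                    n_progenitor_picks = 3000L)
  sim <- generate_genome(cfg)
  idx <- index_insertion_sites(sim$genome)
  pc <- generate_progenitor_catalog(sim$genome, cfg, idx)
  observed <- length(setdiff(unique(pc$truth$gene_id), "intergenic"))
  model <- pick_model("site-uniform", replicates = 300, seed = 91)
  cur <- simulate_pick_curve(idx, sim$genome, model, n_grid = 3000L)
  expect_gte(observed, cur$mean_unique - 2 * cur$sd_unique)
  expect_lte(observed, cur$mean_unique + 2 * cur$sd_unique)
})

test_that("null plates flag outliers at the IQR rule's null rate", {
  cfg <- sim_config(seed = 55)
  layout <- make_cc_layout(sprintf("s%04d", 1:(94 * 20)))
  ro <- generate_plate_readouts(layout, cfg)
  flagged <- 0L; total <- 0L
  for (p in unique(ro$endpoint$plate_id)) {
    sc <- tb_score(ro$endpoint[ro$endpoint$plate_id == p, ])
    out <- call_plate_outliers(sc)
    flagged <- flagged + sum(out$flags$outlier != "none")
    total <- total + nrow(out$flags)
  }
  rate <- flagged / total
  # empirical null rate of the 1.5 IQR rule for n = 94 Gaussian-like wells
  set.seed(56)
  oracle <- mean(replicate(400, {
    v <- rnorm(94)
    q <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    mean(v < q[1] - 1.5 * diff(q) | v > q[2] + 1.5 * diff(q))
  }))
  expect_lt(abs(rate - oracle), 0.01)
})

test_that("control wells carry no strain signal", {
  cfg <- small_cfg()
  layout <- make_cc_layout(sprintf("s%02d", 1:50))
  eff <- data.frame(strain_id = "s01", ph_shift = -0.5, rate_mult = 3,
                    growth_mult = 1)
  ro <- generate_plate_readouts(layout, cfg, eff)
  ctrl <- ro$endpoint[ro$endpoint$control, ]
  expect_true(all(ctrl$od590 < 0.05))
  expect_true(all(is.na(ro$truth$ph_true[ro$truth$well %in% ctrl$well &
                                           ro$truth$plate_id %in% ctrl$plate_id])))
  expect_error(generate_plate_readouts(
    layout, cfg, data.frame(strain_id = "ghost", ph_shift = 0,
                            rate_mult = 1, growth_mult = 1)),
    "absent from layout")
})

test_that("a strongly shifted strain with two wells is nearly always called", {
  hits <- 0L
  for (s in 1:10) {
    cfg <- sim_config(seed = 100 + s)
    strains <- sprintf("s%04d", 1:(94 * 4))
    strains[c(10, 200)] <- "planted"        # two wells on different plates
    layout <- make_cc_layout(strains)
    # >= 4 plate SDs of the TB ratio (null ratio sd ~ 0.033)
    eff <- data.frame(strain_id = "planted", ph_shift = -0.15,
                      rate_mult = 1, growth_mult = 1)
    ro <- generate_plate_readouts(layout, cfg, eff)
    flags <- do.call(rbind, lapply(unique(ro$endpoint$plate_id), function(p) {
      call_plate_outliers(tb_score(
        ro$endpoint[ro$endpoint$plate_id == p, ]))$flags
    }))
    sw <- layout[!is.na(layout$strain_id),
                 c("strain_id", "plate_id", "well")]
    hc <- call_hits(sw, flags)
    hits <- hits + hc$is_hit[hc$strain_id == "planted"]
  }
  expect_gte(hits / 10, 0.95)
})

test_that("noiseless bioleach fixtures recover the planted line exactly", {
  cfg <- small_cfg(ph_meas_sd = 0)
  strains <- data.frame(strain_id = sprintf("m%d", 1:6),
                        true_ph = seq(2.0, 3.0, length.out = 6),
                        n_reps = 3L)
  bl <- generate_bioleach_table(strains, cfg, noise_sd = 0)
  q <- quantify_leachate(bl$leachate,
                         stats::setNames(rep(100, 16), ree_panel()$element))
  fit <- ph_extraction_regression(
    data.frame(ph = bl$ph$ph, total_ree = q$total_ree))
  expect_equal(fit$slope, cfg$bioleach_slope, tolerance = 1e-6)
  expect_equal(fit$intercept, cfg$bioleach_intercept, tolerance = 1e-6)
  expect_equal(fit$correlation, -1, tolerance = 1e-9)
})

test_that("element composition of generated leachate matches the config vector", {
  cfg <- small_cfg()
  strains <- data.frame(strain_id = "m1", true_ph = 2.3, n_reps = 4L)
  bl <- generate_bioleach_table(strains, cfg)
  el <- as.matrix(bl$leachate[, ree_panel()$element])
  shares <- sweep(el, 1, rowSums(el), "/")
  for (i in seq_len(nrow(shares))) {
    expect_equal(unname(shares[i, ]),
                 unname(cfg$composition[ree_panel()$element]),
                 tolerance = 1e-9)
  }
})

test_that("low-leaching samples are routed to the 1/20 dilution branch", {
  cfg <- small_cfg(ph_meas_sd = 0)
  strains <- data.frame(strain_id = c("strong", "weak"),
                        true_ph = c(2.2, 4.7), n_reps = 3L)
  bl <- generate_bioleach_table(strains, cfg, noise_sd = 0)
  d <- tapply(bl$leachate$dilution_factor, bl$leachate$strain_id, unique)
  expect_equal(unname(d[["strong"]]), 200)
  expect_equal(unname(d[["weak"]]), 20)   # floored total below threshold
})
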