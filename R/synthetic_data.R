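#' Simulation configuration for synthetic pipeline inputs
#'
#' Bundles every tunable of the fixture generators, with defaults mirroring
#' the study conditions the pipeline is designed for: a ~3283-gene,
#' 61% GC multi-contig genome, a 49,256-pick progenitor collection, a
#' 185-plate condensed collection with B2/E7 no-bacteria controls, two
#' proxy-wild-type batch backgrounds, a linear thymol blue calibration
#' (pH = ratio + 1.8 over pH 2-3.4) and a negative linear pH-extraction
#' relation.
#'
#' @param seed Integer seed (mandatory; every generator is a pure function
#'   of config + seed).
#' @param n_genes Number of genes (default 3283).
#' @param gene_length_meanlog,gene_length_sdlog Log-normal gene-length
#'   parameters (median ~900 bp).
#' @param min_gene_length Floor on gene length in bp (default 150).
#' @param gc GC fraction (default 0.61). Values >= 0.9 are rejected: TA/AT
#'   sites cannot be guaranteed.
#' @param n_contigs Contigs to split the genome into (default 62).
#' @param intergenic_frac Fraction of the genome outside genes (default
#'   0.13).
#' @param n_progenitor_picks Mutants picked into the progenitor collection
#'   (default 49256).
#' @param cross_contamination Probability a progenitor strain also seeds a
#'   second well (default 0.05).
#' @param n_cc_plates Condensed-collection plates (default 185).
#' @param ph_baseline Wild-type endpoint biolixiviant pH (default 2.3).
#' @param ph_well_sd Per-well endpoint pH noise sd (default 0.03).
#' @param tb_slope,tb_intercept True thymol blue line pH = slope * ratio +
#'   intercept (defaults 1.0 and 1.8).
#' @param a545_base Baseline A545 absorbance (default 0.8).
#' @param abs_sd Absorbance noise sd (default 0.01).
#' @param od_mean_a,od_mean_b Saturated OD590 means of the two mating-batch
#'   backgrounds (defaults 1.3 and 0.9; set B is the lower-density batch).
#' @param od_sd OD noise sd (default 0.05).
#' @param a600_start Initial bromophenol blue A600 (default 1.0).
#' @param bpb_base_vod Baseline acidification rate per OD unit (1/min per
#'   OD; default 0.05).
#' @param kin_sd Per-read kinetic noise sd (default 0.008).
#' @param bioleach_intercept,bioleach_slope Linear pH-extraction relation
#'   total_ree = intercept + slope * pH (ppb; defaults 7600 and -2000, so a
#'   pH 2.3 biolixiviant leaches ~3000 ppb).
#' @param bioleach_floor Minimum leachable total (ppb; default 100).
#' @param bioleach_sd Replicate noise sd on total REE (default 120 ppb).
#' @param ph_meas_sd Direct pH-probe noise sd (default 0.02).
#' @param dilution_default,dilution_low Dilution factors (200; 20 for
#'   low-leaching samples).
#' @param low_total_threshold Undiluted total (ppb) below which the 1/20
#'   dilution branch is used (default 1000).
#' @param composition Named per-element fraction of total REE (must sum to
#'   1); default is a Y/Eu-rich lamp-phosphor-like profile.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed,
                       n_genes = 3283L,
                       gene_length_meanlog = log(900),
                       gene_length_sdlog = 0.55,
                       min_gene_length = 150L,
                       gc = 0.61,
                       n_contigs = 62L,
                       intergenic_frac = 0.13,
                       n_progenitor_picks = 49256L,
                       cross_contamination = 0.05,
                       n_cc_plates = 185L,
                       ph_baseline = 2.3,
                       ph_well_sd = 0.03,
                       tb_slope = 1.0,
                       tb_intercept = 1.8,
                       a545_base = 0.8,
                       abs_sd = 0.01,
                       od_mean_a = 1.3,
                       od_mean_b = 0.9,
                       od_sd = 0.05,
                       a600_start = 1.0,
                       bpb_base_vod = 0.05,
                       kin_sd = 0.008,
                       bioleach_intercept = 7600,
                       bioleach_slope = -2000,
                       bioleach_floor = 100,
                       bioleach_sd = 120,
                       ph_meas_sd = 0.02,
                       dilution_default = 200,
                       dilution_low = 20,
                       low_total_threshold = 1000,
                       composition = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  if (gc >= 0.9) {
    stop("GC fraction ", gc, " rejected: cannot guarantee TA/AT sites")
  }
  if (gc < 0 || intergenic_frac < 0 || intergenic_frac >= 1 ||
      cross_contamination < 0 || cross_contamination > 1) {
    stop("rates/fractions out of range")
  }
  if (is.null(composition)) {
    composition <- c(Sc = 0.001, Y = 0.55, La = 0.12, Ce = 0.10, Pr = 0.01,
                     Nd = 0.015, Sm = 0.004, Eu = 0.07, Gd = 0.03,
                     Tb = 0.04, Dy = 0.005, Ho = 0.002, Er = 0.002,
                     Tm = 0.001, Yb = 0.002, Lu = 0.048)
  }
  if (!setequal(names(composition), ree_panel()$element)) {
    stop("composition must cover the 16-element panel")
  }
  if (abs(sum(composition) - 1) > 1e-9) stop("composition must sum to 1")
  structure(as.list(environment()), class = "sim_config")
}

# count TA/AT dinucleotides in a character base vector over [from, to]
count_ta_at <- function(bases, from, to) {
  if (to - from < 1L) return(0L)
  x1 <- bases[from:(to - 1L)]
  x2 <- bases[(from + 1L):to]
  sum((x1 == "T" & x2 == "A") | (x1 == "A" & x2 == "T"))
}

#' Generate a synthetic annotated genome
#'
#' Random multi-contig sequence at the target GC with non-overlapping genes
#' of log-normal length; every gene is guaranteed at least seven TA/AT
#' insertion sites by per-gene rejection resampling, mirroring the empirical
#' floor that makes every gene disruptable.
#'
#' @param config A [sim_config()].
#' @return List: `genome` (a [genome_annotation()]) and `truth` (gene
#'   lengths and placement).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  base_probs <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
                  G = config$gc / 2, T = (1 - config$gc) / 2)
  lens <- pmax(config$min_gene_length,
               round(stats::rlnorm(config$n_genes,
                                   config$gene_length_meanlog,
                                   config$gene_length_sdlog)))
  genome_size <- ceiling(sum(lens) / (1 - config$intergenic_frac))
  intergenic_total <- genome_size - sum(lens)
  # split genes over contigs in contiguous blocks
  ctg_of_gene <- sort(rep_len(seq_len(config$n_contigs), config$n_genes))
  contig_seqs <- character(config$n_contigs)
  gene_rows <- vector("list", config$n_contigs)
  letters4 <- names(base_probs)
  gene_counter <- 0L
  for (ci in seq_len(config$n_contigs)) {
    gi <- which(ctg_of_gene == ci)
    n_g <- length(gi)
    inter_ci <- round(intergenic_total * n_g / config$n_genes)
    # n_g + 1 gaps, each >= 2 bp
    gap_w <- as.vector(stats::rmultinom(1, max(inter_ci - 2L * (n_g + 1L), 0L),
                                        rep(1, n_g + 1L))) + 2L
    ctg_len <- sum(lens[gi]) + sum(gap_w)
    bases <- sample(letters4, ctg_len, replace = TRUE, prob = base_probs)
    pos <- 0L
    starts <- integer(n_g); ends <- integer(n_g)
    for (j in seq_len(n_g)) {
      pos <- pos + gap_w[j]
      starts[j] <- pos + 1L
      ends[j] <- pos + lens[gi[j]]
      # rejection: resample gene subsequence until >= 7 TA/AT sites
      while (count_ta_at(bases, starts[j], ends[j]) < 7L) {
        bases[starts[j]:ends[j]] <-
          sample(letters4, lens[gi[j]], replace = TRUE, prob = base_probs)
      }
      pos <- ends[j]
    }
    contig_seqs[ci] <- paste(bases, collapse = "")
    gene_rows[[ci]] <- data.frame(
      gene_id = sprintf("GO_%04d", gene_counter + seq_len(n_g)),
      contig_id = sprintf("contig%02d", ci),
      start = starts, end = ends,
      strand = sample(c("+", "-"), n_g, replace = TRUE),
      product = NA_character_,
      stringsAsFactors = FALSE
    )
    gene_counter <- gene_counter + n_g
  }
  names(contig_seqs) <- sprintf("contig%02d", seq_len(config$n_contigs))
  genes <- do.call(rbind, gene_rows)
  genome <- genome_annotation(contig_seqs, genes)
  list(genome = genome,
       truth = list(gene_lengths = lens, genome_size = genome_size))
}

# usable (non-control) wells of an 8x12 plate, in row-major order
usable_wells <- function() {
  w <- expand.grid(col = 1:12, row = WELL_ROWS, stringsAsFactors = FALSE)
  w <- w[, c("row", "col")]
  w <- w[!is_control_well(w$row, w$col), ]
  rownames(w) <- NULL
  w
}

#' Generate a synthetic progenitor catalog
#'
#' Draws picks site-uniformly from the genome's TA/AT sites, assigns them to
#' wells in plate order (94 usable wells per plate; B2/E7 reserved), and adds
#' cross-contamination by duplicating strains into random extra wells at the
#' configured rate. Address probabilities are sampled with an ambiguous
#' (< 0.5) tail.
#'
#' @param genome A [genome_annotation()].
#' @param config A [sim_config()].
#' @param index Optional precomputed [index_insertion_sites()].
#' @return List: `catalog` (data.frame strain_id, contig, position, gene_id,
#'   plate, row, col, probability) and `truth` (true single-well addresses).
#' @export
generate_progenitor_catalog <- function(genome, config, index = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(index)) index <- index_insertion_sites(genome)
  set.seed(config$seed + 1L)
  n <- config$n_progenitor_picks
  site_contig <- rep(names(index$sites), lengths(index$sites))
  site_pos <- unlist(index$sites, use.names = FALSE)
  draws <- sample.int(length(site_pos), n, replace = TRUE)
  g <- genome$genes
  gene_id <- rep("intergenic", n)
  for (ctg in unique(g$contig_id)) {
    gi <- which(g$contig_id == ctg)
    di <- which(site_contig[draws] == ctg)
    if (length(di) == 0L) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = site_pos[draws[di]], width = 1L),
      IRanges::IRanges(start = g$start[gi],
                       end = pmax(g$start[gi] - 1L, g$end[gi] - 1L)),
      select = "first")
    found <- !is.na(hits)
    gene_id[di[found]] <- g$gene_id[gi[hits[found]]]
  }
  uw <- usable_wells()
  wells_per_plate <- nrow(uw)                     # 94
  idx0 <- seq_len(n) - 1L
  plate <- idx0 %/% wells_per_plate + 1L
  slot <- idx0 %% wells_per_plate + 1L
  u <- stats::runif(n)
  prob <- ifelse(u < 0.85, stats::runif(n, 0.7, 1.0),
                 stats::runif(n, 0.2, 0.7))
  catalog <- data.frame(
    strain_id = sprintf("S%05d", seq_len(n)),
    contig = site_contig[draws],
    position = site_pos[draws],
    gene_id = gene_id,
    plate = plate,
    row = uw$row[slot],
    col = uw$col[slot],
    probability = prob,
    stringsAsFactors = FALSE
  )
  truth <- catalog[, c("strain_id", "plate", "row", "col", "gene_id")]
  if (config$cross_contamination > 0) {
    dup <- which(stats::runif(n) < config$cross_contamination)
    if (length(dup) > 0L) {
      target <- sample.int(n, length(dup), replace = TRUE)
      extra <- catalog[dup, ]
      extra$plate <- catalog$plate[target]
      extra$row <- catalog$row[target]
      extra$col <- catalog$col[target]
      catalog <- rbind(catalog, extra)
      rownames(catalog) <- NULL
    }
  }
  list(catalog = catalog, truth = truth)
}

#' Lay out strains on condensed-collection plates
#'
#' @param strain_ids Strains to array, filled in plate order over the 94
#'   usable wells per plate; B2/E7 emitted as no-bacteria controls.
#' @return data.frame: plate_id, well, row, col, strain_id (NA for controls
#'   and empties), occupied, control.
#' @export
make_cc_layout <- function(strain_ids) {
  uw <- usable_wells()
  wpp <- nrow(uw)
  n_plates <- ceiling(length(strain_ids) / wpp)
  all_wells <- expand.grid(col = 1:12, row = WELL_ROWS,
                           plate_id = seq_len(n_plates),
                           stringsAsFactors = FALSE)
  all_wells <- all_wells[, c("plate_id", "row", "col")]
  all_wells$well <- paste0(all_wells$row, all_wells$col)
  all_wells$control <- is_control_well(all_wells$row, all_wells$col)
  all_wells$strain_id <- NA_character_
  usable_idx <- which(!all_wells$control)
  all_wells$strain_id[usable_idx[seq_along(strain_ids)]] <- strain_ids
  all_wells$occupied <- !is.na(all_wells$strain_id)
  all_wells[, c("plate_id", "well", "row", "col", "strain_id", "occupied",
                "control")]
}

#' Generate synthetic plate readouts for the dual dye screens
#'
#' Per occupied well, a true endpoint pH (batch baseline + the strain's
#' planted shift + well noise) is pushed through the true thymol blue line
#' into A435/A545 absorbances with Gaussian noise; a seven-read A600 series
#' declines at a rate scaled by the strain's rate multiplier and its culture
#' density; OD590 is the batch mean times the growth multiplier. Control
#' wells carry blank signatures (no strain signal).
#'
#' @param layout A [make_cc_layout()] table.
#' @param config A [sim_config()].
#' @param effects data.frame `strain_id`, `ph_shift`, `rate_mult`,
#'   `growth_mult`; strains not listed are null (shift 0, multipliers 1).
#'   Every listed strain must be on the layout.
#' @return List: `endpoint` (plate_id, well, row, col, od590, a435, a545,
#'   occupied, control), `kinetics` (plate_id, well, t_min, a600), `truth`
#'   (per-well true pH, V and OD).
#' @export
generate_plate_readouts <- function(layout, config, effects = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(effects)) {
    effects <- data.frame(strain_id = character(0), ph_shift = numeric(0),
                          rate_mult = numeric(0), growth_mult = numeric(0))
  }
  unknown <- setdiff(effects$strain_id,
                     layout$strain_id[!is.na(layout$strain_id)])
  if (length(unknown) > 0L) {
    stop("effect-table strains absent from layout: ",
         paste(unknown, collapse = ", "))
  }
  set.seed(config$seed + 2L)
  n <- nrow(layout)
  m <- match(layout$strain_id, effects$strain_id)
  ph_shift <- ifelse(is.na(m), 0, effects$ph_shift[m])
  rate_mult <- ifelse(is.na(m), 1, effects$rate_mult[m])
  growth_mult <- ifelse(is.na(m), 1, effects$growth_mult[m])
  batch <- assign_pwt_set(pmin(layout$plate_id, 185L))
  od_mean <- ifelse(batch == "A", config$od_mean_a, config$od_mean_b)
  od <- pmax(0.02, od_mean * growth_mult + stats::rnorm(n, 0, config$od_sd))
  ph_true <- config$ph_baseline + ph_shift +
    stats::rnorm(n, 0, config$ph_well_sd)
  ratio_true <- (ph_true - config$tb_intercept) / config$tb_slope
  a545 <- config$a545_base + stats::rnorm(n, 0, config$abs_sd)
  a435 <- ratio_true * a545 + stats::rnorm(n, 0, config$abs_sd)
  v_true <- config$bpb_base_vod * rate_mult * od
  # blank signatures for controls and empty wells
  blank <- !layout$occupied
  od[blank] <- pmax(0.005, stats::rnorm(sum(blank), 0.02, 0.005))
  a545[blank] <- config$a545_base + stats::rnorm(sum(blank), 0, config$abs_sd)
  a435[blank] <- 1.55 * a545[blank] + stats::rnorm(sum(blank), 0,
                                                   config$abs_sd)
  v_true[blank] <- 0
  ph_true[blank] <- NA_real_
  endpoint <- data.frame(plate_id = layout$plate_id, well = layout$well,
                         row = layout$row, col = layout$col,
                         od590 = od, a435 = a435, a545 = a545,
                         occupied = layout$occupied,
                         control = layout$control,
                         stringsAsFactors = FALSE)
  times <- 0:6
  kin <- data.frame(
    plate_id = rep(layout$plate_id, each = length(times)),
    well = rep(layout$well, each = length(times)),
    t_min = rep(times, times = n),
    a600 = config$a600_start - rep(v_true, each = length(times)) *
      rep(times, times = n) +
      stats::rnorm(n * length(times), 0, config$kin_sd),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(plate_id = layout$plate_id, well = layout$well,
                      strain_id = layout$strain_id, ph_true = ph_true,
                      v_true = v_true, od_true = od,
                      stringsAsFactors = FALSE)
  list(endpoint = endpoint, kinetics = kin, truth = truth)
}

#' Generate a synthetic leachate concentration table
#'
#' Total leached REE follows the planted linear pH relation
#' `total = intercept + slope * pH` (slope negative), floored at a small
#' residual, with replicate noise; the total is split across the 16-element
#' panel by the configured composition vector and divided by the dilution
#' factor to give as-measured concentrations. Samples whose undiluted total
#' falls below the quantitation threshold are routed to the 1/20 dilution
#' branch.
#'
#' @param strains data.frame: `strain_id`, `true_ph`, `n_reps`.
#' @param config A [sim_config()].
#' @param noise_sd Override for the replicate noise sd (default
#'   `config$bioleach_sd`; set 0 for exact recovery checks).
#' @return List: `leachate` (sample_id, strain_id, replicate,
#'   dilution_factor + 16 element columns, as-measured ppb), `ph`
#'   (sample_id, strain_id, replicate, ph), `truth` (planted line and
#'   per-sample true totals).
#' @export
generate_bioleach_table <- function(strains, config, noise_sd = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(noise_sd)) noise_sd <- config$bioleach_sd
  set.seed(config$seed + 3L)
  rows <- strains[rep(seq_len(nrow(strains)), strains$n_reps), ]
  rows$replicate <- unlist(lapply(strains$n_reps, seq_len))
  n <- nrow(rows)
  total_true <- pmax(config$bioleach_floor,
                     config$bioleach_intercept +
                       config$bioleach_slope * rows$true_ph)
  total <- pmax(0, total_true + stats::rnorm(n, 0, noise_sd))
  dilution <- ifelse(total < config$low_total_threshold,
                     config$dilution_low, config$dilution_default)
  comp <- config$composition[ree_panel()$element]
  element_meas <- (total %o% comp) / dilution
  colnames(element_meas) <- names(comp)
  leachate <- data.frame(
    sample_id = sprintf("%s_r%d", rows$strain_id, rows$replicate),
    strain_id = rows$strain_id,
    replicate = rows$replicate,
    dilution_factor = dilution,
    stringsAsFactors = FALSE
  )
  leachate <- cbind(leachate, as.data.frame(element_meas))
  ph <- data.frame(sample_id = leachate$sample_id,
                   strain_id = rows$strain_id,
                   replicate = rows$replicate,
                   ph = rows$true_ph + stats::rnorm(n, 0, config$ph_meas_sd),
                   stringsAsFactors = FALSE)
  rownames(leachate) <- NULL
  list(leachate = leachate, ph = ph,
       truth = list(intercept = config$bioleach_intercept,
                    slope = config$bioleach_slope,
                    total_true = total_true))
}

#' Write a synthetic genome to FASTA + GFF3
#'
#' @param genome A [genome_annotation()].
#' @param fasta,gff Output paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_genome_files <- function(genome, fasta, gff) {
  Biostrings::writeXStringSet(genome$contigs, fasta)
  g <- genome$genes
  gr <- GenomicRanges::GRanges(
    seqnames = g$contig_id,
    ranges = IRanges::IRanges(start = g$start, end = g$end),
    strand = g$strand,
    type = "CDS",
    ID = g$gene_id,
    source = "koscreen",
    phase = 0L
  )
  rtracklayer::export(gr, gff, format = "gff3")
  invisible(list(fasta = fasta, gff = gff))
}
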