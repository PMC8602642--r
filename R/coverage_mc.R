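#' Specify a mutant-picking model for saturation simulation
#'
#' Two modes: `"site-uniform"` draws insertions uniformly over every TA/AT
#' site in the genome (intergenic sites included; an intergenic pick consumes
#' a draw and covers nothing, matching colony-level picking), and
#' `"gene-weights"` draws from explicit per-gene probabilities plus an
#' intergenic mass, for reproducing curves when only per-gene site counts are
#' available.
#'
#' @param mode `"site-uniform"` or `"gene-weights"`.
#' @param weights Named per-gene probabilities (gene-weights mode).
#' @param intergenic_mass Probability that a pick hits no gene (gene-weights
#'   mode). `sum(weights) + intergenic_mass` must equal 1.
#' @param replicates Monte Carlo replicates (default 1000).
#' @param seed Integer seed; required for pipeline reproducibility.
#' @return An object of class `pick_model`.
#' @export
pick_model <- function(mode = c("site-uniform", "gene-weights"),
                       weights = NULL, intergenic_mass = 0,
                       replicates = 1000L, seed) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("seed is required")
  if (replicates < 1L) stop("replicates must be >= 1")
  if (mode == "gene-weights") {
    if (is.null(weights) || is.null(names(weights))) {
      stop("gene-weights mode needs named weights")
    }
    if (any(weights < 0) || intergenic_mass < 0) stop("negative probability")
    if (abs(sum(weights) + intergenic_mass - 1) > 1e-12) {
      stop("weights + intergenic_mass must sum to 1")
    }
  }
  structure(list(mode = mode, weights = weights,
                 intergenic_mass = intergenic_mass,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "pick_model")
}

# Per-gene pick probabilities implied by a model (+ intergenic mass).
model_probs <- function(model, index = NULL, genome = NULL) {
  if (model$mode == "gene-weights") {
    return(list(p = model$weights, intergenic = model$intergenic_mass))
  }
  stopifnot(!is.null(index), !is.null(genome))
  if (index$total_sites <= 0L) stop("site-uniform mode needs total_sites > 0")
  p <- index$per_gene_count / index$total_sites
  list(p = p, intergenic = max(0, 1 - sum(p)))
}

#' Closed-form expected unique-gene coverage
#'
#' The expectation of the number of genes hit at least once after `n` i.i.d.
#' picks is `sum_i (1 - (1 - p_i)^n)`.
#'
#' @param model A [pick_model()].
#' @param n_picked Vector of pick counts.
#' @param index,genome Needed in site-uniform mode to derive `p_i = s_i / S`.
#' @return Numeric vector of expected unique-gene counts.
#' @export
expected_unique_genes <- function(model, n_picked, index = NULL,
                                  genome = NULL) {
  p <- model_probs(model, index, genome)$p
  vapply(n_picked, function(n) sum(1 - (1 - p)^n), numeric(1))
}

# First-occurrence counting: given hit positions (draw index) and gene codes
# (0 = intergenic), unique genes covered by the first n draws for each n in
# n_grid.
unique_at_grid <- function(pos, gene, n_grid) {
  keep <- gene > 0L
  pos <- pos[keep]; gene <- gene[keep]
  o <- order(pos)
  pos <- pos[o]; gene <- gene[o]
  first <- !duplicated(gene)
  findInterval(n_grid, sort(pos[first]))
}

#' Simulate a collection-saturation (coverage) curve
#'
#' Per replicate, draws `N` insertions i.i.d. from the pick model and counts
#' genes hit at least once, for each `N` on the grid. The curve reports the
#' mean and standard deviation over replicates; the plotted band is mean
#' +/- 2 sd.
#'
#' @param index An [index_insertion_sites()] result (site-uniform mode).
#' @param genome The matching [genome_annotation()].
#' @param model A [pick_model()].
#' @param n_grid Increasing vector of pick counts.
#' @return A `coverage_curve` data.frame: `n_picked`, `mean_unique`,
#'   `sd_unique`, with attribute `replicates`.
#' @export
simulate_pick_curve <- function(index, genome, model, n_grid) {
  if (is.unsorted(n_grid, strictly = TRUE)) stop("n_grid must be increasing")
  if (any(n_grid < 0)) stop("n_grid values must be >= 0")
  if (!is.null(genome) && nrow(genome$genes) == 0L) stop("empty gene set")
  pr <- model_probs(model, index, genome)
  n_max <- max(n_grid)
  set.seed(model$seed)
  if (model$mode == "site-uniform") {
    # map each site to the gene(s) containing it, once
    g <- genome$genes
    site_contig <- rep(names(index$sites), lengths(index$sites))
    site_pos <- unlist(index$sites, use.names = FALSE)
    gene_code <- integer(length(site_pos))      # 0 = intergenic
    extra <- list()                             # rare multi-overlap sites
    for (ctg in unique(g$contig_id)) {
      gi <- which(g$contig_id == ctg)
      si <- which(site_contig == ctg)
      if (length(si) == 0L) next
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(start = site_pos[si], width = 1L),
        IRanges::IRanges(start = g$start[gi],
                         end = pmax(g$start[gi] - 1L, g$end[gi] - 1L)))
      qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
      firsts <- !duplicated(qh)
      gene_code[si[qh[firsts]]] <- gi[sh[firsts]]
      if (any(!firsts)) {
        for (k in which(!firsts)) {
          key <- as.character(si[qh[k]])
          extra[[key]] <- c(extra[[key]], gi[sh[k]])
        }
      }
    }
    S <- length(site_pos)
    draw_genes <- function() {
      draws <- sample.int(S, n_max, replace = TRUE)
      pos <- seq_len(n_max); gene <- gene_code[draws]
      if (length(extra) > 0L) {
        hit_extra <- which(as.character(draws) %in% names(extra))
        if (length(hit_extra) > 0L) {
          add <- lapply(hit_extra, function(i) extra[[as.character(draws[i])]])
          pos <- c(pos, rep(hit_extra, lengths(add)))
          gene <- c(gene, unlist(add))
        }
      }
      list(pos = pos, gene = gene)
    }
  } else {
    p <- pr$p
    cum <- cumsum(c(p, pr$intergenic))
    draw_genes <- function() {
      u <- stats::runif(n_max) * cum[length(cum)]
      idx <- findInterval(u, cum) + 1L
      idx[idx > length(p)] <- 0L             # intergenic
      list(pos = seq_len(n_max), gene = idx)
    }
  }
  acc <- matrix(0, nrow = model$replicates, ncol = length(n_grid))
  for (r in seq_len(model$replicates)) {
    d <- draw_genes()
    acc[r, ] <- unique_at_grid(d$pos, d$gene, n_grid)
  }
  out <- data.frame(n_picked = n_grid,
                    mean_unique = colMeans(acc),
                    sd_unique = apply(acc, 2, stats::sd))
  attr(out, "replicates") <- model$replicates
  class(out) <- c("coverage_curve", "data.frame")
  out
}

#' Simulate depletion of a sequenced progenitor catalog
#'
#' Draws strains without replacement from the catalog and counts unique
#' disrupted genes; at `n` equal to the catalog size the count is exact and
#' the sd is 0.
#'
#' @param catalog A progenitor catalog data.frame with columns `strain_id`
#'   and `gene_id` (`"intergenic"` entries cover nothing).
#' @param replicates Monte Carlo replicates.
#' @param seed Integer seed.
#' @param n_grid Increasing vector of draw counts, max <= number of strains.
#' @return A `coverage_curve` data.frame as in [simulate_pick_curve()].
#' @export
simulate_depletion_curve <- function(catalog, replicates, seed, n_grid) {
  strains <- unique(catalog[, c("strain_id", "gene_id")])
  strains <- strains[!duplicated(strains$strain_id), ]
  n_strains <- nrow(strains)
  if (max(n_grid) > n_strains) stop("n_grid exceeds catalog size")
  if (is.unsorted(n_grid)) stop("n_grid must be increasing")
  gene_code <- match(strains$gene_id,
                     setdiff(unique(strains$gene_id), "intergenic"))
  gene_code[is.na(gene_code)] <- 0L
  set.seed(as.integer(seed))
  acc <- matrix(0, nrow = replicates, ncol = length(n_grid))
  for (r in seq_len(replicates)) {
    perm <- sample.int(n_strains)
    acc[r, ] <- unique_at_grid(seq_len(n_strains), gene_code[perm], n_grid)
  }
  out <- data.frame(n_picked = n_grid,
                    mean_unique = colMeans(acc),
                    sd_unique = apply(acc, 2, stats::sd))
  attr(out, "replicates") <- replicates
  class(out) <- c("coverage_curve", "data.frame")
  out
}

#' Minimum picks for a target expected coverage fraction
#'
#' Smallest `N` with closed-form expected coverage
#' `sum_i(1 - (1 - p_i)^N) / G >= q`, found by doubling then bisection.
#'
#' @param model A [pick_model()].
#' @param q Target coverage fraction in (0, 1).
#' @param index,genome Needed in site-uniform mode.
#' @return Integer pick count.
#' @export
min_picks_for_coverage <- function(model, q, index = NULL, genome = NULL) {
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  p <- model_probs(model, index, genome)$p
  G <- length(p)
  attainable <- sum(p > 0) / G
  if (attainable < q) {
    stop(sprintf("coverage %g unattainable; maximum attainable is %g",
                 q, attainable))
  }
  cov_at <- function(n) sum(1 - (1 - p)^n) / G
  hi <- 1L
  while (cov_at(hi) < q) hi <- hi * 2L
  lo <- max(1L, hi %/% 2L)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (cov_at(mid) >= q) hi <- mid else lo <- mid + 1L
  }
  hi
}

#' Write a coverage curve as CSV
#'
#' @param curve A `coverage_curve`.
#' @param path Output CSV path (columns n_picked, mean_unique, sd_unique).
#' @return Invisibly, `path`.
#' @export
write_coverage_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve)[, c("n_picked", "mean_unique",
                                            "sd_unique")],
                   path, row.names = FALSE)
  invisible(path)
}
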