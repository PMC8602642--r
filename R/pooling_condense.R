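#' Design Sudoku-style combinatorial pools over a plate collection
#'
#' Plates are virtually arranged row-major on a `grid[1] x grid[2]` grid
#' (default 20 x 27, holding up to 540 plates) and pooled along four axes:
#' plate-grid row, plate-grid column, well row (A-H) and well column (1-12).
#' Every well belongs to exactly one pool per axis, giving
#' `grid[1] + grid[2] + 8 + 12` pools.
#'
#' @param n_plates Number of plates (<= grid capacity).
#' @param grid Integer pair: plate-grid rows, columns.
#' @return An object of class `pool_design`.
#' @export
design_pools <- function(n_plates, grid = c(20L, 27L)) {
  if (n_plates > grid[1] * grid[2]) {
    stop(sprintf("%d plates exceed the %dx%d grid capacity",
                 n_plates, grid[1], grid[2]))
  }
  if (n_plates < 1L) stop("need at least one plate")
  structure(list(n_plates = as.integer(n_plates),
                 grid_rows = as.integer(grid[1]),
                 grid_cols = as.integer(grid[2]),
                 plate_rows = 8L, plate_cols = 12L),
            class = "pool_design")
}

#' @export
print.pool_design <- function(x, ...) {
  cat(sprintf(
    "pool_design: %d plates on a %dx%d grid; %d pools (4 axes)\n",
    x$n_plates, x$grid_rows, x$grid_cols, n_pools(x)))
  invisible(x)
}

#' Number of pools in a design
#' @param design A [design_pools()] result.
#' @return Integer pool count (one pool per axis value).
#' @export
n_pools <- function(design) {
  design$grid_rows + design$grid_cols + design$plate_rows + design$plate_cols
}

WELL_ROWS <- LETTERS[1:8]

# grid cell of a plate (row-major layout)
plate_grid_cell <- function(design, plate) {
  list(row = (plate - 1L) %/% design$grid_cols + 1L,
       col = (plate - 1L) %% design$grid_cols + 1L)
}

#' Pool ids of a well address
#'
#' @param design A [design_pools()] result.
#' @param plate,row,col Well address: plate number, row letter (A-H), column
#'   (1-12). Vectorized.
#' @return data.frame with one pool id column per axis (`pgr`, `pgc`,
#'   `wrow`, `wcol`).
#' @export
address_pools <- function(design, plate, row, col) {
  if (any(plate < 1L | plate > design$n_plates)) {
    stop("plate outside design")
  }
  if (any(!row %in% WELL_ROWS) || any(col < 1L | col > design$plate_cols)) {
    stop("well address outside the 8x12 plate")
  }
  cell <- plate_grid_cell(design, plate)
  data.frame(pgr = sprintf("PGR%02d", cell$row),
             pgc = sprintf("PGC%02d", cell$col),
             wrow = paste0("ROW_", row),
             wcol = sprintf("COL%02d", col),
             stringsAsFactors = FALSE)
}

#' Enumerate every well of a design with its pool memberships
#'
#' @param design A [design_pools()] result.
#' @return data.frame: plate, row, col, pgr, pgc, wrow, wcol.
#' @export
enumerate_wells <- function(design) {
  wells <- expand.grid(col = seq_len(design$plate_cols),
                       row = WELL_ROWS,
                       plate = seq_len(design$n_plates),
                       stringsAsFactors = FALSE)
  wells <- wells[, c("plate", "row", "col")]
  cbind(wells, address_pools(design, wells$plate, wells$row, wells$col))
}

#' Simulate combinatorial pooling of a progenitor catalog
#'
#' A strain appears in a pool iff one of its wells belongs to that pool.
#' Presence/absence is noiseless by default; an optional per-(strain, pool)
#' Bernoulli dropout models missed reads.
#'
#' @param catalog data.frame with columns `strain_id`, `plate`, `row`, `col`.
#' @param design A [design_pools()] result.
#' @param dropout Per-membership dropout probability (default 0).
#' @param seed Seed used when `dropout > 0`.
#' @return Named list: pool id -> character vector of strain ids.
#' @export
simulate_pooling <- function(catalog, design, dropout = 0, seed = 1L) {
  all_pools <- c(sprintf("PGR%02d", seq_len(design$grid_rows)),
                 sprintf("PGC%02d", seq_len(design$grid_cols)),
                 paste0("ROW_", WELL_ROWS),
                 sprintf("COL%02d", seq_len(design$plate_cols)))
  pools <- stats::setNames(vector("list", length(all_pools)), all_pools)
  if (nrow(catalog) == 0L) {
    return(lapply(pools, function(x) character(0)))
  }
  pm <- address_pools(design, catalog$plate, catalog$row, catalog$col)
  member <- data.frame(
    strain_id = rep(catalog$strain_id, 4L),
    pool = c(pm$pgr, pm$pgc, pm$wrow, pm$wcol),
    stringsAsFactors = FALSE
  )
  member <- unique(member)
  if (dropout > 0) {
    set.seed(as.integer(seed))
    member <- member[stats::runif(nrow(member)) >= dropout, ]
  }
  got <- split(member$strain_id, member$pool)
  for (id in names(got)) pools[[id]] <- sort(unique(got[[id]]))
  lapply(pools, function(x) if (is.null(x)) character(0) else x)
}

#' Naive pool-intersection address deconvolution
#'
#' Candidate addresses for a strain are the Cartesian product of its observed
#' coordinates on the four axes, intersected with occupied plate-grid cells.
#' A strain observed in exactly one pool per axis resolves uniquely; a strain
#' absent from some axis is flagged unlocatable rather than guessed. (The
#' Bayesian scoring used for real sequencing data is a separate method and
#' out of scope here.)
#'
#' @param pools Named list pool id -> strain ids, as from
#'   [simulate_pooling()].
#' @param design A [design_pools()] result.
#' @return List with `candidates` (data.frame: strain_id, plate, row, col)
#'   and `unlocatable` (character vector of strain ids).
#' @export
deconvolve_naive <- function(pools, design) {
  strains <- sort(unique(unlist(pools, use.names = FALSE)))
  axis_of <- function(prefix) {
    ids <- grep(prefix, names(pools), value = TRUE)
    stats::setNames(lapply(ids, function(i) pools[[i]]), ids)
  }
  axes <- list(pgr = axis_of("^PGR"), pgc = axis_of("^PGC"),
               wrow = axis_of("^ROW"), wcol = axis_of("^COL"))
  res <- vector("list", length(strains))
  unloc <- character(0)
  for (i in seq_along(strains)) {
    s <- strains[i]
    obs <- lapply(axes, function(ax)
      names(ax)[vapply(ax, function(v) s %in% v, logical(1))])
    if (any(lengths(obs) == 0L)) {
      unloc <- c(unloc, s)
      next
    }
    cand <- expand.grid(pgr = obs$pgr, pgc = obs$pgc,
                        wrow = obs$wrow, wcol = obs$wcol,
                        stringsAsFactors = FALSE)
    gr <- as.integer(sub("PGR", "", cand$pgr))
    gc <- as.integer(sub("PGC", "", cand$pgc))
    plate <- (gr - 1L) * design$grid_cols + gc
    keep <- plate <= design$n_plates      # occupied grid cells only
    if (!any(keep)) {
      unloc <- c(unloc, s)
      next
    }
    res[[i]] <- data.frame(
      strain_id = s,
      plate = plate[keep],
      row = sub("ROW_", "", cand$wrow[keep]),
      col = as.integer(sub("COL", "", cand$wcol[keep])),
      stringsAsFactors = FALSE
    )
  }
  list(candidates = do.call(rbind, res), unlocatable = unloc)
}

#' Curate a condensed-collection picklist
#'
#' For every disrupted gene, candidate strains are ranked by proximity of the
#' insertion to the translation start (ascending) and then by address
#' probability (descending). The best strain is selected, plus a second where
#' available, plus a third when both selections are ambiguous (address
#' probability below `ambiguity_threshold`). Colonies to pick per selected
#' strain are twice the predicted number of co-occupying strains in its
#' source well, capped at ten.
#'
#' @param catalog data.frame: `strain_id`, `gene_id`, `position` (insertion
#'   coordinate), `plate`, `row`, `col`, `probability`.
#' @param genome The [genome_annotation()] supplying gene coordinates and
#'   strands.
#' @param ambiguity_threshold Address probability below which a location is
#'   ambiguous (default 0.5).
#' @return data.frame: gene_id, rank, strain_id, dist_to_start, probability,
#'   colonies_to_pick.
#' @export
curate_condensed <- function(catalog, genome, ambiguity_threshold = 0.5) {
  if (nrow(catalog) == 0L) stop("catalog is empty")
  cat_g <- catalog[catalog$gene_id != "intergenic", , drop = FALSE]
  g <- genome$genes
  m <- match(cat_g$gene_id, g$gene_id)
  if (anyNA(m)) stop("catalog gene ids absent from annotation")
  dist <- ifelse(g$strand[m] == "+",
                 cat_g$position - g$start[m],
                 g$end[m] - cat_g$position)
  cat_g$dist_to_start <- dist
  # predicted strains per source well
  well_key <- paste(catalog$plate, catalog$row, catalog$col, sep = ":")
  occ <- table(well_key)
  cat_g$well_occupancy <- as.integer(
    occ[paste(cat_g$plate, cat_g$row, cat_g$col, sep = ":")])
  picks <- lapply(split(cat_g, cat_g$gene_id), function(gg) {
    gg <- gg[order(gg$dist_to_start, -gg$probability, gg$strain_id), ]
    n_take <- min(2L, nrow(gg))
    sel <- gg[seq_len(n_take), ]
    if (n_take == 2L && all(sel$probability < ambiguity_threshold) &&
        nrow(gg) >= 3L) {
      sel <- gg[1:3, ]
    }
    sel$rank <- seq_len(nrow(sel))
    sel
  })
  out <- do.call(rbind, picks)
  rownames(out) <- NULL
  out$colonies_to_pick <- pmin(10L, 2L * out$well_occupancy)
  out[, c("gene_id", "rank", "strain_id", "dist_to_start", "probability",
          "colonies_to_pick")]
}

#' Reserved no-bacteria control wells on assay plates
#'
#' @param row,col Well coordinates (vectorized).
#' @return Logical: TRUE for wells B2 and E7.
#' @export
is_control_well <- function(row, col) {
  (row == "B" & col == 2L) | (row == "E" & col == 7L)
}
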