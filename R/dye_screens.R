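#' Score a plate with the thymol blue endpoint assay
#'
#' The A435/A545 absorbance ratio of thymol blue is used as a proxy for
#' endpoint biolixiviant pH (the ratio cancels well-to-well background).
#' Controls (B2, E7) and unoccupied wells are excluded; a non-positive A545
#' marks the well invalid rather than propagating a division hazard.
#'
#' @param plate data.frame: `plate_id`, `well`, `row`, `col`, `od590`,
#'   `a435`, `a545`, `occupied` (logical), `control` (logical).
#' @return data.frame of well scores: `plate_id`, `well`, `screen` ("TB"),
#'   `value`, `valid`, `reason_invalid`.
#' @export
tb_score <- function(plate) {
  keep <- plate$occupied & !plate$control
  p <- plate[keep, , drop = FALSE]
  valid <- is.finite(p$a545) & p$a545 > 0 & is.finite(p$a435)
  data.frame(
    plate_id = p$plate_id,
    well = p$well,
    screen = "TB",
    value = ifelse(valid, p$a435 / p$a545, NA_real_),
    valid = valid,
    reason_invalid = ifelse(valid, NA_character_, "division_hazard"),
    stringsAsFactors = FALSE
  )
}

#' Fit a thymol blue pH calibration line
#'
#' Ordinary least squares of pH on the A435/A545 ratio, valid between pH 2.0
#' and 3.4 where the relation is linear.
#'
#' @param standards data.frame with columns `ph` and `ratio`, >= 2 points
#'   with distinct ratios, pH inside [2, 3.4].
#' @return An object of class `tb_calibration`: `slope`, `intercept`,
#'   `r_squared`, `valid_ph_range`.
#' @export
fit_tb_calibration <- function(standards) {
  if (nrow(standards) < 2L) stop("need >= 2 calibration standards")
  if (stats::var(standards$ratio) == 0) stop("zero ratio variance")
  if (any(standards$ph < 2.0 | standards$ph > 3.4)) {
    stop("calibration standards must lie in pH [2, 3.4]")
  }
  fit <- stats::lm(ph ~ ratio, data = standards)
  r2 <- if (stats::var(standards$ph) == 0) 1 else
    stats::cor(standards$ph, standards$ratio)^2
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 valid_ph_range = c(2.0, 3.4)),
            class = "tb_calibration")
}

#' Convert a thymol blue ratio to a pH estimate
#'
#' @param cal A [fit_tb_calibration()] result.
#' @param r A435/A545 ratio (vectorized).
#' @return data.frame: `ph`, `in_range` (FALSE marks extrapolation beyond
#'   the calibrated pH 2-3.4 window; the value is still returned).
#' @export
ratio_to_ph <- function(cal, r) {
  ph <- cal$slope * r + cal$intercept
  data.frame(ph = ph,
             in_range = ph >= cal$valid_ph_range[1] &
               ph <= cal$valid_ph_range[2])
}

#' Acidification rate from a bromophenol blue kinetic series
#'
#' Least-squares slope of A600 on time over the seven one-minute reads; the
#' blue form's absorbance falls as acid accumulates, so the rate is reported
#' as `V = -slope` (positive = faster acidification), with the fit's R
#' squared.
#'
#' @param a600_series Seven finite A600 readings.
#' @param times Read times in minutes (default 0:6).
#' @return List: `V` (1/min), `r_squared`.
#' @export
bpb_rate <- function(a600_series, times = 0:6) {
  if (length(a600_series) != length(times)) {
    stop("a600_series and times lengths differ")
  }
  if (any(!is.finite(a600_series))) stop("non-finite A600 reading")
  if (stats::var(times) == 0) stop("zero time variance")
  tc <- times - mean(times)
  yc <- a600_series - mean(a600_series)
  slope <- sum(tc * yc) / sum(tc^2)
  r2 <- if (stats::var(a600_series) == 0) 0 else
    stats::cor(times, a600_series)^2
  list(V = -slope, r_squared = r2)
}

#' Score a plate with the bromophenol blue rate assay
#'
#' Per-well rate `V` is normalized by culture density (`V/OD590`). Wells are
#' invalid when the kinetic fit's R squared is below `min_r2` (default 0.5),
#' when the culture failed to grow (`od590 < min_od`), or when the well is a
#' control or empty.
#'
#' @param plate Endpoint/OD table as in [tb_score()] (supplies `od590`).
#' @param kinetics Long-form kinetic table: `plate_id`, `well`, `t_min`,
#'   `a600`.
#' @param min_r2 Minimum R squared for the rate fit (default 0.5).
#' @param min_od Minimum OD590 counted as growth (default 0.1).
#' @return data.frame of well scores as in [tb_score()], `screen` = "BPB".
#' @export
bpb_score <- function(plate, kinetics, min_r2 = 0.5, min_od = 0.1) {
  keep <- plate$occupied & !plate$control
  p <- plate[keep, , drop = FALSE]
  value <- rep(NA_real_, nrow(p))
  valid <- rep(FALSE, nrow(p))
  reason <- rep(NA_character_, nrow(p))
  kin_split <- split(kinetics[, c("t_min", "a600")],
                     paste(kinetics$plate_id, kinetics$well, sep = ":"))
  for (i in seq_len(nrow(p))) {
    k <- kin_split[[paste(p$plate_id[i], p$well[i], sep = ":")]]
    if (is.null(k) || nrow(k) < 3L) {
      reason[i] <- "missing_kinetics"
      next
    }
    k <- k[order(k$t_min), ]
    rate <- bpb_rate(k$a600, k$t_min)
    if (!is.finite(p$od590[i]) || p$od590[i] < min_od) {
      reason[i] <- "no_growth"
    } else if (rate$r_squared < min_r2) {
      reason[i] <- "low_r2"
    } else {
      value[i] <- rate$V / p$od590[i]
      valid[i] <- TRUE
    }
  }
  data.frame(plate_id = p$plate_id, well = p$well, screen = "BPB",
             value = value, valid = valid, reason_invalid = reason,
             stringsAsFactors = FALSE)
}

#' Plate-wise IQR outlier calling
#'
#' Quartiles are computed over the plate's valid scores by the inclusive
#' linear-interpolation convention (`quantile` type 7, the spreadsheet
#' default); the bounds are Q1 - 1.5 IQR and Q3 + 1.5 IQR, and wells strictly
#' outside them are flagged `below` or `above`.
#'
#' @param scores Well scores of one plate (from [tb_score()] or
#'   [bpb_score()]); invalid wells are ignored.
#' @param quantile_type `stats::quantile` type (default 7, inclusive
#'   interpolation). Exposed because the convention shifts hit boundaries.
#' @return List: `flags` (data.frame plate_id, well, value, outlier in
#'   {"none","below","above"}), `q1`, `q3`, `lb`, `ub`; or NULL (with a
#'   warning) when fewer than 4 valid scores are available.
#' @export
call_plate_outliers <- function(scores, quantile_type = 7) {
  v <- scores[scores$valid, , drop = FALSE]
  if (nrow(v) < 4L) {
    warning("plate skipped: fewer than 4 valid scores")
    return(NULL)
  }
  q <- stats::quantile(v$value, c(0.25, 0.75), type = quantile_type,
                       names = FALSE)
  iqr <- q[2] - q[1]
  lb <- q[1] - 1.5 * iqr
  ub <- q[2] + 1.5 * iqr
  flag <- rep("none", nrow(v))
  flag[v$value < lb] <- "below"
  flag[v$value > ub] <- "above"
  list(flags = data.frame(plate_id = v$plate_id, well = v$well,
                          value = v$value, outlier = flag,
                          stringsAsFactors = FALSE),
       q1 = q[1], q3 = q[2], lb = lb, ub = ub)
}

#' Call per-strain screen hits from plate outlier flags
#'
#' A strain is a hit when over half of its wells (or 1 of 2) are outliers in
#' a consistent direction; strains with outliers on both sides are not hits
#' (direction-incoherent) and strains with no valid flagged well get no
#' call.
#'
#' @param strain_wells data.frame mapping strains to wells: `strain_id`,
#'   `plate_id`, `well`. Each well may belong to at most one strain.
#' @param flags data.frame of per-well flags (rbind of
#'   [call_plate_outliers()] `$flags` across plates).
#' @return data.frame: `strain_id`, `wells`, `outlier_wells`, `direction`
#'   ("below"/"above"/NA), `is_hit`.
#' @export
call_hits <- function(strain_wells, flags) {
  key_sw <- paste(strain_wells$plate_id, strain_wells$well, sep = ":")
  if (anyDuplicated(key_sw)) stop("a well is assigned to more than one strain")
  key_fl <- paste(flags$plate_id, flags$well, sep = ":")
  m <- match(key_sw, key_fl)
  strain_wells$outlier <- flags$outlier[m]
  sw <- strain_wells[!is.na(strain_wells$outlier), , drop = FALSE]
  out <- lapply(split(sw, sw$strain_id), function(s) {
    n <- nrow(s)
    n_below <- sum(s$outlier == "below")
    n_above <- sum(s$outlier == "above")
    if (n_below > 0L && n_above > 0L) {
      # direction-incoherent: never a hit
      return(data.frame(strain_id = s$strain_id[1], wells = n,
                        outlier_wells = n_below + n_above,
                        direction = NA_character_, is_hit = FALSE,
                        stringsAsFactors = FALSE))
    }
    k <- max(n_below, n_above)
    dir <- if (k == 0L) NA_character_ else
      if (n_below > 0L) "below" else "above"
    hit <- (k > n / 2) || (n == 2L && k >= 1L)
    data.frame(strain_id = s$strain_id[1], wells = n, outlier_wells = k,
               direction = dir, is_hit = hit, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Merge endpoint and rate screen hit sets
#'
#' @param tb_hits,bpb_hits Character vectors of hit gene ids from the thymol
#'   blue and bromophenol blue screens.
#' @return List: `union`, `intersection`, `n_tb`, `n_bpb`, `n_both`,
#'   `n_union`.
#' @export
merge_screens <- function(tb_hits, bpb_hits) {
  tb <- unique(tb_hits); bpb <- unique(bpb_hits)
  u <- union(tb, bpb); b <- intersect(tb, bpb)
  list(union = sort(u), intersection = sort(b),
       n_tb = length(tb), n_bpb = length(bpb),
       n_both = length(b), n_union = length(u))
}
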