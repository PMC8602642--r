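#' Proxy wild-type set for a condensed-collection plate
#'
#' Two mating-batch backgrounds with distinct saturated culture densities run
#' through the collection, so endpoint comparisons use a batch-matched proxy
#' wild-type (pWT) set: set A for plates 1-76, 110-129 and 160-185, set B
#' (the lower-density background) for plates 77-109 and 130-159. Plate 130
#' sits on the printed boundary of both ranges and is assigned to B here;
#' override via `plate130`.
#'
#' @param cc_plate Condensed-collection plate number(s), 1-185.
#' @param plate130 Set for the boundary plate (default "B").
#' @return Character vector of "A"/"B".
#' @export
assign_pwt_set <- function(cc_plate, plate130 = "B") {
  if (any(cc_plate < 1L | cc_plate > 185L)) {
    stop("cc_plate must be in 1..185")
  }
  out <- ifelse(
    (cc_plate >= 1L & cc_plate <= 76L) |
      (cc_plate >= 110L & cc_plate <= 129L) |
      (cc_plate >= 160L & cc_plate <= 185L), "A", "B")
  out[cc_plate == 130L] <- plate130
  out
}

#' Two-sample pooled-variance t comparison against proxy wild type
#'
#' Two-tailed Student's t-test assuming equal variances, with a Bonferroni
#' threshold `alpha/N` for the family of `n_comparisons` strain comparisons.
#' Degenerate zero-variance inputs are resolved deterministically: equal
#' means give p = 1, unequal means are significant and flagged.
#'
#' @param mut_values,wt_values Numeric measurement vectors (>= 2 each).
#' @param n_comparisons Family size N for the Bonferroni correction.
#' @param alpha Family-wise level (default 0.05).
#' @return List of class `pwt_comparison`: `n_mut`, `n_wt`, `t_stat`, `df`,
#'   `p_value`, `alpha_adj`, `significant`, `direction` ("higher"/"lower"/
#'   NA; mutant relative to pWT), `degenerate_variance`.
#' @export
compare_to_pwt <- function(mut_values, wt_values, n_comparisons,
                           alpha = 0.05) {
  n1 <- length(mut_values); n2 <- length(wt_values)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 values per group")
  if (n_comparisons < 1L) stop("n_comparisons must be >= 1")
  m1 <- mean(mut_values); m2 <- mean(wt_values)
  dfree <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * stats::var(mut_values) +
            (n2 - 1) * stats::var(wt_values)) / dfree
  degen <- sp2 == 0
  if (degen) {
    if (m1 == m2) {
      t_stat <- 0; p <- 1
    } else {
      t_stat <- sign(m1 - m2) * Inf; p <- 0
    }
  } else {
    t_stat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    p <- 2 * stats::pt(-abs(t_stat), dfree)
  }
  alpha_adj <- alpha / n_comparisons
  structure(list(
    n_mut = n1, n_wt = n2, t_stat = t_stat, df = dfree, p_value = p,
    alpha_adj = alpha_adj, significant = p < alpha_adj,
    direction = if (m1 == m2) NA_character_ else
      if (m1 > m2) "higher" else "lower",
    mean_mut = m1, mean_wt = m2,
    degenerate_variance = degen
  ), class = "pwt_comparison")
}

#' Classify a confirmed strain from its phenotype comparisons
#'
#' Headline hit categories require an unchanged growth rate: strains whose
#' growth comparison is significant are labelled "growth-confounded" and
#' excluded from the headline sets. Otherwise the label combines the
#' significant phenotypes: "acidity+" (lower endpoint pH, more acid),
#' "acidity-" (higher pH), "rate+"/"rate-" (faster/slower acidification),
#' joined with "/" when several apply, or "none".
#'
#' @param ph Endpoint-pH `pwt_comparison` (direction "lower" = more acidic),
#'   or NULL if missing.
#' @param rate Acidification-rate `pwt_comparison`, or NULL.
#' @param growth Growth (saturated OD) `pwt_comparison`; required.
#' @return Character category label.
#' @export
classify_strain <- function(ph, rate, growth) {
  if (is.null(growth)) stop("growth comparison is required")
  if (growth$significant) return("growth-confounded")
  parts <- character(0)
  if (is.null(ph) || is.null(rate)) {
    warning("missing phenotype comparison; partial label")
  }
  if (!is.null(ph) && ph$significant) {
    parts <- c(parts, if (ph$direction == "lower") "acidity+" else "acidity-")
  }
  if (!is.null(rate) && rate$significant) {
    parts <- c(parts, if (rate$direction == "higher") "rate+" else "rate-")
  }
  if (length(parts) == 0L) "none" else paste(parts, collapse = "/")
}

#' Run the confirmation stage over a long-form measurement table
#'
#' Convenience driver: for each strain and phenotype, compares the strain's
#' replicate measurements with the pooled proxy wild-type values of the same
#' phenotype using [compare_to_pwt()].
#'
#' @param measurements data.frame: `strain_id`, `phenotype`, `value`; pWT
#'   rows carry `strain_id` in `pwt_ids`.
#' @param pwt_ids Character vector of proxy wild-type strain ids.
#' @param n_comparisons Family size N; defaults to the number of non-pWT
#'   strains tested per phenotype.
#' @param alpha Family-wise level (default 0.05).
#' @return data.frame with one row per strain x phenotype mirroring
#'   `pwt_comparison`.
#' @export
confirm_strains <- function(measurements, pwt_ids, n_comparisons = NULL,
                            alpha = 0.05) {
  out <- list()
  for (phen in unique(measurements$phenotype)) {
    mm <- measurements[measurements$phenotype == phen, , drop = FALSE]
    wt <- mm$value[mm$strain_id %in% pwt_ids]
    strains <- setdiff(unique(mm$strain_id), pwt_ids)
    N <- if (is.null(n_comparisons)) length(strains) else n_comparisons
    for (s in strains) {
      v <- mm$value[mm$strain_id == s]
      if (length(v) < 2L) next
      cmp <- compare_to_pwt(v, wt, N, alpha)
      out[[length(out) + 1L]] <- data.frame(
        strain_id = s, phenotype = phen, n_mut = cmp$n_mut, n_wt = cmp$n_wt,
        t_stat = cmp$t_stat, df = cmp$df, p_value = cmp$p_value,
        alpha_adj = cmp$alpha_adj, significant = cmp$significant,
        direction = ifelse(is.null(cmp$direction), NA, cmp$direction),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
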