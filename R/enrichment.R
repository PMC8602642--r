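#' Build a gene ontology annotation map
#'
#' @param gene_to_terms data.frame with columns `gene_id`, `term_id` (one row
#'   per assignment; genes may be absent, i.e. unannotated).
#' @param term_meta data.frame with columns `term_id`, `name`, `category`
#'   ("BP"/"MF"/"CC"). Every term used must have meta.
#' @return Object of class `go_map`.
#' @export
go_map <- function(gene_to_terms, term_meta) {
  missing_meta <- setdiff(gene_to_terms$term_id, term_meta$term_id)
  if (length(missing_meta) > 0L) {
    stop("terms without metadata: ", paste(missing_meta, collapse = ", "))
  }
  if (!all(term_meta$category %in% c("BP", "MF", "CC"))) {
    stop("category must be BP, MF or CC")
  }
  structure(list(gene_to_terms = unique(gene_to_terms),
                 term_meta = term_meta),
            class = "go_map")
}

#' Read a gene ontology map from TSV files
#'
#' @param gene_terms_tsv TSV with columns gene_id, term_id.
#' @param term_meta_tsv TSV with columns term_id, name, category.
#' @return A [go_map()].
#' @export
read_go_map <- function(gene_terms_tsv, term_meta_tsv) {
  g2t <- utils::read.delim(gene_terms_tsv, stringsAsFactors = FALSE)
  meta <- utils::read.delim(term_meta_tsv, stringsAsFactors = FALSE)
  go_map(g2t, meta)
}

#' One-sided Fisher's exact gene-ontology enrichment
#'
#' For every term annotated to at least one study gene, the over-
#' representation p-value is the hypergeometric upper tail
#' `P(X >= k | N, K, n)` with `N` background genes, `K` of them carrying the
#' term, and `k` of the `n` study genes carrying it. Terms are reported
#' sorted by ascending p (ties broken by term id) and marked significant at
#' raw `p < alpha` by default; no graph propagation is applied (the map is
#' used as given).
#'
#' @param study Character vector of study gene ids (must be a subset of
#'   `background`).
#' @param background Character vector of background gene ids.
#' @param map A [go_map()].
#' @param alpha Significance threshold on the (possibly adjusted) p (default
#'   0.05, raw).
#' @param adjust Multiplicity adjustment passed to [stats::p.adjust()]
#'   (default "none", mirroring raw-p reporting).
#' @return data.frame: `term_id`, `name`, `category`, `k`, `n`, `K`, `N`,
#'   `p_value`, `p_adjusted`, `significant`.
#' @export
fisher_enrichment <- function(study, background, map, alpha = 0.05,
                              adjust = "none") {
  study <- unique(study); background <- unique(background)
  offenders <- setdiff(study, background)
  if (length(offenders) > 0L) {
    stop("study genes not in background: ",
         paste(utils::head(offenders, 10L), collapse = ", "))
  }
  g2t <- map$gene_to_terms
  g2t <- g2t[g2t$gene_id %in% background, , drop = FALSE]
  N <- length(background); n <- length(study)
  K_tab <- table(g2t$term_id)
  k_tab <- table(g2t$term_id[g2t$gene_id %in% study])
  terms <- names(k_tab)[k_tab >= 1L]            # k = 0 cannot be enriched
  if (length(terms) == 0L) {
    return(data.frame(term_id = character(0), name = character(0),
                      category = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p_value = numeric(0),
                      p_adjusted = numeric(0), significant = logical(0)))
  }
  k <- as.integer(k_tab[terms])
  K <- as.integer(K_tab[terms])
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  m <- match(terms, map$term_meta$term_id)
  res <- data.frame(
    term_id = terms,
    name = map$term_meta$name[m],
    category = map$term_meta$category[m],
    k = k, n = n, K = K, N = N,
    p_value = p,
    p_adjusted = stats::p.adjust(p, method = adjust),
    stringsAsFactors = FALSE
  )
  res$significant <- res$p_adjusted < alpha
  res <- res[order(res$p_value, res$term_id), ]
  rownames(res) <- NULL
  res
}

#' Bar-chart-ready enrichment report
#'
#' @param results A [fisher_enrichment()] table.
#' @param top_m Keep at most this many top terms (default all significant).
#' @param alpha Threshold line (default 0.05).
#' @return data.frame: `term_id`, `name`, `category`, `neg_log10_p`,
#'   `label` ("k (K)": study genes with the term, out of the genome total in
#'   parentheses), `p_value`; attribute `threshold` = alpha.
#' @export
enrichment_report <- function(results, top_m = NULL, alpha = 0.05) {
  if (nrow(results) == 0L) stop("no enrichment results")
  r <- results[results$significant, , drop = FALSE]
  if (!is.null(top_m)) r <- utils::head(r, top_m)
  out <- data.frame(
    term_id = r$term_id,
    name = r$name,
    category = r$category,
    neg_log10_p = -log10(r$p_value),
    label = sprintf("%d (%d)", r$k, r$K),
    p_value = r$p_value,
    stringsAsFactors = FALSE
  )
  attr(out, "threshold") <- alpha
  out
}
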