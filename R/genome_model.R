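#' Construct a genome annotation object
#'
#' Bundles contig sequences with a gene table into the container the rest of
#' the pipeline consumes. Coordinates are 1-based inclusive (GFF3 convention).
#'
#' @param contigs Named character vector or [Biostrings::DNAStringSet] of
#'   contig sequences. Only A/C/G/T/N are accepted.
#' @param genes data.frame with columns `gene_id`, `contig_id`, `start`,
#'   `end`, `strand` (`"+"`/`"-"`) and optionally `product`.
#' @return An object of class `genome_annotation`: a list with elements
#'   `contigs` (DNAStringSet) and `genes` (data.frame).
#' @export
genome_annotation <- function(contigs, genes) {
  if (is.character(contigs)) {
    if (is.null(names(contigs)) || anyNA(names(contigs))) {
      stop("contigs must be named")
    }
    bad <- grepl("[^ACGTN]", contigs)
    if (any(bad)) {
      stop("contig sequences contain characters outside A/C/G/T/N: ",
           paste(names(contigs)[bad], collapse = ", "))
    }
    contigs <- Biostrings::DNAStringSet(contigs)
  }
  if (!methods::is(contigs, "DNAStringSet")) {
    stop("contigs must be a named character vector or DNAStringSet")
  }
  bad <- vapply(seq_along(contigs), function(i) {
    freq <- Biostrings::alphabetFrequency(contigs[[i]])
    sum(freq) - sum(freq[c("A", "C", "G", "T", "N")]) > 0
  }, logical(1))
  if (any(bad)) {
    stop("contig sequences contain characters outside A/C/G/T/N: ",
         paste(names(contigs)[bad], collapse = ", "))
  }
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  req <- c("gene_id", "contig_id", "start", "end", "strand")
  if (!all(req %in% names(genes))) {
    stop("genes table must have columns: ", paste(req, collapse = ", "))
  }
  if (!"product" %in% names(genes)) genes$product <- NA_character_
  if (nrow(genes) == 0L) stop("gene count must be > 0")
  if (anyDuplicated(genes$gene_id)) stop("gene_id must be unique genome-wide")
  if (!all(genes$contig_id %in% names(contigs))) {
    stop("gene contigs absent from assembly: ",
         paste(setdiff(genes$contig_id, names(contigs)), collapse = ", "))
  }
  if (any(genes$start > genes$end)) stop("gene start must be <= end")
  if (any(genes$start < 1L)) stop("gene start must be >= 1")
  clen <- stats::setNames(Biostrings::width(contigs), names(contigs))
  if (any(genes$end > clen[genes$contig_id])) {
    stop("gene coordinates exceed contig bounds")
  }
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  structure(list(contigs = contigs, genes = genes),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d contig(s), %.3f Mb, %d gene(s)\n",
              length(x$contigs), sum(Biostrings::width(x$contigs)) / 1e6,
              nrow(x$genes)))
  invisible(x)
}

#' Read a genome annotation from FASTA + GFF3
#'
#' @param fasta Path to a (multi-)FASTA assembly.
#' @param gff Path to a GFF3 annotation.
#' @param feature_type GFF3 feature type to take genes from, `"CDS"` or
#'   `"gene"`.
#' @return A [genome_annotation()] object.
#' @export
read_genome <- function(fasta, gff, feature_type = c("CDS", "gene")) {
  feature_type <- match.arg(feature_type)
  contigs <- Biostrings::readDNAStringSet(fasta)
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  gr <- rtracklayer::import(gff, format = "gff3")
  gr <- gr[gr$type == feature_type]
  if (length(gr) == 0L) stop("no features of type ", feature_type, " in ", gff)
  ids <- if (!is.null(gr$ID)) gr$ID else paste0("feat", seq_along(gr))
  genes <- data.frame(
    gene_id = as.character(ids),
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    product = if (!is.null(gr$product)) as.character(gr$product) else NA_character_,
    stringsAsFactors = FALSE
  )
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"
  genome_annotation(contigs, genes)
}

#' Index mariner transposon insertion sites (TA/AT dinucleotides)
#'
#' Scans the forward strand of every contig for "TA" and "AT" dinucleotides
#' (overlapping occurrences counted; the two words jointly capture both
#' orientations of the mariner TA target, so a single-strand scan suffices
#' and a double-strand scan would double count). A site is addressed by the
#' 1-based position of its first base and belongs to a gene when that base
#' lies in `[start, end - 1]`. `N` never matches.
#'
#' @param genome A [genome_annotation()].
#' @return An object of class `insertion_site_index`: list with `sites`
#'   (named list of strictly increasing integer positions per contig),
#'   `per_gene_count` (named integer, one per gene) and `total_sites`.
#' @export
index_insertion_sites <- function(genome) {
  stopifnot(inherits(genome, "genome_annotation"))
  if (any(Biostrings::width(genome$contigs) == 0L)) {
    stop("contig sequences must be non-empty")
  }
  sites <- lapply(seq_along(genome$contigs), function(i) {
    seq_i <- genome$contigs[[i]]
    p <- sort(c(Biostrings::start(Biostrings::matchPattern("TA", seq_i)),
                Biostrings::start(Biostrings::matchPattern("AT", seq_i))))
    as.integer(p)
  })
  names(sites) <- names(genome$contigs)
  genes <- genome$genes
  per_gene <- integer(nrow(genes))
  names(per_gene) <- genes$gene_id
  for (ctg in unique(genes$contig_id)) {
    idx <- which(genes$contig_id == ctg)
    p <- sites[[ctg]]
    if (length(p) == 0L) next
    # gene interval for site first-base membership: [start, end - 1]
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = p, width = 1L),
      IRanges::IRanges(start = genes$start[idx],
                       end = pmax(genes$start[idx] - 1L, genes$end[idx] - 1L))
    )
    cnt <- tabulate(S4Vectors::subjectHits(hits), nbins = length(idx))
    per_gene[idx] <- cnt
  }
  structure(list(sites = sites,
                 per_gene_count = per_gene,
                 total_sites = sum(lengths(sites))),
            class = "insertion_site_index")
}

#' @export
print.insertion_site_index <- function(x, ...) {
  cat(sprintf("insertion_site_index: %d sites on %d contig(s); %d gene(s)\n",
              x$total_sites, length(x$sites), length(x$per_gene_count)))
  invisible(x)
}

#' Map an insertion coordinate to the gene(s) it disrupts
#'
#' An insertion disrupts every gene whose `[start, end - 1]` interval contains
#' its first-base position; positions covered by no gene are intergenic.
#'
#' @param index An [index_insertion_sites()] result.
#' @param genome The matching [genome_annotation()].
#' @param contig Contig identifier.
#' @param pos 1-based first-base position; must be an indexed TA/AT site.
#' @return Character vector of disrupted gene ids, or `"intergenic"`.
#' @export
map_insertion <- function(index, genome, contig, pos) {
  stopifnot(inherits(index, "insertion_site_index"))
  if (!contig %in% names(index$sites)) stop("unknown contig: ", contig)
  if (!pos %in% index$sites[[contig]]) {
    stop("position ", pos, " on ", contig,
         " is not a TA/AT insertion site")
  }
  g <- genome$genes
  hit <- g$contig_id == contig & g$start <= pos & pos <= g$end - 1L
  if (!any(hit)) return("intergenic")
  g$gene_id[hit]
}

#' Genes with no recovered disruption (essentiality candidates)
#'
#' @param genome A [genome_annotation()].
#' @param disrupted Character vector of disrupted gene ids (must all be
#'   annotated).
#' @return Character vector: annotated ids minus `disrupted`.
#' @export
undisrupted_genes <- function(genome, disrupted) {
  all_ids <- genome$genes$gene_id
  extra <- setdiff(disrupted, all_ids)
  if (length(extra) > 0L) {
    stop("disrupted ids absent from annotation: ",
         paste(extra, collapse = ", "))
  }
  setdiff(all_ids, disrupted)
}

#' Fraction of insertions in the first half of their gene
#'
#' Relative position is measured from the translation start: for a `+` strand
#' gene `(pos - start)/(end - start)`, for `-` strand `(end - pos)/(end -
#' start)`; entries with relative position < 0.5 count as first-half.
#'
#' @param entries data.frame with columns `gene_id` and `pos`.
#' @param genome A [genome_annotation()].
#' @return Fraction in `[0, 1]`.
#' @export
first_half_fraction <- function(entries, genome) {
  g <- genome$genes
  m <- match(entries$gene_id, g$gene_id)
  if (anyNA(m)) stop("unknown gene ids in entries")
  start <- g$start[m]; end <- g$end[m]; strand <- g$strand[m]
  if (any(end == start)) stop("zero-length gene in entries")
  if (any(entries$pos < start | entries$pos > end)) {
    stop("entry position outside its gene")
  }
  rel <- ifelse(strand == "+",
                (entries$pos - start) / (end - start),
                (end - entries$pos) / (end - start))
  mean(rel < 0.5)
}

#' Write an insertion site index as tab-separated tables
#'
#' @param index An [index_insertion_sites()] result.
#' @param sites_path Output TSV (contig, position).
#' @param genes_path Optional output TSV (gene_id, n_sites).
#' @return Invisibly, `sites_path`.
#' @export
write_site_index <- function(index, sites_path, genes_path = NULL) {
  df <- data.frame(
    contig = rep(names(index$sites), lengths(index$sites)),
    position = unlist(index$sites, use.names = FALSE)
  )
  utils::write.table(df, sites_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(genes_path)) {
    gdf <- data.frame(gene_id = names(index$per_gene_count),
                      n_sites = as.integer(index$per_gene_count))
    utils::write.table(gdf, genes_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(sites_path)
}
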