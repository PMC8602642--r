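# Shared fixture builders and independent oracles (built in code; no files).

# small annotated genome: genes laid end to end with 10 bp gaps on one contig
toy_genome <- function(gene_lengths, seed = 42, gc = 0.5) {
  set.seed(seed)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  n <- length(gene_lengths)
  starts <- integer(n); ends <- integer(n)
  pos <- 0L
  for (i in seq_len(n)) {
    pos <- pos + 10L
    starts[i] <- pos + 1L
    ends[i] <- pos + gene_lengths[i]
    pos <- ends[i]
  }
  seq_len_total <- pos + 10L
  bases <- sample(names(probs), seq_len_total, replace = TRUE, prob = probs)
  genome_annotation(
    c(ctg1 = paste(bases, collapse = "")),
    data.frame(gene_id = sprintf("g%03d", seq_len(n)), contig_id = "ctg1",
               start = starts, end = ends,
               strand = rep(c("+", "-"), length.out = n),
               stringsAsFactors = FALSE))
}

# a genome with n genes but trivial sequence, for set-arithmetic tests
flat_genome <- function(n) {
  len <- 10L
  starts <- (seq_len(n) - 1L) * (len + 2L) + 1L
  seqs <- paste(rep("TA", n * (len + 2L) / 2 + 10L), collapse = "")
  genome_annotation(
    c(c1 = seqs),
    data.frame(gene_id = sprintf("g%05d", seq_len(n)), contig_id = "c1",
               start = starts, end = starts + len - 1L,
               strand = "+", stringsAsFactors = FALSE))
}

# oracle: brute-force sliding-window TA/AT scan on a character string
oracle_site_scan <- function(s) {
  ch <- strsplit(s, "")[[1]]
  if (length(ch) < 2L) return(integer(0))
  di <- paste0(ch[-length(ch)], ch[-1])
  which(di %in% c("TA", "AT"))
}

# oracle: inclusive linear-interpolation quantile (spreadsheet convention)
oracle_quantile_inc <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# oracle: hypergeometric upper tail by direct combinatorial sum
oracle_hyper_tail <- function(k, N, K, n) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# a simple endpoint plate table around given well values
plate_from_values <- function(values, plate_id = 1L) {
  n <- length(values)
  data.frame(plate_id = plate_id,
             well = paste0("W", seq_len(n)),
             row = rep("A", n), col = seq_len(n),
             od590 = 1, a435 = values, a545 = 1,
             occupied = TRUE, control = FALSE,
             stringsAsFactors = FALSE)
}
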