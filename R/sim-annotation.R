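#' Simulate gene models and CpG-island intervals
#'
#' Places `n_genes` non-overlapping genes on a single synthetic chromosome,
#' assigns each a strand, a transcription start site (TSS; the left span end
#' on `+`, the right span end on `-`), a gene-type label, and a single exon
#' spanning the gene. A CpG island (CGI) is placed over the promoter of a
#' `cgi_promoter_fraction` share of genes. All coordinates are 1-based
#' inclusive.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `methnet_annotation` with elements
#'   `genes` (data.frame: gene_id, chrom, strand, start, end, tss, gene_type,
#'   exon_starts, exon_ends) and `cgi` (data.frame: chrom, start, end),
#'   both 1-based inclusive.
#' @examples
#' ann <- simulate_annotation(sim_config(n_genes = 5, genome_length = 1e5))
#' ann$genes
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "methnet_config"))
  n <- config$n_genes
  empty_genes <- data.frame(
    gene_id = character(), chrom = character(), strand = character(),
    start = integer(), end = integer(), tss = integer(),
    gene_type = character(), exon_starts = character(),
    exon_ends = character(), stringsAsFactors = FALSE)
  empty_cgi <- data.frame(chrom = character(), start = integer(),
                          end = integer(), stringsAsFactors = FALSE)
  if (n == 0L) {
    out <- list(genes = empty_genes, cgi = empty_cgi)
    class(out) <- "methnet_annotation"
    return(out)
  }

  # Each gene lives in its own slot; 1500 bp margins keep promoters (+-1 kb)
  # and promoter CGIs inside the slot so neighbouring genes never collide.
  slot <- config$genome_length %/% n
  margin <- 1500L
  max_len <- 6000L
  if (slot < 2L * margin + 2000L)
    stop("genome_length too small to place ", n, " non-overlapping genes ",
         "with 1 kb promoters: need >= ", n * (2L * margin + 2000L), " bp")
  len_hi <- min(max_len, slot - 2L * margin)

  with_seed(stream_seed(config$seed, "annotation"), {
    lens <- sample(2000:len_hi, n, replace = TRUE)
    offs <- vapply(lens, function(l) {
      lo <- margin
      hi <- slot - l - margin
      if (hi <= lo) lo else sample(lo:hi, 1L)
    }, integer(1))
    start <- (seq_len(n) - 1L) * slot + offs + 1L
    end <- start + lens - 1L
    strand <- sample(c("+", "-"), n, replace = TRUE)
    tss <- ifelse(strand == "+", start, end)
    gene_type <- sample(c("protein-coding", "lncRNA", "miRNA", "pseudogene"),
                        n, replace = TRUE, prob = c(0.70, 0.15, 0.10, 0.05))
    genes <- data.frame(
      gene_id = sprintf("G%04d", seq_len(n)), chrom = "chr1",
      strand = strand, start = as.integer(start), end = as.integer(end),
      tss = as.integer(tss), gene_type = gene_type,
      exon_starts = as.character(start), exon_ends = as.character(end),
      stringsAsFactors = FALSE)

    n_cgi <- round(config$cgi_promoter_fraction * n)
    cgi <- empty_cgi
    if (n_cgi > 0) {
      idx <- sort(sample.int(n, n_cgi))
      w_left <- sample(300:800, n_cgi, replace = TRUE)
      w_right <- sample(300:800, n_cgi, replace = TRUE)
      cgi <- data.frame(
        chrom = "chr1",
        start = pmax(1L, as.integer(genes$tss[idx] - w_left)),
        end = as.integer(genes$tss[idx] + w_right),
        stringsAsFactors = FALSE)
    }
    out <- list(genes = genes, cgi = cgi)
    class(out) <- "methnet_annotation"
    out
  })
}
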