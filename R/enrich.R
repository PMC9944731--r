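#' Hypergeometric overrepresentation analysis
#'
#' Tests each pathway gene set for overrepresentation in an input gene list
#' with the cumulative (upper-tail) hypergeometric test: with a universe of
#' N genes, K of them in the set and n input genes, the p-value is
#' P(X >= x) for an observed overlap of x. Results are filtered at
#' p < `p_cutoff` (strict) and sorted by p ascending, overlap descending,
#' then pathway id. A Benjamini-Hochberg column over all tested sets is
#' carried along for transparency (no filtering is applied to it).
#'
#' @param genes Input gene list; genes outside the universe are dropped with
#'   a message.
#' @param gene_sets Named list of character vectors (e.g. [read_gmt()]).
#' @param universe Background gene universe; defaults to the union of all
#'   gene sets.
#' @param p_cutoff Retention cutoff on the hypergeometric p (default 0.05,
#'   strict).
#' @return data.frame: pathway_id, set_size (K), input_size (n), overlap (x),
#'   p_value, q_value, overlap_genes (comma-joined). Attribute `n_dropped`
#'   counts input genes outside the universe.
#' @examples
#' sets <- list(A = c("g1", "g2", "g3"), B = c("g4", "g5"))
#' ora(c("g1", "g2"), sets)
#' @export
ora <- function(genes, gene_sets, universe = NULL, p_cutoff = 0.05) {
  if (is.null(universe)) universe <- unique(unlist(gene_sets))
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty gene universe")
  genes <- unique(genes)
  dropped <- setdiff(genes, universe)
  if (length(dropped) > 0)
    message("ora: dropping ", length(dropped), " input gene(s) not in universe")
  genes <- intersect(genes, universe)
  N <- length(universe)
  n <- length(genes)

  rows <- lapply(names(gene_sets), function(id) {
    set <- intersect(gene_sets[[id]], universe)
    K <- length(set)
    hit <- intersect(genes, set)
    x <- length(hit)
    p <- stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway_id = id, set_size = K, input_size = n, overlap = x,
               p_value = p,
               overlap_genes = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[res$p_value < p_cutoff, , drop = FALSE]
  res <- res[order(res$p_value, -res$overlap, res$pathway_id), , drop = FALSE]
  res <- res[, c("pathway_id", "set_size", "input_size", "overlap",
                 "p_value", "q_value", "overlap_genes")]
  rownames(res) <- NULL
  attr(res, "n_dropped") <- length(dropped)
  res
}

#' Gene recurrence across top enriched pathways
#'
#' Counts, for each input gene, how many of the `top_k` most significant
#' pathways contain it in their overlap, identifying the most recurrent gene
#' across the top pathways. Every input gene is listed, including zero
#' counts; ties sort lexicographically.
#'
#' @param ora_results An [ora()] result (sorted by significance).
#' @param genes The input gene list used for the ORA.
#' @param top_k Number of top pathways to scan (default 10).
#' @return data.frame gene_id/n_pathways sorted by count descending.
#' @export
gene_recurrence <- function(ora_results, genes, top_k = 10) {
  top <- utils::head(ora_results, top_k)
  counts <- stats::setNames(integer(length(unique(genes))), sort(unique(genes)))
  for (i in seq_len(nrow(top))) {
    hit <- strsplit(top$overlap_genes[i], ",", fixed = TRUE)[[1]]
    hit <- hit[nzchar(hit)]
    counts[hit] <- counts[hit] + 1L
  }
  out <- data.frame(gene_id = names(counts), n_pathways = as.integer(counts),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_pathways, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
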