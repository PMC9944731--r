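#' Barabasi-Albert scale-free graph by preferential attachment
#'
#' The classic construction started from `m` isolated nodes: each subsequent
#' node attaches `m` edges to distinct existing nodes chosen with probability
#' proportional to their current degree (the first new node attaches to the
#' initial nodes uniformly). Yields exactly `m * (n - m)` edges, no
#' self-loops and no duplicate edges.
#'
#' @param n Number of nodes (>= m + 1).
#' @param m Attachment parameter.
#' @return Two-column integer matrix of edges (node indices in 1..n).
#' @keywords internal
ba_graph_edges <- function(n, m) {
  stopifnot(n >= m + 1, m >= 1)
  edges <- matrix(0L, nrow = m * (n - m), ncol = 2)
  targets <- seq_len(m)
  repeated <- integer() # one entry per edge endpoint: degree-proportional pool
  e <- 0L
  for (v in (m + 1L):n) {
    for (t in targets) {
      e <- e + 1L
      edges[e, ] <- c(t, v)
    }
    repeated <- c(repeated, targets, rep.int(v, m))
    # draw m distinct targets, degree-proportionally
    new_targets <- integer()
    while (length(new_targets) < m) {
      cand <- repeated[sample.int(length(repeated), 1L)]
      if (!cand %in% new_targets) new_targets <- c(new_targets, cand)
    }
    targets <- new_targets
  }
  edges
}

#' Simulate the tissue PPI graph, disease-gene catalog and pathway sets
#'
#' Builds a scale-free protein-protein interaction network over the gene
#' universe, a disease-gene catalog annotated with publication counts (a
#' quarter of entries get exactly one publication so the >= 2-publication
#' filter is exercised), and pathway gene sets whose first few sets overlap
#' the planted genes by construction so overrepresentation analysis has
#' signal.
#'
#' Planted hub structure: `config$n_hub_planted` planted genes are each wired
#' to `config$hub_wiring` catalog genes holding >= 2 publications; any other
#' planted gene that reaches degree >= 10 inside the planted-gene/filtered-
#' catalog universe has excess catalog edges removed deterministically, so the
#' designated genes are exactly the recoverable disease-subnetwork hubs.
#'
#' @param annotation A [simulate_annotation()] result.
#' @param ground_truth The `ground_truth` element of a [simulate_methylome()]
#'   result generated under the same config (planted wiring needs it).
#' @param config The shared [sim_config()].
#' @return List with `ppi` (data.frame geneA/geneB), `catalog` (data.frame
#'   gene/n_publications), `pathways` (named list of gene-id vectors) and
#'   `planted_hub_genes` (character vector, also appended to ground truth by
#'   [simulate_study()]).
#' @export
simulate_ppi_and_catalogs <- function(annotation, ground_truth, config) {
  stopifnot(inherits(annotation, "methnet_annotation"),
            inherits(config, "methnet_config"))
  genes <- annotation$genes$gene_id
  n <- length(genes)
  m <- config$ppi_attachment
  if (n < m + 1) stop("need at least ppi_attachment + 1 genes for the PPI graph")
  planted <- ground_truth$planted_genes$gene_id

  with_seed(stream_seed(config$seed, "graph"), {
    perm <- sample(genes) # detach BA node age from gene-id order
    e_idx <- ba_graph_edges(n, m)
    ppi <- data.frame(geneA = perm[e_idx[, 1]], geneB = perm[e_idx[, 2]],
                      stringsAsFactors = FALSE)

    # Disease catalog: genes not planted (the planted DMGs are "novel"),
    # ~40% of the universe, 25% with exactly one supporting publication.
    pool <- setdiff(genes, planted)
    catalog_size <- min(length(pool), max(config$hub_wiring + 5L, round(0.4 * n)))
    cat_genes <- sort(sample(pool, catalog_size))
    pubs <- 1L + stats::rpois(catalog_size, 2)
    # a quarter of entries get exactly one publication, but always reserve
    # enough >=2-publication genes to wire the planted hubs
    n_ones <- min(max(1L, round(0.25 * catalog_size)),
                  max(0L, catalog_size - config$hub_wiring))
    ones <- sample.int(catalog_size, n_ones)
    pubs[ones] <- 1L
    reserve <- setdiff(seq_len(catalog_size), ones)
    pubs[reserve] <- pmax(pubs[reserve], 2L)
    catalog <- data.frame(gene = cat_genes, n_publications = as.integer(pubs),
                          stringsAsFactors = FALSE)

    # Wire designated planted hubs to >=2-publication catalog genes.
    designated <- character()
    strong_cat <- catalog$gene[catalog$n_publications >= 2]
    if (length(planted) > 0 && config$n_hub_planted > 0) {
      wiring <- min(config$hub_wiring, length(strong_cat))
      if (wiring < config$hub_wiring)
        message("simulate_ppi_and_catalogs: only ", wiring,
                " >=2-publication catalog genes available for hub wiring ",
                "(requested ", config$hub_wiring, ")")
      designated <- sort(sample(planted, min(config$n_hub_planted, length(planted))))
      for (g in designated) {
        partners <- sample(strong_cat, wiring)
        ppi <- rbind(ppi, data.frame(geneA = g, geneB = partners,
                                     stringsAsFactors = FALSE))
      }
    }
    # canonical undirected edge key; drop duplicates and self-loops
    a <- pmin(ppi$geneA, ppi$geneB)
    b <- pmax(ppi$geneA, ppi$geneB)
    keep <- !duplicated(paste(a, b)) & a != b
    ppi <- data.frame(geneA = a[keep], geneB = b[keep], stringsAsFactors = FALSE)

    # Trim accidental hubs among non-designated planted genes so planted hub
    # structure is exact by construction (degree measured inside the
    # planted-DMG + filtered-catalog universe, the disease-subnetwork rule).
    universe <- c(planted, strong_cat)
    repeat {
      deg <- universe_degree(ppi, planted, universe)
      bad <- setdiff(names(deg)[deg >= 10], designated)
      if (length(bad) == 0) break
      g <- bad[[1]]
      inc <- which((ppi$geneA == g & ppi$geneB %in% universe) |
                   (ppi$geneB == g & ppi$geneA %in% universe))
      other <- ifelse(ppi$geneA[inc] == g, ppi$geneB[inc], ppi$geneA[inc])
      # prefer dropping edges to non-designated partners
      inc <- inc[order(other %in% designated, other)]
      n_drop <- deg[[g]] - 9L
      ppi <- ppi[-inc[seq_len(n_drop)], , drop = FALSE]
    }
    rownames(ppi) <- NULL

    # Pathways: first ceil(n_pathways/5) sets are seeded with planted genes.
    pathways <- list()
    if (config$n_pathways > 0) {
      sizes <- sample(config$pathway_size_range[1]:config$pathway_size_range[2],
                      config$n_pathways, replace = TRUE)
      sizes <- pmin(sizes, n)
      n_seeded <- ceiling(config$n_pathways / 5)
      pathways <- lapply(seq_len(config$n_pathways), function(i) {
        sz <- sizes[i]
        if (i <= n_seeded && length(planted) > 0) {
          n_pl <- min(length(planted), max(1L, round(0.3 * sz)))
          pl <- sample(planted, n_pl)
          sort(c(pl, sample(setdiff(genes, pl), sz - n_pl)))
        } else sort(sample(genes, sz))
      })
      names(pathways) <- sprintf("PW%03d", seq_len(config$n_pathways))
    }

    list(ppi = ppi, catalog = catalog, pathways = pathways,
         planted_hub_genes = designated)
  })
}

# Degree of each gene in `of` within the subgraph induced by `universe`.
universe_degree <- function(edges, of, universe) {
  in_u <- edges$geneA %in% universe & edges$geneB %in% universe
  ea <- edges$geneA[in_u]; eb <- edges$geneB[in_u]
  stats::setNames(vapply(of, function(g) sum(ea == g) + sum(eb == g),
                         integer(1)), of)
}
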