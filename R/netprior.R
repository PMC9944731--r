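#' First-order PPI subnetwork around seed genes
#'
#' Maps seed genes (DMGs) into a tissue PPI edge list and extracts the
#' subgraph induced on the seeds plus their direct interactors. Seeds absent
#' from the PPI are dropped and counted.
#'
#' @param seeds Character vector of seed gene ids.
#' @param ppi data.frame of undirected edges (first two columns are the
#'   endpoints).
#' @return Object of class `methnet_subnetwork`: list with `graph` (igraph),
#'   `nodes` (data.frame gene_id/is_seed), `n_seeds_retained`,
#'   `n_seeds_dropped`.
#' @examples
#' ppi <- data.frame(geneA = c("a", "a", "a", "b"),
#'                   geneB = c("b", "c", "d", "e"))
#' sn <- first_order_subnetwork("a", ppi)
#' sn
#' @export
first_order_subnetwork <- function(seeds, ppi) {
  g <- igraph::simplify(igraph::graph_from_data_frame(ppi[, 1:2],
                                                      directed = FALSE))
  present <- intersect(seeds, igraph::V(g)$name)
  dropped <- setdiff(seeds, present)
  if (length(present) == 0) {
    warning("no seed gene maps into the PPI; returning empty subnetwork")
    sub <- igraph::make_empty_graph(0, directed = FALSE)
    nodes <- data.frame(gene_id = character(), is_seed = logical(),
                        stringsAsFactors = FALSE)
  } else {
    nbrs <- unique(unlist(lapply(
      igraph::adjacent_vertices(g, present), names)))
    keep <- union(present, nbrs)
    sub <- igraph::induced_subgraph(g, keep)
    nodes <- data.frame(gene_id = igraph::V(sub)$name,
                        is_seed = igraph::V(sub)$name %in% present,
                        stringsAsFactors = FALSE)
  }
  out <- list(graph = sub, nodes = nodes,
              n_seeds_retained = length(present),
              n_seeds_dropped = length(dropped))
  class(out) <- "methnet_subnetwork"
  out
}

#' Compute degree and betweenness centrality for a subnetwork
#'
#' Degree is the incident-edge count within the subnetwork; betweenness is
#' standard shortest-path betweenness, unnormalized, endpoints excluded.
#'
#' @param subnetwork A `methnet_subnetwork`.
#' @return The subnetwork with `degree` and `betweenness` columns added to
#'   `nodes`.
#' @export
compute_centralities <- function(subnetwork) {
  stopifnot(inherits(subnetwork, "methnet_subnetwork"))
  g <- subnetwork$graph
  if (igraph::vcount(g) == 0) {
    subnetwork$nodes$degree <- integer()
    subnetwork$nodes$betweenness <- numeric()
    return(subnetwork)
  }
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  idx <- match(subnetwork$nodes$gene_id, igraph::V(g)$name)
  subnetwork$nodes$degree <- as.integer(deg[idx])
  subnetwork$nodes$betweenness <- as.numeric(btw[idx])
  subnetwork
}

#' Select hub genes by degree centrality
#'
#' Hubs are seed nodes whose degree within the subnetwork is at least
#' `threshold` (inclusive), sorted by degree descending with lexicographic
#' tie-break.
#'
#' @param subnetwork A `methnet_subnetwork` with centralities computed.
#' @param threshold Degree threshold (default 10, inclusive).
#' @return data.frame gene_id/degree (possibly empty).
#' @export
select_hubs <- function(subnetwork, threshold = 10) {
  nodes <- subnetwork$nodes
  if (is.null(nodes$degree)) stop("run compute_centralities() first")
  hubs <- nodes[nodes$is_seed & nodes$degree >= threshold, , drop = FALSE]
  hubs <- hubs[order(-hubs$degree, hubs$gene_id),
               c("gene_id", "degree"), drop = FALSE]
  rownames(hubs) <- NULL
  hubs
}

#' Filter a disease-gene catalog by publication support
#'
#' Removes genes annotated with fewer than `min_publications` supporting
#' publications (the single-publication entries being likely false
#' positives).
#'
#' @param catalog data.frame with `gene` and `n_publications`.
#' @param min_publications Minimum count retained (default 2, inclusive).
#' @return Filtered catalog.
#' @export
filter_disease_catalog <- function(catalog, min_publications = 2) {
  catalog[catalog$n_publications >= min_publications, , drop = FALSE]
}

#' Promoter-restricted disease subnetwork merged over hub neighborhoods
#'
#' Restricts the reference edge list to the universe of promoter DMGs plus
#' publication-filtered disease genes, flags as hubs the DMG nodes with
#' degree >= `hub_threshold` inside that restricted graph, extracts each
#' hub's first-order neighborhood (with induced edges), and merges the
#' per-hub subnetworks by set union. Non-hub DMGs that appear in the merged
#' network (because they interact with a hub or its partners) are reported
#' separately. DMG-DMG edges are retained when present in the reference
#' edges.
#'
#' @param promoter_dmgs Character vector of promoter-annotated DMG ids.
#' @param catalog A publication-filtered disease catalog
#'   ([filter_disease_catalog()]).
#' @param reference_edges data.frame of undirected reference edges.
#' @param hub_threshold Degree threshold for hub DMGs (default 10).
#' @return List of class `methnet_disease_network`: `merged`
#'   (a `methnet_subnetwork` whose nodes carry role flags), `hub_dmgs`,
#'   `nonhub_dmgs` (non-hub DMGs inside the merged network), `counts`
#'   (node/edge/hub counts), `universe_graph` (igraph of the full restricted
#'   network).
#' @export
disease_subnetwork <- function(promoter_dmgs, catalog, reference_edges,
                               hub_threshold = 10) {
  disease_genes <- catalog$gene
  universe <- union(promoter_dmgs, disease_genes)
  e <- reference_edges[, 1:2]
  names(e) <- c("a", "b")
  e <- e[e$a %in% universe & e$b %in% universe, , drop = FALSE]
  g <- igraph::simplify(igraph::graph_from_data_frame(
    e, directed = FALSE,
    vertices = data.frame(name = universe, stringsAsFactors = FALSE)))

  deg <- igraph::degree(g)
  dmg_in <- intersect(promoter_dmgs, names(deg))
  hub_dmgs <- sort(dmg_in[deg[dmg_in] >= hub_threshold])

  empty_sub <- function() {
    sn <- list(graph = igraph::make_empty_graph(0, directed = FALSE),
               nodes = data.frame(gene_id = character(), is_seed = logical(),
                                  stringsAsFactors = FALSE),
               n_seeds_retained = 0L, n_seeds_dropped = 0L)
    class(sn) <- "methnet_subnetwork"
    sn
  }
  if (length(hub_dmgs) == 0) {
    warning("no hub DMG at degree >= ", hub_threshold,
            "; returning empty merged network")
    out <- list(merged = empty_sub(), hub_dmgs = character(),
                nonhub_dmgs = character(),
                counts = list(n_nodes = 0L, n_edges = 0L, n_hub_dmgs = 0L,
                              n_nonhub_dmgs = 0L),
                universe_graph = g)
    class(out) <- "methnet_disease_network"
    return(out)
  }

  # union of per-hub first-order neighborhoods, then induced edges
  node_union <- hub_dmgs
  for (h in hub_dmgs)
    node_union <- union(node_union,
                        names(igraph::neighbors(g, h)))
  merged_g <- igraph::induced_subgraph(g, node_union)
  # keep only edges belonging to some per-hub subgraph (hub + neighbors)
  keep_edge <- rep(FALSE, igraph::ecount(merged_g))
  ends <- igraph::ends(merged_g, igraph::E(merged_g))
  for (h in hub_dmgs) {
    hood <- c(h, names(igraph::neighbors(g, h)))
    keep_edge <- keep_edge | (ends[, 1] %in% hood & ends[, 2] %in% hood)
  }
  merged_g <- igraph::subgraph_from_edges(merged_g,
                                          igraph::E(merged_g)[keep_edge],
                                          delete.vertices = FALSE)

  nodes <- data.frame(
    gene_id = igraph::V(merged_g)$name,
    is_seed = igraph::V(merged_g)$name %in% promoter_dmgs,
    is_disease_gene = igraph::V(merged_g)$name %in% disease_genes,
    stringsAsFactors = FALSE)
  sn <- list(graph = merged_g, nodes = nodes,
             n_seeds_retained = sum(nodes$is_seed),
             n_seeds_dropped = length(setdiff(promoter_dmgs, nodes$gene_id)))
  class(sn) <- "methnet_subnetwork"
  sn <- compute_centralities(sn)
  sn$nodes$hub_flag <- sn$nodes$gene_id %in% hub_dmgs

  nonhub <- sort(setdiff(intersect(nodes$gene_id, promoter_dmgs), hub_dmgs))
  out <- list(
    merged = sn, hub_dmgs = hub_dmgs, nonhub_dmgs = nonhub,
    counts = list(n_nodes = igraph::vcount(merged_g),
                  n_edges = igraph::ecount(merged_g),
                  n_hub_dmgs = length(hub_dmgs),
                  n_nonhub_dmgs = length(nonhub)),
    universe_graph = g)
  class(out) <- "methnet_disease_network"
  out
}

#' @export
print.methnet_subnetwork <- function(x, ...) {
  cat(sprintf("methnet subnetwork: %d nodes, %d edges, %d seeds (%d dropped)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              x$n_seeds_retained, x$n_seeds_dropped))
  invisible(x)
}

#' @export
print.methnet_disease_network <- function(x, ...) {
  cat(sprintf(
    "methnet disease subnetwork: %d nodes, %d edges; %d hub DMGs, %d non-hub DMGs\n",
    x$counts$n_nodes, x$counts$n_edges, x$counts$n_hub_dmgs,
    x$counts$n_nonhub_dmgs))
  invisible(x)
}

#' Export a subnetwork in SIF and node-table form
#'
#' @param subnetwork A `methnet_subnetwork`.
#' @param sif_path,nodes_path Output paths (either may be NULL to skip).
#' @return Invisibly, the written paths.
#' @export
export_subnetwork <- function(subnetwork, sif_path = NULL, nodes_path = NULL) {
  paths <- character()
  if (!is.null(sif_path)) {
    ends <- igraph::ends(subnetwork$graph, igraph::E(subnetwork$graph))
    writeLines(sprintf("%s\tpp\t%s", ends[, 1], ends[, 2]), sif_path)
    paths <- c(paths, sif_path)
  }
  if (!is.null(nodes_path)) {
    utils::write.table(subnetwork$nodes, nodes_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- c(paths, nodes_path)
  }
  invisible(paths)
}

#' Share of hub genes annotated to promoters
#'
#' Reporting helper: given a hub list and a DMG table with promoter flags,
#' returns the rounded percentage of hubs whose gene has at least one
#' promoter dmCpG.
#'
#' @param hubs data.frame from [select_hubs()] (or character vector of ids).
#' @param dmg_table The `table` element of a [collate_dmgs()] result.
#' @return List with `n_hubs`, `n_promoter` and `pct_promoter`.
#' @export
hub_promoter_share <- function(hubs, dmg_table) {
  ids <- if (is.data.frame(hubs)) hubs$gene_id else hubs
  flag <- dmg_table$promoter_flag[match(ids, dmg_table$gene_id)]
  n_prom <- sum(flag, na.rm = TRUE)
  list(n_hubs = length(ids), n_promoter = n_prom,
       pct_promoter = if (length(ids) > 0) round(100 * n_prom / length(ids))
                      else NA_real_)
}
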