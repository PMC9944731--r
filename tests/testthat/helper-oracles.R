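# Independent oracles used to cross-check the implementation. These stay
# deliberately naive: enumeration and set arithmetic, no shared code paths
# with the package internals.

# Betweenness by exhaustive simple-path enumeration: for every ordered node
# pair, list all simple paths, keep the shortest, and credit interior nodes
# with the fraction of shortest paths passing through them.
bf_betweenness <- function(edges, nodes) {
  adj <- lapply(nodes, function(v) character())
  names(adj) <- nodes
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  all_paths <- function(from, to) {
    out <- list()
    walk <- function(path) {
      last <- path[length(path)]
      if (last == to) {
        out[[length(out) + 1L]] <<- path
        return()
      }
      for (nxt in adj[[last]]) if (!nxt %in% path) walk(c(path, nxt))
    }
    walk(from)
    out
  }
  btw <- setNames(numeric(length(nodes)), nodes)
  pairs <- utils::combn(nodes, 2)
  for (k in seq_len(ncol(pairs))) {
    s <- pairs[1, k]; t <- pairs[2, k]
    paths <- all_paths(s, t)
    if (length(paths) == 0) next
    lens <- lengths(paths)
    sp <- paths[lens == min(lens)]
    for (p in sp) {
      interior <- setdiff(p, c(s, t))
      btw[interior] <- btw[interior] + 1 / length(sp)
    }
  }
  btw
}

# Upper-tail hypergeometric P(X >= x) by full enumeration of all n-subsets
# of a size-N universe with K marked elements (feasible for N <= 16), or by
# the explicit combinatorial sum otherwise. Never calls phyper.
hyper_enum <- function(N, K, n, x) {
  if (N <= 16) {
    draws <- utils::combn(N, n)
    overlaps <- colSums(draws <= K) # mark elements 1..K
    mean(overlaps >= x)
  } else {
    j <- x:min(K, n)
    sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
  }
}

# Exact two-sided Wilcoxon rank-sum p by enumerating every assignment of
# ranks to group 1 (no ties assumed).
wilcox_enum <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  assignments <- utils::combn(n1 + n2, n1) # rank sets given to group 1
  w_all <- colSums(assignments)
  p_low <- mean(w_all <= w_obs)
  p_high <- mean(w_all >= w_obs)
  min(1, 2 * min(p_low, p_high))
}

# Node/edge union over per-hub first-order subgraphs by plain set
# arithmetic on an edge list.
merge_union_oracle <- function(edges, hubs) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  nbrs <- function(v) {
    c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1])
  }
  node_set <- character()
  edge_set <- character()
  for (h in hubs) {
    hood <- unique(c(h, nbrs(h)))
    node_set <- union(node_set, hood)
    in_hood <- edges[, 1] %in% hood & edges[, 2] %in% hood
    edge_set <- union(edge_set, key(edges[in_hood, 1], edges[in_hood, 2]))
  }
  list(n_nodes = length(node_set), n_edges = length(edge_set),
       nodes = sort(node_set))
}

# Small deterministic coverage tables for two samples.
toy_tables <- function() {
  mk <- function(pos, m, t) data.frame(chrom = "chr1", pos = pos,
                                       strand = "+", n_meth = m, n_total = t,
                                       stringsAsFactors = FALSE)
  list(
    case_1 = mk(c(100, 200, 300, 400, 500), c(8, 1, 10, 5, 0),
                c(10, 12, 15, 10, 11)),
    case_2 = mk(c(100, 200, 300, 400, 500), c(9, 2, 12, 4, 1),
                c(11, 13, 14, 12, 10)),
    ctrl_1 = mk(c(100, 200, 300, 400, 500), c(1, 1, 2, 5, 0),
                c(10, 9, 16, 11, 12)),
    ctrl_2 = mk(c(100, 200, 300, 400, 500), c(0, 2, 1, 6, 1),
                c(12, 14, 13, 10, 13)))
}

toy_groups <- c(case_1 = "case", case_2 = "case",
                ctrl_1 = "control", ctrl_2 = "control")
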