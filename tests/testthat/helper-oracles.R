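# Independent brute-force oracles used to validate the graph and FDR
# operations. Deliberately naive: plain data structures, no igraph.

# Benjamini-Hochberg step-up applied literally to the definition:
# q_(i) = min_{j >= i} p_(j) * m / j, capped at 1, back in input order.
oracle_bh <- function(p) {
  m <- length(p)
  if (m == 0L) return(numeric(0))
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(p[ord][i:m] * m / (i:m)))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Connected components by union-find on an edge list (two-column character
# matrix) plus isolated nodes; returns list of sorted node sets ordered by
# size desc then smallest member.
oracle_components <- function(nodes, edges) {
  parent <- stats::setNames(seq_along(nodes), nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(edges) > 0L) {
    for (k in seq_len(nrow(edges))) {
      ri <- find(match(edges[k, 1L], nodes))
      rj <- find(match(edges[k, 2L], nodes))
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_along(nodes), find, numeric(1))
  sets <- split(nodes, roots)
  sets <- lapply(sets, sort)
  ord <- order(-vapply(sets, length, integer(1)),
               vapply(sets, `[`, character(1), 1L))
  unname(sets[ord])
}

# One-step neighbourhood by direct enumeration over the edge list.
oracle_expand <- function(nodeset, edges) {
  nb <- character(0)
  if (length(edges) > 0L) {
    for (k in seq_len(nrow(edges))) {
      if (edges[k, 1L] %in% nodeset) nb <- c(nb, edges[k, 2L])
      if (edges[k, 2L] %in% nodeset) nb <- c(nb, edges[k, 1L])
    }
  }
  sort(unique(c(nodeset, nb)))
}

# Distinct seed neighbours per node, counted straight off the edge list.
oracle_seed_partners <- function(node, seeds, edges) {
  partners <- character(0)
  if (length(edges) > 0L) {
    for (k in seq_len(nrow(edges))) {
      if (edges[k, 1L] == node && edges[k, 2L] %in% seeds) {
        partners <- c(partners, edges[k, 2L])
      }
      if (edges[k, 2L] == node && edges[k, 1L] %in% seeds) {
        partners <- c(partners, edges[k, 1L])
      }
    }
  }
  length(unique(partners))
}

# Namespacing helpers mirroring the package's node naming.
protein_id_vec <- function(x) paste0("P:", toupper(x))
protein_edges <- function(edges) {
  if (length(edges) == 0L) return(matrix(character(0), ncol = 2L))
  cbind(protein_id_vec(edges[, 1L]), protein_id_vec(edges[, 2L]))
}

# Random simple undirected graph as a character edge matrix over n nodes.
random_edge_table <- function(n, p = 0.06) {
  nodes <- sprintf("N%03d", seq_len(n))
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < p
  edges <- cbind(nodes[pairs[keep, 1L]], nodes[pairs[keep, 2L]])
  list(nodes = nodes, edges = edges)
}

# Wrap an edge table as an unannotated protein-only mb_network keeping
# every node and edge; `seeds` controls the is_seed flag only.
edges_to_network <- function(nodes, edges, seeds = character(0)) {
  ppi <- data.frame(protein_a = edges[, 1L], protein_b = edges[, 2L],
                    stringsAsFactors = FALSE)
  # building with all nodes as seeds retains the full graph
  net <- suppressWarnings(build_base_network(nodes, ppi))
  net <- igraph::set_vertex_attr(net, "is_seed",
                                 value = igraph::V(net)$label %in% seeds)
  if (!inherits(net, "mb_network")) class(net) <- c("mb_network", class(net))
  net
}
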