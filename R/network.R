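## Network builder: seed-anchored base PPI network, drug-target grafting,
## per-comparison expression annotation, connected components.
##
## The network is an undirected igraph with namespaced vertex names
## ("P:<SYMBOL>" for proteins, "D:<drug id>" for drugs), vertex attributes
## node_type ("protein"/"drug"), is_seed, label (bare symbol or drug name),
## and per-comparison attributes "<cmp>_lfc/_p/_q/_called"; edges carry
## edge_type ("ppi"/"drug_target").

protein_id <- function(symbol) paste0("P:", toupper(symbol))

# igraph mutators return plain igraph objects; restore our class and the
# comparison registry after each modification
as_mb_network <- function(g, comparisons = NULL) {
  if (!inherits(g, "mb_network")) class(g) <- c("mb_network", class(g))
  if (!is.null(comparisons)) attr(g, "comparisons") <- comparisons
  g
}
drug_id <- function(id) paste0("D:", id)
strip_ns <- function(x) sub("^[PD]:", "", x)

#' Map mouse seed symbols to human orthologs
#'
#' Takes the union of all human symbols mapped from any input mouse symbol
#' (one-to-many homology keeps all targets). Unmapped inputs are reported,
#' not fatal.
#'
#' @param mouse_symbols character vector of mouse gene symbols.
#' @param orthologs data.frame with columns `mouse_symbol`, `human_symbol`.
#' @return list with `seeds` (sorted human symbols) and `unmapped`
#'   (mouse symbols with no ortholog row).
#' @export
map_seeds <- function(mouse_symbols, orthologs) {
  stopifnot(all(c("mouse_symbol", "human_symbol") %in% names(orthologs)))
  mouse_symbols <- unique(as.character(mouse_symbols))
  hit <- orthologs$mouse_symbol %in% mouse_symbols
  mapped_mouse <- unique(orthologs$mouse_symbol[hit])
  unmapped <- setdiff(mouse_symbols, mapped_mouse)
  if (length(unmapped) > 0L) {
    np_warn("seeds", sprintf("%d seed symbol(s) without human ortholog: %s",
                             length(unmapped),
                             paste(utils::head(unmapped, 5L), collapse = ", ")))
  }
  list(seeds = sort(unique(toupper(orthologs$human_symbol[hit]))),
       unmapped = unmapped)
}

#' Build the seed-anchored base PPI network
#'
#' Keeps exactly the interactions that involve at least one seed protein
#' (edges between two non-seed proteins are excluded; set
#' `include_neighbor_edges = TRUE` for the permissive variant that also
#' keeps edges between two retained neighbours). Seeds with no retrieved
#' interaction are kept as isolated nodes. Symbols are upper-cased before
#' matching; self-loops and duplicate pairs are removed.
#'
#' @param seeds character vector of human seed symbols.
#' @param ppi data.frame with columns `protein_a`, `protein_b`.
#' @param include_neighbor_edges also keep edges between two non-seed
#'   proteins when both already appear as seed neighbours.
#' @return an `mb_network` (classed igraph).
#' @export
build_base_network <- function(seeds, ppi, include_neighbor_edges = FALSE) {
  stopifnot(all(c("protein_a", "protein_b") %in% names(ppi)))
  seeds <- unique(toupper(as.character(seeds)))
  if (length(seeds) == 0L) {
    np_warn("network", "empty seed set: base network is empty")
  }
  a <- toupper(as.character(ppi$protein_a))
  b <- toupper(as.character(ppi$protein_b))
  ok <- nzchar(a) & nzchar(b)
  if (!all(ok)) np_stop("network", "PPI table contains empty symbols")
  loops <- a == b
  if (any(loops)) {
    np_warn("network", sprintf("removed %d self-loop(s) from PPI input", sum(loops)))
    a <- a[!loops]; b <- b[!loops]
  }
  key <- paste(pmin(a, b), pmax(a, b))
  dup <- duplicated(key)
  a <- a[!dup]; b <- b[!dup]

  keep <- a %in% seeds | b %in% seeds
  if (include_neighbor_edges) {
    nodes0 <- union(seeds, union(a[keep], b[keep]))
    keep <- keep | (a %in% nodes0 & b %in% nodes0)
  }
  a <- a[keep]; b <- b[keep]
  nodes <- sort(union(seeds, union(a, b)))

  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  igraph::V(g)$name <- protein_id(nodes)
  igraph::V(g)$label <- nodes
  igraph::V(g)$node_type <- "protein"
  igraph::V(g)$is_seed <- nodes %in% seeds
  if (length(a) > 0L) {
    g <- igraph::add_edges(g, rbind(protein_id(a), protein_id(b)),
                           attr = list(edge_type = rep("ppi", length(a))))
  }
  class(g) <- c("mb_network", class(g))
  g
}

#' Graft drug-target interactions onto the network
#'
#' For every drug-target row whose target protein is present in the
#' network, adds the drug node (once) and a `drug_target` edge. Drugs with
#' no target in the network are omitted, so every drug node has degree
#' >= 1. Idempotent: re-applying the same table changes nothing.
#'
#' @param network an `mb_network`.
#' @param drugs data.frame with columns `drug_id`, `drug_name`,
#'   `target_symbol`.
#' @return the augmented `mb_network`.
#' @export
attach_drugs <- function(network, drugs) {
  stopifnot(inherits(network, "mb_network"),
            all(c("drug_id", "drug_name", "target_symbol") %in% names(drugs)))
  drugs <- unique(drugs[, c("drug_id", "drug_name", "target_symbol")])
  tgt <- protein_id(drugs$target_symbol)
  present <- tgt %in% igraph::V(network)$name[igraph::V(network)$node_type == "protein"]
  drugs <- drugs[present, , drop = FALSE]
  tgt <- tgt[present]
  cmps <- network_comparisons(network)
  if (nrow(drugs) == 0L) return(network)

  new_drugs <- unique(drugs[, c("drug_id", "drug_name")])
  have <- drug_id(new_drugs$drug_id) %in% igraph::V(network)$name
  if (any(!have)) {
    add <- new_drugs[!have, , drop = FALSE]
    network <- igraph::add_vertices(
      network, nrow(add),
      attr = list(name = drug_id(add$drug_id), label = add$drug_name,
                  node_type = rep("drug", nrow(add)),
                  is_seed = rep(FALSE, nrow(add))))
  }
  # add only edges not already present (keeps the operation idempotent)
  want <- cbind(drug_id(drugs$drug_id), tgt)
  existing <- igraph::as_edgelist(network)
  ekey <- paste(pmin(existing[, 1L], existing[, 2L]),
                pmax(existing[, 1L], existing[, 2L]))
  wkey <- paste(pmin(want[, 1L], want[, 2L]), pmax(want[, 1L], want[, 2L]))
  new <- !wkey %in% ekey & !duplicated(wkey)
  if (any(new)) {
    network <- igraph::add_edges(
      network, t(want[new, , drop = FALSE]),
      attr = list(edge_type = rep("drug_target", sum(new))))
  }
  as_mb_network(network, cmps)
}

#' Annotate protein nodes with per-comparison expression statistics
#'
#' Attaches, for every comparison, the gene-level best-probe statistics
#' (`<cmp>_lfc`, `<cmp>_p`, `<cmp>_q`) and the over-expression call flag
#' (`<cmp>_called`) to every protein node. Proteins absent from the
#' expression data get `NA` statistics, `called = FALSE` and
#' `measured = FALSE`. Drug nodes are never annotated.
#'
#' @param network an `mb_network`.
#' @param de_by_comparison named list of `gene_calls` objects (names are
#'   the comparison labels).
#' @return the annotated `mb_network`.
#' @export
annotate_de <- function(network, de_by_comparison) {
  stopifnot(inherits(network, "mb_network"), is.list(de_by_comparison))
  if (is.null(names(de_by_comparison)) || any(!nzchar(names(de_by_comparison)))) {
    np_stop("annotate", "de_by_comparison must be a named list")
  }
  is_prot <- igraph::V(network)$node_type == "protein"
  sym <- strip_ns(igraph::V(network)$name)
  measured <- rep(FALSE, length(sym))
  for (cmp in names(de_by_comparison)) {
    calls <- de_by_comparison[[cmp]]
    stopifnot(inherits(calls, "gene_calls"))
    idx <- match(sym, calls$gene)
    idx[!is_prot] <- NA_integer_
    measured <- measured | !is.na(idx)
    network <- igraph::set_vertex_attr(network, paste0(cmp, "_lfc"),
                                       value = calls$lfc[idx])
    network <- igraph::set_vertex_attr(network, paste0(cmp, "_p"),
                                       value = calls$p[idx])
    network <- igraph::set_vertex_attr(network, paste0(cmp, "_q"),
                                       value = calls$q[idx])
    called <- calls$called[idx]
    called[is.na(called)] <- FALSE
    called[!is_prot] <- FALSE
    network <- igraph::set_vertex_attr(network, paste0(cmp, "_called"),
                                       value = called)
  }
  network <- igraph::set_vertex_attr(network, "measured",
                                     value = measured & is_prot)
  as_mb_network(network,
                union(attr(network, "comparisons") %||% character(0),
                      names(de_by_comparison)))
}

#' Comparisons a network has been annotated with
#' @param network an `mb_network`.
#' @return character vector of comparison labels.
#' @export
network_comparisons <- function(network) {
  attr(network, "comparisons") %||% character(0)
}

#' Connected components of a network
#'
#' @param network an `mb_network` (or plain igraph).
#' @return list of character vectors of node names (each sorted), ordered
#'   by decreasing size then by lexicographic smallest member.
#' @export
connected_components <- function(network) {
  comp <- igraph::components(network)
  sets <- split(igraph::V(network)$name, comp$membership)
  sets <- lapply(sets, sort)
  ord <- order(-vapply(sets, length, integer(1)),
               vapply(sets, `[`, character(1), 1L))
  unname(sets[ord])
}

#' @export
print.mb_network <- function(x, ...) {
  nt <- igraph::V(x)$node_type
  et <- igraph::E(x)$edge_type %||% character(0)
  cat(sprintf("Drug-target interaction network: %d nodes (%d proteins, %d seeds, %d drugs), %d edges (%d ppi, %d drug-target)\n",
              igraph::vcount(x), sum(nt == "protein"),
              sum(igraph::V(x)$is_seed), sum(nt == "drug"),
              igraph::ecount(x), sum(et == "ppi"), sum(et == "drug_target")))
  cmps <- network_comparisons(x)
  if (length(cmps) > 0L) {
    cat(sprintf("  annotated comparisons: %s\n", paste(cmps, collapse = ", ")))
  }
  invisible(x)
}

#' Summary counts for a network
#' @param object an `mb_network`.
#' @param ... unused.
#' @return named list of counts (nodes, proteins, seeds, drugs, edges by type).
#' @export
summary.mb_network <- function(object, ...) {
  nt <- igraph::V(object)$node_type
  et <- if (igraph::ecount(object) > 0L) igraph::E(object)$edge_type else character(0)
  list(nodes = igraph::vcount(object),
       proteins = sum(nt == "protein"),
       seeds = sum(igraph::V(object)$is_seed),
       drugs = sum(nt == "drug"),
       edges = igraph::ecount(object),
       ppi_edges = sum(et == "ppi"),
       drug_target_edges = sum(et == "drug_target"),
       components = length(connected_components(object)))
}
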