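## Target discovery: per-comparison and common sub-network extraction,
## druggable over-expressed proteins with their seed (CIS) partners, and
## bridging-node detection.

#' Select significantly up-regulated protein nodes
#'
#' Protein nodes whose over-expression call for `comparison` is positive.
#' With `alpha = NULL` the call flag stored during [annotate_de()] is used;
#' supplying `alpha` (and optionally `min_lfc`) recomputes the selection
#' from the stored q-values and fold changes. Drug nodes are never
#' selected.
#'
#' @param network an annotated `mb_network`.
#' @param comparison comparison label.
#' @param alpha optional FDR threshold overriding the stored call flag.
#' @param min_lfc minimum log2 fold change when `alpha` is supplied.
#' @return character vector of selected node names (`"P:<SYMBOL>"`).
#' @export
select_upregulated <- function(network, comparison, alpha = NULL, min_lfc = 0) {
  stopifnot(inherits(network, "mb_network"))
  if (!comparison %in% network_comparisons(network)) {
    np_stop("discover", sprintf("network not annotated for comparison '%s'",
                                comparison))
  }
  is_prot <- igraph::V(network)$node_type == "protein"
  if (is.null(alpha)) {
    sel <- igraph::vertex_attr(network, paste0(comparison, "_called"))
  } else {
    assert_scalar_prob(alpha, "alpha", stage = "discover")
    q <- igraph::vertex_attr(network, paste0(comparison, "_q"))
    lfc <- igraph::vertex_attr(network, paste0(comparison, "_lfc"))
    sel <- !is.na(q) & q < alpha & !is.na(lfc) & lfc > min_lfc
  }
  sort(igraph::V(network)$name[is_prot & sel])
}

#' One-step neighbourhood expansion
#'
#' Expands a node set to include all direct neighbours — both neighbouring
#' proteins and any drugs targeting the input proteins — and returns the
#' induced subgraph on the expanded set (edges between two neighbours are
#' kept; set `star_only = TRUE` to keep only edges incident to the input
#' set). Records per-node provenance: `overexpressed` (input), `drug`, or
#' `neighbor`.
#'
#' @param network an `mb_network`.
#' @param nodeset character vector of protein node names to expand from.
#' @param star_only drop edges between two non-input nodes.
#' @return a `subnetwork`: list with `graph` (induced `mb_network`),
#'   `provenance` (named character) and `origin` (the input node set).
#' @export
expand_one_step <- function(network, nodeset, star_only = FALSE) {
  stopifnot(inherits(network, "mb_network"))
  nodeset <- unique(nodeset)
  bad <- setdiff(nodeset, igraph::V(network)$name)
  if (length(bad) > 0L) {
    np_stop("discover", sprintf("node(s) not in network: %s",
                                paste(utils::head(bad, 5L), collapse = ", ")))
  }
  if (length(nodeset) == 0L) {
    np_warn("discover", "empty input node set: empty subnetwork")
    g <- igraph::induced_subgraph(network, integer(0))
    class(g) <- c("mb_network", class(g))
    attr(g, "comparisons") <- network_comparisons(network)
    return(structure(list(graph = g,
                          provenance = stats::setNames(character(0), character(0)),
                          origin = character(0)),
                     class = "subnetwork"))
  }
  nb <- unique(unlist(lapply(igraph::adjacent_vertices(network, nodeset),
                             names), use.names = FALSE))
  all_nodes <- union(nodeset, nb)
  g <- igraph::induced_subgraph(network, all_nodes)
  if (star_only && igraph::ecount(g) > 0L) {
    el <- igraph::as_edgelist(g)
    keep <- el[, 1L] %in% nodeset | el[, 2L] %in% nodeset
    g <- igraph::delete_edges(g, which(!keep))
  }
  class(g) <- c("mb_network", class(g))
  attr(g, "comparisons") <- network_comparisons(network)
  prov <- ifelse(igraph::V(g)$name %in% nodeset, "overexpressed",
                 ifelse(igraph::V(g)$node_type == "drug", "drug", "neighbor"))
  structure(list(graph = g,
                 provenance = stats::setNames(prov, igraph::V(g)$name),
                 origin = nodeset),
            class = "subnetwork")
}

#' Refined network around the commonly over-expressed genes
#'
#' The sub-network induced by the genes significantly over-expressed in
#' every tumour subgroup plus their direct protein interactors and any
#' drugs targeting them — [expand_one_step()] applied to the common gene
#' set.
#'
#' @param network an annotated `mb_network`.
#' @param common_genes character vector of gene symbols (from
#'   [intersect_common()]).
#' @param ... passed to [expand_one_step()].
#' @return a `subnetwork`.
#' @export
build_refined_common <- function(network, common_genes, ...) {
  ids <- protein_id(common_genes)
  present <- ids[ids %in% igraph::V(network)$name]
  if (length(present) == 0L && length(common_genes) > 0L) {
    np_warn("discover", "no common gene present in the network")
  }
  expand_one_step(network, present, ...)
}

#' @export
print.subnetwork <- function(x, ...) {
  cat(sprintf("Subnetwork: %d nodes (%d over-expressed, %d neighbours, %d drugs), %d edges\n",
              igraph::vcount(x$graph),
              sum(x$provenance == "overexpressed"),
              sum(x$provenance == "neighbor"),
              sum(x$provenance == "drug"),
              igraph::ecount(x$graph)))
  invisible(x)
}

# adjacency helpers on a subnetwork graph
adjacent_names <- function(g, node) {
  names(igraph::adjacent_vertices(g, node)[[1]])
}

#' Report druggable over-expressed proteins and their seed partners
#'
#' One row per over-expressed protein carrying at least one drug-target
#' edge in the subnetwork. Seed partners are the seed proteins adjacent to
#' it (sorted); rows are ordered by decreasing seed-partner count, then by
#' symbol.
#'
#' @param sub a `subnetwork` from [expand_one_step()] or
#'   [build_refined_common()].
#' @return a `druggable_report` data.frame: `protein`, `seed_partners`
#'   (';'-joined), `n_seed_partners`, `drugs` (';'-joined `id|name`),
#'   `n_drugs`, `degree`, plus one logical `called_<cmp>` column per
#'   annotated comparison.
#' @export
report_druggable <- function(sub) {
  stopifnot(inherits(sub, "subnetwork"))
  g <- sub$graph
  over <- names(sub$provenance)[sub$provenance == "overexpressed"]
  if (length(over) == 0L) return(empty_druggable_report(g))
  el <- if (igraph::ecount(g) > 0L) igraph::as_edgelist(g) else
    matrix(character(0), ncol = 2L)
  et <- if (igraph::ecount(g) > 0L) igraph::E(g)$edge_type else character(0)
  seeds <- igraph::V(g)$name[igraph::V(g)$is_seed]
  labels <- stats::setNames(igraph::V(g)$label, igraph::V(g)$name)

  rows <- lapply(over, function(v) {
    inc <- el[, 1L] == v | el[, 2L] == v
    other <- ifelse(el[inc, 1L] == v, el[inc, 2L], el[inc, 1L])
    typ <- et[inc]
    drugs <- sort(other[typ == "drug_target"])
    if (length(drugs) == 0L) return(NULL)
    partners <- sort(strip_ns(intersect(other[typ == "ppi"], seeds)))
    data.frame(
      protein = strip_ns(v),
      seed_partners = paste(partners, collapse = ";"),
      n_seed_partners = length(partners),
      drugs = paste(paste0(strip_ns(drugs), "|", labels[drugs]), collapse = ";"),
      n_drugs = length(drugs),
      degree = sum(inc),
      stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty_druggable_report(g))
  rep_ <- do.call(rbind, rows)
  for (cmp in network_comparisons(g)) {
    called <- igraph::vertex_attr(g, paste0(cmp, "_called"))
    rep_[[paste0("called_", cmp)]] <-
      called[match(protein_id(rep_$protein), igraph::V(g)$name)]
  }
  rep_ <- rep_[order(-rep_$n_seed_partners, rep_$protein), , drop = FALSE]
  rownames(rep_) <- NULL
  class(rep_) <- c("druggable_report", "data.frame")
  rep_
}

empty_druggable_report <- function(g) {
  rep_ <- data.frame(protein = character(0), seed_partners = character(0),
                     n_seed_partners = integer(0), drugs = character(0),
                     n_drugs = integer(0), degree = integer(0),
                     stringsAsFactors = FALSE)
  for (cmp in network_comparisons(g)) rep_[[paste0("called_", cmp)]] <- logical(0)
  class(rep_) <- c("druggable_report", "data.frame")
  rep_
}

#' Find bridging nodes
#'
#' Bridging nodes are over-expressed druggable proteins adjacent to at
#' least `min_partners` distinct seed proteins — they connect otherwise
#' separate seed-centred regions of the network and are prime candidates
#' for therapies hitting several driver hubs at once.
#'
#' @param sub a `subnetwork`.
#' @param min_partners minimum number of distinct seed partners (>= 2).
#' @return a data.frame subset of [report_druggable()] rows, sorted by
#'   decreasing partner count.
#' @export
find_bridging <- function(sub, min_partners = 2L) {
  if (!is.numeric(min_partners) || min_partners < 2L) {
    np_stop("discover", "min_partners must be >= 2")
  }
  rep_ <- report_druggable(sub)
  out <- rep_[rep_$n_seed_partners >= min_partners, , drop = FALSE]
  out <- out[order(-out$n_seed_partners, out$protein), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank druggable targets
#'
#' Stable priority order for therapeutic candidates: number of subgroups
#' in which the protein is called over-expressed (desc), seed-partner
#' count (desc), subnetwork degree (desc), then symbol (asc).
#'
#' @param report a `druggable_report` from [report_druggable()].
#' @return the report rows in priority order, with a `rank` column.
#' @export
rank_targets <- function(report) {
  stopifnot(inherits(report, "data.frame"))
  called_cols <- grep("^called_", names(report), value = TRUE)
  n_called <- if (length(called_cols) > 0L) {
    rowSums(as.matrix(report[, called_cols, drop = FALSE]), na.rm = TRUE)
  } else rep(0, nrow(report))
  ord <- order(-n_called, -report$n_seed_partners, -report$degree,
               report$protein)
  out <- report[ord, , drop = FALSE]
  out$n_subgroups_called <- n_called[ord]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
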