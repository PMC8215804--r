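## Interchange: schema-validated TSV readers, expression-matrix I/O, and
## Cytoscape-importable network writers (SIF, GraphML, node-attribute TSV)
## with round-trip readers.
##
## Canonical dialect: tab-delimited UTF-8, '#' comment lines ignored.

#' Read and validate a delimited table
#'
#' @param path file path.
#' @param schema named list: `columns` (required column names), optional
#'   `key` (column set whose duplicated rows are dropped with a warning)
#'   and `no_empty` (columns that must not contain empty strings).
#' @param stage label used in error/warning messages.
#' @return data.frame with (at least) the schema columns.
#' @export
read_table <- function(path, schema, stage = "read") {
  if (!file.exists(path)) np_stop(stage, sprintf("file not found: %s", path))
  tab <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                      comment.char = "#", stringsAsFactors = FALSE,
                      check.names = FALSE),
    error = function(e) np_stop(stage, sprintf("cannot read %s: %s", path,
                                               conditionMessage(e))))
  missing <- setdiff(schema$columns, names(tab))
  if (length(missing) > 0L) {
    np_stop(stage, sprintf("%s: missing required column(s): %s", path,
                           paste(missing, collapse = ", ")))
  }
  for (col in schema$no_empty %||% character(0)) {
    if (any(!nzchar(trimws(as.character(tab[[col]]))))) {
      np_stop(stage, sprintf("%s: empty values in column '%s'", path, col))
    }
  }
  if (!is.null(schema$key)) {
    dup <- duplicated(tab[, schema$key, drop = FALSE])
    if (any(dup)) {
      np_warn(stage, sprintf("%s: dropped %d duplicate row(s) on key (%s)",
                             path, sum(dup), paste(schema$key, collapse = ", ")))
      tab <- tab[!dup, , drop = FALSE]
      rownames(tab) <- NULL
    }
  }
  tab
}

schema_annotation <- list(columns = c("sample_id", "group"),
                          key = "sample_id", no_empty = c("sample_id", "group"))
schema_probe_map <- list(columns = c("probe_id", "gene_symbol"),
                         key = "probe_id", no_empty = c("probe_id", "gene_symbol"))
schema_orthologs <- list(columns = c("mouse_symbol", "human_symbol"),
                         key = c("mouse_symbol", "human_symbol"),
                         no_empty = c("mouse_symbol", "human_symbol"))
schema_ppi <- list(columns = c("protein_a", "protein_b"),
                   no_empty = c("protein_a", "protein_b"))
schema_drugs <- list(columns = c("drug_id", "drug_name", "target_symbol"),
                     key = c("drug_id", "target_symbol"),
                     no_empty = c("drug_id", "target_symbol"))

#' Read pipeline input tables
#'
#' Convenience wrappers around [read_table()] with the canonical schemas.
#' @param path file path.
#' @name readers
#' @export
read_sample_annotation <- function(path) read_table(path, schema_annotation, "annot")

#' @rdname readers
#' @export
read_probe_map <- function(path) read_table(path, schema_probe_map, "probes")

#' @rdname readers
#' @export
read_ortholog_table <- function(path) read_table(path, schema_orthologs, "orthologs")

#' @rdname readers
#' @export
read_ppi_edges <- function(path) read_table(path, schema_ppi, "ppi")

#' @rdname readers
#' @export
read_drug_targets <- function(path) read_table(path, schema_drugs, "drugs")

#' Read / write a probe-by-sample expression matrix
#'
#' TSV with a `probe_id` first column and one column per sample.
#' @param path file path.
#' @return numeric matrix with probe rownames and sample colnames.
#' @export
read_expression_matrix <- function(path) {
  tab <- read_table(path, list(columns = "probe_id", key = "probe_id",
                               no_empty = "probe_id"), "expression")
  mat <- as.matrix(tab[, setdiff(names(tab), "probe_id"), drop = FALSE])
  if (!is.numeric(mat)) np_stop("expression", "non-numeric expression values")
  rownames(mat) <- tab$probe_id
  mat
}

#' @rdname read_expression_matrix
#' @param mat numeric matrix to write.
#' @export
write_expression_matrix <- function(mat, path) {
  stopifnot(is.matrix(mat))
  tab <- data.frame(probe_id = rownames(mat), mat, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write_tsv(tab, path)
}

# plain TSV writer: no quoting, no rownames, deterministic formatting
write_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a network to disk
#'
#' Formats: `"sif"` (Cytoscape simple interaction format; relations `pp`
#' for protein-protein and `dt` for drug-target edges, plus singleton
#' lines for isolated nodes), `"graphml"` (all node and edge attributes),
#' `"node_tsv"` (one row per node with all attributes).
#'
#' @param network an `mb_network`.
#' @param path output file path.
#' @param format one of `"sif"`, `"graphml"`, `"node_tsv"`.
#' @return invisibly, `path`.
#' @seealso [read_network()] for the inverse.
#' @export
write_network <- function(network, path, format = c("sif", "graphml", "node_tsv")) {
  stopifnot(inherits(network, "mb_network"))
  format <- match.arg(format)
  if (format == "sif") {
    lines <- character(0)
    if (igraph::ecount(network) > 0L) {
      el <- igraph::as_edgelist(network)
      rel <- ifelse(igraph::E(network)$edge_type == "drug_target", "dt", "pp")
      # canonical orientation: drug first for dt, lexicographic for pp
      swap <- (rel == "dt" & !startsWith(el[, 1L], "D:")) |
        (rel == "pp" & el[, 1L] > el[, 2L])
      el[swap, ] <- el[swap, c(2L, 1L), drop = FALSE]
      lines <- paste(el[, 1L], rel, el[, 2L], sep = "\t")
      lines <- sort(lines)
    }
    isolated <- igraph::V(network)$name[igraph::degree(network) == 0L]
    writeLines(c(lines, sort(isolated)), path)
  } else if (format == "graphml") {
    g <- network
    class(g) <- setdiff(class(g), "mb_network")
    igraph::write_graph(g, path, format = "graphml")
  } else {
    attrs <- igraph::vertex_attr(network)
    tab <- data.frame(attrs[setdiff(names(attrs), "name")],
                      check.names = FALSE, stringsAsFactors = FALSE)
    tab <- cbind(data.frame(node_id = igraph::V(network)$name,
                            stringsAsFactors = FALSE), tab)
    tab <- tab[order(tab$node_id), , drop = FALSE]
    write_tsv(tab, path)
  }
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' GraphML restores the full network (nodes, edges, all attributes); SIF
#' restores the topology and node/edge types (namespaced ids carry the
#' type). `node_tsv` is attribute-only and has no reader.
#'
#' @param path file path.
#' @param format `"graphml"` or `"sif"`.
#' @return an `mb_network`.
#' @export
read_network <- function(path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  if (!file.exists(path)) np_stop("read", sprintf("file not found: %s", path))
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    # igraph adds a synthetic 'id' vertex attribute on read; drop it
    if ("id" %in% igraph::vertex_attr_names(g)) {
      g <- igraph::delete_vertex_attr(g, "id")
    }
    # NA numeric attributes round-trip as NaN; normalize back to NA
    for (a in igraph::vertex_attr_names(g)) {
      v <- igraph::vertex_attr(g, a)
      if (is.numeric(v) && any(is.nan(v))) {
        v[is.nan(v)] <- NA_real_
        g <- igraph::set_vertex_attr(g, a, value = v)
      }
    }
    class(g) <- c("mb_network", class(g))
    cmps <- unique(sub("_called$", "",
                       grep("_called$", igraph::vertex_attr_names(g), value = TRUE)))
    if (length(cmps) > 0L) attr(g, "comparisons") <- cmps
    g
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    n_fields <- lengths(parts)
    if (any(!n_fields %in% c(1L, 3L))) np_stop("read", "malformed SIF line")
    edges <- do.call(rbind, parts[n_fields == 3L])
    singles <- unlist(parts[n_fields == 1L])
    nodes <- sort(unique(c(edges[, 1L], edges[, 3L], singles)))
    g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
    igraph::V(g)$name <- nodes
    igraph::V(g)$node_type <- ifelse(startsWith(nodes, "D:"), "drug", "protein")
    igraph::V(g)$label <- strip_ns(nodes)
    igraph::V(g)$is_seed <- FALSE
    if (!is.null(edges)) {
      g <- igraph::add_edges(g, rbind(edges[, 1L], edges[, 3L]),
                             attr = list(edge_type = ifelse(edges[, 2L] == "dt",
                                                            "drug_target", "ppi")))
    }
    class(g) <- c("mb_network", class(g))
    g
  }
}

#' Test two networks for graph equality
#'
#' Equal iff they have the same node names, the same node attributes, and
#' the same unordered typed edge set.
#'
#' @param a,b `mb_network` objects.
#' @param attrs compare vertex attributes too (default TRUE).
#' @return logical.
#' @export
network_equal <- function(a, b, attrs = TRUE) {
  na_ <- sort(igraph::V(a)$name); nb <- sort(igraph::V(b)$name)
  if (!identical(na_, nb)) return(FALSE)
  ekey <- function(g) {
    if (igraph::ecount(g) == 0L) return(character(0))
    el <- igraph::as_edgelist(g)
    sort(paste(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]),
               igraph::E(g)$edge_type))
  }
  if (!identical(ekey(a), ekey(b))) return(FALSE)
  if (attrs) {
    an <- sort(setdiff(igraph::vertex_attr_names(a), "name"))
    bn <- sort(setdiff(igraph::vertex_attr_names(b), "name"))
    if (!identical(an, bn)) return(FALSE)
    oa <- order(igraph::V(a)$name); ob <- order(igraph::V(b)$name)
    for (at in an) {
      va <- igraph::vertex_attr(a, at)[oa]
      vb <- igraph::vertex_attr(b, at)[ob]
      if (is.numeric(va) && is.numeric(vb)) {
        same <- (is.na(va) & is.na(vb)) |
          (!is.na(va) & !is.na(vb) & abs(va - vb) < 1e-9)
        if (!all(same)) return(FALSE)
      } else if (!identical(as.character(va), as.character(vb))) {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' Write a run manifest
#'
#' JSON record of the inputs (with checksums), parameters and per-stage
#' counts of a pipeline run.
#'
#' @param manifest named list (see [run_pipeline()]).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
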