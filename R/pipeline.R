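## End-to-end pipeline: normalize -> per-subgroup differential expression ->
## over-expression calls -> common intersection -> seed-anchored network ->
## drug grafting -> annotation -> subgroup + common subnetworks -> reports.

#' Analyze a study in memory
#'
#' Runs the complete analysis on in-memory inputs (e.g. the output of
#' [simulate_study()], or tables assembled from files). Stages:
#' normalization, moderated-t differential expression of each tumour group
#' against the pooled normal reference, gene-level over-expression calls,
#' intersection across subgroups, seed-anchored network construction with
#' drug-target grafting and expression annotation, one-step subnetwork
#' expansion per subgroup and around the common gene set, and the
#' druggable/bridging target reports.
#'
#' @param study list with elements `matrix`, `annotation`, `probe_map`,
#'   `seeds` (human symbols), `ppi`, `drugs` (see [simulate_study()]).
#' @param case_groups tumour group labels; default: every annotation group
#'   not starting with `"normal"`.
#' @param reference_groups reference labels, pooled; default: groups
#'   starting with `"normal"`.
#' @param alpha FDR threshold for over-expression calls.
#' @param min_lfc minimum log2 fold change for calls.
#' @param normalize normalization steps (see [normalize_expression()]),
#'   or `NULL` to skip.
#' @param include_neighbor_edges passed to [build_base_network()].
#' @param star_only passed to [expand_one_step()].
#' @return an `mb_run` object: list with `de`, `calls`, `common`,
#'   `network`, `subnetworks` (one per subgroup plus `"common"`),
#'   `druggable` (reports per subnetwork), `bridging` (common
#'   subnetwork), `ranked` (prioritized common targets), `params`,
#'   `counts`.
#' @export
analyze_study <- function(study,
                          case_groups = NULL, reference_groups = NULL,
                          alpha = 0.05, min_lfc = 0,
                          normalize = "center_scale",
                          include_neighbor_edges = FALSE,
                          star_only = FALSE) {
  assert_scalar_prob(alpha, "alpha", stage = "params")
  for (el in c("matrix", "annotation", "probe_map", "seeds", "ppi", "drugs")) {
    if (is.null(study[[el]])) np_stop("inputs", sprintf("study element '%s' missing", el))
  }
  groups <- unique(study$annotation$group)
  if (is.null(reference_groups)) {
    reference_groups <- grep("^normal", groups, value = TRUE)
  }
  if (is.null(case_groups)) {
    case_groups <- setdiff(groups, c(reference_groups, "WNT", "other"))
  }
  if (length(reference_groups) == 0L) np_stop("params", "no reference group")
  if (length(case_groups) == 0L) np_stop("params", "no case group")

  mat <- study$matrix
  if (!is.null(normalize)) mat <- normalize_expression(mat, normalize)

  de <- list(); calls <- list()
  for (cg in case_groups) {
    spec <- comparison_spec(cg, cg, reference_groups)
    de[[cg]] <- moderated_ttest(mat, study$annotation, spec)
    calls[[cg]] <- call_overexpressed(de[[cg]], study$probe_map,
                                      alpha = alpha, min_lfc = min_lfc)
  }
  common <- if (length(calls) >= 2L) intersect_common(calls) else
    called_genes(calls[[1L]])

  network <- build_base_network(study$seeds, study$ppi,
                                include_neighbor_edges = include_neighbor_edges)
  network <- attach_drugs(network, study$drugs)
  network <- annotate_de(network, calls)

  subnetworks <- list()
  druggable <- list()
  for (cg in case_groups) {
    up <- select_upregulated(network, cg)
    subnetworks[[cg]] <- expand_one_step(network, up, star_only = star_only)
    druggable[[cg]] <- report_druggable(subnetworks[[cg]])
  }
  subnetworks$common <- build_refined_common(network, common,
                                             star_only = star_only)
  druggable$common <- report_druggable(subnetworks$common)
  bridging <- find_bridging(subnetworks$common)
  ranked <- rank_targets(druggable$common)

  counts <- list(
    probes = nrow(study$matrix),
    probes_used = nrow(mat),
    samples = ncol(study$matrix),
    genes_called = lapply(calls, function(x) sum(x$called)),
    common_genes = length(common),
    network = summary(network)[c("nodes", "proteins", "seeds", "drugs",
                                 "edges", "ppi_edges", "drug_target_edges",
                                 "components")],
    subnetworks = lapply(subnetworks, function(s) {
      list(nodes = igraph::vcount(s$graph), edges = igraph::ecount(s$graph))
    }),
    druggable_rows = lapply(druggable, nrow),
    bridging_rows = nrow(bridging)
  )

  structure(list(de = de, calls = calls, common = common, network = network,
                 subnetworks = subnetworks, druggable = druggable,
                 bridging = bridging, ranked = ranked,
                 params = list(case_groups = case_groups,
                               reference_groups = reference_groups,
                               alpha = alpha, min_lfc = min_lfc,
                               normalize = normalize,
                               include_neighbor_edges = include_neighbor_edges,
                               star_only = star_only),
                 counts = counts),
            class = "mb_run")
}

#' @export
print.mb_run <- function(x, ...) {
  cat("Drug-target network analysis run\n")
  cat(sprintf("  comparisons: %s vs {%s} (alpha = %g)\n",
              paste(x$params$case_groups, collapse = ", "),
              paste(x$params$reference_groups, collapse = ", "),
              x$params$alpha))
  for (cg in x$params$case_groups) {
    cat(sprintf("  %s: %d genes called over-expressed\n", cg,
                sum(x$calls[[cg]]$called)))
  }
  cat(sprintf("  common over-expressed genes: %d\n", length(x$common)))
  cat(sprintf("  network: %d nodes / %d edges; common subnetwork: %d nodes / %d edges\n",
              x$counts$network$nodes, x$counts$network$edges,
              x$counts$subnetworks$common$nodes,
              x$counts$subnetworks$common$edges))
  cat(sprintf("  druggable common targets: %d; bridging nodes: %d\n",
              nrow(x$druggable$common), nrow(x$bridging)))
  invisible(x)
}

#' Build a run configuration
#'
#' @param inputs named list of input file paths: `expression`,
#'   `annotation`, `probes`, `orthologs`, `ppi`, `drugs`, `seeds` (plain
#'   text, one mouse seed symbol per line).
#' @param out_dir output directory.
#' @param case_groups,reference_groups,alpha,min_lfc,normalize,include_neighbor_edges,star_only
#'   see [analyze_study()].
#' @param rng_seed recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return a `run_config` list.
#' @export
run_config <- function(inputs, out_dir,
                       case_groups = NULL, reference_groups = NULL,
                       alpha = 0.05, min_lfc = 0,
                       normalize = "center_scale",
                       include_neighbor_edges = FALSE, star_only = FALSE,
                       rng_seed = 1L) {
  need <- c("expression", "annotation", "probes", "orthologs", "ppi",
            "drugs", "seeds")
  missing <- setdiff(need, names(inputs))
  if (length(missing) > 0L) {
    np_stop("config", sprintf("missing input path(s): %s",
                              paste(missing, collapse = ", ")))
  }
  assert_scalar_prob(alpha, "alpha")
  structure(list(inputs = inputs[need], out_dir = out_dir,
                 case_groups = case_groups,
                 reference_groups = reference_groups,
                 alpha = alpha, min_lfc = min_lfc, normalize = normalize,
                 include_neighbor_edges = include_neighbor_edges,
                 star_only = star_only, rng_seed = as.integer(rng_seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]: an `inputs` mapping,
#' `out_dir`, and optional parameters. Relative input paths are resolved
#' against the configuration file's directory.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) np_stop("config", sprintf("file not found: %s", path))
  y <- yaml::read_yaml(path)
  if (is.null(y$inputs)) np_stop("config", "config must contain an 'inputs' mapping")
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  }
  inputs <- lapply(y$inputs, resolve)
  run_config(
    inputs = inputs,
    out_dir = resolve(y$out_dir %||% file.path(base, "netpharm_out")),
    case_groups = y$case_groups,
    reference_groups = y$reference_groups,
    alpha = y$alpha %||% 0.05,
    min_lfc = y$min_lfc %||% 0,
    normalize = unlist(y$normalize) %||% "center_scale",
    include_neighbor_edges = isTRUE(y$include_neighbor_edges),
    star_only = isTRUE(y$star_only),
    rng_seed = y$rng_seed %||% 1L
  )
}

#' Run the full pipeline from files
#'
#' Reads the input tables named in `config`, maps the mouse seed symbols
#' to human orthologs, runs [analyze_study()], and writes all outputs to
#' `config$out_dir`: per-comparison DE tables and gene calls, the common
#' gene list, the full annotated network and every subnetwork (GraphML +
#' SIF + node TSV), the druggable/bridging/ranked reports, and a JSON run
#' manifest with input checksums and per-stage counts.
#'
#' @param config a `run_config` from [run_config()] or
#'   [read_run_config()].
#' @return invisibly, the `mb_run` with an added `files` element.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inp <- config$inputs
  for (p in unlist(inp)) {
    if (!file.exists(p)) np_stop("inputs", sprintf("input file not found: %s", p))
  }
  mat <- read_expression_matrix(inp$expression)
  annotation <- read_sample_annotation(inp$annotation)
  probe_map <- read_probe_map(inp$probes)
  orthologs <- read_ortholog_table(inp$orthologs)
  ppi <- read_ppi_edges(inp$ppi)
  drugs <- read_drug_targets(inp$drugs)
  mouse_seeds <- readLines(inp$seeds)
  mouse_seeds <- trimws(mouse_seeds[nzchar(trimws(mouse_seeds))])
  seeds <- map_seeds(mouse_seeds, orthologs)$seeds

  run <- analyze_study(
    list(matrix = mat, annotation = annotation, probe_map = probe_map,
         seeds = seeds, ppi = ppi, drugs = drugs),
    case_groups = config$case_groups,
    reference_groups = config$reference_groups,
    alpha = config$alpha, min_lfc = config$min_lfc,
    normalize = config$normalize,
    include_neighbor_edges = config$include_neighbor_edges,
    star_only = config$star_only)

  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  save_tab <- function(tab, name) {
    p <- file.path(out, name)
    write_tsv(as.data.frame(tab), p)
    files[[name]] <<- p
  }
  for (cg in run$params$case_groups) {
    de_tab <- as.data.frame(run$de[[cg]])
    de_tab$gene_symbol <- probe_map$gene_symbol[match(de_tab$probe_id,
                                                      probe_map$probe_id)]
    save_tab(de_tab[, c("probe_id", "gene_symbol", "lfc", "t", "p", "q")],
             sprintf("de_%s.tsv", cg))
    save_tab(as.data.frame(run$calls[[cg]]), sprintf("calls_%s.tsv", cg))
  }
  writeLines(run$common, file.path(out, "common_genes.txt"))
  files[["common_genes.txt"]] <- file.path(out, "common_genes.txt")

  save_net <- function(net, stem) {
    for (fmt in c("graphml", "sif", "node_tsv")) {
      ext <- c(graphml = "graphml", sif = "sif", node_tsv = "nodes.tsv")[[fmt]]
      p <- file.path(out, paste0(stem, ".", ext))
      write_network(net, p, fmt)
      files[[basename(p)]] <<- p
    }
  }
  save_net(run$network, "network")
  for (nm in names(run$subnetworks)) {
    save_net(run$subnetworks[[nm]]$graph, paste0("subnet_", nm))
    save_tab(run$druggable[[nm]], sprintf("druggable_%s.tsv", nm))
  }
  save_tab(run$bridging, "bridging_common.tsv")
  save_tab(run$ranked, "ranked_targets.tsv")

  manifest <- list(
    tool = "netpharm",
    version = as.character(utils::packageVersion("netpharm")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    rng_seed = config$rng_seed,
    inputs = lapply(inp, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    parameters = run$params,
    counts = run$counts
  )
  p <- file.path(out, "manifest.json")
  write_manifest(manifest, p)
  files[["manifest.json"]] <- p

  run$files <- files
  run$manifest <- manifest
  invisible(run)
}
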