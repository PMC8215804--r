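## Synthetic-data generator: produces every pipeline input (gene universe,
## seed genes, ortholog map, PPI edges, drug-target table, probe map,
## expression matrix) with planted, recorded ground truth so the full
## pipeline can be validated end to end without any external database.

#' Configuration for the synthetic-data generator
#'
#' Defines a complete synthetic study: a gene universe with a subset of
#' seed (mutagenesis-hit) genes, an Erdős–Rényi background interactome with
#' deterministic seed and bridging wiring overlaid, a drug-target table, and
#' a probe-level log2 expression matrix in which chosen genes are
#' over-expressed by `effect_lfc` in chosen tumour groups.
#'
#' If `planted_per_group` is `NULL`, planted sets are constructed
#' automatically: `n_planted_common` genes over-expressed in every tumour
#' group (of which `n_bridging` are wired to at least 2 seeds and given a
#' drug, making them recoverable bridging targets), plus
#' `n_planted_specific` extra genes per tumour group.
#'
#' @param n_genes number of genes in the universe.
#' @param n_seeds number of seed genes (must be < `n_genes`).
#' @param mean_degree expected background PPI degree per gene.
#' @param n_drugs number of drugs in the drug-target table.
#' @param targets_per_drug targets sampled per background drug.
#' @param groups named integer vector: samples per group label. Tumour
#'   groups are those named in `planted_per_group` (or, with automatic
#'   planting, all groups whose label does not start with `"normal"`).
#' @param planted_per_group optional named list: group label -> character
#'   vector of over-expressed gene symbols.
#' @param n_planted_common,n_planted_specific,n_bridging automatic-planting
#'   sizes (ignored when `planted_per_group` is given).
#' @param effect_lfc planted log2 fold change (> 0).
#' @param noise_sd within-group standard deviation on the log2 scale (> 0).
#' @param probes_per_gene_max maximum probes per gene (each gene gets
#'   1..max probes, uniformly).
#' @param one_to_many_frac fraction of mouse symbols mapped to two human
#'   symbols in the ortholog table.
#' @param rng_seed root seed; per-artifact sub-streams are derived from it
#'   so artifacts are individually stable.
#' @return a `sim_config` object (validated list).
#' @export
sim_config <- function(n_genes = 500L, n_seeds = 25L, mean_degree = 4,
                       n_drugs = 60L, targets_per_drug = 2L,
                       groups = c(SHH = 12L, Gp3 = 12L, Gp4 = 12L,
                                  normal_fetal = 6L, normal_adult = 6L),
                       planted_per_group = NULL,
                       n_planted_common = 20L, n_planted_specific = 10L,
                       n_bridging = 8L,
                       effect_lfc = 1.5, noise_sd = 0.7,
                       probes_per_gene_max = 3L, one_to_many_frac = 0.1,
                       rng_seed = 1L) {
  if (n_genes < 1L) np_stop("config", "n_genes must be positive")
  if (n_seeds < 1L || n_seeds >= n_genes) {
    np_stop("config", "n_seeds must satisfy 1 <= n_seeds < n_genes")
  }
  if (mean_degree < 0) np_stop("config", "mean_degree must be >= 0")
  if (effect_lfc < 0) np_stop("config", "effect_lfc must be >= 0")
  if (noise_sd <= 0) np_stop("config", "noise_sd must be > 0")
  if (probes_per_gene_max < 1L) np_stop("config", "probes_per_gene_max must be >= 1")
  if (is.null(names(groups)) || any(!nzchar(names(groups))) ||
      anyDuplicated(names(groups))) {
    np_stop("config", "groups must have unique non-empty labels")
  }
  if (any(groups < 1L)) np_stop("config", "every group needs >= 1 sample")
  cfg <- list(
    n_genes = as.integer(n_genes), n_seeds = as.integer(n_seeds),
    mean_degree = mean_degree, n_drugs = as.integer(n_drugs),
    targets_per_drug = as.integer(targets_per_drug),
    groups = groups, planted_per_group = planted_per_group,
    n_planted_common = as.integer(n_planted_common),
    n_planted_specific = as.integer(n_planted_specific),
    n_bridging = as.integer(n_bridging),
    effect_lfc = effect_lfc, noise_sd = noise_sd,
    probes_per_gene_max = as.integer(probes_per_gene_max),
    one_to_many_frac = one_to_many_frac,
    rng_seed = as.integer(rng_seed)
  )
  structure(cfg, class = "sim_config")
}

tumour_groups <- function(config) {
  if (!is.null(config$planted_per_group)) return(names(config$planted_per_group))
  grep("^normal", names(config$groups), value = TRUE, invert = TRUE)
}

#' Generate the gene universe, seed set and ortholog table
#'
#' Human symbols are upper-case (`GENE0001`, ...); mouse symbols are the
#' title-case counterparts (`Gene0001`), exercising the ortholog-mapping
#' code path. A configurable fraction of mouse symbols additionally map to
#' a second human symbol (one-to-many homology).
#'
#' @param config a [sim_config()].
#' @return list with `genes` (character), `seeds` (character subset) and
#'   `orthologs` (data.frame `mouse_symbol`, `human_symbol`).
#' @export
generate_universe <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genes <- sprintf("GENE%04d", seq_len(config$n_genes))
  with_substream(config$rng_seed, 1L, {
    seeds <- sort(sample(genes, config$n_seeds))
    mouse <- paste0("Gene", substring(genes, 5L))
    orth <- data.frame(mouse_symbol = mouse, human_symbol = genes,
                       stringsAsFactors = FALSE)
    n_multi <- floor(config$one_to_many_frac * config$n_genes)
    if (n_multi > 0L && config$n_genes >= 2L) {
      donors <- sample(seq_len(config$n_genes), n_multi)
      extra_to <- vapply(donors, function(i) {
        sample(setdiff(seq_len(config$n_genes), i), 1L)
      }, integer(1))
      orth <- rbind(orth, data.frame(mouse_symbol = mouse[donors],
                                     human_symbol = genes[extra_to],
                                     stringsAsFactors = FALSE))
      orth <- unique(orth)
    }
    orth <- orth[order(orth$mouse_symbol, orth$human_symbol), , drop = FALSE]
    rownames(orth) <- NULL
    list(genes = genes, seeds = seeds, orthologs = orth)
  })
}

# Planted sets (automatic mode): common genes shared by all tumour groups,
# a bridging-designated subset of those, and per-group extras. All drawn
# from non-seed genes so over-expression calls concern network neighbours,
# not the seeds themselves.
planted_structure <- function(universe, config) {
  if (!is.null(config$planted_per_group)) {
    planted <- lapply(config$planted_per_group, function(g) sort(unique(as.character(g))))
    bad <- setdiff(unlist(planted), universe$genes)
    if (length(bad) > 0L) {
      np_stop("config", sprintf("planted gene(s) not in universe: %s",
                                paste(utils::head(bad, 5L), collapse = ", ")))
    }
    common <- sort(Reduce(intersect, planted))
    # explicit mode: bridging candidates are all common genes; actual
    # bridging truth is determined by the realized wiring + drug table
    return(list(planted = planted, common = common, bridging_request = common))
  }
  non_seed <- setdiff(universe$genes, universe$seeds)
  need <- config$n_planted_common +
    config$n_planted_specific * length(tumour_groups(config))
  if (need > length(non_seed)) {
    np_stop("config", "not enough non-seed genes for the requested planted sets")
  }
  with_substream(config$rng_seed, 2L, {
    picked <- sample(non_seed, need)
    common <- sort(picked[seq_len(config$n_planted_common)])
    bridging_request <- sort(common[seq_len(min(config$n_bridging, length(common)))])
    rest <- picked[-seq_len(config$n_planted_common)]
    planted <- list()
    tg <- tumour_groups(config)
    for (i in seq_along(tg)) {
      extra <- rest[seq.int((i - 1L) * config$n_planted_specific + 1L,
                            i * config$n_planted_specific)]
      planted[[tg[i]]] <- sort(c(common, extra))
    }
    list(planted = planted, common = common, bridging_request = bridging_request)
  })
}

#' Generate a synthetic PPI edge table
#'
#' Background edges follow an Erdős–Rényi model at the configured mean
#' degree; on top of that, every seed is guaranteed degree >= 1 and every
#' requested bridging gene is wired to at least 2 distinct seeds. The
#' result is undirected, self-loop-free and duplicate-free.
#'
#' @param universe output of [generate_universe()].
#' @param config a [sim_config()].
#' @param bridging character vector of genes to wire to >= 2 seeds
#'   (default: the automatic planted bridging set).
#' @return data.frame with columns `protein_a`, `protein_b`.
#' @export
generate_ppi <- function(universe, config,
                         bridging = planted_structure(universe, config)$bridging_request) {
  stopifnot(inherits(config, "sim_config"))
  genes <- universe$genes
  seeds <- universe$seeds
  stopifnot(all(seeds %in% genes))
  if (length(bridging) > 0L && length(seeds) < 2L) {
    np_stop("config", "bridging wiring requires at least 2 seeds")
  }
  n <- length(genes)
  with_substream(config$rng_seed, 3L, {
    edges <- matrix(integer(0), ncol = 2L)
    # deterministic wiring: bridging genes to 2-3 distinct seeds each
    if (length(bridging) > 0L) {
      wire <- lapply(bridging, function(g) {
        k <- min(length(seeds), sample(2:3, 1L))
        cbind(match(g, genes), match(sample(seeds, k), genes))
      })
      edges <- rbind(edges, do.call(rbind, wire))
    }
    # Erdős–Rényi background over all unordered pairs
    if (config$mean_degree > 0 && n >= 2L) {
      p_edge <- min(1, config$mean_degree / (n - 1))
      # sample pair indices without materializing all n(n-1)/2 pairs at once
      n_pairs <- n * (n - 1) / 2
      m_bg <- stats::rbinom(1L, n_pairs, p_edge)
      if (m_bg > 0L) {
        k <- sort(sample(n_pairs, m_bg))  # 1-based linear pair index
        # invert the row-major upper-triangle linear index
        i <- floor((2 * n - 1 - sqrt((2 * n - 1)^2 - 8 * k)) / 2) + 1
        offset <- (i - 1) * (2 * n - i) / 2
        j <- (k - offset) + i
        edges <- rbind(edges, cbind(as.integer(i), as.integer(j)))
      }
    }
    # seed attachment: every seed gets degree >= 1
    deg_nodes <- unique(as.vector(edges))
    lonely <- setdiff(match(seeds, genes), deg_nodes)
    if (length(lonely) > 0L) {
      partners <- vapply(lonely, function(s) sample(setdiff(seq_len(n), s), 1L),
                         integer(1))
      edges <- rbind(edges, cbind(lonely, partners))
    }
    # canonical form: sorted pairs, no loops, no duplicates
    keep <- edges[, 1L] != edges[, 2L]
    edges <- edges[keep, , drop = FALSE]
    a <- pmin(edges[, 1L], edges[, 2L])
    b <- pmax(edges[, 1L], edges[, 2L])
    ord <- order(a, b)
    a <- a[ord]; b <- b[ord]
    dup <- duplicated(cbind(a, b))
    data.frame(protein_a = genes[a[!dup]], protein_b = genes[b[!dup]],
               stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic drug-target table
#'
#' Every requested bridging gene receives at least one dedicated drug;
#' remaining drugs pick `targets_per_drug` targets at random from the
#' universe. Drug ids follow a DrugBank-like pattern (`DSYN0001`, ...).
#'
#' @param universe output of [generate_universe()].
#' @param config a [sim_config()].
#' @param bridging genes guaranteed at least one drug.
#' @return data.frame with columns `drug_id`, `drug_name`, `target_symbol`;
#'   (`drug_id`, `target_symbol`) pairs unique.
#' @export
generate_drug_targets <- function(universe, config,
                                  bridging = planted_structure(universe, config)$bridging_request) {
  stopifnot(inherits(config, "sim_config"))
  if (length(universe$genes) == 0L) np_stop("config", "empty gene universe")
  if (config$targets_per_drug < 1L) np_stop("config", "targets_per_drug must be >= 1")
  with_substream(config$rng_seed, 4L, {
    n_drugs <- max(config$n_drugs, length(bridging))
    ids <- sprintf("DSYN%04d", seq_len(n_drugs))
    names_ <- sprintf("drug_%04d", seq_len(n_drugs))
    rows <- vector("list", n_drugs)
    for (i in seq_len(n_drugs)) {
      if (i <= length(bridging)) {
        tgt <- bridging[i]
        extra <- config$targets_per_drug - 1L
        if (extra > 0L) {
          tgt <- c(tgt, sample(setdiff(universe$genes, tgt),
                               min(extra, length(universe$genes) - 1L)))
        }
      } else {
        tgt <- sample(universe$genes, min(config$targets_per_drug,
                                          length(universe$genes)))
      }
      rows[[i]] <- data.frame(drug_id = ids[i], drug_name = names_[i],
                              target_symbol = tgt, stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
    tab <- unique(tab)
    rownames(tab) <- NULL
    tab
  })
}

#' Generate the probe-level expression matrix with planted over-expression
#'
#' Each gene gets 1..`probes_per_gene_max` probes. Probe values are a
#' probe-specific baseline (N(7, 1) log2 intensity) plus i.i.d. Gaussian
#' noise with standard deviation `noise_sd`; for each tumour group, every
#' probe of a planted gene gains `effect_lfc` in that group's samples.
#' Normal groups are never shifted.
#'
#' @param universe output of [generate_universe()].
#' @param config a [sim_config()].
#' @return list with `matrix` (probe x sample), `annotation` (data.frame
#'   `sample_id`, `group`), `probe_map` (data.frame `probe_id`,
#'   `gene_symbol`) and `truth` (a `synthetic_truth` object: planted sets
#'   per group, their intersection `planted_common`, and the requested
#'   bridging genes).
#' @export
generate_expression <- function(universe, config) {
  stopifnot(inherits(config, "sim_config"))
  if (length(config$groups) == 0L) np_stop("config", "groups must be non-empty")
  ps <- planted_structure(universe, config)
  with_substream(config$rng_seed, 5L, {
    n_probes_per_gene <- if (config$probes_per_gene_max == 1L) {
      rep(1L, config$n_genes)
    } else {
      sample(config$probes_per_gene_max, config$n_genes, replace = TRUE)
    }
    gene_of_probe <- rep(universe$genes, n_probes_per_gene)
    probe_ids <- paste0(tolower(gene_of_probe), "_p",
                        unlist(lapply(n_probes_per_gene, seq_len)))
    m <- length(probe_ids)

    grp_labels <- rep(names(config$groups), config$groups)
    sample_ids <- paste0(grp_labels, "_s",
                         unlist(lapply(config$groups, seq_len)))
    n_s <- length(sample_ids)

    baseline <- stats::rnorm(m, mean = 7, sd = 1)
    mat <- baseline + matrix(stats::rnorm(m * n_s, sd = config$noise_sd),
                             nrow = m, ncol = n_s)
    for (g in names(ps$planted)) {
      cols <- which(grp_labels == g)
      rows <- which(gene_of_probe %in% ps$planted[[g]])
      if (length(rows) > 0L && length(cols) > 0L) {
        mat[rows, cols] <- mat[rows, cols] + config$effect_lfc
      }
    }
    rownames(mat) <- probe_ids
    colnames(mat) <- sample_ids

    truth <- structure(list(planted_overexpressed = ps$planted,
                            planted_common = ps$common,
                            bridging_request = ps$bridging_request),
                       class = "synthetic_truth")
    list(matrix = mat,
         annotation = data.frame(sample_id = sample_ids, group = grp_labels,
                                 stringsAsFactors = FALSE),
         probe_map = data.frame(probe_id = probe_ids,
                                gene_symbol = gene_of_probe,
                                stringsAsFactors = FALSE),
         truth = truth)
  })
}

#' Generate a complete synthetic study
#'
#' Runs all four generators and finalizes the ground truth: the planted
#' bridging set is computed from the *realized* artifacts — planted-common
#' genes with at least one drug and at least 2 distinct seed neighbours in
#' the emitted PPI — so recovery tests compare against what the data
#' actually contain.
#'
#' @param config a [sim_config()].
#' @return a `synthetic_study` list: `genes`, `seeds`, `orthologs`, `ppi`,
#'   `drugs`, `matrix`, `annotation`, `probe_map`, `truth`, `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  uni <- generate_universe(config)
  ps <- planted_structure(uni, config)
  ppi <- generate_ppi(uni, config, bridging = ps$bridging_request)
  drugs <- generate_drug_targets(uni, config, bridging = ps$bridging_request)
  expr <- generate_expression(uni, config)

  # realized bridging truth: common + drugged + >= 2 distinct seed partners
  drugged <- unique(drugs$target_symbol)
  partners <- seed_partner_counts(ppi, uni$seeds)
  bridging <- sort(intersect(
    ps$common,
    intersect(drugged, names(partners)[partners >= 2L])
  ))
  expr$truth$planted_bridging <- bridging

  structure(c(list(genes = uni$genes, seeds = uni$seeds,
                   orthologs = uni$orthologs, ppi = ppi, drugs = drugs),
              expr[c("matrix", "annotation", "probe_map", "truth")],
              list(config = config)),
            class = "synthetic_study")
}

# distinct-seed-neighbour counts per gene, straight from the edge table
seed_partner_counts <- function(ppi, seeds) {
  long <- rbind(data.frame(g = ppi$protein_a, s = ppi$protein_b),
                data.frame(g = ppi$protein_b, s = ppi$protein_a))
  long <- long[long$s %in% seeds, , drop = FALSE]
  long <- unique(long)
  if (nrow(long) == 0L) return(integer(0))
  tab <- table(long$g)
  stats::setNames(as.integer(tab), names(tab))
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic study:\n")
  cat(sprintf("  %d genes (%d seeds), %d PPI edges, %d drug-target rows\n",
              length(x$genes), length(x$seeds), nrow(x$ppi), nrow(x$drugs)))
  cat(sprintf("  expression: %d probes x %d samples (groups: %s)\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(names(x$config$groups), collapse = ", ")))
  cat(sprintf("  planted: %d common over-expressed, %d bridging\n",
              length(x$truth$planted_common),
              length(x$truth$planted_bridging)))
  invisible(x)
}

#' Write all artifacts of a synthetic study as TSV files
#'
#' @param study a `synthetic_study` from [simulate_study()].
#' @param dir output directory (created if missing).
#' @return invisibly, a named character vector of the file paths written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    annotation = file.path(dir, "samples.tsv"),
    probe_map = file.path(dir, "probes.tsv"),
    orthologs = file.path(dir, "orthologs.tsv"),
    ppi = file.path(dir, "ppi.tsv"),
    drugs = file.path(dir, "drugs.tsv"),
    seeds = file.path(dir, "seeds.txt"),
    truth = file.path(dir, "truth.tsv")
  )
  write_expression_matrix(study$matrix, paths["expression"])
  write_tsv(study$annotation, paths["annotation"])
  write_tsv(study$probe_map, paths["probe_map"])
  write_tsv(study$orthologs, paths["orthologs"])
  write_tsv(study$ppi, paths["ppi"])
  write_tsv(study$drugs, paths["drugs"])
  # seeds are distributed as mouse symbols, exercising ortholog mapping
  mouse_seeds <- study$orthologs$mouse_symbol[
    match(study$seeds, study$orthologs$human_symbol)]
  writeLines(mouse_seeds, paths["seeds"])
  truth_rows <- do.call(rbind, c(
    lapply(names(study$truth$planted_overexpressed), function(g) {
      data.frame(set = g, gene = study$truth$planted_overexpressed[[g]],
                 stringsAsFactors = FALSE)
    }),
    list(data.frame(set = "common", gene = study$truth$planted_common,
                    stringsAsFactors = FALSE),
         data.frame(set = "bridging", gene = study$truth$planted_bridging,
                    stringsAsFactors = FALSE))
  ))
  write_tsv(truth_rows, paths["truth"])
  invisible(paths)
}
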