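# Synthetic-data generator: cardinality contracts, graph sanity,
# determinism, planted-effect realization, truth consistency.

test_that("universe generation honours cardinalities and determinism", {
  cfg <- sim_config(n_genes = 5L, n_seeds = 2L, n_planted_common = 1L,
                    n_planted_specific = 0L, n_bridging = 1L, rng_seed = 1L)
  uni <- generate_universe(cfg)
  expect_length(uni$genes, 5L)
  expect_false(anyDuplicated(uni$genes) > 0L)
  expect_length(uni$seeds, 2L)
  expect_true(all(uni$seeds %in% uni$genes))
  expect_gte(nrow(uni$orthologs), 5L)
  # mouse symbols are title-case variants of the human symbols
  expect_true(all(grepl("^Gene", uni$orthologs$mouse_symbol)))
  expect_identical(uni, generate_universe(cfg))

  expect_error(sim_config(n_genes = 5L, n_seeds = 5L), "n_seeds")
})

test_that("ortholog table is a bijection when one-to-many fraction is zero", {
  cfg <- sim_config(n_genes = 40L, n_seeds = 4L, one_to_many_frac = 0,
                    n_planted_common = 2L, n_planted_specific = 0L,
                    n_bridging = 2L, rng_seed = 3L)
  orth <- generate_universe(cfg)$orthologs
  expect_identical(nrow(orth), 40L)
  expect_false(anyDuplicated(orth$mouse_symbol) > 0L)
  expect_false(anyDuplicated(orth$human_symbol) > 0L)

  cfg2 <- sim_config(n_genes = 40L, n_seeds = 4L, one_to_many_frac = 0.25,
                     n_planted_common = 2L, n_planted_specific = 0L,
                     n_bridging = 2L, rng_seed = 3L)
  orth2 <- generate_universe(cfg2)$orthologs
  expect_gt(nrow(orth2), 40L)
  expect_true(anyDuplicated(orth2$mouse_symbol) > 0L)
})

test_that("generated PPI is simple, covers seeds, and wires bridging genes", {
  cfg <- sim_config(n_genes = 120L, n_seeds = 10L, mean_degree = 3,
                    n_planted_common = 6L, n_planted_specific = 2L,
                    n_bridging = 4L, rng_seed = 11L)
  uni <- generate_universe(cfg)
  bridging <- c("GENE0001", "GENE0002")
  bridging <- setdiff(bridging, uni$seeds)
  ppi <- generate_ppi(uni, cfg, bridging = bridging)

  expect_true(all(ppi$protein_a %in% uni$genes))
  expect_true(all(ppi$protein_b %in% uni$genes))
  expect_false(any(ppi$protein_a == ppi$protein_b))
  key <- paste(pmin(ppi$protein_a, ppi$protein_b),
               pmax(ppi$protein_a, ppi$protein_b))
  expect_false(anyDuplicated(key) > 0L)
  # every seed has degree >= 1
  expect_true(all(uni$seeds %in% c(ppi$protein_a, ppi$protein_b)))
  # every bridging gene is adjacent to >= 2 distinct seeds
  for (g in bridging) {
    expect_gte(oracle_seed_partners(g, uni$seeds, as.matrix(ppi)), 2L)
  }
  expect_identical(ppi, generate_ppi(uni, cfg, bridging = bridging))
})

test_that("mean_degree = 0 yields only the deterministic attachment edges", {
  cfg <- sim_config(n_genes = 30L, n_seeds = 3L, mean_degree = 0,
                    n_planted_common = 1L, n_planted_specific = 0L,
                    n_bridging = 0L, rng_seed = 2L)
  uni <- generate_universe(cfg)
  ppi <- generate_ppi(uni, cfg, bridging = character(0))
  # only seed attachment: one edge per seed
  expect_identical(nrow(ppi), 3L)

  # bridging with < 2 seeds is impossible
  cfg1 <- sim_config(n_genes = 30L, n_seeds = 1L, n_planted_common = 1L,
                     n_planted_specific = 0L, n_bridging = 1L, rng_seed = 2L)
  uni1 <- generate_universe(cfg1)
  expect_error(generate_ppi(uni1, cfg1, bridging = "GENE0002"), "2 seeds")
})

test_that("drug table covers bridging genes with unique (drug, target) pairs", {
  cfg <- sim_config(n_genes = 50L, n_seeds = 5L, n_drugs = 3L,
                    targets_per_drug = 2L, n_planted_common = 2L,
                    n_planted_specific = 0L, n_bridging = 2L, rng_seed = 5L)
  uni <- generate_universe(cfg)
  tab <- generate_drug_targets(uni, cfg, bridging = character(0))
  expect_identical(nrow(tab), 6L)
  expect_length(unique(tab$drug_id), 3L)
  expect_false(anyDuplicated(tab[, c("drug_id", "target_symbol")]) > 0L)
  expect_identical(tab, generate_drug_targets(uni, cfg, bridging = character(0)))

  tab2 <- generate_drug_targets(uni, cfg, bridging = c("GENE0007", "GENE0009"))
  expect_true(all(c("GENE0007", "GENE0009") %in% tab2$target_symbol))
})

test_that("expression realizes the planted log2 effect", {
  cfg <- sim_config(n_genes = 60L, n_seeds = 5L,
                    groups = c(Gp3 = 10L, normal_fetal = 10L),
                    planted_per_group = list(Gp3 = c("GENE0005", "GENE0010")),
                    effect_lfc = 3, noise_sd = 0.1,
                    probes_per_gene_max = 2L, rng_seed = 9L)
  uni <- generate_universe(cfg)
  ex <- generate_expression(uni, cfg)
  grp <- ex$annotation$group[match(colnames(ex$matrix), ex$annotation$sample_id)]
  planted_probes <- ex$probe_map$probe_id[
    ex$probe_map$gene_symbol %in% c("GENE0005", "GENE0010")]
  for (pr in planted_probes) {
    dm <- mean(ex$matrix[pr, grp == "Gp3"]) -
      mean(ex$matrix[pr, grp == "normal_fetal"])
    expect_lt(abs(dm - 3), 0.2)
  }
  # unplanted probes show only noise
  other <- setdiff(rownames(ex$matrix), planted_probes)[1:10]
  for (pr in other) {
    dm <- mean(ex$matrix[pr, grp == "Gp3"]) -
      mean(ex$matrix[pr, grp == "normal_fetal"])
    expect_lt(abs(dm), 0.5)
  }
  expect_error(
    generate_expression(uni, sim_config(
      n_genes = 60L, n_seeds = 5L,
      groups = c(Gp3 = 10L, normal_fetal = 10L),
      planted_per_group = list(Gp3 = "NOT_A_GENE"), rng_seed = 9L)),
    "not in universe")
})

test_that("probe map is a bijection when probes_per_gene_max is 1", {
  cfg <- sim_config(n_genes = 40L, n_seeds = 4L, probes_per_gene_max = 1L,
                    n_planted_common = 2L, n_planted_specific = 1L,
                    n_bridging = 1L, rng_seed = 4L)
  uni <- generate_universe(cfg)
  ex <- generate_expression(uni, cfg)
  expect_identical(nrow(ex$probe_map), 40L)
  expect_false(anyDuplicated(ex$probe_map$gene_symbol) > 0L)
})

test_that("truth is internally consistent and matches the realized artifacts", {
  study <- simulate_study(sim_config(n_genes = 200L, n_seeds = 12L,
                                     n_planted_common = 8L,
                                     n_planted_specific = 4L,
                                     n_bridging = 4L, rng_seed = 21L))
  tr <- study$truth
  tumours <- setdiff(names(study$config$groups),
                     grep("^normal", names(study$config$groups), value = TRUE))
  expect_identical(tr$planted_common,
                   sort(Reduce(intersect, tr$planted_overexpressed[tumours])))
  expect_true(all(tr$planted_bridging %in% tr$planted_common))
  # realized definition: drugged and >= 2 distinct seed partners
  for (g in tr$planted_bridging) {
    expect_true(g %in% study$drugs$target_symbol)
    expect_gte(oracle_seed_partners(g, study$seeds, as.matrix(study$ppi)), 2L)
  }
  # full-study determinism (byte-identical artifacts)
  study2 <- simulate_study(study$config)
  expect_identical(study[names(study) != "config"],
                   study2[names(study2) != "config"])
})

test_that("written study round-trips through the TSV readers", {
  study <- simulate_study(sim_config(n_genes = 80L, n_seeds = 6L,
                                     n_planted_common = 4L,
                                     n_planted_specific = 2L,
                                     n_bridging = 2L, rng_seed = 13L))
  dir <- withr::local_tempdir()
  paths <- write_study(study, dir)
  expect_true(all(file.exists(paths)))
  mat <- read_expression_matrix(paths[["expression"]])
  expect_equal(mat, study$matrix, tolerance = 1e-12)
  expect_identical(read_sample_annotation(paths[["annotation"]]),
                   study$annotation)
  expect_identical(read_ppi_edges(paths[["ppi"]]), study$ppi)
  expect_identical(read_drug_targets(paths[["drugs"]]), study$drugs)
  # seeds file holds mouse symbols that map back to the human seed set
  mouse <- readLines(paths[["seeds"]])
  mapped <- map_seeds(mouse, read_ortholog_table(paths[["orthologs"]]))$seeds
  expect_true(all(study$seeds %in% mapped))
})
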