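# Target discovery: up-regulated node selection, one-step expansion,
# refined common subnetwork, druggable/bridging reports, ranking.

example_annotated <- function() {
  ex <- example_inputs()
  net <- attach_drugs(build_base_network(ex$seeds, ex$ppi), ex$drugs)
  annotate_de(net, ex$calls)
}

test_that("up-regulated selection respects calls, direction and node type", {
  net <- example_annotated()
  up <- select_upregulated(net, "Gp3")
  expect_identical(up, sort(paste0("P:", sort(unique(
    example_inputs()$drugs$target_symbol)))))
  expect_false(any(startsWith(up, "D:")))
  # recomputation from q/lfc: stricter alpha shrinks, looser never shrinks
  expect_identical(select_upregulated(net, "Gp3", alpha = 0.01), up)
  expect_length(select_upregulated(net, "Gp3", alpha = 1e-4), 0L)
  expect_error(select_upregulated(net, "nope"), "not annotated")
})

test_that("one-step expansion is the induced closed neighbourhood", {
  # path A-B-C: expanding {A} reaches B but not C
  net <- edges_to_network(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  sub <- expand_one_step(net, "P:A")
  expect_identical(sort(igraph::V(sub$graph)$name), c("P:A", "P:B"))
  expect_equal(igraph::ecount(sub$graph), 1L)
  expect_identical(unname(sub$provenance[order(names(sub$provenance))]),
                   c("overexpressed", "neighbor"))

  # drugs targeting the input are pulled in
  netd <- attach_drugs(net, data.frame(drug_id = "D1", drug_name = "d",
                                       target_symbol = "A"))
  subd <- expand_one_step(netd, "P:A")
  expect_true("D:D1" %in% igraph::V(subd$graph)$name)
  expect_identical(unname(subd$provenance["D:D1"]), "drug")

  # empty input: empty subnetwork with a warning
  expect_warning(sub0 <- expand_one_step(net, character(0)), "empty")
  expect_equal(igraph::vcount(sub0$graph), 0L)
})

test_that("expansion matches brute-force neighbourhood enumeration", {
  set.seed(77)
  for (i in 1:25) {
    g <- random_edge_table(sample(5:80, 1))
    net <- edges_to_network(g$nodes, g$edges)
    origin <- protein_id_vec(sample(g$nodes, sample(1:4, 1)))
    sub <- expand_one_step(net, origin)
    expect_identical(sort(igraph::V(sub$graph)$name),
                     oracle_expand(origin, protein_edges(g$edges)))
    # induced semantics: every edge of the parent graph between kept nodes
    kept <- igraph::V(sub$graph)$name
    pe <- protein_edges(g$edges)
    inside <- pe[, 1] %in% kept & pe[, 2] %in% kept
    expect_equal(igraph::ecount(sub$graph), sum(inside))
    # provenance invariant: every node is input, neighbour or drug
    expect_true(all(sub$provenance %in% c("overexpressed", "neighbor", "drug")))
    expect_identical(sort(names(sub$provenance)[sub$provenance == "overexpressed"]),
                     sort(origin))
  }
})

test_that("refined common subnetwork around one gene matches the example", {
  net <- example_annotated()
  sub <- build_refined_common(net, "TUBB")
  expect_identical(sort(igraph::V(sub$graph)$name),
                   c("D:DB04845", "P:CDKN2A", "P:MAP3K1", "P:TJP1", "P:TUBB"))
  expect_warning(sub0 <- build_refined_common(net, character(0)), "empty")
  expect_equal(igraph::vcount(sub0$graph), 0L)
  expect_identical(nrow(report_druggable(sub0)), 0L)
})

test_that("druggable report reproduces the example protein-seed mapping", {
  net <- example_annotated()
  sub <- build_refined_common(net, intersect_common(example_inputs()$calls))
  rep_ <- report_druggable(sub)
  expect_identical(nrow(rep_), 10L)
  want <- c(AURKA = "CDKN2A", CAD = "MAP3K1", CDK4 = "CDKN2A",
            CDK6 = "CDKN2A;ZEB1", CHEK2 = "PPP2R5E", P4HB = "PTN",
            PTPRS = "PTN", SLC1A5 = "MAP3K1", SNRPA = "CDKN2A",
            TUBB = "CDKN2A;MAP3K1;TJP1")
  got <- setNames(rep_$seed_partners, rep_$protein)
  expect_identical(got[order(names(got))], want)
  # sorted by partner count desc then symbol
  expect_identical(rep_$protein[1:2], c("TUBB", "CDK6"))
  expect_true(all(rep_$n_drugs >= 1))
  # per-comparison flags present and true here
  expect_true(all(rep_$called_SHH & rep_$called_Gp3 & rep_$called_Gp4))
})

test_that("over-expressed proteins without drugs or without seed partners", {
  # A (drugged, no seed partner), B (seed partner, no drug)
  net <- edges_to_network(c("S", "A", "B", "C"),
                          rbind(c("S", "B"), c("A", "C")), seeds = "S")
  net <- attach_drugs(net, data.frame(drug_id = "D1", drug_name = "d",
                                      target_symbol = "A"))
  sub <- expand_one_step(net, c("P:A", "P:B"))
  rep_ <- report_druggable(sub)
  expect_identical(rep_$protein, "A")       # B has no drug: no row
  expect_identical(rep_$seed_partners, "")  # A has no adjacent seed
})

test_that("bridging detection matches the example and the oracle", {
  net <- example_annotated()
  sub <- build_refined_common(net, intersect_common(example_inputs()$calls))
  br <- find_bridging(sub)
  expect_identical(br$protein, c("TUBB", "CDK6"))
  expect_identical(br$n_seed_partners, c(3L, 2L))
  expect_error(find_bridging(sub, min_partners = 1), "min_partners")

  # star around one seed: nothing bridges
  star <- edges_to_network(c("S", "A", "B"), rbind(c("S", "A"), c("S", "B")),
                           seeds = "S")
  star <- attach_drugs(star, data.frame(drug_id = "D1", drug_name = "d",
                                        target_symbol = c("A", "B")))
  ssub <- expand_one_step(star, c("P:A", "P:B"))
  expect_identical(nrow(find_bridging(ssub)), 0L)

  # random graphs: per-node distinct-seed adjacency equals the oracle count
  set.seed(31)
  for (i in 1:15) {
    g <- random_edge_table(sample(8:60, 1))
    seeds <- sample(g$nodes, 3)
    net_i <- edges_to_network(g$nodes, g$edges, seeds = seeds)
    over <- setdiff(g$nodes, seeds)
    net_i <- attach_drugs(net_i, data.frame(drug_id = paste0("D", seq_along(over)),
                                            drug_name = "d",
                                            target_symbol = over))
    sub_i <- expand_one_step(net_i, protein_id_vec(over))
    rep_i <- report_druggable(sub_i)
    for (k in seq_len(nrow(rep_i))) {
      expect_identical(rep_i$n_seed_partners[k],
                       oracle_seed_partners(protein_id_vec(rep_i$protein[k]),
                                            protein_id_vec(seeds),
                                            protein_edges(g$edges)))
    }
    br_i <- find_bridging(sub_i)
    expect_true(all(br_i$protein %in% rep_i$protein))
  }
})

test_that("ranking is by subgroup support, partners, degree, then symbol", {
  net <- example_annotated()
  sub <- build_refined_common(net, intersect_common(example_inputs()$calls))
  rk <- rank_targets(report_druggable(sub))
  expect_identical(rk$protein[1:2], c("TUBB", "CDK6"))
  expect_identical(rk$rank, seq_len(nrow(rk)))
  # tie-break: equal keys fall back to lexicographic symbol order
  ties <- rk[rk$n_subgroups_called == 3 & rk$n_seed_partners == 1 &
               rk$degree == 2, "protein"]
  expect_identical(ties, sort(ties))
  # single row ranks as itself
  one <- report_druggable(build_refined_common(net, "AURKA"))
  expect_identical(rank_targets(one)$protein, "AURKA")
})

test_that("relaxing alpha never shrinks selection, subnetwork or report", {
  study <- simulate_study(sim_config(n_genes = 150L, n_seeds = 10L,
                                     n_planted_common = 6L,
                                     n_planted_specific = 2L,
                                     n_bridging = 3L, rng_seed = 17L))
  run1 <- suppressWarnings(analyze_study(study, alpha = 0.01))
  run2 <- suppressWarnings(analyze_study(study, alpha = 0.2))
  for (cg in run1$params$case_groups) {
    expect_true(all(called_genes(run1$calls[[cg]]) %in%
                      called_genes(run2$calls[[cg]])))
  }
  expect_true(all(run1$common %in% run2$common))
  expect_true(all(igraph::V(run1$subnetworks$common$graph)$name %in%
                    igraph::V(run2$subnetworks$common$graph)$name))
  expect_true(all(run1$druggable$common$protein %in%
                    run2$druggable$common$protein))
  # consistency between reports: bridging is a subset with matching counts
  m <- match(run1$bridging$protein, run1$druggable$common$protein)
  expect_false(anyNA(m))
  expect_identical(run1$bridging$n_seed_partners,
                   run1$druggable$common$n_seed_partners[m])
})
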