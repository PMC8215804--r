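# netpharm

Seed-anchored drug–target network analysis for tumour subgroups.

## The problem

Medulloblastoma, the most common malignant paediatric brain tumour, splits
into molecular subgroups (WNT, SHH, Group 3, Group 4) with few actionable
mutations, which limits mutation-driven drug selection. An alternative is
*systems pharmacogenomics*: start from genes functionally implicated in
tumour growth by an insertional-mutagenesis screen (common insertion
sites, "CIS" — the network *seeds*), build the protein–protein interaction
(PPI) neighbourhood of their human orthologs, graft known drug–target
interactions onto it, and overlay per-subgroup differential expression
against normal cerebellum. Druggable proteins that are over-expressed in
**every** non-WNT subgroup and sit next to several seed proteins are prime
repurposing candidates: inhibiting one of them may perturb several driver
hubs at once.

`netpharm` implements that pipeline as a tested, reusable R package for
bioinformaticians who want to apply or stress-test the approach — with a
synthetic-data generator that plants known over-expressed and bridging
genes so every stage can be validated against ground truth.

## The method

For each tumour subgroup *g* versus pooled normal cerebellum, each probe
gets an empirical-Bayes moderated t-statistic. With per-probe pooled
variance s²_g on d degrees of freedom and a scaled inverse-chi-square
prior (d₀, s₀²) fitted across probes by method of moments on log s²_g:

    s̃²_g = (d₀·s₀² + d·s²_g) / (d₀ + d)
    t̃_g  = (mean_case − mean_ref) / (s̃_g · √(1/n₁ + 1/n₂)),   df = d₀ + d

Two-sided p-values are adjusted by Benjamini–Hochberg step-up
(q_(i) = min_{j≥i} p_(j)·m/j). A gene is called over-expressed if **any**
of its probes has q < α (default 0.05) with positive log₂ fold change.

The network stages:

1. **Seeds** — mouse CIS symbols are mapped to human orthologs
   (one-to-many mappings keep all targets).
2. **Base network** — exactly the PPI edges incident to at least one seed.
3. **Drugs** — a drug node and a `drug_target` edge for every drug whose
   target protein is in the network.
4. **Annotation** — each protein node carries per-comparison fold change,
   p, q, and the call flag.
5. **Subnetworks** — the called nodes plus their direct neighbours
   (induced subgraph), per subgroup and for the genes common to all
   subgroups.
6. **Reports** — druggable over-expressed proteins with their seed
   partners; *bridging nodes* (≥ 2 distinct seed partners); a stable
   priority ranking (subgroup support, seed partners, degree, symbol).

## Worked example

The package bundles a small network of six seed proteins and ten
druggable interactors reported for non-WNT medulloblastoma (two
drug assignments are literature-grounded — ixabepilone→TUBB,
palbociclib→CDK4/CDK6 — the rest are synthetic stand-ins; see
`?example_inputs`):

```r
library(netpharm)
ex  <- example_inputs()
net <- build_base_network(ex$seeds, ex$ppi)
net <- attach_drugs(net, ex$drugs)
net <- annotate_de(net, ex$calls)
net
#> Drug-target interaction network: 25 nodes (16 proteins, 6 seeds, 9 drugs), 23 edges (13 ppi, 10 drug-target)
#>   annotated comparisons: SHH, Gp3, Gp4

sub <- build_refined_common(net, intersect_common(ex$calls))
rank_targets(report_druggable(sub))[, c("rank", "protein", "seed_partners", "drugs")]
#>    rank protein      seed_partners                   drugs
#> 1     1    TUBB CDKN2A;MAP3K1;TJP1     DB04845|ixabepilone
#> 2     2    CDK6        CDKN2A;ZEB1     DB09073|palbociclib
#> 3     3   AURKA             CDKN2A      DSYN0001|alisertib
#> ...

find_bridging(sub)[, c("protein", "seed_partners", "drugs")]
#>   protein      seed_partners               drugs
#> 1    TUBB CDKN2A;MAP3K1;TJP1 DB04845|ixabepilone
#> 2    CDK6        CDKN2A;ZEB1 DB09073|palbociclib
```

TUBB tops the ranking because it is over-expressed in all three subgroups
and touches three distinct seed proteins; TUBB and CDK6 are the two
bridging nodes. The base network has 16 proteins in 3 connected
components (the central one holds 11 nodes).

Synthetic end-to-end run with planted truth:

```r
study <- simulate_study(sim_config(rng_seed = 7))
run   <- analyze_study(study)
run
#> Drug-target network analysis run
#>   comparisons: SHH, Gp3, Gp4 vs {normal_fetal, normal_adult} (alpha = 0.05)
#>   ...
mean(study$truth$planted_common %in% run$common)   # planted-gene recovery
```

A file-based run (`run_pipeline(read_run_config("run.yaml"))`, or the
`netpharm` script under `inst/scripts/` with subcommands `simulate`,
`de`, `build-net`, `discover`, `run`) writes DE tables, gene calls,
GraphML/SIF/TSV networks importable into Cytoscape, the target reports,
and a JSON manifest with input checksums and per-stage counts.

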