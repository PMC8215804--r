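---
title: "Methods: seed-anchored drug-target network analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seed-anchored drug-target network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

# Overview

`netpharm` turns a list of functionally validated candidate cancer genes
— common insertion sites (CIS) from a transposon mutagenesis screen in a
mouse medulloblastoma model — into a prioritized list of druggable
therapeutic targets shared by the non-WNT tumour subgroups (SHH, Group 3,
Group 4). The pipeline has three statistical/combinatorial layers:

1. per-subgroup differential expression versus normal cerebellum with
   empirical-Bayes variance moderation and Benjamini–Hochberg FDR;
2. a seed-anchored protein interaction network with drug–target edges
   grafted on and expression statistics attached to protein nodes;
3. subnetwork extraction and target reports: druggable over-expressed
   proteins, their seed partners, and bridging nodes.

This vignette documents the model assumptions, the tunable parameters,
the synthetic-data generator and what it does (and does not) emulate, and
the design decisions taken where the procedure was genuinely open.

# Differential expression model

For probe $g$ in a two-group comparison with $n_1$ case and $n_2$
reference samples, let $s_g^2$ be the pooled within-group sample variance
on $d = n_1 + n_2 - 2$ degrees of freedom. We assume log2 intensities are
Gaussian with equal variance in both groups, and place the standard
scaled inverse-$\chi^2$ prior on the true residual variances:
$\sigma_g^{-2} \sim \frac{1}{d_0 s_0^2}\chi^2_{d_0}$. The posterior-mean
variance and moderated statistic are

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d}, \qquad
  \tilde t_g = \frac{\bar y_{g,\text{case}} - \bar y_{g,\text{ref}}}
                    {\tilde s_g \sqrt{1/n_1 + 1/n_2}},$$

with $\tilde t_g \sim t_{d_0 + d}$ under the null. $(d_0, s_0^2)$ are
fitted by method of moments on $z_g = \log s_g^2$, using the exact mean
and variance of log-$\chi^2$ variables (digamma/trigamma identities; the
trigamma inverse is solved by Newton iteration). Two limits pin the
implementation down and are tested: $d_0 = 0$ reproduces the ordinary
pooled two-sample $t$ exactly, and $d_0 \to \infty$ shrinks every
variance to $s_0^2$. On data with genuinely heterogeneous per-probe
variances the fitted prior agrees with `limma`'s to ~1e-6, which is used
as an independent cross-check in the test suite (never as the
implementation).

P-values are two-sided; the over-expression direction filter is applied
afterwards at the calling stage. FDR control is the Benjamini–Hochberg
step-up $q_{(i)} = \min_{j \ge i} p_{(j)} m / j$, validated in the tests
against a brute-force enumeration of that definition.

**Degenerate inputs.** A probe with zero pooled variance and $d_0 = 0$
gets $t = 0, p = 1$ when the mean difference is zero, otherwise
$t = \pm\infty$ with $p = 0$ and a warning — the tail value of the
reference distribution at an infinite statistic. Zero-variance rows or
columns encountered during normalization are dropped with a warning, not
an error, since single degenerate probes should not abort a run.

# Normalization

Two steps are available and composable via `normalize_expression()`:

- `center_scale`: each sample column standardized to mean 0, SD 1
  ("comparable distributions" across arrays). **This is the pipeline
  default before differential expression.**
- `zscore_rows`: each probe row standardized to mean 0, SD 1 — useful for
  visualization and clustering.

Row z-scoring is deliberately *not* part of the default DE path. The
two-sample $t$ is invariant to rescaling a row by a constant, so row
standardization cannot add power; what it does do is equalize each
probe's *total* (signal + noise) variance, so truly differential probes
end up with systematically smaller within-group variances than null
probes of the same total variance. Under variance moderation this is
actively harmful: the shrinkage target $s_0^2$ is dominated by null
probes, and true positives have their moderated statistics deflated
(in the synthetic regime below, enough to cut planted-gene sensitivity
from ~1.0 to ~0.75). Users who want the row-standardized matrix for
other purposes can still request it.

# Gene-level calls and the common set

Probes map to genes through the probe map; when several probes measure
one gene, **all** probes count and the gene is called over-expressed if
*any* probe has $q < \alpha$ and log2 fold change above `min_lfc`. The
gene's representative ("best") probe — smallest $q$, ties broken by
larger $|$lfc$|$ then probe id — provides the statistics attached to its
network node. Defaults: $\alpha = 0.05$, `min_lfc = 0` (significance and
direction only; no fold-change cutoff is imposed beyond direction, and
the threshold is configurable). The *common* set is the intersection of
the called sets across all tumour subgroups; the comparisons use the
pooled foetal + adult normal cerebellum samples as one reference (a
single contrast per subgroup, configurable through `comparison_spec()`).
WNT-like or otherwise excluded samples are simply never part of any
configured case or reference group, so they do not enter the model fits.

# Network construction

- **Base network:** exactly the PPI edges with at least one seed
  endpoint. Edges between two non-seed neighbours are excluded by
  default (the strict reading of "interactions involving the seeds");
  `include_neighbor_edges = TRUE` gives the permissive variant. Seeds
  without any retrieved interaction remain as isolated nodes.
- **Namespacing:** protein nodes are `P:<SYMBOL>` and drug nodes
  `D:<drug id>`, so a drug name can never collide with a gene symbol.
  Input symbols are upper-cased before matching; self-loops and
  duplicate unordered pairs are removed (undirected edge identity is the
  sorted id pair).
- **Drugs:** one node per drug with at least one target in the network
  and one `drug_target` edge per (drug, present target) pair —
  re-applying the same table is a no-op, and drug nodes always have
  degree ≥ 1.
- **Subnetworks:** one-step expansion takes the called nodes plus all
  direct neighbours (proteins and drugs) and keeps the induced subgraph
  — edges between two neighbours are retained, matching how such
  networks are displayed; `star_only = TRUE` drops them.
- **Components** are reported largest-first with deterministic
  tie-breaking (lexicographic smallest member), and the "central
  component" of a refined network is its largest connected component.

# Target reports

A **druggable target row** is an over-expressed protein with at least one
drug edge in the subnetwork, its adjacent seed proteins (sorted), its
drugs, its degree, and its per-subgroup call flags. A **bridging node**
is such a protein with ≥ 2 *distinct* seed partners: it connects
otherwise separate seed-centred regions of the network, so one inhibitor
may perturb several driver hubs. The threshold of 2 operationalizes the
canonical examples (a tubulin chain touching two to three CIS hubs; CDK6
touching two); a betweenness-based definition was considered and
deliberately left out of scope — it needs a null model for edge
sampling that the underlying procedure never specifies.

Ranking is a stable sort on (number of subgroups called, seed-partner
count, subnetwork degree, symbol), so reruns produce byte-identical
reports. All report sort orders and tie-breaks are fixed for diffable
outputs.

# The synthetic-data generator

`simulate_study()` emulates all pipeline inputs with known ground truth:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 500 | gene universe size (network-scale, not array-scale) |
| `n_seeds` | 25 | seed genes |
| `mean_degree` | 4 | Erdős–Rényi background PPI degree |
| `groups` | SHH/Gp3/Gp4 = 12 each; normal foetal/adult = 6 each | samples |
| `effect_lfc` | 1.5 | planted log2 over-expression |
| `noise_sd` | 0.7 | within-group SD (log2) |
| `probes_per_gene_max` | 3 | probes per gene, uniform 1..max |
| `n_planted_common` / `n_planted_specific` / `n_bridging` | 20 / 10 / 8 | planted structure |
| `one_to_many_frac` | 0.1 | mouse symbols with two human orthologs |

The effect size and noise level correspond to a raw two-sample $t$ of
about 5 at 12 samples per group — a clearly detectable but not trivial
planted signal. Planted bridging genes are deterministically wired to
2–3 distinct seeds and guaranteed a drug; the recorded bridging *truth*
is computed from the realized artifacts (planted-common genes that are
drugged and have ≥ 2 seed neighbours in the emitted edge table), so
recovery tests are exact set comparisons. One root seed feeds
per-artifact RNG sub-streams, so regenerating one artifact never
perturbs another and all outputs are byte-reproducible.

What the generator does **not** emulate: Affymetrix probe-intensity
distributions or normalization artefacts, scale-free/assortative PPI
degree structure, correlated expression between interacting genes, and
per-probe variance heterogeneity (noise is i.i.d. Gaussian with one SD,
matching the moderated-t model's equal-variance case; under this design
the fitted prior df is effectively infinite). Passing recovery tests
therefore demonstrates the pipeline's correctness and calibration under
its own model assumptions — not robustness to real-array artefacts, and
no degree-preserving network null model is implied.

# Problem sizes and validation regimes

The test suite and the acceptance script use: the bundled 16-protein
worked example (exact, deterministic); 100-graph brute-force oracle
sweeps (n ≤ 100) for expansion, components and bridging; 200 random
p-vectors against the step-up definition; a 5000-probe null calibration
at 12 samples/group (nominal level recovered within three binomial
standard errors; FDR-adjusted call fraction ≤ α + 3·SE); and 20
synthetic studies at the default regime for planted recovery
(sensitivity ≥ 0.95 for common and bridging targets, empirical false
discovery ≤ 0.10). These sizes keep each validation exact or
well-powered while remaining quick to rerun.

# Known limitations

- The moderated-t implementation covers the two-group design the
  pipeline needs; there are no multi-factor linear models, batch
  correction, or array preprocessing (RMA and relatives are upstream of
  this package's inputs).
- Drug–target edges are treated as unweighted, validated interactions;
  there is no affinity scoring, ADMET, or brain-penetrance modelling —
  ranking is purely topological/statistical.
- Reproducing the exact published sizes of networks built from specific
  interactome and drug-database snapshots is out of scope: those depend
  on database versions that cannot be pinned here. The bundled example
  instead fixes a fully enumerable network whose expected outputs are
  known by hand.
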