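## Bundled worked example: a small medulloblastoma seed network of six
## mutagenesis-screen (CIS) driver proteins and the ten over-expressed
## druggable interactors reported for non-WNT tumours, used in the README,
## the documentation examples and the validation suite.

#' A small worked-example network of druggable medulloblastoma targets
#'
#' Six seed proteins from the insertional-mutagenesis screen (CDKN2A,
#' ZEB1, MAP3K1, TJP1, PTN, PPP2R5E), thirteen protein-protein
#' interactions linking them to ten druggable proteins over-expressed in
#' all three non-WNT medulloblastoma subgroups (AURKA, CAD, CDK4, CDK6,
#' CHEK2, P4HB, PTPRS, SLC1A5, SNRPA, TUBB), a drug table and matching
#' over-expression calls for SHH, Gp3 and Gp4.
#'
#' Two drug-target rows are literature-grounded (ixabepilone/DB04845 ->
#' TUBB; palbociclib/DB09073 -> CDK4 and CDK6); the remaining rows are
#' synthetic stand-ins (ids `DSYN...`) so that every over-expressed
#' protein in the example is druggable. The expression statistics are
#' synthetic too: this fixture exercises the network operations, not the
#' expression model.
#'
#' @return list with `seeds` (character), `ppi` (data.frame), `drugs`
#'   (data.frame) and `calls` (named list of `gene_calls` for SHH, Gp3,
#'   Gp4).
#' @examples
#' ex <- example_inputs()
#' net <- build_base_network(ex$seeds, ex$ppi)
#' net <- attach_drugs(net, ex$drugs)
#' net <- annotate_de(net, ex$calls)
#' sub <- build_refined_common(net, intersect_common(ex$calls))
#' report_druggable(sub)
#' @export
example_inputs <- function() {
  seeds <- c("CDKN2A", "ZEB1", "MAP3K1", "TJP1", "PTN", "PPP2R5E")
  ppi <- data.frame(
    protein_a = c("CDK6", "CDK6", "TUBB", "TUBB", "TUBB", "AURKA", "SNRPA",
                  "CDK4", "CAD", "SLC1A5", "CHEK2", "P4HB", "PTPRS"),
    protein_b = c("CDKN2A", "ZEB1", "CDKN2A", "MAP3K1", "TJP1", "CDKN2A",
                  "CDKN2A", "CDKN2A", "MAP3K1", "MAP3K1", "PPP2R5E", "PTN",
                  "PTN"),
    stringsAsFactors = FALSE)
  drugs <- data.frame(
    drug_id = c("DB04845", "DB09073", "DB09073", "DSYN0001", "DSYN0002",
                "DSYN0003", "DSYN0004", "DSYN0005", "DSYN0006", "DSYN0007"),
    drug_name = c("ixabepilone", "palbociclib", "palbociclib", "alisertib",
                  "sparfosic acid", "prexasertib", "bacitracin",
                  "ptprs_ligand", "v_9302", "snrpa_ligand"),
    target_symbol = c("TUBB", "CDK4", "CDK6", "AURKA", "CAD", "CHEK2",
                      "P4HB", "PTPRS", "SLC1A5", "SNRPA"),
    stringsAsFactors = FALSE)

  over <- sort(unique(drugs$target_symbol))
  genes <- sort(c(seeds, over))
  calls <- list()
  for (cmp in c("SHH", "Gp3", "Gp4")) {
    tab <- data.frame(
      gene = genes,
      probe_id = paste0(tolower(genes), "_p1"),
      lfc = ifelse(genes %in% over, 1.4, -0.2),
      t = ifelse(genes %in% over, 5.0, -0.7),
      p = ifelse(genes %in% over, 1e-4, 0.5),
      q = ifelse(genes %in% over, 1e-3, 0.6),
      called = genes %in% over,
      stringsAsFactors = FALSE)
    calls[[cmp]] <- structure(tab, class = c("gene_calls", "data.frame"),
                              comparison = cmp, alpha = 0.05, min_lfc = 0)
  }
  list(seeds = seeds, ppi = ppi, drugs = drugs, calls = calls)
}
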