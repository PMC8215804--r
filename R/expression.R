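## Expression analysis: normalization, empirical-Bayes moderated t-test,
## Benjamini-Hochberg FDR, gene-level over-expression calls and the common
## (all-subgroup) intersection.

#' Normalize an expression matrix
#'
#' Applies one or more normalization steps to a probe-by-sample matrix of
#' log2 intensities. `"zscore_rows"` standardizes each probe row to mean 0
#' and sample standard deviation 1; `"center_scale"` does the same for each
#' sample column, ensuring comparable distributions across samples before
#' differential expression. Steps are applied in the order given.
#'
#' Rows (or columns) with zero variance cannot be standardized; they are
#' dropped with a warning rather than aborting the run.
#'
#' @param mat numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids).
#' @param modes character vector, any of `"zscore_rows"`, `"center_scale"`.
#' @return the normalized matrix (possibly with fewer rows/columns).
#' @examples
#' m <- rbind(p1 = c(1, 2, 3), p2 = c(5, 5, 6))
#' colnames(m) <- c("s1", "s2", "s3")
#' normalize_expression(m, "zscore_rows")
#' @export
normalize_expression <- function(mat, modes = c("zscore_rows", "center_scale")) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (ncol(mat) < 2L) np_stop("normalize", "need at least 2 samples")
  modes <- match.arg(modes, c("zscore_rows", "center_scale"), several.ok = TRUE)
  for (mode in modes) {
    if (mode == "zscore_rows") {
      sds <- apply(mat, 1L, stats::sd)
      bad <- !is.finite(sds) | sds == 0
      if (any(bad)) {
        np_warn("normalize", sprintf(
          "dropping %d zero-variance probe row(s): %s", sum(bad),
          paste(utils::head(rownames(mat)[bad], 5L), collapse = ", ")))
        mat <- mat[!bad, , drop = FALSE]
        sds <- sds[!bad]
      }
      mat <- (mat - rowMeans(mat)) / sds
    } else {
      sds <- apply(mat, 2L, stats::sd)
      bad <- !is.finite(sds) | sds == 0
      if (any(bad)) {
        np_warn("normalize", sprintf(
          "dropping %d zero-variance sample column(s): %s", sum(bad),
          paste(utils::head(colnames(mat)[bad], 5L), collapse = ", ")))
        mat <- mat[, !bad, drop = FALSE]
        sds <- sds[!bad]
      }
      mat <- sweep(sweep(mat, 2L, colMeans(mat)), 2L, sds, `/`)
    }
  }
  mat
}

#' Specify a two-group comparison
#'
#' @param name label for the comparison (e.g. `"Gp3"`).
#' @param case_group group label(s) forming the case side.
#' @param reference_group group label(s) forming the reference side; several
#'   labels (e.g. foetal and adult normal cerebellum) are pooled.
#' @return a `comparison_spec` object.
#' @export
comparison_spec <- function(name, case_group, reference_group) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (length(intersect(case_group, reference_group)) > 0L) {
    np_stop("de", "case and reference groups must be disjoint")
  }
  structure(list(name = name, case_group = as.character(case_group),
                 reference_group = as.character(reference_group)),
            class = "comparison_spec")
}

# Invert the trigamma function by Newton iteration (monotone decreasing on
# (0, Inf)); used by the method-of-moments fit of the prior df.
trigamma_inverse <- function(y) {
  if (!is.finite(y) || y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2L)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

# Method-of-moments fit of the scaled inverse-chi-square prior (d0, s0^2)
# for per-probe sample variances s2, all with residual df `df`. Works on
# z = log(s2): under the model, z - digamma(df/2) + log(df/2) has mean
# log(s0^2) + digamma(d0/2) - log(d0/2) and variance
# trigamma(df/2) + trigamma(d0/2).
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L) {
    return(list(d0 = 0, s0_sq = if (any(ok)) mean(s2[ok]) else NA_real_))
  }
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(mean(e))
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Empirical-Bayes moderated two-sample t-test
#'
#' For each probe, computes the difference of group means (the log2 fold
#' change, case minus reference), the pooled sample variance s_g^2 with
#' d_g = n1 + n2 - 2 residual degrees of freedom, and a moderated variance
#' that shrinks s_g^2 toward a prior s_0^2 fitted across probes:
#'
#'   s~_g^2 = (d0 * s0^2 + d_g * s_g^2) / (d0 + d_g)
#'
#' The moderated statistic t~_g = dm_g / (s~_g * sqrt(1/n1 + 1/n2)) is
#' referred to a t distribution on d0 + d_g degrees of freedom (two-sided).
#' The prior parameters (d0, s0^2) are fitted by method of moments on the
#' log sample variances. With `d0 = 0` the statistic reduces exactly to the
#' ordinary pooled-variance two-sample t.
#'
#' @param mat numeric probe-by-sample matrix (log2 scale).
#' @param annot data.frame with columns `sample_id`, `group` covering every
#'   column of `mat`.
#' @param spec a [comparison_spec()].
#' @param d0 optional prior degrees of freedom override; `NULL` (default)
#'   fits d0 and s0^2 from the data, `0` gives the classic pooled t,
#'   `Inf` fully shrinks every variance to s0^2 (supply `s0_sq`).
#' @param s0_sq optional prior variance override (used with non-NULL `d0`).
#' @return a `de_table`: data.frame with one row per probe (`probe_id`,
#'   `lfc`, `s2`, `s2_post`, `t`, `df_total`, `p`, `q`) and attributes
#'   `d0`, `s0_sq`, `df_residual`, `comparison`. `q` is the
#'   Benjamini-Hochberg adjusted p-value (see [adjust_bh()]).
#' @seealso [call_overexpressed()] to collapse probes to gene-level calls.
#' @export
moderated_ttest <- function(mat, annot, spec, d0 = NULL, s0_sq = NULL) {
  stopifnot(is.matrix(mat), inherits(spec, "comparison_spec"))
  annot <- validate_annotation(annot, colnames(mat))
  grp <- annot$group[match(colnames(mat), annot$sample_id)]
  case_idx <- which(grp %in% spec$case_group)
  ref_idx <- which(grp %in% spec$reference_group)
  n1 <- length(case_idx); n2 <- length(ref_idx)
  if (n1 < 2L || n2 < 2L) {
    np_stop("de", sprintf(
      "comparison '%s' needs >= 2 samples per side (case %d, reference %d)",
      spec$name, n1, n2))
  }

  case <- mat[, case_idx, drop = FALSE]
  ref <- mat[, ref_idx, drop = FALSE]
  lfc <- rowMeans(case) - rowMeans(ref)
  df_g <- n1 + n2 - 2L
  # pooled within-group variance, vectorized over probes
  ss_case <- rowSums((case - rowMeans(case))^2)
  ss_ref <- rowSums((ref - rowMeans(ref))^2)
  s2 <- (ss_case + ss_ref) / df_g

  if (is.null(d0)) {
    prior <- fit_variance_prior(s2, df_g)
    d0 <- prior$d0
    s0_sq <- prior$s0_sq
  } else if (is.null(s0_sq)) {
    s0_sq <- if (d0 > 0) mean(s2[is.finite(s2) & s2 > 0]) else NA_real_
  }

  s2_post <- if (is.infinite(d0)) {
    rep(s0_sq, length(s2))
  } else if (d0 == 0) {
    s2
  } else {
    (d0 * s0_sq + df_g * s2) / (d0 + df_g)
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tstat <- lfc / se
  # degenerate probes: zero moderated variance (possible only when d0 = 0)
  degen <- !is.finite(tstat)
  if (any(degen)) {
    zero_delta <- degen & lfc == 0
    tstat[zero_delta] <- 0
    tstat[degen & !zero_delta] <- sign(lfc[degen & !zero_delta]) * Inf
    if (any(degen & !zero_delta)) {
      np_warn("de", sprintf(
        "%d probe(s) with zero pooled variance and nonzero mean difference; statistic set to +/-Inf",
        sum(degen & !zero_delta)))
    }
  }
  df_total <- d0 + df_g
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  q <- adjust_bh(p)

  res <- data.frame(
    probe_id = rownames(mat) %||% as.character(seq_len(nrow(mat))),
    lfc = lfc, s2 = s2, s2_post = s2_post, t = tstat,
    df_total = df_total, p = p, q = q,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(res, class = c("de_table", "data.frame"),
            d0 = d0, s0_sq = s0_sq, df_residual = df_g,
            comparison = spec$name,
            n_case = n1, n_ref = n2)
}

#' @export
print.de_table <- function(x, ...) {
  cat(sprintf("Differential expression table '%s': %d probes\n",
              attr(x, "comparison") %||% "?", nrow(x)))
  cat(sprintf("  empirical-Bayes prior: d0 = %.3g, s0^2 = %.4g (residual df = %d)\n",
              attr(x, "d0"), attr(x, "s0_sq"), attr(x, "df_residual")))
  cat(sprintf("  probes with q < 0.05: %d (%d up, %d down)\n",
              sum(x$q < 0.05), sum(x$q < 0.05 & x$lfc > 0),
              sum(x$q < 0.05 & x$lfc < 0)))
  invisible(x)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Computes q_(i) = min over j >= i of p_(j) * m / j (capped at 1) for the
#' order statistics p_(1) <= ... <= p_(m), returned in the input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return numeric vector of adjusted values, monotone non-decreasing in p.
#' @examples
#' adjust_bh(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
adjust_bh <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    np_stop("fdr", "p-values must be numeric in [0, 1] with no NA")
  }
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  q
}

validate_annotation <- function(annot, sample_ids, stage = "annot") {
  if (!is.data.frame(annot) || !all(c("sample_id", "group") %in% names(annot))) {
    np_stop(stage, "annotation must be a data.frame with columns sample_id, group")
  }
  missing <- setdiff(sample_ids, annot$sample_id)
  if (length(missing) > 0L) {
    np_stop(stage, sprintf("samples without annotation: %s",
                           paste(utils::head(missing, 5L), collapse = ", ")))
  }
  if (anyDuplicated(annot$sample_id)) {
    np_stop(stage, "duplicate sample_id in annotation")
  }
  annot
}

#' Call over-expressed genes from a probe-level DE table
#'
#' A gene is called over-expressed if any of its probes is significant
#' (q < `alpha`) with log2 fold change above `min_lfc` — every probe of a
#' gene counts, with no prior probe selection. The gene's reported "best"
#' probe is the one with the smallest q (ties broken by largest absolute
#' fold change, then lexicographic probe id), and its statistics annotate
#' the gene's network node downstream.
#'
#' @param de a `de_table` from [moderated_ttest()].
#' @param probe_map data.frame with columns `probe_id`, `gene_symbol`.
#' @param alpha FDR threshold in (0, 1).
#' @param min_lfc minimum log2 fold change (default 0: significance and
#'   direction only).
#' @return a `gene_calls` object: data.frame with one row per gene
#'   (`gene`, `probe_id`, `lfc`, `t`, `p`, `q`, `called`) plus attributes
#'   `comparison`, `alpha`, `min_lfc`.
#' @export
call_overexpressed <- function(de, probe_map, alpha = 0.05, min_lfc = 0) {
  assert_scalar_prob(alpha, "alpha", stage = "calls")
  stopifnot(inherits(de, "de_table"),
            all(c("probe_id", "gene_symbol") %in% names(probe_map)))
  idx <- match(de$probe_id, probe_map$probe_id)
  unmapped <- is.na(idx)
  if (any(unmapped)) {
    np_warn("calls", sprintf("dropping %d probe(s) absent from the probe map",
                             sum(unmapped)))
  }
  d <- de[!unmapped, , drop = FALSE]
  d$gene <- probe_map$gene_symbol[idx[!unmapped]]

  # best probe per gene: smallest q, then largest |lfc|, then probe id
  ord <- order(d$gene, d$q, -abs(d$lfc), d$probe_id)
  d <- d[ord, , drop = FALSE]
  best <- d[!duplicated(d$gene), , drop = FALSE]
  hit <- d$q < alpha & d$lfc > min_lfc
  called_genes <- unique(d$gene[hit])

  res <- data.frame(
    gene = best$gene, probe_id = best$probe_id, lfc = best$lfc,
    t = best$t, p = best$p, q = best$q,
    called = best$gene %in% called_genes,
    row.names = NULL, stringsAsFactors = FALSE
  )
  res <- res[order(res$gene), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("gene_calls", "data.frame"),
            comparison = attr(de, "comparison"), alpha = alpha,
            min_lfc = min_lfc)
}

#' Genes called over-expressed in a `gene_calls` object
#' @param calls a `gene_calls` object.
#' @return character vector of called gene symbols (sorted).
#' @export
called_genes <- function(calls) {
  stopifnot(inherits(calls, "gene_calls"))
  sort(calls$gene[calls$called])
}

#' @export
print.gene_calls <- function(x, ...) {
  cat(sprintf("Gene calls '%s': %d genes, %d called over-expressed (alpha = %g, min lfc = %g)\n",
              attr(x, "comparison") %||% "?", nrow(x), sum(x$called),
              attr(x, "alpha"), attr(x, "min_lfc")))
  invisible(x)
}

#' Intersect over-expression calls across comparisons
#'
#' Returns the genes called over-expressed in every supplied comparison —
#' the "commonly over-expressed" set across the non-WNT tumour subgroups.
#'
#' @param call_sets list of `gene_calls` objects (at least 2).
#' @return sorted character vector of common genes.
#' @export
intersect_common <- function(call_sets) {
  if (!is.list(call_sets) || length(call_sets) < 2L) {
    np_stop("common", "need at least 2 call sets to intersect")
  }
  sort(Reduce(intersect, lapply(call_sets, called_genes)))
}
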