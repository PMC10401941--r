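# Expression-side validation: CPM filtering, median-of-ratios size factors,
# pseudocount log2 fold changes, a Welch-t differential test with BH
# adjustment, target-set ECDF/KS derepression tests, concordance
# classification, threshold gene sets, sample clustering, and delta-Ct
# quantification.
#
# The differential-expression engine is a deliberately simple, fully
# documented one (median-of-ratios normalization + Welch t on log2
# normalized counts): the set-level statistics this pipeline consumes
# (fold-change signs, ECDF shifts) are robust to it.

#' Remove lowly expressed genes by mean CPM
#'
#' A gene is kept iff its mean counts-per-million across all samples is at
#' least `min_mean_cpm` (boundary value kept). Library sizes are column
#' sums.
#'
#' @param counts Gene-by-sample count matrix.
#' @param min_mean_cpm Mean CPM threshold (default 2).
#' @return The filtered matrix, with attributes `n_kept` and `n_removed`.
#' @export
cpm_filter <- function(counts, min_mean_cpm = 2) {
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("library size <= 0 in at least one sample")
  cpm <- sweep(counts, 2, lib, "/") * 1e6
  keep <- rowMeans(cpm) >= min_mean_cpm
  if (!any(keep)) stop("CPM filter removed all genes")
  out <- counts[keep, , drop = FALSE]
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over reference genes (genes with nonzero
#' counts in every sample) of the ratio of the count to the gene's
#' geometric mean across samples. Corrects sequencing depth; only factor
#' ratios between samples are identified.
#'
#' @param counts Gene-by-sample count matrix.
#' @return Positive numeric vector, one factor per sample.
#' @export
size_factors_median_of_ratios <- function(counts) {
  ref <- rowSums(counts == 0) == 0
  if (!any(ref)) {
    stop("no gene has nonzero counts in all samples; consider a pseudo-reference")
  }
  x <- counts[ref, , drop = FALSE]
  geo <- exp(rowMeans(log(x)))
  apply(x, 2, function(col) stats::median(col / geo))
}

#' Log2 fold changes between two sample groups
#'
#' Means of size-factor-normalized counts per group, with a pseudocount to
#' keep the log ratio finite: `log2((mean_A + pc) / (mean_B + pc))` for the
#' contrast "A_vs_B", so a positive value means higher in A.
#'
#' @param counts Count matrix.
#' @param size_factors Per-sample factors (e.g.
#'   [size_factors_median_of_ratios()]).
#' @param a_cols,b_cols Column names or indices of the two groups.
#' @param pseudocount Added to each group mean (default 0.5).
#' @param label Contrast label, e.g. `"WT_vs_scr"`.
#' @return data.frame: gene_id, log2fc, mean_norm_a, mean_norm_b, contrast.
#' @export
gene_log2fc <- function(counts, size_factors, a_cols, b_cols,
                        pseudocount = 0.5, label = "A_vs_B") {
  norm <- sweep(counts, 2, size_factors, "/")
  a <- norm[, a_cols, drop = FALSE]
  b <- norm[, b_cols, drop = FALSE]
  if (ncol(a) < 2L || ncol(b) < 2L) stop("each group needs >= 2 samples")
  ma <- rowMeans(a); mb <- rowMeans(b)
  data.frame(
    gene_id = rownames(counts),
    log2fc = log2((ma + pseudocount) / (mb + pseudocount)),
    mean_norm_a = ma, mean_norm_b = mb,
    contrast = label, stringsAsFactors = FALSE
  )
}

#' Welch t-test per gene on log2 normalized counts
#'
#' Two-sided p-values; zero within-group variance in both groups yields
#' p = 1 when the means are equal and p ~ 0 when they differ.
#'
#' @inheritParams gene_log2fc
#' @return Numeric p-value vector (one per gene).
#' @export
gene_de_test <- function(counts, size_factors, a_cols, b_cols,
                         pseudocount = 0.5) {
  norm <- log2(sweep(counts, 2, size_factors, "/") + pseudocount)
  a <- norm[, a_cols, drop = FALSE]
  b <- norm[, b_cols, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  if (na < 2L || nb < 2L) stop("each group needs >= 2 samples")
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t_stat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t_stat), df = df)
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(ma[degenerate] == mb[degenerate], 1, 0)
  unname(p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: `padj_(i) = min_{j >= i} (m / j) p_(j)`, capped
#' at 1, monotone non-decreasing in p, order-invariant in the gene -> padj
#' mapping.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Full two-group differential expression analysis
#'
#' Convenience wrapper: size factors on the full matrix, fold changes and
#' Welch-t p-values on the selected samples, BH adjustment within the
#' contrast.
#'
#' @param counts Filtered count matrix.
#' @param samples Sample table with a `sample_id` column.
#' @param column Metadata column defining groups (default `"genotype"`).
#' @param a,b Group levels; the contrast is reported as a_vs_b.
#' @param subset Optional logical vector over `samples` rows restricting
#'   which samples enter (e.g. one stimulation condition).
#' @param size_factors Optional precomputed factors.
#' @param pseudocount Pseudocount for fold changes and log tests.
#' @return DE table: gene_id, log2fc, p_value, padj, group means, contrast.
#' @export
de_analysis <- function(counts, samples, column = "genotype", a, b,
                        subset = NULL, size_factors = NULL, pseudocount = 0.5) {
  if (!is.null(subset)) samples <- samples[subset, , drop = FALSE]
  a_ids <- samples$sample_id[samples[[column]] == a]
  b_ids <- samples$sample_id[samples[[column]] == b]
  if (length(a_ids) == 0L || length(b_ids) == 0L) {
    stop(sprintf("group missing from sample table: %s",
                 paste(c(a, b)[c(length(a_ids), length(b_ids)) == 0], collapse = ", ")))
  }
  use <- counts[, c(a_ids, b_ids), drop = FALSE]
  if (is.null(size_factors)) size_factors <- size_factors_median_of_ratios(use)
  fc <- gene_log2fc(use, size_factors, a_ids, b_ids, pseudocount,
                    label = paste0(a, "_vs_", b))
  fc$p_value <- gene_de_test(use, size_factors, a_ids, b_ids, pseudocount)
  fc$padj <- bh_adjust(fc$p_value)
  fc
}

#' Target-set ECDF shift test (two-sample Kolmogorov-Smirnov)
#'
#' Compares the distribution of log2 fold changes of the target genes with
#' that of all other tested genes. D is the supremum ECDF gap; the p-value
#' is the asymptotic two-sided KS p. The direction is the sign of the
#' median difference (target minus background).
#'
#' @param de DE table (needs gene_id and log2fc).
#' @param targets Character vector of target gene ids (a gene set).
#' @param background Optional explicit background ids; default all tested
#'   genes not in `targets`.
#' @return A list of class `ks_shift`: D, p_value, n_target, n_background,
#'   direction, median_target, median_background.
#' @export
ecdf_shift_test <- function(de, targets, background = NULL) {
  tv <- de$log2fc[de$gene_id %in% targets]
  bg_ids <- if (is.null(background)) setdiff(de$gene_id, targets) else background
  bv <- de$log2fc[de$gene_id %in% bg_ids]
  if (length(tv) < 2L) stop("need >= 2 target genes among tested genes")
  if (length(bv) == 0L) stop("empty background set")
  ks <- suppressWarnings(stats::ks.test(tv, bv, exact = FALSE))
  structure(list(
    D = unname(ks$statistic), p_value = ks$p.value,
    n_target = length(tv), n_background = length(bv),
    direction = sign(stats::median(tv) - stats::median(bv)),
    median_target = stats::median(tv), median_background = stats::median(bv)
  ), class = "ks_shift")
}

#' @export
print.ks_shift <- function(x, ...) {
  cat(sprintf("KS shift test: D=%.4f, p=%.3g (targets n=%d %s background n=%d)\n",
              x$D, x$p_value,
              x$n_target, if (x$direction >= 0) "above" else "below",
              x$n_background))
  invisible(x)
}

#' Concordance classification of target genes across two contrasts
#'
#' Classifies each target gene by two strict sign conditions: downregulated
#' in the sponge-mutant contrast (`log2fc > 0` for control-vs-mutant) and
#' upregulated in the knockout contrast (`log2fc < 0` for
#' control-vs-knockout). Genes missing from either DE table are reported
#' and excluded from the denominator.
#'
#' @param de_scr DE table for the control-vs-sponge-mutant contrast.
#' @param de_ko DE table for the control-vs-knockout contrast.
#' @param targets Character vector of target gene ids.
#' @return A list of class `venn_counts`: n_targets, n_down_in_scr,
#'   n_up_in_ko, n_both, n_either, n_neither, corresponding percentages,
#'   and missing gene ids.
#' @export
concordance_venn <- function(de_scr, de_ko, targets) {
  s <- de_scr$log2fc[match(targets, de_scr$gene_id)]
  k <- de_ko$log2fc[match(targets, de_ko$gene_id)]
  missing <- targets[is.na(s) | is.na(k)]
  ok <- !(is.na(s) | is.na(k))
  s <- s[ok]; k <- k[ok]
  down_scr <- s > 0        # higher in control than sponge-mutant
  up_ko <- k < 0           # higher in knockout than control
  n <- length(s)
  pct <- function(x) if (n > 0) 100 * x / n else NA_real_
  structure(list(
    n_targets = n,
    n_down_in_scr = sum(down_scr),
    n_up_in_ko = sum(up_ko),
    n_both = sum(down_scr & up_ko),
    n_either = sum(down_scr | up_ko),
    n_neither = sum(!down_scr & !up_ko),
    pct_down_in_scr = pct(sum(down_scr)),
    pct_up_in_ko = pct(sum(up_ko)),
    pct_both = pct(sum(down_scr & up_ko)),
    pct_either = pct(sum(down_scr | up_ko)),
    missing = missing
  ), class = "venn_counts")
}

#' @export
print.venn_counts <- function(x, ...) {
  cat(sprintf(
    "concordance: %d targets; down-in-mutant %d (%.0f%%), up-in-ko %d (%.0f%%), both %d (%.0f%%), either %d (%.0f%%)\n",
    x$n_targets, x$n_down_in_scr, x$pct_down_in_scr, x$n_up_in_ko,
    x$pct_up_in_ko, x$n_both, x$pct_both, x$n_either, x$pct_either
  ))
  invisible(x)
}

#' Threshold-defined gene set
#'
#' Genes with `log2fc > lfc_min` and `padj < padj_max` (both strict), e.g.
#' the costimulation-responsive set (log2FC > 1.5, adjusted p < 0.001).
#'
#' @param de DE table with log2fc and padj.
#' @param lfc_min Strict lower bound on log2fc.
#' @param padj_max Strict upper bound on adjusted p.
#' @return A list of class `gene_set`: ids, provenance.
#' @export
threshold_gene_set <- function(de, lfc_min = 1.5, padj_max = 0.001) {
  ids <- de$gene_id[de$log2fc > lfc_min & de$padj < padj_max]
  structure(list(
    ids = ids,
    provenance = sprintf("log2fc > %g & padj < %g on contrast %s",
                         lfc_min, padj_max, de$contrast[1])
  ), class = "gene_set")
}

#' Relative expression from qPCR Ct values (2^-dCt)
#'
#' Technical duplicates (vectors) are averaged before the subtraction.
#'
#' @param ct_target Ct value(s) of the assayed RNA.
#' @param ct_reference Ct value(s) of the housekeeping reference.
#' @return `2^-(mean(ct_target) - mean(ct_reference))`.
#' @examples
#' qpcr_rel_expr(25, 20)  # 2^-5
#' @export
qpcr_rel_expr <- function(ct_target, ct_reference) {
  stopifnot(all(is.finite(ct_target)), all(is.finite(ct_reference)))
  2^-(mean(ct_target) - mean(ct_reference))
}
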