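# Differential expression with the expression filter and BH correction,
# methylation-expression concordance, replication concordance, and
# absolute-vs-relative methylation validation.

#' Differential expression with expression filtering and BH correction
#'
#' Genes whose larger group-mean expression falls below the pooled
#' `expression_percentile`-th percentile of all gene-level group means are
#' excluded before testing ("filtered by expression"); the rest get a
#' two-sample t-test and Benjamini-Hochberg step-up correction, with
#' significance at adjusted p < `alpha`.
#'
#' @param expr Matrix genes x samples (log2 scale).
#' @param groups Named `control`/`case` vector per sample.
#' @param expression_percentile Filter percentile (default 20).
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @param var_equal Pooled-variance t (default) or Welch.
#' @return data.frame per tested gene: `gene`, `mean_control`, `mean_case`,
#'   `log_fc`, `t_statistic`, `p_value`, `bh_adjusted_p`, `passes_filter`;
#'   excluded-gene count in attribute `"n_filtered"`.
#' @export
differential_expression <- function(expr, groups,
                                    expression_percentile = 20,
                                    alpha = 0.05, var_equal = TRUE) {
  expr <- as.matrix(expr)
  groups <- groups[colnames(expr)]
  if (anyNA(groups)) stopf("group labels missing for some samples")
  if (sum(groups == "control") < 2 || sum(groups == "case") < 2)
    stopf("need at least 2 samples per group")
  m_ctrl <- rowMeans(expr[, groups == "control", drop = FALSE])
  m_case <- rowMeans(expr[, groups == "case", drop = FALSE])
  cutoff <- quantile(c(m_ctrl, m_case), expression_percentile / 100,
                     names = FALSE)
  tested <- pmax(m_ctrl, m_case) > cutoff
  if (!any(tested)) {
    warning("all genes fall below the expression filter; nothing tested")
    out <- data.frame(gene = character(), mean_control = numeric(),
                      mean_case = numeric(), log_fc = numeric(),
                      t_statistic = numeric(), p_value = numeric(),
                      bh_adjusted_p = numeric(), passes_filter = logical(),
                      stringsAsFactors = FALSE)
    attr(out, "n_filtered") <- nrow(expr)
    return(out)
  }
  stats <- locus_differential_test(expr[tested, , drop = FALSE],
                                   groups = groups, var_equal = var_equal)
  adj <- p.adjust(stats$p_value, method = "BH")
  out <- data.frame(gene = stats$fragment_id,
                    mean_control = unname(m_ctrl[stats$fragment_id]),
                    mean_case = unname(m_case[stats$fragment_id]),
                    log_fc = stats$delta,
                    t_statistic = stats$t_statistic,
                    p_value = stats$p_value,
                    bh_adjusted_p = adj,
                    passes_filter = adj < alpha,
                    stringsAsFactors = FALSE)
  attr(out, "n_filtered") <- sum(!tested)
  out
}

#' Methylation-expression concordance of DMR genes
#'
#' Overlaps the genes nearest to DMRs with the significantly differentially
#' expressed genes, and counts sign agreement under the convention that
#' hypomethylation in cases (positive methylation delta on the HpaII/MspI
#' scale) paired with up-regulation in cases (positive expression log-fold
#' change) is concordant, and vice versa.
#'
#' @param dmr_genes data.frame with columns `gene` and `direction`
#'   (`hypo`/`hyper`), one row per DMR-gene link; duplicate genes are
#'   collapsed (a gene counts once; conflicting directions resolved by
#'   majority, ties -> hypo).
#' @param de Output of [differential_expression()].
#' @return List of class `concordance_result`: `n_dmr_genes`, `n_de_genes`,
#'   `n_overlap`, `fraction` (overlap / DMR genes), `n_concordant`,
#'   `concordance_fraction` (among the overlap) and the per-gene table.
#' @export
dmr_expression_concordance <- function(dmr_genes, de) {
  if (nrow(dmr_genes) == 0) stopf("empty DMR-gene mapping")
  agg <- tapply(dmr_genes$direction == "hypo", dmr_genes$gene, mean)
  genes <- data.frame(gene = names(agg),
                      direction = ifelse(agg >= 0.5, "hypo", "hyper"),
                      stringsAsFactors = FALSE)
  sig <- de[de$passes_filter, , drop = FALSE]
  merged <- merge(genes, sig[, c("gene", "log_fc")], by = "gene")
  merged$concordant <- (merged$direction == "hypo") == (merged$log_fc > 0)
  structure(list(
    n_dmr_genes = nrow(genes),
    n_de_genes = nrow(sig),
    n_overlap = nrow(merged),
    fraction = nrow(merged) / nrow(genes),
    n_concordant = sum(merged$concordant),
    concordance_fraction = if (nrow(merged)) mean(merged$concordant) else NA_real_,
    table = merged
  ), class = "concordance_result")
}

#' Replication concordance against an external methylation platform
#'
#' A discovery DMR gene is confirmed when the replication platform's signed
#' absolute-methylation difference (case - control) is nonzero, significant
#' under the supplied rule, and sign-matched: discovery `hypo` (less
#' methylated in cases on the HpaII/MspI ratio scale) matches a negative
#' replication difference. Replication tables with multiple probes per gene
#' are collapsed to the probe with the largest |difference|.
#'
#' @param discovery data.frame with `gene` and `direction` (`hypo`/`hyper`).
#' @param replication data.frame with `gene`, `difference` and optionally
#'   `p` (plus an ignored `probe` column).
#' @param significance Either `"default"` (|difference| > 0, and p < 0.05
#'   when a `p` column is present) or a function of the collapsed
#'   replication table returning a logical vector.
#' @param drop_missing Exclude genes absent from the replication table from
#'   the denominator (default TRUE); they are reported either way.
#' @return List of class `concordance_result`: `n_genes`, `n_missing`,
#'   `n_concordant`, `fraction` and the per-gene table.
#' @export
replication_concordance <- function(discovery, replication,
                                    significance = "default",
                                    drop_missing = TRUE) {
  if (!"difference" %in% names(replication))
    stopf("replication table needs a signed `difference` column")
  agg <- tapply(discovery$direction == "hypo", discovery$gene, mean)
  disc <- data.frame(gene = names(agg),
                     direction = ifelse(agg >= 0.5, "hypo", "hyper"),
                     stringsAsFactors = FALSE)
  rep_dt <- data.table::as.data.table(replication)
  rep_dt <- rep_dt[order(-abs(difference))][, .SD[1], by = gene]
  merged <- merge(disc, as.data.frame(rep_dt), by = "gene", all.x = TRUE)
  missing <- is.na(merged$difference)
  present <- merged[!missing, , drop = FALSE]
  sig <- if (is.function(significance)) significance(present)
         else abs(present$difference) > 0 &
              (if ("p" %in% names(present)) present$p < 0.05 else TRUE)
  sign_match <- (present$direction == "hypo") == (present$difference < 0)
  present$concordant <- sig & sign_match
  denom <- if (drop_missing) nrow(present) else nrow(merged)
  structure(list(
    n_genes = denom,
    n_missing = sum(missing),
    n_concordant = sum(present$concordant),
    fraction = if (denom) sum(present$concordant) / denom else NA_real_,
    table = present
  ), class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  nm <- setdiff(names(x), "table")
  for (k in nm) cat(sprintf("%s: %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Correlate absolute methylation with relative HpaII/MspI ratios
#'
#' Pearson correlation of matched pairs of absolute methylation (percent,
#' e.g. MassArray EpiTyper) and relative log2(HpaII/MspI). The assay
#' semantics predict a negative correlation: more methylation, less HpaII
#' amplification, lower ratio.
#'
#' @param absolute Numeric vector of absolute methylation percentages.
#' @param relative Numeric vector of matched log-ratios (same length).
#' @return List with `r` (NA with a warning when either side is constant),
#'   `n`, and the paired audit `table`.
#' @export
absolute_relative_correlation <- function(absolute, relative) {
  if (length(absolute) != length(relative))
    stopf("absolute and relative vectors must be matched")
  ok <- !is.na(absolute) & !is.na(relative)
  absolute <- absolute[ok]; relative <- relative[ok]
  if (length(absolute) < 3) stopf("need at least 3 matched pairs")
  r <- if (sd(absolute) == 0 || sd(relative) == 0) {
    warning("zero variance on one side; correlation undefined")
    NA_real_
  } else cor(absolute, relative, method = "pearson")
  list(r = r, n = length(absolute),
       table = data.frame(absolute = absolute, relative = relative))
}
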