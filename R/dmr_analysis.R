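# Per-locus differential testing of the methylation matrix, DMR filtering,
# direction summaries, volcano and clustering outputs.

#' Per-locus two-sample t-test of the methylation matrix
#'
#' Pooled-variance two-sample t-test of each fragment's centered
#' log2(HpaII/MspI) between cases and controls (Welch available via
#' `var_equal = FALSE`), with `delta = mean(case) - mean(control)` so that a
#' positive delta means less methylation in cases (hypomethylation). Loci
#' with fewer than two non-missing values in either group, or missing in
#' more than `max_failed_fraction` of either group's samples, are skipped
#' and counted in the attached QC summary.
#'
#' @param mm A [methylation_matrix()], or a plain matrix with `groups`
#'   supplied.
#' @param groups Named `control`/`case` vector per sample (defaults to
#'   `mm$groups`).
#' @param var_equal Pooled-variance t (TRUE, default) or Welch.
#' @param max_failed_fraction Missingness cutoff per group (default 0.5).
#' @return data.frame (one row per tested locus): `fragment_id`, `delta`,
#'   `t_statistic`, `df`, `p_value`, `n_case`, `n_control`; skipped-locus
#'   counts in attribute `"qc"`.
#' @export
locus_differential_test <- function(mm, groups = NULL, var_equal = TRUE,
                                    max_failed_fraction = 0.5) {
  if (inherits(mm, "MethylationMatrix")) {
    mat <- mm$values
    groups <- groups %||% mm$groups
  } else mat <- as.matrix(mm)
  if (is.null(groups)) stopf("group labels are required")
  groups <- groups[colnames(mat)]
  if (anyNA(groups)) stopf("group labels missing for some samples")
  case <- mat[, groups == "case", drop = FALSE]
  ctrl <- mat[, groups == "control", drop = FALSE]
  n1 <- rowSums(!is.na(ctrl))
  n2 <- rowSums(!is.na(case))
  ok_counts <- n1 >= 2 & n2 >= 2
  ok_missing <- (ncol(ctrl) - n1) <= max_failed_fraction * ncol(ctrl) &
                (ncol(case) - n2) <= max_failed_fraction * ncol(case)
  keep <- ok_counts & ok_missing
  qc <- c(tested = sum(keep),
          skipped_low_n = sum(!ok_counts),
          skipped_missingness = sum(ok_counts & !ok_missing))
  if (sum(!keep))
    msg("skipping %d of %d loci (low n or excess missingness)",
        sum(!keep), nrow(mat))
  ctrl <- ctrl[keep, , drop = FALSE]; case <- case[keep, , drop = FALSE]
  n1 <- n1[keep]; n2 <- n2[keep]
  m1 <- rowMeans(ctrl, na.rm = TRUE)
  m2 <- rowMeans(case, na.rm = TRUE)
  v1 <- rowSums((ctrl - m1)^2, na.rm = TRUE) / (n1 - 1)
  v2 <- rowSums((case - m2)^2, na.rm = TRUE) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- (m2 - m1) / se
  tstat[se == 0 & m1 == m2] <- 0
  p <- 2 * pt(-abs(tstat), df)
  out <- data.frame(fragment_id = rownames(mat)[keep],
                    delta = m2 - m1,
                    t_statistic = tstat,
                    df = df,
                    p_value = p,
                    n_control = n1,
                    n_case = n2,
                    stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "qc") <- qc
  out
}

#' Call differentially methylated regions
#'
#' Strict-inequality filter on the per-locus statistics: `p_value <
#' p_threshold` and fold change above `delta_threshold` (on the log scale,
#' |delta| > cutoff, the default; on the ratio scale, 2^|delta| - 1 >
#' cutoff). Survivors are ranked by |t| descending and given a direction:
#' `hypo` (delta > 0, less methylated in cases) or `hyper`.
#'
#' @param stats Output of [locus_differential_test()].
#' @param p_threshold,delta_threshold Filter cutoffs (defaults 0.01 / 0.5).
#' @param fold_change_scale `"log"` (default) or `"ratio"`.
#' @return Object of class `DMRSet`: the surviving rows plus a `direction`
#'   column, thresholds kept as attributes.
#' @export
call_dmrs <- function(stats, p_threshold = 0.01, delta_threshold = 0.5,
                      fold_change_scale = c("log", "ratio")) {
  fold_change_scale <- match.arg(fold_change_scale)
  if (p_threshold <= 0 || delta_threshold <= 0)
    stopf("thresholds must be positive")
  fc <- switch(fold_change_scale,
               log = abs(stats$delta),
               ratio = 2^abs(stats$delta) - 1)
  keep <- stats$p_value < p_threshold & fc > delta_threshold
  out <- stats[which(keep), , drop = FALSE]
  out <- out[order(-abs(out$t_statistic)), , drop = FALSE]
  out$direction <- ifelse(out$delta > 0, "hypo", "hyper")
  rownames(out) <- NULL
  structure(out, class = c("DMRSet", "data.frame"),
            p_threshold = p_threshold, delta_threshold = delta_threshold,
            fold_change_scale = fold_change_scale)
}

#' Direction composition of a DMR set
#'
#' @param dmrs A [call_dmrs()] result (or any data.frame with a `delta`
#'   column).
#' @param category Optional factor/character per DMR (e.g. genomic
#'   category).
#' @return List with `n`, `n_hypo`, `n_hyper`, `hypo_fraction` (NA when
#'   empty) and, when `category` is given, a per-category data.frame.
#' @export
summarize_directions <- function(dmrs, category = NULL) {
  n <- nrow(dmrs)
  n_hypo <- sum(dmrs$delta > 0)
  res <- list(n = n, n_hypo = n_hypo, n_hyper = n - n_hypo,
              hypo_fraction = if (n > 0) n_hypo / n else NA_real_)
  if (!is.null(category)) {
    stopifnot(length(category) == n)
    tab <- table(category = category,
                 direction = ifelse(dmrs$delta > 0, "hypo", "hyper"))
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    res$by_category <- df
  }
  res
}

#' Select stringent loci and cluster samples and loci
#'
#' Reproduces the heatmap selection: loci at `p_value < p_cut` and |delta|
#' >= `delta_cut`, then unsupervised agglomerative clustering (average
#' linkage) of both samples and loci under squared Euclidean dissimilarity,
#' missing entries excluded pairwise.
#'
#' @param mm A [methylation_matrix()].
#' @param stats Output of [locus_differential_test()].
#' @param p_cut,delta_cut Selection thresholds (defaults 1.5e-4 / 0.5; note
#'   the delta filter is >= here).
#' @return List with `loci` (selected fragment ids), `sample_hclust`,
#'   `loci_hclust`, `sample_order`, `loci_order` and `sample_partition`
#'   (2-group cut of the sample tree).
#' @export
select_and_cluster_heatmap <- function(mm, stats, p_cut = 1.5e-4,
                                       delta_cut = 0.5) {
  sel <- stats$fragment_id[stats$p_value < p_cut & abs(stats$delta) >= delta_cut]
  if (length(sel) < 2) stopf("fewer than 2 loci survive the selection")
  sub <- mm$values[sel, , drop = FALSE]
  d_samples <- dist(t(sub))^2
  d_loci <- dist(sub)^2
  hs <- hclust(d_samples, method = "average")
  hl <- hclust(d_loci, method = "average")
  list(loci = sel,
       sample_hclust = hs,
       loci_hclust = hl,
       sample_order = hs$labels[hs$order],
       loci_order = hl$labels[hl$order],
       sample_partition = cutree(hs, k = 2))
}

#' Volcano-plot table
#'
#' One row per tested locus: x = delta (methylation difference), y =
#' -log2(p). Zero p-values are floored at 1e-300.
#'
#' @param stats Output of [locus_differential_test()].
#' @return data.frame with `fragment_id`, `delta`, `neg_log2_p`.
#' @export
volcano_table <- function(stats) {
  p <- stats$p_value
  if (any(p == 0)) {
    msg("%d zero p-values floored at 1e-300", sum(p == 0))
    p <- pmax(p, 1e-300)
  }
  data.frame(fragment_id = stats$fragment_id,
             delta = stats$delta,
             neg_log2_p = -log2(p),
             stringsAsFactors = FALSE)
}
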