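# End-to-end runs: simulate -> process -> call -> annotate -> integrate,
# with all intermediates on disk and a machine-readable report whose counts
# are re-derived from the written files.

#' Pipeline configuration
#'
#' Nested configuration of a full run. Serializes losslessly to YAML (see
#' [read_pipeline_config()]); the applied values are echoed into the run
#' report.
#'
#' @param sim A [sim_config()].
#' @param processing A [processing_params()].
#' @param p_threshold,delta_threshold DMR filter (defaults 0.01 / 0.5).
#' @param cluster_p,cluster_delta Heatmap selection (defaults 1.5e-4 / 0.5).
#' @param promoter_up,promoter_down,tts_window Annotation windows (bp).
#' @param n_permutations DHS permutation count (default 999).
#' @param expression_percentile,alpha Expression filter percentile and
#'   BH-adjusted significance cutoff.
#' @param seed Master seed; overrides `sim$seed` and seeds the permutation
#'   stream.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            processing = processing_params(),
                            p_threshold = 0.01,
                            delta_threshold = 0.5,
                            cluster_p = 1.5e-4,
                            cluster_delta = 0.5,
                            promoter_up = 1000,
                            promoter_down = 500,
                            tts_window = 500,
                            n_permutations = 999L,
                            expression_percentile = 20,
                            alpha = 0.05,
                            seed = NULL) {
  if (p_threshold <= 0 || delta_threshold <= 0 || cluster_p <= 0)
    stopf("thresholds must be positive")
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  structure(list(sim = sim, processing = processing,
                 p_threshold = p_threshold, delta_threshold = delta_threshold,
                 cluster_p = cluster_p, cluster_delta = cluster_delta,
                 promoter_up = promoter_up, promoter_down = promoter_down,
                 tts_window = tts_window,
                 n_permutations = as.integer(n_permutations),
                 expression_percentile = expression_percentile,
                 alpha = alpha),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; `sim` and
#' `processing` are nested maps passed to [sim_config()] /
#' [processing_params()].
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("sim", "processing"))]
  args$sim <- do.call(sim_config, y$sim %||% list())
  args$processing <- do.call(processing_params, y$processing %||% list())
  do.call(pipeline_config, args)
}

#' Run the pipeline end to end
#'
#' Simulates a HELP experiment (unless stage inputs are supplied), processes
#' probes to the methylation matrix, tests and calls DMRs, annotates them
#' against genes / chromatin states / DHS peaks, and integrates expression,
#' replication and MassArray tables. All intermediates are written under
#' `out_dir`; the returned report carries per-file checksums and counts
#' re-derived from the on-disk artifacts, and identical config + seed gives
#' an identical report.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return The run report (list of class `run_report`), also written as
#'   `report.json` and `report.txt` under `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("helpdmr_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "simulate"
  report <- list(parameters = serialize_config(config))
  tryCatch({
    sim <- simulate_help_dataset(config$sim, out_dir = file.path(out_dir, "sim"))

    stage <- "process"
    proc <- process_help_experiment(sim$probes, sim$fragment_map$fragments,
                                    config$processing)
    write_methylation_matrix(proc$matrix, file.path(out_dir, "methylation_matrix.tsv"))
    write_tsv(proc$statuses, file.path(out_dir, "statuses.tsv"))

    stage <- "call"
    stats <- locus_differential_test(proc$matrix)
    dmrs <- call_dmrs(stats, config$p_threshold, config$delta_threshold,
                      config$processing$fold_change_scale)
    frag <- proc$matrix$fragments
    stats_out <- cbind(frag[match(stats$fragment_id, frag$fragment_id),
                            c("chrom", "start", "end")], stats)
    write_tsv(stats_out, file.path(out_dir, "locus_stats.tsv"))
    dmr_bed <- frag[match(dmrs$fragment_id, frag$fragment_id),
                    c("chrom", "start", "end")]
    dmr_bed$name <- dmrs$fragment_id
    dmr_bed$score <- -log2(pmax(dmrs$p_value, 1e-300))
    write_bed(dmr_bed, file.path(out_dir, "dmrs.bed"))
    write_tsv(volcano_table(stats), file.path(out_dir, "volcano.tsv"))
    clust <- tryCatch(
      select_and_cluster_heatmap(proc$matrix, stats,
                                 config$cluster_p, config$cluster_delta),
      error = function(e) NULL)
    if (!is.null(clust))
      write_tsv(data.frame(sample_id = clust$sample_order,
                           partition = clust$sample_partition[clust$sample_order]),
                file.path(out_dir, "cluster_samples.tsv"))

    stage <- "annotate"
    ann <- NULL
    if (nrow(dmrs) > 0) {
      dmr_iv <- frag[match(dmrs$fragment_id, frag$fragment_id),
                     c("chrom", "start", "end", "fragment_id")]
      names(dmr_iv)[4] <- "name"
      arr_iv <- frag[, c("chrom", "start", "end", "fragment_id")]
      names(arr_iv)[4] <- "name"
      ann <- annotate_dmrs(dmr_iv, arr_iv, sim$tracks$genes, sim$tracks$states,
                           sim$tracks$dhs, sim$fragment_map$genome,
                           n_permutations = config$n_permutations,
                           seed = config$sim$seed,
                           promoter_up = config$promoter_up,
                           promoter_down = config$promoter_down,
                           tts_window = config$tts_window)
      write_tsv(ann$dmr_annotation, file.path(out_dir, "dmr_annotation.tsv"))
      write_tsv(ann$enrichment, file.path(out_dir, "refseq_enrichment.tsv"))
      write_tsv(ann$states$distribution,
                file.path(out_dir, "state_distribution.tsv"))
    }

    stage <- "integrate"
    de <- differential_expression(sim$expression$expr, sim$expression$groups,
                                  config$expression_percentile, config$alpha)
    write_tsv(de, file.path(out_dir, "differential_expression.tsv"))
    conc <- repl <- NULL
    if (!is.null(ann)) {
      dmr_genes <- data.frame(gene = ann$dmr_annotation$nearest_gene,
                              direction = dmrs$direction,
                              stringsAsFactors = FALSE)
      conc <- dmr_expression_concordance(dmr_genes, de)
      repl <- replication_concordance(dmr_genes, sim$replication)
      write_tsv(conc$table, file.path(out_dir, "concordance.tsv"))
    }
    mass <- absolute_relative_correlation(sim$massarray$abs_methylation_pct,
                                          sim$massarray$help_logratio)

    stage <- "report"
    dirs <- summarize_directions(dmrs)
    report$counts <- list(
      n_fragments = nrow(frag),
      n_tested = nrow(stats),
      n_dmrs = nrow(dmrs),
      n_hypo = dirs$n_hypo,
      hypo_fraction = dirs$hypo_fraction,
      mean_dmr_size = if (nrow(dmrs))
        mean(frag$size[match(dmrs$fragment_id, frag$fragment_id)]) else NA_real_,
      n_dmr_genes = if (!is.null(conc)) conc$n_dmr_genes else 0L,
      n_de_genes = sum(de$passes_filter),
      n_dmr_genes_de = if (!is.null(conc)) conc$n_overlap else 0L
    )
    report$thresholds <- list(p_threshold = config$p_threshold,
                              delta_threshold = config$delta_threshold)
    report$dhs <- list(
      observed = if (!is.null(ann)) ann$dhs_test$observed else NA,
      p_value = if (!is.null(ann)) ann$dhs_test$p_value else NA)
    report$concordance <- list(
      dmr_expression_fraction = if (!is.null(conc)) conc$fraction else NA,
      expression_sign_concordance =
        if (!is.null(conc)) conc$concordance_fraction else NA,
      replication_fraction = if (!is.null(repl)) repl$fraction else NA,
      massarray_correlation = mass$r
    )
    files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
    files <- files[!grepl("report\\.(json|txt)$", files)]
    report$checksums <- as.list(tools::md5sum(files))
    names(report$checksums) <- basename(files)
    # report counts must be re-derivable from disk: recount the headline ones
    dmr_disk <- read_bed(file.path(out_dir, "dmrs.bed"))
    stopifnot(nrow(dmr_disk) == report$counts$n_dmrs)
    report$results_dir <- out_dir
    class(report) <- "run_report"
    jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(format_report(report), file.path(out_dir, "report.txt"))
    report
  }, error = function(e) {
    stopf("pipeline failed at stage '%s': %s (partial outputs in %s)",
          stage, conditionMessage(e), out_dir)
  })
}

serialize_config <- function(config) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else unname(x)
  }
  strip(config)
}

format_report <- function(report) {
  c <- report$counts
  c(sprintf("helpdmr run report"),
    sprintf("fragments: %d, tested loci: %d", c$n_fragments, c$n_tested),
    sprintf("DMRs (p < %g, |delta| > %g): %d (%.1f%% hypomethylated in cases)",
            report$thresholds$p_threshold, report$thresholds$delta_threshold,
            c$n_dmrs, 100 * c$hypo_fraction),
    sprintf("mean DMR fragment size: %.0f bp", c$mean_dmr_size),
    sprintf("DMRs overlapping DHS peaks: %d (permutation p = %.4g)",
            report$dhs$observed, report$dhs$p_value),
    sprintf("DMR genes: %d; differentially expressed among them: %d (%.0f%%)",
            c$n_dmr_genes, c$n_dmr_genes_de,
            100 * report$concordance$dmr_expression_fraction),
    sprintf("replication concordance: %.1f%%",
            100 * report$concordance$replication_fraction),
    sprintf("MassArray vs HELP correlation: %.3f",
            report$concordance$massarray_correlation))
}

#' @export
print.run_report <- function(x, ...) {
  writeLines(format_report(x))
  invisible(x)
}
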