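# Synthetic HELP experiment generator. Produces probe-level two-channel
# intensity tables, fragment maps, annotation tracks and expression matrices
# with a known planted truth, so every downstream stage of the pipeline can
# be tested against ground truth without any external data.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic HELP experiment. The defaults describe
#' the study conditions the pipeline is calibrated against: 12 control vs 14
#' case arrays, 10,000 HpaII-amplifiable fragments (HAFs) of 200-2,000 bp
#' with mean size ~443 bp, 500 planted DMRs of magnitude `effect_mean` = 1.0
#' on the log2(HpaII/MspI) scale with 70% hypomethylated in cases,
#' per-sample log-ratio noise sd 0.5, and expression coupling at ~40% of
#' DMR genes with 98% sign concordance.
#'
#' @param seed Master seed; all output tables draw from independent
#'   sub-streams derived from it, so identical configs give byte-identical
#'   outputs and regenerating one table does not perturb the others.
#' @param n_fragments,n_random_probes Number of HAFs and of random
#'   (background) probes on the array.
#' @param n_control,n_case Sample counts per clinical group.
#' @param n_dmr Number of fragments with a planted case-control shift.
#' @param hypo_fraction Proportion of planted DMRs that are hypomethylated in
#'   cases (positive shift of the log2 HpaII/MspI ratio).
#' @param effect_mean,effect_sd Magnitude distribution of the planted shift
#'   Delta (|Delta| = |N(effect_mean, effect_sd)|, log2 units).
#' @param ratio_noise_sd Per-sample sd of the fragment log2 ratio
#'   (biological + array noise).
#' @param probes_per_fragment Probes tiling each fragment (per channel).
#' @param probe_noise_sd Multiplicative probe-level noise: each probe is the
#'   channel mean times `exp(N(0, probe_noise_sd))`.
#' @param mspi_meanlog,mspi_sdlog Log-normal parameters of the MspI
#'   (methylation-insensitive) channel intensity of amplifying fragments.
#' @param bg_meanlog,bg_sdlog Log-normal parameters of the background
#'   (random-probe / failed-fragment) intensity distribution.
#' @param failed_rate Fraction of fragments that fail to amplify (both
#'   channels drawn from background in every sample).
#' @param baseline,k Methylation-to-ratio link: a fragment with methylation
#'   fraction m has expected log2(HpaII/MspI) = `baseline - k * m`, the
#'   monotone-decreasing link the assay semantics require.
#' @param size_meanlog,size_sdlog,size_range Fragment-size distribution:
#'   log-normal truncated to `size_range` (defaults give mean ~443 bp within
#'   the 200-2,000 bp HAF bounds).
#' @param gap_range Uniform bounds of the gap between consecutive fragments.
#' @param n_chrom Chromosomes the fragments are spread over.
#' @param gene_coverage Fraction of fragments with an associated gene model.
#' @param coupling_prob Probability that a DMR fragment's gene carries a true
#'   expression change.
#' @param concordance_prob Probability that a coupled gene's expression
#'   change has the concordant sign (hypomethylated -> up-regulated).
#' @param expr_base_mean,expr_gene_sd,expr_noise_sd,expr_effect Expression
#'   model: per-gene baseline N(`expr_base_mean`, `expr_gene_sd`), per-sample
#'   noise sd `expr_noise_sd`, coupled genes shifted by `expr_effect` in
#'   cases (log2 units).
#' @param n_states,state_mean_len Chromatin-state segmentation: number of
#'   distinct labels and mean segment length (bp).
#' @param n_dhs,dhs_size_range,dhs_preference DNase-hypersensitive-site
#'   peaks: count, size bounds, and the fraction of peaks planted directly on
#'   DMR fragments (0 = no enrichment).
#' @param replication_concordance Probability that a DMR gene's synthetic
#'   replication-platform difference is sign-concordant with discovery.
#' @param repl_effect_mean,repl_effect_sd Magnitude (absolute methylation
#'   percentage points) of replication differences at DMR genes.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_fragments = 10000L,
                       n_random_probes = 2000L,
                       n_control = 12L,
                       n_case = 14L,
                       n_dmr = 500L,
                       hypo_fraction = 0.7,
                       effect_mean = 1.0,
                       effect_sd = 0,
                       ratio_noise_sd = 0.5,
                       probes_per_fragment = 3L,
                       probe_noise_sd = 0.2,
                       mspi_meanlog = log(2000),
                       mspi_sdlog = 0.3,
                       bg_meanlog = log(60),
                       bg_sdlog = 0.4,
                       failed_rate = 0.02,
                       baseline = 1,
                       k = 2,
                       size_meanlog = log(380),
                       size_sdlog = 0.45,
                       size_range = c(200L, 2000L),
                       gap_range = c(3000L, 8000L),
                       n_chrom = 2L,
                       gene_coverage = 1.0,
                       coupling_prob = 0.4,
                       concordance_prob = 0.98,
                       expr_base_mean = 8,
                       expr_gene_sd = 1.5,
                       expr_noise_sd = 0.5,
                       expr_effect = 1.0,
                       n_states = 10L,
                       state_mean_len = 2000,
                       n_dhs = 1000L,
                       dhs_size_range = c(150L, 500L),
                       dhs_preference = 0.3,
                       replication_concordance = 0.98,
                       repl_effect_mean = 5,
                       repl_effect_sd = 1.5) {
  cfg <- as.list(environment())
  counts <- c("n_fragments", "n_random_probes", "n_control", "n_case",
              "n_dmr", "probes_per_fragment", "n_states", "n_dhs", "n_chrom")
  for (nm in counts) {
    if (length(cfg[[nm]]) != 1 || is.na(cfg[[nm]]) || cfg[[nm]] < 0)
      stopf("%s must be a single non-negative number", nm)
    cfg[[nm]] <- as.integer(cfg[[nm]])
  }
  for (nm in c("hypo_fraction", "gene_coverage", "coupling_prob",
               "concordance_prob", "dhs_preference", "replication_concordance"))
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) stopf("%s must lie in [0, 1]", nm)
  if (cfg$n_dmr > cfg$n_fragments) stopf("n_dmr exceeds n_fragments")
  if (cfg$size_range[1] >= cfg$size_range[2]) stopf("invalid size_range")
  structure(cfg, class = "sim_config")
}

sample_ids <- function(config) {
  c(sprintf("CTL%02d", seq_len(config$n_control)),
    sprintf("CKD%02d", seq_len(config$n_case)))
}

#' Sample identifiers and group labels of a simulated experiment
#'
#' @param config A [sim_config()].
#' @return Named character vector: names are sample ids (`CTL01`...,
#'   `CKD01`...), values are `control`/`case`.
#' @export
sample_groups <- function(config) {
  ids <- sample_ids(config)
  setNames(rep(c("control", "case"), c(config$n_control, config$n_case)), ids)
}

# Deterministic sub-stream helpers shared between truth and annotation
# generation, so DHS placement can prefer planted DMR loci without the truth
# object being passed around.
select_dmr_indices <- function(config) {
  if (config$n_dmr == 0L) return(list(idx = integer(), hypo = integer()))
  with_seed(child_seed(config$seed, "dmr_select"), {
    idx <- sample.int(config$n_fragments, config$n_dmr)
    n_hypo <- round(config$n_dmr * config$hypo_fraction)
    list(idx = idx, hypo = idx[seq_len(n_hypo)])
  })
}

gene_assignment <- function(config) {
  n_genes <- floor(config$gene_coverage * config$n_fragments)
  if (n_genes == 0L) return(integer())
  with_seed(child_seed(config$seed, "genes"), {
    covered <- sort(sample.int(config$n_fragments, n_genes))
    setNames(covered, sprintf("GENE%05d", covered))
  })
}

#' Generate the fragment map of a synthetic HELP array
#'
#' Places `n_fragments` non-overlapping, sorted HpaII-amplifiable fragments
#' across `n_chrom` chromosomes, with sizes drawn from a truncated log-normal
#' within the 200-2,000 bp HAF bounds, and emits the identifiers of the
#' array's random (background) probes.
#'
#' @param config A [sim_config()].
#' @return A list of class `fragment_map` with elements `fragments`
#'   (data.frame: `fragment_id`, `chrom`, `start`, `end`, `size`; 0-based
#'   half-open), `genome` (data.frame: `chrom`, `length`) and
#'   `random_probes` (character vector of probe ids).
#' @export
generate_fragment_map <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_fragments
  sizes <- with_seed(child_seed(config$seed, "map"), {
    draw_trunc_sizes(n, config)
  })
  gaps <- with_seed(child_seed(config$seed, "map") + 1L, {
    if (n > 0) round(runif(n, config$gap_range[1], config$gap_range[2])) else numeric()
  })
  chrom_names <- sprintf("chr%d", seq_len(config$n_chrom))
  if (n > 0) {
    per_chrom <- rep(ceiling(n / config$n_chrom), config$n_chrom)
    chrom_idx <- rep(seq_len(config$n_chrom), per_chrom)[seq_len(n)]
    start <- integer(n)
    pos <- rep(0L, config$n_chrom)
    for (i in seq_len(n)) {
      ci <- chrom_idx[i]
      start[i] <- pos[ci] + gaps[i]
      pos[ci] <- start[i] + sizes[i]
    }
    fragments <- data.frame(
      fragment_id = sprintf("HAF%06d", seq_len(n)),
      chrom = chrom_names[chrom_idx],
      start = as.integer(start),
      end = as.integer(start + sizes),
      size = as.integer(sizes),
      stringsAsFactors = FALSE
    )
    lens <- vapply(seq_len(config$n_chrom), function(ci) {
      ends <- fragments$end[chrom_idx == ci]
      if (length(ends)) max(ends) + 10000L else 100000L
    }, integer(1))
  } else {
    fragments <- data.frame(fragment_id = character(), chrom = character(),
                            start = integer(), end = integer(),
                            size = integer(), stringsAsFactors = FALSE)
    lens <- rep(100000L, config$n_chrom)
  }
  structure(list(
    fragments = fragments,
    genome = data.frame(chrom = chrom_names, length = lens,
                        stringsAsFactors = FALSE),
    random_probes = if (config$n_random_probes > 0)
      sprintf("RNDP%05d", seq_len(config$n_random_probes)) else character()
  ), class = "fragment_map")
}

# Rejection sampling from the truncated log-normal size distribution;
# bounded retries so an infeasible size_range fails loudly.
draw_trunc_sizes <- function(n, config) {
  if (n == 0) return(numeric())
  out <- numeric(0)
  for (attempt in 1:200) {
    x <- round(rlnorm(max(2L * n, 100L), config$size_meanlog, config$size_sdlog))
    x <- x[x >= config$size_range[1] & x <= config$size_range[2]]
    out <- c(out, x)
    if (length(out) >= n) return(out[seq_len(n)])
  }
  stopf("could not draw fragment sizes within [%d, %d]: infeasible configuration",
        config$size_range[1], config$size_range[2])
}

#' Plant the methylation truth of a synthetic experiment
#'
#' Selects `n_dmr` fragments and assigns them a case-control shift Delta on
#' the log2(HpaII/MspI) scale: positive Delta = hypomethylated in cases
#' (`hypo_fraction` of planted DMRs, up to integer rounding), negative =
#' hypermethylated. All other fragments are null (Delta = 0). Also draws the
#' per-fragment control mean ratio through the methylation link
#' `baseline - k * m`, flags failing fragments, and couples a subset of DMR
#' genes to expression changes.
#'
#' @param fragment_map A [generate_fragment_map()] result.
#' @param config The same [sim_config()].
#' @return A list of class `sim_truth`: `fragments` (data.frame with
#'   `fragment_id`, `meth_fraction`, `control_mean`, `delta`, `direction`,
#'   `failed`, `gene`), `coupled` (data.frame `fragment_id`, `gene`,
#'   `expr_sign`), and `genes` (named integer vector mapping gene name to
#'   fragment index).
#' @export
simulate_methylation_truth <- function(fragment_map, config) {
  stopifnot(inherits(fragment_map, "fragment_map"))
  n <- nrow(fragment_map$fragments)
  if (config$n_dmr > n) stopf("n_dmr (%d) exceeds available fragments (%d)",
                              config$n_dmr, n)
  sel <- select_dmr_indices(config)
  genes <- gene_assignment(config)
  tr <- with_seed(child_seed(config$seed, "truth"), {
    m <- runif(n)
    control_mean <- config$baseline - config$k * m
    delta <- numeric(n)
    if (length(sel$idx)) {
      mag <- abs(rnorm(length(sel$idx), config$effect_mean, config$effect_sd))
      sgn <- ifelse(sel$idx %in% sel$hypo, 1, -1)
      delta[sel$idx] <- sgn * mag
    }
    failed <- runif(n) < config$failed_rate
    direction <- rep("null", n)
    direction[delta > 0] <- "hypo"
    direction[delta < 0] <- "hyper"
    gene_of <- rep(NA_character_, n)
    gene_of[genes] <- names(genes)
    # expression coupling: DMR fragments with a gene, kept w.p. coupling_prob
    dmr_with_gene <- sel$idx[!is.na(gene_of[sel$idx])]
    keep <- dmr_with_gene[runif(length(dmr_with_gene)) < config$coupling_prob]
    concord <- runif(length(keep)) < config$concordance_prob
    # hypomethylation in cases (delta > 0) -> up-regulation when concordant
    expr_sign <- ifelse(concord, sign(delta[keep]), -sign(delta[keep]))
    list(
      fragments = data.frame(
        fragment_id = fragment_map$fragments$fragment_id,
        meth_fraction = m,
        control_mean = control_mean,
        delta = delta,
        direction = direction,
        failed = failed,
        gene = gene_of,
        stringsAsFactors = FALSE
      ),
      coupled = data.frame(
        fragment_id = fragment_map$fragments$fragment_id[keep],
        gene = gene_of[keep],
        expr_sign = as.integer(expr_sign),
        stringsAsFactors = FALSE
      )
    )
  })
  structure(c(tr, list(genes = genes)), class = "sim_truth")
}

#' Simulate probe-level two-channel intensities
#'
#' Emits one intensity per probe per channel per array. Amplifying fragments
#' draw a per-(fragment, sample) MspI channel mean from a log-normal and an
#' HpaII mean of `MspI * 2^r`, where the sample's log-ratio `r` is the
#' fragment's control mean, plus the planted shift for case samples, plus
#' N(0, `ratio_noise_sd`) — more methylation means a lower HpaII signal.
#' Failed fragments and random probes draw from the background distribution
#' in both channels. Probe intensities are the channel mean times
#' log-normal multiplicative noise.
#'
#' @param truth A [simulate_methylation_truth()] result.
#' @param fragment_map The matching fragment map.
#' @param config The same [sim_config()].
#' @return A `data.table` probe table (columns `probe_id`, `fragment_id`,
#'   `sample_id`, `group`, `channel`, `intensity`), with the per-(fragment,
#'   sample) channel means attached as attribute `"channel_means"`.
#' @export
simulate_probe_intensities <- function(truth, fragment_map, config) {
  stopifnot(inherits(truth, "sim_truth"))
  if (!identical(truth$fragments$fragment_id, fragment_map$fragments$fragment_id))
    stopf("truth and fragment map disagree on fragment ids")
  ids <- sample_ids(config)
  groups <- sample_groups(config)
  n_frag <- nrow(fragment_map$fragments)
  n_samp <- length(ids)
  ppf <- config$probes_per_fragment

  with_seed(child_seed(config$seed, "probes"), {
    # per-(fragment, sample) channel means; fragment-major order
    is_case <- rep(groups == "case", each = n_frag)
    r <- rep(truth$fragments$control_mean, n_samp) +
      rep(truth$fragments$delta, n_samp) * is_case +
      rnorm(n_frag * n_samp, 0, config$ratio_noise_sd)
    mspi_mean <- rlnorm(n_frag * n_samp, config$mspi_meanlog, config$mspi_sdlog)
    hpaii_mean <- mspi_mean * 2^r
    failed <- rep(truth$fragments$failed, n_samp)
    if (any(failed)) {
      # failed fragments have no amplified product: the channel "mean" is at
      # background level and each probe is an independent background draw
      mspi_mean[failed] <- exp(config$bg_meanlog)
      hpaii_mean[failed] <- exp(config$bg_meanlog)
    }
    means <- data.table::data.table(
      fragment_id = rep(fragment_map$fragments$fragment_id, n_samp),
      sample_id = rep(ids, each = n_frag),
      hpaii_mean = hpaii_mean,
      mspi_mean = mspi_mean
    )
    frag_probes <- if (n_frag > 0 && ppf > 0) {
      long <- means[rep(seq_len(.N), each = ppf)]
      long[, probe_id := sprintf("%s_P%d", fragment_id,
                                 rep(seq_len(ppf), n_frag * n_samp))]
      noise <- function(n) exp(rnorm(n, 0, config$probe_noise_sd))
      hp <- long[, .(probe_id, fragment_id, sample_id, channel = "HpaII",
                     intensity = hpaii_mean * noise(.N))]
      ms <- long[, .(probe_id, fragment_id, sample_id, channel = "MspI",
                     intensity = mspi_mean * noise(.N))]
      failed_long <- rep(failed, each = ppf)
      if (any(failed_long)) {
        nf <- sum(failed_long)
        hp[failed_long, intensity := rlnorm(nf, config$bg_meanlog,
                                            config$bg_sdlog)]
        ms[failed_long, intensity := rlnorm(nf, config$bg_meanlog,
                                            config$bg_sdlog)]
      }
      rbind(hp, ms)
    } else NULL
    n_rand <- length(fragment_map$random_probes)
    rand_probes <- if (n_rand > 0) {
      data.table::CJ(probe_id = fragment_map$random_probes, sample_id = ids,
                     channel = c("HpaII", "MspI"), sorted = FALSE)[
        , `:=`(fragment_id = "RANDOM",
               intensity = rlnorm(.N, config$bg_meanlog, config$bg_sdlog))][
        , .(probe_id, fragment_id, sample_id, channel, intensity)]
    } else NULL
    out <- rbind(frag_probes, rand_probes)
    out[, group := unname(groups[sample_id])]
    data.table::setcolorder(out, c("probe_id", "fragment_id", "sample_id",
                                   "group", "channel", "intensity"))
    data.table::setattr(out, "channel_means", means)
    out[]
  })
}

#' Simulate a gene expression matrix coupled to the planted methylation truth
#'
#' Every gene in the generated gene models gets a log2-scale expression
#' profile; coupled genes (see [simulate_methylation_truth()]) are shifted by
#' `expr_effect` in case samples with the sign recorded in the truth
#' (hypomethylated fragment -> up-regulated gene when concordant).
#'
#' @param truth A `sim_truth`.
#' @param config The same [sim_config()].
#' @return List with `expr` (matrix genes x samples), `groups` (named vector),
#'   and `truth` (data.frame `gene`, `true_lfc`).
#' @export
simulate_expression <- function(truth, config) {
  stopifnot(inherits(truth, "sim_truth"))
  gene_names <- names(truth$genes)
  if (length(gene_names) == 0) stopf("truth contains no genes")
  ids <- sample_ids(config)
  groups <- sample_groups(config)
  with_seed(child_seed(config$seed, "expression"), {
    n_g <- length(gene_names)
    base <- rnorm(n_g, config$expr_base_mean, config$expr_gene_sd)
    mat <- matrix(rnorm(n_g * length(ids), 0, config$expr_noise_sd),
                  nrow = n_g) + base
    dimnames(mat) <- list(gene_names, ids)
    true_lfc <- setNames(numeric(n_g), gene_names)
    if (nrow(truth$coupled)) {
      shift <- truth$coupled$expr_sign * config$expr_effect
      true_lfc[truth$coupled$gene] <- shift
      case_cols <- which(groups == "case")
      mat[truth$coupled$gene, case_cols] <-
        mat[truth$coupled$gene, case_cols, drop = FALSE] + shift
    }
    list(expr = mat, groups = groups,
         truth = data.frame(gene = gene_names, true_lfc = unname(true_lfc),
                            stringsAsFactors = FALSE))
  })
}

#' Generate annotation tracks for the synthetic genome
#'
#' Builds refFlat-style gene models over a `gene_coverage` fraction of
#' fragments (each with a 3-exon structure and coding bounds so that UTR
#' categories are resolvable), a chromatin-state segmentation that tiles each
#' chromosome with `n_states` distinct labels and no gaps, and DHS peaks of
#' which a `dhs_preference` fraction is planted directly on DMR fragments.
#'
#' @param fragment_map A [generate_fragment_map()] result.
#' @param config The same [sim_config()].
#' @return List with `genes` (refFlat-style data.frame), `states` (BED-style
#'   data.frame, `name` = state label), `dhs` (BED-style data.frame) and
#'   `genome`.
#' @export
generate_annotation_tracks <- function(fragment_map, config) {
  stopifnot(inherits(fragment_map, "fragment_map"))
  fr <- fragment_map$fragments
  genome <- fragment_map$genome
  chrom_len <- setNames(genome$length, genome$chrom)
  genes_idx <- gene_assignment(config)

  genes <- with_seed(child_seed(config$seed, "tracks"), {
    if (length(genes_idx) == 0) {
      data.frame(gene = character(), chrom = character(), strand = character(),
                 txStart = integer(), txEnd = integer(),
                 cdsStart = integer(), cdsEnd = integer(),
                 exonStarts = character(), exonEnds = character(),
                 stringsAsFactors = FALSE)
    } else {
      f <- fr[genes_idx, ]
      # extents kept below half the minimum inter-fragment gap so each
      # fragment's own gene has the closest TSS
      ext5 <- round(runif(nrow(f), 200, 1000))
      ext3 <- round(runif(nrow(f), 200, 1000))
      strand <- sample(c("+", "-"), nrow(f), replace = TRUE)
      txStart <- pmax(0L, f$start - ext5)
      txEnd <- pmin(unname(chrom_len[f$chrom]), f$end + ext3)
      e1s <- txStart; e1e <- txStart + 200L
      e2s <- f$start; e2e <- f$end
      e3s <- txEnd - 200L; e3e <- txEnd
      data.frame(
        gene = names(genes_idx), chrom = f$chrom, strand = strand,
        txStart = as.integer(txStart), txEnd = as.integer(txEnd),
        cdsStart = as.integer(e2s), cdsEnd = as.integer(e2e),
        exonStarts = paste(e1s, e2s, e3s, sep = ","),
        exonEnds = paste(e1e, e2e, e3e, sep = ","),
        stringsAsFactors = FALSE
      )
    }
  })

  states <- with_seed(child_seed(config$seed, "states"), {
    labels <- sprintf("E%d", seq_len(config$n_states))
    do.call(rbind, lapply(genome$chrom, function(ch) {
      L <- chrom_len[[ch]]
      lens <- integer(0)
      while (sum(lens) < L)
        lens <- c(lens, pmax(200L, as.integer(round(
          stats::rexp(256, 1 / config$state_mean_len)))))
      ends <- cumsum(as.numeric(lens))
      n_seg <- which(ends >= L)[1]
      ends <- pmin(ends[seq_len(n_seg)], L)
      starts <- c(0, head(ends, -1))
      keep <- ends > starts
      data.frame(chrom = ch, start = as.integer(starts[keep]),
                 end = as.integer(ends[keep]),
                 name = sample(labels, sum(keep), replace = TRUE),
                 stringsAsFactors = FALSE)
    }))
  })

  sel <- select_dmr_indices(config)
  dhs <- with_seed(child_seed(config$seed, "dhs"), {
    n <- config$n_dhs
    if (n == 0) {
      data.frame(chrom = character(), start = integer(), end = integer(),
                 name = character(), stringsAsFactors = FALSE)
    } else {
      sizes <- round(runif(n, config$dhs_size_range[1], config$dhs_size_range[2]))
      n_pref <- if (length(sel$idx)) round(config$dhs_preference * n) else 0L
      chrom <- character(n); start <- integer(n)
      if (n_pref > 0) {
        on_dmr <- sample(sel$idx, n_pref, replace = n_pref > length(sel$idx))
        mid <- (fr$start[on_dmr] + fr$end[on_dmr]) %/% 2L
        chrom[seq_len(n_pref)] <- fr$chrom[on_dmr]
        start[seq_len(n_pref)] <- pmax(0L, as.integer(mid - sizes[seq_len(n_pref)] %/% 2L))
      }
      if (n_pref < n) {
        rest <- (n_pref + 1L):n
        ci <- sample(seq_len(nrow(genome)), length(rest), replace = TRUE,
                     prob = genome$length)
        chrom[rest] <- genome$chrom[ci]
        start[rest] <- as.integer(floor(runif(length(rest), 0,
                                              genome$length[ci] - sizes[rest])))
      }
      end <- pmin(as.integer(start + sizes), unname(chrom_len[chrom]))
      out <- data.frame(chrom = chrom, start = as.integer(start),
                        end = as.integer(end),
                        name = sprintf("DHS%05d", seq_len(n)),
                        stringsAsFactors = FALSE)
      out[order(out$chrom, out$start), ]
    }
  })
  list(genes = genes, states = states, dhs = dhs, genome = genome)
}

#' Simulate a replication-platform methylation-difference table
#'
#' Emulates an external validation cohort profiled on a bisulfite array:
#' per-gene signed differences in absolute methylation (case - control,
#' percentage points). DMR genes get a difference whose sign is concordant
#' with discovery with probability `replication_concordance` — a
#' hypomethylated (in cases) fragment corresponds to a negative absolute
#' methylation difference — and a small p-value; null genes get noise.
#'
#' @param truth A `sim_truth`.
#' @param config The same [sim_config()].
#' @return data.frame with columns `gene`, `probe`, `difference`, `p`.
#' @export
simulate_replication_table <- function(truth, config) {
  stopifnot(inherits(truth, "sim_truth"))
  gene_names <- names(truth$genes)
  frag <- truth$fragments
  dmr_gene <- frag$gene[frag$delta != 0 & !is.na(frag$gene)]
  delta_of <- setNames(frag$delta, frag$gene)[dmr_gene]
  with_seed(child_seed(config$seed, "replication"), {
    diff <- rnorm(length(gene_names), 0, 1)
    p <- runif(length(gene_names))
    names(diff) <- names(p) <- gene_names
    if (length(dmr_gene)) {
      concord <- runif(length(dmr_gene)) < config$replication_concordance
      # discovery hypo (delta > 0, ratio scale) = methylation loss = negative
      # absolute-methylation difference in replication
      sgn <- ifelse(concord, -sign(delta_of), sign(delta_of))
      diff[dmr_gene] <- sgn * abs(rnorm(length(dmr_gene),
                                        config$repl_effect_mean,
                                        config$repl_effect_sd))
      p[dmr_gene] <- runif(length(dmr_gene), 0, 0.01)
    }
    data.frame(gene = gene_names,
               probe = sprintf("%s_cg1", gene_names),
               difference = unname(diff), p = unname(p),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a MassArray-style absolute methylation table
#'
#' Picks loci spanning the methylation range and reports their absolute
#' methylation (percent, with measurement noise) next to the fragment's true
#' control-mean log2(HpaII/MspI) ratio, emulating site-specific bisulfite
#' validation of relative array ratios.
#'
#' @param truth A `sim_truth`.
#' @param config The same [sim_config()].
#' @param n_loci Number of assayed loci.
#' @return data.frame with columns `fragment_id`, `abs_methylation_pct`,
#'   `help_logratio`.
#' @export
simulate_massarray_table <- function(truth, config, n_loci = 24L) {
  stopifnot(inherits(truth, "sim_truth"))
  frag <- truth$fragments
  with_seed(child_seed(config$seed, "massarray"), {
    idx <- order(frag$meth_fraction)[round(seq(1, nrow(frag), length.out = n_loci))]
    pct <- pmin(100, pmax(0, frag$meth_fraction[idx] * 100 + rnorm(n_loci, 0, 5)))
    data.frame(fragment_id = frag$fragment_id[idx],
               abs_methylation_pct = pct,
               help_logratio = frag$control_mean[idx],
               stringsAsFactors = FALSE)
  })
}

#' Write a complete synthetic HELP experiment to disk
#'
#' Runs every generator stage under one master seed and writes the standard
#' plain-text interchange files (probe TSV, fragment/state/DHS BED, refFlat
#' gene models, expression TSV, group table, truth tables).
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if absent). `NULL` skips writing.
#' @return Invisibly, a list with all generated objects and (when written)
#'   `files`, the named vector of output paths.
#' @export
simulate_help_dataset <- function(config, out_dir = NULL) {
  fmap <- generate_fragment_map(config)
  truth <- simulate_methylation_truth(fmap, config)
  probes <- simulate_probe_intensities(truth, fmap, config)
  tracks <- generate_annotation_tracks(fmap, config)
  expr <- simulate_expression(truth, config)
  repl <- simulate_replication_table(truth, config)
  massarray <- simulate_massarray_table(truth, config)
  out <- list(config = config, fragment_map = fmap, truth = truth,
              probes = probes, tracks = tracks, expression = expr,
              replication = repl, massarray = massarray)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(out_dir, f)
    files <- c(
      probes = write_probe_table(probes, p("probes.tsv")),
      fragments = write_bed(cbind(fmap$fragments[c("chrom", "start", "end")],
                                  name = fmap$fragments$fragment_id),
                            p("fragments.bed")),
      genome = write_tsv(fmap$genome, p("genome.tsv")),
      genes = write_refflat(tracks$genes, p("genes.refflat.tsv")),
      states = write_bed(tracks$states, p("states.bed")),
      dhs = write_bed(tracks$dhs, p("dhs.bed")),
      expression = {
        edt <- data.table::data.table(gene = rownames(expr$expr))
        write_tsv(cbind(edt, data.table::as.data.table(expr$expr)),
                  p("expression.tsv"))
      },
      groups = write_tsv(data.frame(sample_id = names(expr$groups),
                                    group = unname(expr$groups)),
                         p("groups.tsv")),
      truth_fragments = write_tsv(truth$fragments, p("truth_fragments.tsv")),
      truth_coupled = write_tsv(truth$coupled, p("truth_coupled.tsv")),
      replication = write_tsv(repl, p("replication.tsv")),
      massarray = write_tsv(massarray, p("massarray.tsv"))
    )
    out$files <- files
  }
  invisible(out)
}
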