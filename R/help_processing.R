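# From probe-level two-channel intensities to a normalized, centered
# log2(HpaII/MspI) methylation matrix with per-fragment status calls.

#' Processing parameters
#'
#' @param trim_fraction Fraction trimmed from each tail when summarizing
#'   probes to a fragment signal (default 0.25, i.e. a 25% trimmed mean).
#' @param mad_multiplier Background threshold = median + `mad_multiplier` *
#'   robust scale of the random-probe signals (default 2.5).
#' @param mad_type Robust scale convention: `"median"` = median absolute
#'   deviation about the median (no consistency factor, the default) or
#'   `"mean"` = mean absolute deviation about the median.
#' @param window_size,window_step Sliding-window quantile normalization over
#'   size-sorted fragments: fragments per window and step between window
#'   starts (default 1000 with step = half a window, i.e. half-overlapping
#'   windows; the step is capped at the window size so windows always tile).
#' @param fold_change_scale How the downstream fold-change filter interprets
#'   its cutoff: `"log"` (difference of group means of log2 ratios, default)
#'   or `"ratio"` (|2^delta - 1|).
#' @param max_failed_fraction Loci failed in more than this fraction of the
#'   samples of either group are dropped before testing (default 0.5).
#' @param epsilon Intensity floor applied before taking logs.
#' @return Object of class `processing_params`.
#' @export
processing_params <- function(trim_fraction = 0.25,
                              mad_multiplier = 2.5,
                              mad_type = c("median", "mean"),
                              window_size = 1000L,
                              window_step = NULL,
                              fold_change_scale = c("log", "ratio"),
                              max_failed_fraction = 0.5,
                              epsilon = 1e-6) {
  if (trim_fraction < 0 || trim_fraction >= 0.5)
    stopf("trim_fraction must lie in [0, 0.5)")
  if (mad_multiplier <= 0) stopf("mad_multiplier must be positive")
  if (window_size < 2) stopf("window_size must be >= 2")
  window_step <- window_step %||% max(1L, window_size %/% 2L)
  structure(list(
    trim_fraction = trim_fraction,
    mad_multiplier = mad_multiplier,
    mad_type = match.arg(mad_type),
    window_size = as.integer(window_size),
    window_step = as.integer(window_step),
    fold_change_scale = match.arg(fold_change_scale),
    max_failed_fraction = max_failed_fraction,
    epsilon = epsilon
  ), class = "processing_params")
}

#' Trimmed-mean summarization of probe signals
#'
#' Robust fragment-level signal: sort the probe intensities, drop
#' `floor(trim_fraction * n)` values from each end, and average the rest
#' (the median when trimming would empty the set).
#'
#' @param x Numeric probe intensities (at least one).
#' @param trim_fraction Fraction trimmed from each tail, in `[0, 0.5)`.
#' @return The trimmed mean.
#' @export
trimmed_mean <- function(x, trim_fraction = 0.25) {
  if (length(x) == 0) stopf("cannot summarize an empty probe set")
  if (trim_fraction < 0 || trim_fraction >= 0.5)
    stopf("trim_fraction must lie in [0, 0.5)")
  n <- length(x)
  k <- floor(trim_fraction * n)
  if (n - 2 * k <= 0) return(median(x))
  s <- sort(x)
  mean(s[(k + 1):(n - k)])
}

#' Summarize probe intensities to per-fragment channel signals
#'
#' @param probes Probe table (see [read_probe_table()]); rows with
#'   `fragment_id == "RANDOM"` are excluded here and used by
#'   [background_threshold()].
#' @param trim_fraction Passed to [trimmed_mean()].
#' @return data.table with one row per (fragment, sample): `fragment_id`,
#'   `sample_id`, `group`, `hpaii`, `mspi`.
#' @export
summarize_fragment_signal <- function(probes, trim_fraction = 0.25) {
  dt <- data.table::as.data.table(probes)[fragment_id != "RANDOM"]
  if (nrow(dt) == 0) stopf("no fragment probes to summarize")
  long <- dt[, .(value = trimmed_mean(intensity, trim_fraction)),
             by = .(fragment_id, sample_id, group, channel)]
  wide <- data.table::dcast(long, fragment_id + sample_id + group ~ channel,
                            value.var = "value")
  data.table::setnames(wide, c("HpaII", "MspI"), c("hpaii", "mspi"))
  wide[]
}

#' Background intensity threshold from random probes
#'
#' The level below which a channel is indistinguishable from background:
#' median of the random-probe signals plus `mad_multiplier` robust scale
#' units. The scale is the median absolute deviation about the median by
#' default (`mad_type = "median"`, no consistency factor), or the mean
#' absolute deviation about the median (`mad_type = "mean"`).
#'
#' @param background Numeric vector of random-probe intensities (>= 2).
#' @param mad_multiplier Multiplier on the robust scale (default 2.5).
#' @param mad_type `"median"` or `"mean"`.
#' @return The threshold (same units as the input).
#' @export
background_threshold <- function(background, mad_multiplier = 2.5,
                                 mad_type = c("median", "mean")) {
  mad_type <- match.arg(mad_type)
  if (length(background) < 2) stopf("need at least 2 background signals")
  med <- median(background)
  scale <- switch(mad_type,
                  median = stats::mad(background, constant = 1),
                  mean = mean(abs(background - med)))
  med + mad_multiplier * scale
}

#' Classify each (fragment, sample) as failed, methylated or amplifying
#'
#' A fragment whose MspI signal is within background failed to amplify by
#' PCR ("failed"); one whose MspI is above background but whose HpaII signal
#' is within background is fully methylated ("methylated"); the rest amplify
#' in both channels ("amplifying") and carry quantitative ratio information.
#'
#' @param signals Output of [summarize_fragment_signal()].
#' @param threshold Background threshold, typically per sample: either a
#'   single number or a named vector indexed by `sample_id`.
#' @return The input with a `status` column added.
#' @export
classify_fragment_status <- function(signals, threshold) {
  dt <- data.table::as.data.table(signals)
  thr <- if (length(threshold) == 1L) rep(unname(threshold), nrow(dt))
         else unname(threshold[dt$sample_id])
  if (anyNA(thr)) stopf("threshold missing for some samples")
  if (any(thr <= 0)) stopf("threshold must be positive")
  dt[, status := ifelse(mspi <= thr, "failed",
                 ifelse(hpaii <= thr, "methylated", "amplifying"))]
  dt[]
}

#' Sliding-window quantile normalization over size-sorted fragments
#'
#' Intra-array normalization of log2(HpaII/MspI) ratios: fragments are
#' sorted by size, grouped into fixed-count windows (density-adaptive by
#' construction) stepping by `window_step`, and within each window every
#' sample's values are replaced by the across-sample mean of the order
#' statistics at their quantile. Fragments covered by several overlapping
#' windows get the average of their windowed values. Missing entries (failed
#' or methylated calls) are ignored per sample. Within-sample rank order is
#' preserved inside each window.
#'
#' @param ratios Matrix fragments x samples of log-ratios (may contain NA).
#' @param sizes Fragment sizes (bp), one per row of `ratios`.
#' @param window_size,window_step Fragments per window and step; a window
#'   larger than the fragment count degrades to one window (with a message).
#' @return Matrix of the same shape with normalized values.
#' @export
window_quantile_normalize <- function(ratios, sizes,
                                      window_size = 1000L,
                                      window_step = 500L) {
  ratios <- as.matrix(ratios)
  n <- nrow(ratios)
  if (length(sizes) != n) stopf("sizes must match rows of ratios")
  if (ncol(ratios) < 1) stopf("need at least one sample")
  if (ncol(ratios) == 1L) return(ratios)
  if (window_size > n) {
    msg("window_size %d exceeds fragment count %d; using a single window",
        window_size, n)
    window_size <- n
  }
  window_step <- min(window_step, window_size) # no coverage gaps
  ord <- order(sizes)
  starts <- unique(c(seq(1L, max(1L, n - window_size + 1L), by = window_step),
                     n - window_size + 1L))
  acc <- matrix(0, n, ncol(ratios))
  cov <- numeric(n)
  for (s in starts) {
    rows <- ord[s:(s + window_size - 1L)]
    acc[rows, ] <- acc[rows, , drop = FALSE] +
      quantile_normalize_window(ratios[rows, , drop = FALSE])
    cov[rows] <- cov[rows] + 1
  }
  out <- acc / cov
  out[is.na(ratios)] <- NA_real_
  dimnames(out) <- dimnames(ratios)
  out
}

# Quantile normalization of one window across samples, NA-tolerant: each
# sample's non-missing values are mapped through the mean empirical quantile
# function of all samples, evaluated at the value's own quantile. With equal
# non-missing counts this is exactly the textbook mean-of-order-statistics
# normalization.
quantile_normalize_window <- function(w) {
  n_obs <- colSums(!is.na(w))
  usable <- which(n_obs >= 1L)
  if (length(usable) < 2L) return(w)
  L <- max(n_obs[usable])
  p_grid <- (seq_len(L) - 0.5) / L
  qf <- vapply(usable, function(j) {
    v <- sort(w[!is.na(w[, j]), j])
    if (length(v) == 1L) rep(v, L)
    else approx((seq_along(v) - 0.5) / length(v), v, xout = p_grid,
                rule = 2)$y
  }, numeric(L))
  ref <- rowMeans(qf)
  out <- w
  for (j in usable) {
    obs <- which(!is.na(w[, j]))
    r <- rank(w[obs, j], ties.method = "average")
    q <- (r - 0.5) / length(obs)
    out[obs, j] <- approx(p_grid, ref, xout = q, rule = 2)$y
  }
  out
}

#' Methylation matrix container
#'
#' @param values Matrix fragments x samples of centered log2(HpaII/MspI).
#' @param fragments data.frame with `fragment_id`, `chrom`, `start`, `end`,
#'   `size` matching the rows.
#' @param groups Named character vector (`control`/`case`) per sample, or
#'   NULL.
#' @param labels Optional matrix of per-entry `methylated`/`hypomethylated`
#'   labels.
#' @return Object of class `MethylationMatrix`.
#' @export
methylation_matrix <- function(values, fragments, groups = NULL, labels = NULL) {
  if (nrow(values) != nrow(fragments))
    stopf("values and fragments disagree on fragment count")
  structure(list(values = values, fragments = fragments,
                 groups = groups, labels = labels),
            class = "MethylationMatrix")
}

#' @export
print.MethylationMatrix <- function(x, ...) {
  cat(sprintf("MethylationMatrix: %d fragments x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$groups))
    cat(sprintf("  groups: %s\n",
                paste(sprintf("%s=%d", names(table(x$groups)),
                              table(x$groups)), collapse = ", ")))
  cat(sprintf("  missing entries: %.1f%%\n", 100 * mean(is.na(x$values))))
  invisible(x)
}

#' Assemble the centered methylation matrix
#'
#' Combines summarized signals, status calls and normalized log-ratios into
#' the analysis substrate: entries are the per-array-centered
#' log2(HpaII/MspI) of amplifying (fragment, sample) pairs, missing
#' elsewhere. Centering subtracts each array's mean over amplifying loci, so
#' every column mean is zero; by the sign of the centered ratio each entry
#' is labelled `methylated` (< 0) or `hypomethylated` (> 0).
#'
#' @param statuses Output of [classify_fragment_status()].
#' @param normalized Matrix fragments x samples of normalized log-ratios
#'   (from [window_quantile_normalize()]), rows named by fragment id.
#' @param fragments Fragment annotation data.frame (`fragment_id`, `chrom`,
#'   `start`, `end`, `size`).
#' @param groups Named group vector per sample.
#' @return A [methylation_matrix()].
#' @export
build_methylation_matrix <- function(statuses, normalized, fragments,
                                     groups = NULL) {
  st <- data.table::as.data.table(statuses)
  if (!all(rownames(normalized) %in% st$fragment_id))
    stopf("normalized matrix and statuses disagree on fragment ids")
  keep <- data.table::dcast(st, fragment_id ~ sample_id,
                            value.var = "status")
  keep <- as.matrix(keep, rownames = "fragment_id")
  keep <- keep[rownames(normalized), colnames(normalized), drop = FALSE]
  vals <- normalized
  vals[keep != "amplifying"] <- NA_real_
  centers <- colMeans(vals, na.rm = TRUE)
  centers[is.na(centers)] <- 0
  vals <- sweep(vals, 2, centers)
  labels <- matrix(NA_character_, nrow(vals), ncol(vals),
                   dimnames = dimnames(vals))
  labels[!is.na(vals) & vals < 0] <- "methylated"
  labels[!is.na(vals) & vals > 0] <- "hypomethylated"
  fragments <- fragments[match(rownames(vals), fragments$fragment_id), ]
  methylation_matrix(vals, fragments, groups = groups, labels = labels)
}

#' Run the full HELP processing stage
#'
#' Probe table in, methylation matrix out: trimmed-mean summarization,
#' per-array background thresholds from the random probes, status
#' classification, log2(HpaII/MspI) of amplifying pairs, sliding-window
#' quantile normalization over size-sorted fragments, and per-array
#' centering.
#'
#' @param probes Probe table (see [read_probe_table()]).
#' @param fragments Fragment annotation (`fragment_id`, `chrom`, `start`,
#'   `end`, `size`).
#' @param params A [processing_params()].
#' @return List with `matrix` (a [methylation_matrix()]), `signals`,
#'   `statuses`, `thresholds` (per sample) and `status_counts`.
#' @export
process_help_experiment <- function(probes, fragments,
                                    params = processing_params()) {
  probes <- data.table::as.data.table(probes)
  signals <- summarize_fragment_signal(probes, params$trim_fraction)
  rand <- probes[fragment_id == "RANDOM"]
  if (nrow(rand) == 0) stopf("probe table contains no random probes")
  thresholds <- vapply(split(rand$intensity, rand$sample_id),
                       background_threshold,
                       numeric(1),
                       mad_multiplier = params$mad_multiplier,
                       mad_type = params$mad_type)
  statuses <- classify_fragment_status(signals, thresholds)
  groups <- {
    g <- unique(statuses[, .(sample_id, group)])
    setNames(g$group, g$sample_id)
  }
  st <- data.table::copy(statuses)
  st[, value := ifelse(status == "amplifying",
                       log2(pmax(hpaii, params$epsilon) /
                            pmax(mspi, params$epsilon)),
                       NA_real_)]
  wide <- data.table::dcast(st, fragment_id ~ sample_id, value.var = "value")
  ratio_mat <- as.matrix(wide, rownames = "fragment_id")
  fragments <- fragments[match(rownames(ratio_mat), fragments$fragment_id), ]
  if (anyNA(fragments$size)) stopf("every fragment needs a size")
  normalized <- window_quantile_normalize(ratio_mat, fragments$size,
                                          params$window_size,
                                          params$window_step)
  mm <- build_methylation_matrix(statuses, normalized, fragments,
                                 groups = groups)
  list(matrix = mm,
       signals = signals,
       statuses = statuses,
       thresholds = thresholds,
       status_counts = table(statuses$status))
}
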