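# Shared fixtures, built once per test run and cached.

# Small experiment: quick enough for per-module tests.
small_config <- function(seed = 42, ...) {
  sim_config(seed = seed, n_fragments = 1200, n_dmr = 80,
             n_random_probes = 400, ...)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

small_sim <- function() cached("small_sim", simulate_help_dataset(small_config()))

small_processed <- function() cached("small_processed", {
  sim <- small_sim()
  suppressMessages(process_help_experiment(
    sim$probes, sim$fragment_map$fragments, processing_params()))
})

# Study-scale run at the default conditions (12 vs 14 arrays, 10,000
# fragments, 500 planted DMRs of |Delta| = 1, noise sd 0.5, 70% hypo).
study_run <- function() cached("study_run", {
  sim <- simulate_help_dataset(sim_config(seed = 2024))
  proc <- suppressMessages(process_help_experiment(
    sim$probes, sim$fragment_map$fragments, processing_params()))
  stats <- suppressMessages(locus_differential_test(proc$matrix))
  dmrs <- call_dmrs(stats)
  list(sim = sim, proc = proc, stats = stats, dmrs = dmrs)
})

# Brute-force oracles, deliberately naive and independent of the package's
# code paths.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in rev(seq_len(m))) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- min(1, running)
  }
  adj
}

oracle_overlap_pairs <- function(a, b) {
  # all-pairs scan on 0-based half-open intervals; returns "i:j" keys of
  # pairs sharing >= 1 bp
  out <- character(0)
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] == b$chrom[j] &&
        min(a$end[i], b$end[j]) - max(a$start[i], b$start[j]) >= 1)
      out <- c(out, paste0(i, ":", j))
  }
  out
}

overlap_pair_keys <- function(res, states) {
  if (nrow(res$assignments) == 0) return(character(0))
  paste0(res$assignments$dmr, ":", match(res$assignments$state, states$name))
}

oracle_quantile_normalize <- function(m) {
  # textbook mean-of-order-statistics quantile normalization, no NA support
  ranks <- apply(m, 2, rank, ties.method = "average")
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) out[, j] <- approx(seq_len(nrow(m)), ref,
                                                 xout = ranks[, j])$y
  out
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 5000,
                             max_len = 300) {
  start <- sample.int(max_pos, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample.int(max_len, n, replace = TRUE),
             stringsAsFactors = FALSE)
}
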