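test_that("fragment maps respect HAF size bounds and are sorted and disjoint", {
  cfg <- sim_config(seed = 5, n_fragments = 300, n_dmr = 30,
                    n_random_probes = 50)
  fmap <- generate_fragment_map(cfg)
  fr <- fmap$fragments
  expect_equal(nrow(fr), 300)
  expect_true(all(fr$size >= 200 & fr$size <= 2000))
  expect_true(all(fr$end > fr$start))
  expect_equal(fr$size, fr$end - fr$start)
  # brute-force O(n^2) pairwise disjointness scan per chromosome
  for (ch in unique(fr$chrom)) {
    f <- fr[fr$chrom == ch, ]
    expect_false(is.unsorted(f$start))
    disjoint <- outer(f$end, f$start, `<=`) | outer(f$start, f$end, `>=`)
    diag(disjoint) <- TRUE
    expect_true(all(disjoint))
  }
  expect_true(all(fr$end <= fmap$genome$length[match(fr$chrom, fmap$genome$chrom)]))
})

test_that("an empty fragment map still emits random probes", {
  fmap <- generate_fragment_map(sim_config(n_fragments = 0, n_dmr = 0,
                                           n_random_probes = 25))
  expect_equal(nrow(fmap$fragments), 0)
  expect_length(fmap$random_probes, 25)
})

test_that("planted truth honors DMR count, direction mix and effect magnitude", {
  cfg <- sim_config(seed = 9, n_fragments = 1000, n_dmr = 200,
                    hypo_fraction = 0.7, effect_mean = 1.2, effect_sd = 0.2,
                    n_random_probes = 10)
  truth <- simulate_methylation_truth(generate_fragment_map(cfg), cfg)
  planted <- truth$fragments[truth$fragments$delta != 0, ]
  expect_equal(nrow(planted), 200)
  expect_equal(sum(planted$delta > 0), round(200 * 0.7))
  expect_identical(planted$direction, ifelse(planted$delta > 0, "hypo", "hyper"))
  # truth-table average of |Delta| vs the configured effect-distribution mean
  expect_lt(abs(mean(abs(planted$delta)) - 1.2), 3 * 0.2 / sqrt(200))

  null_cfg <- sim_config(seed = 9, n_fragments = 100, n_dmr = 0,
                         n_random_probes = 10)
  null_truth <- simulate_methylation_truth(generate_fragment_map(null_cfg), null_cfg)
  expect_true(all(null_truth$fragments$delta == 0))
  expect_error(sim_config(n_fragments = 10, n_dmr = 11), "n_dmr")
})

test_that("noiseless probe intensities reproduce the configured channel means", {
  cfg <- sim_config(seed = 3, n_fragments = 60, n_dmr = 5, n_control = 3,
                    n_case = 3, probe_noise_sd = 0, failed_rate = 0,
                    n_random_probes = 30)
  fmap <- generate_fragment_map(cfg)
  truth <- simulate_methylation_truth(fmap, cfg)
  probes <- simulate_probe_intensities(truth, fmap, cfg)
  means <- attr(probes, "channel_means")
  sig <- summarize_fragment_signal(probes, trim_fraction = 0.25)
  merged <- merge(sig, means, by = c("fragment_id", "sample_id"))
  expect_equal(merged$hpaii, merged$hpaii_mean, tolerance = 1e-12)
  expect_equal(merged$mspi, merged$mspi_mean, tolerance = 1e-12)
})

test_that("fragments flagged failed are classified failed downstream", {
  cfg <- sim_config(seed = 21, n_fragments = 800, n_dmr = 0,
                    failed_rate = 0.2, n_random_probes = 400)
  fmap <- generate_fragment_map(cfg)
  truth <- simulate_methylation_truth(fmap, cfg)
  probes <- simulate_probe_intensities(truth, fmap, cfg)
  sig <- summarize_fragment_signal(probes)
  rand <- probes[probes$fragment_id == "RANDOM", ]
  thr <- vapply(split(rand$intensity, rand$sample_id), background_threshold,
                numeric(1))
  st <- classify_fragment_status(sig, thr)
  failed_ids <- truth$fragments$fragment_id[truth$fragments$failed]
  calls <- st[st$fragment_id %in% failed_ids, ]
  expect_gt(mean(calls$status == "failed"), 0.95)
  # non-failed fragments amplify essentially always at default intensities
  ok <- st[!st$fragment_id %in% failed_ids, ]
  expect_gt(mean(ok$status == "amplifying"), 0.99)
})

test_that("expression coupling spans its deterministic and null limits", {
  cfg1 <- sim_config(seed = 8, n_fragments = 400, n_dmr = 60,
                     coupling_prob = 1, concordance_prob = 1,
                     n_random_probes = 10)
  fmap <- generate_fragment_map(cfg1)
  truth <- simulate_methylation_truth(fmap, cfg1)
  expect_equal(nrow(truth$coupled), 60)
  # hypomethylated fragment (delta > 0) -> up-regulated coupled gene
  delta_of <- setNames(truth$fragments$delta, truth$fragments$fragment_id)
  expect_true(all(truth$coupled$expr_sign ==
                    sign(delta_of[truth$coupled$fragment_id])))
  expr <- simulate_expression(truth, cfg1)
  expect_true(all(expr$truth$true_lfc[match(truth$coupled$gene,
                                            expr$truth$gene)] != 0))

  cfg0 <- sim_config(seed = 8, n_fragments = 400, n_dmr = 60,
                     coupling_prob = 0, n_random_probes = 10)
  truth0 <- simulate_methylation_truth(generate_fragment_map(cfg0), cfg0)
  expr0 <- simulate_expression(truth0, cfg0)
  expect_equal(nrow(truth0$coupled), 0)
  expect_true(all(expr0$truth$true_lfc == 0))
})

test_that("realized coupling sign-concordance tracks the configured probability", {
  q <- 0.9
  cfg <- sim_config(seed = 12, n_fragments = 2000, n_dmr = 400,
                    coupling_prob = 1, concordance_prob = q,
                    n_random_probes = 10)
  truth <- simulate_methylation_truth(generate_fragment_map(cfg), cfg)
  delta_of <- setNames(truth$fragments$delta, truth$fragments$fragment_id)
  concord <- truth$coupled$expr_sign == sign(delta_of[truth$coupled$fragment_id])
  n <- length(concord)
  expect_lt(abs(mean(concord) - q), 3 * sqrt(q * (1 - q) / n))
})

test_that("annotation tracks partition chromosomes and cover the configured genes", {
  cfg <- sim_config(seed = 31, n_fragments = 500, n_dmr = 40,
                    gene_coverage = 0.6, n_random_probes = 10)
  fmap <- generate_fragment_map(cfg)
  tracks <- generate_annotation_tracks(fmap, cfg)
  # state segments tile each chromosome with no gaps or overlaps
  for (ch in fmap$genome$chrom) {
    s <- tracks$states[tracks$states$chrom == ch, ]
    s <- s[order(s$start), ]
    expect_equal(s$start[1], 0)
    expect_equal(s$end[nrow(s)],
                 fmap$genome$length[fmap$genome$chrom == ch])
    expect_equal(s$start[-1], s$end[-nrow(s)])
  }
  expect_equal(length(unique(tracks$states$name)), 10)
  expect_equal(nrow(tracks$genes), floor(0.6 * 500))
  # exon structure: sorted, non-overlapping, within tx bounds
  ex_s <- lapply(strsplit(tracks$genes$exonStarts, ","), as.integer)
  ex_e <- lapply(strsplit(tracks$genes$exonEnds, ","), as.integer)
  for (i in seq_len(nrow(tracks$genes))) {
    expect_true(all(ex_s[[i]] >= tracks$genes$txStart[i]))
    expect_true(all(ex_e[[i]] <= tracks$genes$txEnd[i]))
    expect_true(all(diff(as.vector(rbind(ex_s[[i]], ex_e[[i]]))) >= 0))
  }
  expect_true(all(tracks$dhs$end > tracks$dhs$start))
})

test_that("identical configs give byte-identical outputs; truth round-trips", {
  cfg <- sim_config(seed = 77, n_fragments = 150, n_dmr = 10,
                    n_random_probes = 40, n_control = 3, n_case = 3)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- simulate_help_dataset(cfg, d1)
  s2 <- simulate_help_dataset(cfg, d2)
  for (f in basename(s1$files)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  # lossless round-trip of the truth table through TSV
  rt <- as.data.frame(data.table::fread(file.path(d1, "truth_fragments.tsv"),
                                        na.strings = ""))
  expect_equal(rt$delta, s1$truth$fragments$delta)
  expect_equal(rt$control_mean, s1$truth$fragments$control_mean)
  expect_identical(rt$direction, s1$truth$fragments$direction)
  expect_identical(rt$failed, s1$truth$fragments$failed)
})
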