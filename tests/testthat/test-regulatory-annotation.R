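# Toy gene model used throughout: one + strand gene at 10000-16000 with
# three exons and coding bounds, one - strand gene further downstream.
toy_genes <- data.frame(
  gene = c("ALPHA", "BETA"),
  chrom = "chr1",
  strand = c("+", "-"),
  txStart = c(10000L, 40000L),
  txEnd = c(16000L, 46000L),
  cdsStart = c(11000L, 41000L),
  cdsEnd = c(15000L, 45000L),
  exonStarts = c("10000,11000,15500", "40000,41000,45500"),
  exonEnds = c("10400,15000,16000", "40400,45000,46000"),
  stringsAsFactors = FALSE
)

iv <- function(start, end, chrom = "chr1")
  data.frame(chrom = chrom, start = start, end = end, stringsAsFactors = FALSE)

test_that("category assignment follows the documented priority rules", {
  # fully inside the coding part of an exon
  expect_equal(as.character(
    assign_refseq_category(iv(12000, 12300), toy_genes)$category), "exon")
  # overlapping both the promoter window and the first exon -> promoter wins
  expect_equal(as.character(
    assign_refseq_category(iv(9500, 10200), toy_genes)$category), "promoter")
  expect_equal(as.character(
    assign_refseq_category(iv(10500, 10900), toy_genes)$category), "intron")
  # exonic sequence upstream of cdsStart on the + strand is 5'UTR once the
  # promoter window no longer reaches into the gene
  expect_equal(as.character(
    assign_refseq_category(iv(10100, 10350), toy_genes,
                           promoter_down = 0)$category), "utr5")
  # exonic sequence past cdsEnd on the + strand is 3'UTR
  expect_equal(as.character(
    assign_refseq_category(iv(15600, 15800), toy_genes)$category), "utr3")
  # far from everything
  expect_equal(as.character(
    assign_refseq_category(iv(25000, 25400), toy_genes)$category), "intergenic")
  # strand awareness: BETA's promoter sits above txEnd
  expect_equal(as.character(
    assign_refseq_category(iv(46300, 46600), toy_genes)$category), "promoter")
  # TTS window of the - strand gene is around txStart
  expect_equal(as.character(
    assign_refseq_category(iv(39600, 39700), toy_genes)$category), "tts")
})

test_that("every interval gets exactly one category and a nearest gene", {
  set.seed(8)
  ivs <- random_intervals(120, chroms = "chr1", max_pos = 60000)
  ann <- assign_refseq_category(ivs, toy_genes)
  expect_false(anyNA(ann$category))
  expect_equal(nrow(ann), 120)
  expect_true(all(ann$nearest_gene %in% toy_genes$gene))
  # midpoint equidistant between the two TSSs (10000 and 46000) -> ALPHA
  mid_iv <- iv(27900, 28100)  # midpoint 28000, distance 18000 to both
  expect_equal(assign_refseq_category(mid_iv, toy_genes)$nearest_gene, "ALPHA")
})

test_that("enrichment ratios are observed over background fractions", {
  arr <- rep(c("promoter", "intron", "intergenic"), c(20, 30, 50))
  dmr <- rep(c("promoter", "intron", "intergenic"), c(1, 4, 5))
  er <- refseq_enrichment_ratios(dmr, arr)
  expect_equal(er$enrichment_ratio[er$category == "promoter"], 0.5)
  expect_equal(er$enrichment_ratio[er$category == "intron"], (0.4) / (0.3))
  expect_equal(sum(er$observed_fraction), 1)
  expect_equal(sum(er$background_fraction), 1)
  # self-comparison: every ratio exactly 1
  expect_true(all(refseq_enrichment_ratios(arr, arr)$enrichment_ratio == 1))
  # absent background category reported missing
  suppressMessages(
    er2 <- refseq_enrichment_ratios(c(dmr, "utr5"), arr))
  expect_true(is.na(er2$enrichment_ratio[er2$category == "utr5"]))
})

test_that("uniform random DMR subsets give ratios consistent with 1", {
  set.seed(15)
  arr <- sample(c("promoter", "exon", "intron", "intergenic"), 4000,
                replace = TRUE, prob = c(0.15, 0.2, 0.35, 0.3))
  for (rep_i in 1:5) {
    sub <- sample(arr, 400)
    er <- refseq_enrichment_ratios(sub, arr)
    for (k in seq_len(nrow(er))) {
      bg <- er$background_fraction[k]
      se <- sqrt(bg * (1 - bg) / 400) / bg
      expect_lt(abs(er$enrichment_ratio[k] - 1), 4 * se)
    }
  }
})

test_that("chromatin-state overlap honors the 1 bp half-open rule", {
  states <- data.frame(chrom = "chr1", start = c(0, 199, 250),
                       end = c(199, 250, 1000),
                       name = c("E1", "E2", "E3"), stringsAsFactors = FALSE)
  # [100,200) vs [199,250): shares exactly 1 bp -> counted
  res <- chromatin_state_overlap(iv(100, 200), states)
  expect_setequal(res$assignments$state, c("E1", "E2"))
  # [100,200) vs [200,250): half-open boundary, no shared base
  states2 <- data.frame(chrom = "chr1", start = c(0, 200),
                        end = c(200, 250), name = c("E1", "E2"),
                        stringsAsFactors = FALSE)
  res2 <- chromatin_state_overlap(iv(100, 200), states2)
  expect_identical(res2$assignments$state, "E1")
  # min_overlap above the shared length suppresses the assignment
  res3 <- chromatin_state_overlap(iv(100, 200), states, min_overlap = 2)
  expect_identical(res3$assignments$state, "E1")
})

test_that("interval overlap agrees with the brute-force all-pairs oracle", {
  set.seed(23)
  dmrs <- random_intervals(200)
  states <- random_intervals(120)
  states$name <- sprintf("S%03d", seq_len(nrow(states)))
  res <- suppressMessages(chromatin_state_overlap(dmrs, states))
  expect_setequal(overlap_pair_keys(res, states),
                  oracle_overlap_pairs(dmrs, states))
})

test_that("matched random loci respect count, size and bounds", {
  genome <- data.frame(chrom = c("chrA", "chrB"), length = c(2e6, 1e6))
  loci <- matched_random_loci(n = 4751, mean_size = 443, genome, seed = 3)
  expect_equal(nrow(loci), 4751)
  expect_true(all(loci$end - loci$start == 443))
  expect_true(all(loci$start >= 0))
  expect_true(all(loci$end <= genome$length[match(loci$chrom, genome$chrom)]))
  # chromosomes sampled proportional to length
  frac_a <- mean(loci$chrom == "chrA")
  expect_lt(abs(frac_a - 2 / 3), 3 * sqrt(2 / 9 / 4751))
  expect_equal(nrow(matched_random_loci(0, 443, genome)), 0)
  # bit-identical under a fixed seed
  expect_identical(matched_random_loci(50, 100, genome, seed = 9),
                   matched_random_loci(50, 100, genome, seed = 9))
  short <- data.frame(chrom = c("chrA", "tiny"), length = c(2e6, 100))
  expect_message(out <- matched_random_loci(10, 443, short, seed = 1),
                 "excluding")
  expect_true(all(out$chrom == "chrA"))
})

test_that("DHS permutation test behaves at its limits and under planting", {
  genome <- data.frame(chrom = "chr1", length = 100000)
  dmrs <- matched_random_loci(30, 400, genome, seed = 5)
  # peaks covering the whole genome: observed = |DMRs| and p = 1
  allpeaks <- data.frame(chrom = "chr1", start = 0, end = 100000)
  sat <- dhs_enrichment_test(dmrs, allpeaks, genome, n_permutations = 99)
  expect_equal(sat$observed, 30)
  expect_equal(sat$p_value, 1)
  # planted preference: peaks placed on the DMRs themselves
  peaks <- dmrs
  peaks$start <- peaks$start + 100
  res <- dhs_enrichment_test(dmrs, peaks, genome, n_permutations = 199,
                             seed = 4)
  expect_lte(res$p_value, 0.05)
  expect_gt(res$p_value, 0)
  expect_lte(res$p_value, 1)
  # bit-identical under a fixed seed
  res2 <- dhs_enrichment_test(dmrs, peaks, genome, n_permutations = 199,
                              seed = 4)
  expect_identical(res$null, res2$null)
})
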