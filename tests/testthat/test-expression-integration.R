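make_expr <- function(n_genes = 50, n_per_group = 4, effect_genes = NULL,
                      effect = 0, seed = 1) {
  set.seed(seed)
  ids <- c(paste0("C", seq_len(n_per_group)), paste0("K", seq_len(n_per_group)))
  groups <- setNames(rep(c("control", "case"), each = n_per_group), ids)
  expr <- matrix(rnorm(n_genes * length(ids), 8, 0.5), n_genes,
                 dimnames = list(sprintf("G%03d", seq_len(n_genes)), ids))
  if (length(effect_genes))
    expr[effect_genes, groups == "case"] <-
      expr[effect_genes, groups == "case"] + effect
  list(expr = expr, groups = groups)
}

test_that("BH adjustment matches the step-up oracle through the DE interface", {
  d <- make_expr(40, 4, effect_genes = 1:5, effect = 3)
  de <- differential_expression(d$expr, d$groups, expression_percentile = 0)
  expect_equal(de$bh_adjusted_p, oracle_bh(de$p_value), tolerance = 1e-12)
  expect_true(all(de$bh_adjusted_p >= de$p_value))
  # step-up monotonicity along the ranked list
  o <- order(de$p_value)
  expect_true(!is.unsorted(de$bh_adjusted_p[o]))
  expect_true(all(de$passes_filter == (de$bh_adjusted_p < 0.05)))
})

test_that("the expression filter excludes low-expressed genes before testing", {
  d <- make_expr(100, 4)
  d$expr[1:30, ] <- d$expr[1:30, ] - 10  # park 30 genes at the bottom
  de <- differential_expression(d$expr, d$groups, expression_percentile = 20)
  # genes whose better group mean is still far below the pooled 20th
  # percentile must not be tested
  gm <- pmax(rowMeans(d$expr[, d$groups == "control"]),
             rowMeans(d$expr[, d$groups == "case"]))
  lowest <- names(sort(gm))[1:5]
  expect_false(any(lowest %in% de$gene))
  expect_gt(attr(de, "n_filtered"), 0)
  expect_true(all(rownames(d$expr)[31:100] %in% de$gene))
  # degenerate case: nothing strictly above the cutoff
  const <- matrix(5, 10, 8, dimnames = list(paste0("g", 1:10),
                                            names(d$groups)))
  expect_warning(de0 <- differential_expression(const, d$groups), "filter")
  expect_equal(nrow(de0), 0)
})

test_that("DMR-expression concordance counts overlap and sign agreement", {
  de <- data.frame(gene = c("A", "B", "C", "D"),
                   log_fc = c(2, -1, 0.5, 1),
                   passes_filter = c(TRUE, TRUE, FALSE, TRUE),
                   stringsAsFactors = FALSE)
  dmr_genes <- data.frame(gene = c("A", "B", "E"),
                          direction = c("hypo", "hypo", "hyper"),
                          stringsAsFactors = FALSE)
  res <- dmr_expression_concordance(dmr_genes, de)
  expect_equal(res$n_dmr_genes, 3)
  expect_equal(res$n_overlap, 2)       # A and B pass; C fails filter; E absent
  expect_equal(res$n_concordant, 1)    # hypo+up (A) yes, hypo+down (B) no
  expect_equal(res$fraction, 2 / 3)
  # disjoint gene sets
  none <- dmr_expression_concordance(
    data.frame(gene = "Z", direction = "hypo"), de)
  expect_equal(none$n_overlap, 0)
  expect_error(dmr_expression_concordance(dmr_genes[0, ], de), "empty")
})

test_that("concordance overlap equals a naive set intersection and ignores row order", {
  set.seed(5)
  symbols <- sprintf("SYM%03d", 1:100)
  dmr_g <- sample(symbols, 40)
  de_g <- sample(symbols, 35)
  de <- data.frame(gene = de_g, log_fc = rnorm(35), passes_filter = TRUE,
                   stringsAsFactors = FALSE)
  dmr <- data.frame(gene = dmr_g, direction = "hypo", stringsAsFactors = FALSE)
  res <- dmr_expression_concordance(dmr, de)
  expect_equal(res$n_overlap, length(intersect(dmr_g, de_g)))
  shuffled <- dmr_expression_concordance(dmr[sample(nrow(dmr)), , drop = FALSE],
                                         de[sample(nrow(de)), , drop = FALSE])
  expect_equal(shuffled$n_overlap, res$n_overlap)
  expect_equal(shuffled$n_concordant, res$n_concordant)
})

test_that("replication concordance applies the sign and significance rules", {
  disc <- data.frame(gene = c("A", "B", "C"),
                     direction = c("hypo", "hyper", "hypo"),
                     stringsAsFactors = FALSE)
  repl <- data.frame(gene = c("A", "B", "C"),
                     difference = c(-4, 6, 2),  # C: sign mismatch for hypo
                     p = c(0.001, 0.01, 0.002),
                     stringsAsFactors = FALSE)
  res <- replication_concordance(disc, repl)
  expect_equal(res$n_concordant, 2)
  expect_equal(res$fraction, 2 / 3)
  # perfect replication
  repl$difference <- c(-4, 6, -2)
  expect_equal(replication_concordance(disc, repl)$fraction, 1)
  # non-significant replication does not confirm
  repl$p <- c(0.001, 0.5, 0.002)
  expect_equal(replication_concordance(disc, repl)$n_concordant, 2)
  # probe collapse: the probe with the largest |difference| represents the gene
  multi <- data.frame(gene = c("A", "A"), probe = c("p1", "p2"),
                      difference = c(1, -9), p = c(0.001, 0.001))
  one <- replication_concordance(disc[1, , drop = FALSE], multi)
  expect_equal(one$table$difference, -9)
  expect_equal(one$fraction, 1)
  # genes absent from the replication table
  miss <- replication_concordance(disc, repl[1:2, ], drop_missing = TRUE)
  expect_equal(miss$n_missing, 1)
  expect_equal(miss$n_genes, 2)
  keep <- replication_concordance(disc, repl[1:2, ], drop_missing = FALSE)
  expect_equal(keep$n_genes, 3)
})

test_that("random replication signs give ~50% concordance", {
  set.seed(31)
  genes <- sprintf("g%03d", 1:400)
  disc <- data.frame(gene = genes,
                     direction = sample(c("hypo", "hyper"), 400, TRUE),
                     stringsAsFactors = FALSE)
  repl <- data.frame(gene = genes,
                     difference = sample(c(-1, 1), 400, TRUE),
                     stringsAsFactors = FALSE)
  res <- replication_concordance(disc, repl)
  expect_lt(abs(res$fraction - 0.5), 3 * sqrt(0.25 / 400))
})

test_that("measured expression concordance converges to the configured coupling", {
  for (q in c(0.5, 1.0)) {
    cfg <- sim_config(seed = 100 + round(100 * q), n_fragments = 1500,
                      n_dmr = 250, coupling_prob = 1, concordance_prob = q,
                      expr_effect = 2, n_random_probes = 10)
    truth <- simulate_methylation_truth(generate_fragment_map(cfg), cfg)
    ex <- simulate_expression(truth, cfg)
    de <- differential_expression(ex$expr, ex$groups)
    dirs <- ifelse(truth$fragments$delta > 0, "hypo", "hyper")
    dmr_genes <- data.frame(
      gene = truth$fragments$gene[truth$fragments$delta != 0],
      direction = dirs[truth$fragments$delta != 0],
      stringsAsFactors = FALSE)
    res <- dmr_expression_concordance(dmr_genes, de)
    n <- res$n_overlap
    expect_gt(n, 100)  # strong planted effects are detected
    tol <- 3 * sqrt(q * (1 - q) / n) + 0.02
    expect_lt(abs(res$concordance_fraction - q), tol)
  }
})

test_that("absolute-vs-relative correlation is Pearson on matched pairs", {
  res <- absolute_relative_correlation(c(0, 50, 100), c(0, -1, -2))
  expect_equal(res$r, -1)
  expect_equal(res$n, 3)
  set.seed(2)
  a <- runif(20, 0, 100)
  noisy <- -0.02 * a + rnorm(20, 0, 0.1)
  expect_equal(absolute_relative_correlation(a, noisy)$r,
               cor(a, noisy), tolerance = 1e-12)
  expect_warning(cz <- absolute_relative_correlation(c(5, 5, 5), c(1, 2, 3)),
                 "zero variance")
  expect_true(is.na(cz$r))
  expect_error(absolute_relative_correlation(c(1, 2), c(3, 4)), "3 matched")
})
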