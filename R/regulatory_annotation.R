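# Genomic context of DMRs: RefSeq-style category assignment and enrichment,
# chromatin-state overlap, and DHS enrichment against matched random loci.
# All user-facing coordinates are 0-based half-open; conversion to the
# 1-based closed GRanges convention happens at the boundary.

refseq_categories <- c("promoter", "utr5", "utr3", "tts", "exon",
                       "intron", "intergenic")

# Expand refFlat-style gene models into per-category feature intervals
# (0-based half-open data.frames).
gene_model_features <- function(genes, promoter_up = 1000,
                                promoter_down = 500, tts_window = 500) {
  has_cds <- all(c("cdsStart", "cdsEnd") %in% names(genes))
  if (!has_cds)
    msg("gene models lack coding bounds; UTR categories collapse into exon")
  feats <- list()
  add <- function(cat, chrom, start, end) {
    keep <- end > start
    if (any(keep))
      feats[[length(feats) + 1]] <<- data.frame(
        chrom = chrom[keep], start = start[keep], end = end[keep],
        category = cat, stringsAsFactors = FALSE)
  }
  plus <- genes$strand == "+"
  tss <- ifelse(plus, genes$txStart, genes$txEnd)
  tts <- ifelse(plus, genes$txEnd, genes$txStart)
  add("promoter", genes$chrom,
      pmax(0, ifelse(plus, tss - promoter_up, tss - promoter_down)),
      ifelse(plus, tss + promoter_down, tss + promoter_up))
  add("tts", genes$chrom, pmax(0, tts - tts_window), tts + tts_window)
  ex_s <- lapply(strsplit(genes$exonStarts, ","), as.integer)
  ex_e <- lapply(strsplit(genes$exonEnds, ","), as.integer)
  n_ex <- lengths(ex_s)
  exon_df <- data.frame(chrom = rep(genes$chrom, n_ex),
                        start = unlist(ex_s), end = unlist(ex_e),
                        gene_row = rep(seq_len(nrow(genes)), n_ex),
                        stringsAsFactors = FALSE)
  if (has_cds) {
    cs <- genes$cdsStart[exon_df$gene_row]
    ce <- genes$cdsEnd[exon_df$gene_row]
    pl <- plus[exon_df$gene_row]
    # upstream-of-CDS exon pieces = 5'UTR on +, 3'UTR on -
    left_s <- exon_df$start; left_e <- pmin(exon_df$end, cs)
    right_s <- pmax(exon_df$start, ce); right_e <- exon_df$end
    add5 <- function(s, e, sel) add("utr5", exon_df$chrom[sel], s[sel], e[sel])
    add3 <- function(s, e, sel) add("utr3", exon_df$chrom[sel], s[sel], e[sel])
    add5(left_s, left_e, pl); add3(left_s, left_e, !pl)
    add3(right_s, right_e, pl); add5(right_s, right_e, !pl)
    add("exon", exon_df$chrom, pmax(exon_df$start, cs), pmin(exon_df$end, ce))
  } else {
    add("exon", exon_df$chrom, exon_df$start, exon_df$end)
  }
  # introns: gaps between consecutive exons
  int_list <- mapply(function(s, e, ch) {
    if (length(s) < 2) return(NULL)
    data.frame(chrom = ch, start = e[-length(e)], end = s[-1],
               stringsAsFactors = FALSE)
  }, ex_s, ex_e, genes$chrom, SIMPLIFY = FALSE)
  introns <- do.call(rbind, int_list)
  if (!is.null(introns) && nrow(introns))
    add("intron", introns$chrom, introns$start, introns$end)
  do.call(rbind, feats)
}

#' Assign genomic intervals to RefSeq-style categories and nearest genes
#'
#' Each interval gets exactly one category from promoter, 5'UTR, 3'UTR,
#' TTS, exon, intron, intergenic, resolved by fixed priority (promoter >
#' 5'UTR > 3'UTR > TTS > exon > intron > intergenic) so small regulatory
#' categories are not swallowed by gene-body overlap. The promoter window is
#' strand-aware TSS -`promoter_up`/+`promoter_down` bp; the TTS window is
#' +/- `tts_window` bp. The nearest gene is the one whose TSS is closest to
#' the interval midpoint, ties broken by lexicographic gene name.
#'
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param genes refFlat-style gene models (see [read_refflat()]).
#' @param promoter_up,promoter_down,tts_window Window sizes in bp.
#' @return The input with `category` and `nearest_gene` columns added.
#' @export
assign_refseq_category <- function(intervals, genes, promoter_up = 1000,
                                   promoter_down = 500, tts_window = 500) {
  if (nrow(genes) == 0) stopf("gene models are empty")
  feats <- gene_model_features(genes, promoter_up, promoter_down, tts_window)
  q <- as_granges(intervals)
  category <- rep("intergenic", nrow(intervals))
  unassigned <- rep(TRUE, nrow(intervals))
  for (cat in setdiff(refseq_categories, "intergenic")) {
    f <- feats[feats$category == cat, , drop = FALSE]
    if (!nrow(f)) next
    hit <- IRanges::overlapsAny(q, as_granges(f), minoverlap = 1L)
    category[unassigned & hit] <- cat
    unassigned <- unassigned & !hit
  }
  intervals$category <- factor(category, levels = refseq_categories)
  intervals$nearest_gene <- nearest_tss_gene(intervals, genes)
  intervals
}

# Nearest gene by |interval midpoint - TSS|, ties broken by lexicographic
# gene name. findInterval over per-chromosome sorted unique TSS positions
# keeps this O((n + m) log m).
nearest_tss_gene <- function(intervals, genes) {
  tss <- ifelse(genes$strand == "+", genes$txStart, genes$txEnd)
  mid <- (intervals$start + intervals$end) %/% 2
  out <- rep(NA_character_, nrow(intervals))
  by_chrom <- split(seq_len(nrow(genes)), genes$chrom)
  for (ch in unique(intervals$chrom)) {
    gi <- by_chrom[[ch]]
    if (is.null(gi)) gi <- seq_len(nrow(genes)) # no gene on this chromosome
    pos <- tss[gi]
    u <- sort(unique(pos))
    # lexicographically smallest gene name at each unique TSS position
    best_name <- vapply(split(genes$gene[gi], match(pos, u)),
                        min, character(1))[as.character(seq_along(u))]
    qi <- which(intervals$chrom == ch)
    j <- findInterval(mid[qi], u)
    lo <- pmax(j, 1L); hi <- pmin(j + 1L, length(u))
    d_lo <- abs(mid[qi] - u[lo]); d_hi <- abs(u[hi] - mid[qi])
    pick <- ifelse(d_lo < d_hi, lo,
            ifelse(d_hi < d_lo, hi, NA_integer_))
    tie <- is.na(pick)
    out[qi[!tie]] <- best_name[pick[!tie]]
    if (any(tie)) # equidistant flanking TSSs: min name across both
      out[qi[tie]] <- pmin(best_name[lo[tie]], best_name[hi[tie]])
  }
  out
}

#' RefSeq-category enrichment of DMRs relative to the array
#'
#' For each category, the enrichment ratio is the fraction of DMRs in that
#' category divided by the fraction of all array fragments in it — the
#' background is the composition of the methylation array itself, not the
#' genome.
#'
#' @param dmr_categories Factor/character of categories of the DMRs.
#' @param array_categories Factor/character of categories of all array
#'   fragments (same category set).
#' @return data.frame per category: `observed`, `observed_fraction`,
#'   `background_fraction`, `enrichment_ratio` (NA where the background
#'   fraction is zero).
#' @export
refseq_enrichment_ratios <- function(dmr_categories, array_categories) {
  levels <- union(unique(as.character(array_categories)),
                  unique(as.character(dmr_categories)))
  obs <- table(factor(dmr_categories, levels = levels))
  bg <- table(factor(array_categories, levels = levels))
  obs_f <- as.numeric(obs) / max(1, sum(obs))
  bg_f <- as.numeric(bg) / max(1, sum(bg))
  ratio <- ifelse(bg_f > 0, obs_f / bg_f, NA_real_)
  if (any(bg_f == 0 & obs_f > 0))
    msg("categories absent from the array background: ratio reported NA")
  data.frame(category = levels,
             observed = as.integer(obs),
             observed_fraction = obs_f,
             background_fraction = bg_f,
             enrichment_ratio = ratio,
             stringsAsFactors = FALSE)
}

#' Chromatin-state composition of a DMR set
#'
#' Assigns every DMR each state segment it overlaps by at least
#' `min_overlap` bp (half-open: touching boundaries do not overlap). DMRs
#' spanning a state boundary are counted once per overlapped state; DMRs
#' falling entirely into segmentation gaps are reported unassigned.
#'
#' @param dmrs data.frame of intervals (`chrom`, `start`, `end`, optional
#'   `name`).
#' @param states BED-style data.frame with state labels in `name`.
#' @param min_overlap Minimum shared basepairs (default 1).
#' @return List with `assignments` (data.frame dmr index/name x state),
#'   `distribution` (per-state counts and fractions of assignments),
#'   `n_multi_state` and `n_unassigned`.
#' @export
chromatin_state_overlap <- function(dmrs, states, min_overlap = 1L) {
  q <- as_granges(dmrs)
  s <- as_granges(states)
  hits <- GenomicRanges::findOverlaps(q, s, minoverlap = min_overlap)
  qi <- S4Vectors::queryHits(hits)
  assignments <- data.frame(
    dmr = if (!is.null(dmrs$name)) dmrs$name[qi] else qi,
    state = states$name[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE)
  tab <- table(assignments$state)
  n_multi <- sum(tabulate(qi, nbins = nrow(dmrs)) > 1)
  n_unassigned <- nrow(dmrs) - length(unique(qi))
  if (n_multi) msg("%d DMRs overlap more than one state", n_multi)
  if (n_unassigned) msg("%d DMRs fall into segmentation gaps", n_unassigned)
  list(assignments = assignments,
       distribution = data.frame(
         state = names(tab),
         count = as.integer(tab),
         fraction = as.numeric(tab) / max(1, sum(tab)),
         stringsAsFactors = FALSE),
       n_multi_state = n_multi,
       n_unassigned = n_unassigned)
}

#' Matched random genomic loci
#'
#' The null model for interval-enrichment tests: `n` loci of fixed size
#' `mean_size` (matching the DMR count and mean fragment size), placed
#' uniformly with chromosomes sampled proportional to length, always fully
#' inside chromosome bounds.
#'
#' @param n Number of loci (defaults to the study's 4,751).
#' @param mean_size Locus size in bp (defaults to the study's 443).
#' @param genome data.frame `chrom`, `length`.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return data.frame of intervals `chrom`, `start`, `end`, `name`.
#' @export
matched_random_loci <- function(n = 4751L, mean_size = 443L, genome,
                                seed = 1L) {
  if (n < 0) stopf("n must be >= 0")
  if (nrow(genome) == 0) stopf("genome is empty")
  usable <- genome$length >= mean_size
  if (!all(usable)) {
    msg("excluding %d chromosomes shorter than %d bp", sum(!usable), mean_size)
    genome <- genome[usable, , drop = FALSE]
    if (nrow(genome) == 0) stopf("no chromosome can hold a %d bp locus", mean_size)
  }
  if (n == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      stringsAsFactors = FALSE))
  with_seed(seed, {
    ci <- sample.int(nrow(genome), n, replace = TRUE, prob = genome$length)
    start <- as.integer(floor(runif(n, 0, genome$length[ci] - mean_size + 1)))
    data.frame(chrom = genome$chrom[ci], start = start,
               end = as.integer(start + mean_size),
               name = sprintf("RAND%05d", seq_len(n)),
               stringsAsFactors = FALSE)
  })
}

#' DHS enrichment of DMRs via matched random loci
#'
#' Observed statistic: number of DMRs overlapping at least one DHS peak by
#' >= 1 bp. Null distribution: the same statistic over `n_permutations`
#' matched random locus sets (same count, same mean size). Empirical
#' p-value uses the add-one rule, `(1 + #(null >= observed)) /
#' (n_permutations + 1)`, so it is never 0 and never exceeds 1.
#'
#' @param dmrs data.frame of DMR intervals (needs `chrom`, `start`, `end`).
#' @param dhs data.frame of DHS peak intervals.
#' @param genome data.frame `chrom`, `length`.
#' @param n_permutations Number of matched random sets (default 999).
#' @param seed Master seed for the permutation stream.
#' @param mean_size Size of the random loci; defaults to the rounded mean
#'   DMR size.
#' @return List with `observed`, `n_dmrs`, `mean_size`, `null` (vector of
#'   null counts) and `p_value`.
#' @export
dhs_enrichment_test <- function(dmrs, dhs, genome, n_permutations = 999L,
                                seed = 1L, mean_size = NULL) {
  if (n_permutations < 1) stopf("n_permutations must be >= 1")
  mean_size <- as.integer(mean_size %||% round(mean(dmrs$end - dmrs$start)))
  peaks <- as_granges(dhs)
  observed <- sum(IRanges::overlapsAny(as_granges(dmrs), peaks, minoverlap = 1L))
  null <- vapply(seq_len(n_permutations), function(b) {
    rnd <- matched_random_loci(nrow(dmrs), mean_size, genome,
                               seed = child_seed(seed, "dhs") + b)
    sum(IRanges::overlapsAny(as_granges(rnd), peaks, minoverlap = 1L))
  }, numeric(1))
  list(observed = observed,
       n_dmrs = nrow(dmrs),
       mean_size = mean_size,
       null = null,
       p_value = (1 + sum(null >= observed)) / (n_permutations + 1))
}

#' Annotate a DMR set end to end
#'
#' Convenience wrapper: RefSeq category + nearest gene for DMRs and for the
#' whole array (the enrichment background), category enrichment ratios,
#' chromatin-state composition, and the DHS permutation test.
#'
#' @param dmr_intervals,array_intervals data.frames of intervals; the array
#'   set is the enrichment background.
#' @param genes,states,dhs,genome Annotation inputs (see the individual
#'   operations).
#' @param n_permutations,seed Permutation-test parameters.
#' @param promoter_up,promoter_down,tts_window Category windows (bp).
#' @return List with `dmr_annotation`, `enrichment`, `states`, `dhs_test`.
#' @export
annotate_dmrs <- function(dmr_intervals, array_intervals, genes, states,
                          dhs, genome, n_permutations = 999L, seed = 1L,
                          promoter_up = 1000, promoter_down = 500,
                          tts_window = 500) {
  dmr_ann <- assign_refseq_category(dmr_intervals, genes, promoter_up,
                                    promoter_down, tts_window)
  arr_ann <- assign_refseq_category(array_intervals, genes, promoter_up,
                                    promoter_down, tts_window)
  list(dmr_annotation = dmr_ann,
       array_annotation = arr_ann,
       enrichment = refseq_enrichment_ratios(dmr_ann$category,
                                             arr_ann$category),
       states = chromatin_state_overlap(dmr_ann, states),
       dhs_test = dhs_enrichment_test(dmr_ann, dhs, genome,
                                      n_permutations = n_permutations,
                                      seed = seed))
}
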