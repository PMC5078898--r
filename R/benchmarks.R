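# Recovery scoring against planted truth, and the property benchmarks the
# package uses to validate itself on synthetic data. Each benchmark builds
# its own dataset with the generator, runs the relevant stages, and scores
# the result against the truth tables; they are reused by the test suite
# and the reproduction script.

#' Score called intervals against planted truth intervals
#'
#' A truth interval is recovered when some called interval reciprocally
#' overlaps it by at least `min_reciprocal` (intersection at least that
#' fraction of both widths); a called interval is a true positive when it
#' reciprocally overlaps some truth interval.
#'
#' @param called,truth Interval tables (`chrom`, `start`, `end`).
#' @param min_reciprocal Reciprocal-overlap fraction (default 0.5).
#' @return List: `sensitivity`, `precision`, `n_called`, `n_truth`.
#' @export
score_interval_recovery <- function(called, truth, min_reciprocal = 0.5) {
  called <- as.data.table(called); truth <- as.data.table(truth)
  if (nrow(truth) == 0) stop("empty truth set")
  if (nrow(called) == 0)
    return(list(sensitivity = 0, precision = NA_real_, n_called = 0L,
                n_truth = nrow(truth)))
  cg <- as_granges(called[, .(chrom, start, end)])
  tg <- as_granges(truth[, .(chrom, start, end)])
  hits <- GenomicRanges::findOverlaps(cg, tg)
  if (length(hits) == 0)
    return(list(sensitivity = 0, precision = 0, n_called = nrow(called),
                n_truth = nrow(truth)))
  inter <- GenomicRanges::width(GenomicRanges::pintersect(
    cg[queryHits(hits)], tg[subjectHits(hits)]))
  wq <- GenomicRanges::width(cg[queryHits(hits)])
  ws <- GenomicRanges::width(tg[subjectHits(hits)])
  good <- inter >= min_reciprocal * wq & inter >= min_reciprocal * ws
  list(sensitivity = length(unique(subjectHits(hits)[good])) / nrow(truth),
       precision = length(unique(queryHits(hits)[good])) / nrow(called),
       n_called = nrow(called), n_truth = nrow(truth))
}

#' Overlap-based scoring of called differential regions
#'
#' Sensitivity: fraction of planted differential domains overlapped
#' (>= 1 bp) by a called region. Empirical FDR: fraction of called
#' regions overlapping no planted differential domain.
#'
#' @param called Called DMR table.
#' @param truth_dmrs Planted differential domain intervals.
#' @return List: `sensitivity`, `fdr`, `n_called`.
#' @export
score_dmr_recovery <- function(called, truth_dmrs) {
  called <- as.data.table(called); truth_dmrs <- as.data.table(truth_dmrs)
  if (nrow(truth_dmrs) == 0) stop("empty truth set")
  if (nrow(called) == 0)
    return(list(sensitivity = 0, fdr = NA_real_, n_called = 0L))
  cg <- as_granges(called[, .(chrom, start, end)])
  tg <- as_granges(truth_dmrs[, .(chrom, start, end)])
  hits <- GenomicRanges::findOverlaps(cg, tg)
  list(sensitivity = length(unique(subjectHits(hits))) / nrow(truth_dmrs),
       fdr = 1 - length(unique(queryHits(hits))) / nrow(called),
       n_called = nrow(called))
}

#' Null calibration of the segmentation stage
#'
#' Simulates background-only tag sets (no planted domains) and measures
#' the fraction of windows whose count exceeds the permutation threshold
#' at the given alpha; averaged over simulations, this should not exceed
#' alpha by more than Monte-Carlo slack.
#'
#' @param n_sims Number of background simulations.
#' @param n_permutations,alpha Segmentation null settings.
#' @param chrom_length,n_tags Background geometry (default 10 Mb, 100k
#'   tags).
#' @param seed Integer seed.
#' @return List: `mean_fraction_called`, `per_sim` fractions.
#' @export
benchmark_null_calibration <- function(n_sims = 20, n_permutations = 500,
                                       alpha = 0.01, chrom_length = 10e6,
                                       n_tags = 1e5, seed = 1L) {
  fr <- vapply(seq_len(n_sims), function(s) {
    p <- sim_params(chrom_length = chrom_length,
                    background_rate = n_tags / chrom_length,
                    n_domains = 0, library_size = n_tags,
                    n_genes = 0, n_de = 0, rng_seed = seed + 1000L * s)
    gg <- simulate_genome_and_genes(p)
    truth <- simulate_truth(p, gg$genome, gg$genes)
    ts <- simulate_dip_tags(gg$genome, truth, p, p$conditions[1],
                            seed = p$rng_seed)
    wc <- count_windows(ts, gg$genome, 1000, 500)
    null <- permutation_null(ts, gg$genome, 1000, 500, n_permutations,
                             alpha, seed = p$rng_seed + 7L)
    mean(wc$windows$count > null$threshold)
  }, 0)
  list(mean_fraction_called = mean(fr), per_sim = fr)
}

#' Planted-domain recovery of the segmentation stage
#'
#' Default generator conditions: 200 planted 1-kb domains at fold 8 over
#' a 0.01 tags/bp Poisson background on 10 Mb; segmentation at the
#' default window geometry and threshold; scored at 50% reciprocal
#' overlap.
#'
#' @param config A [pipeline_config()].
#' @param seed Integer seed.
#' @return [score_interval_recovery()] output.
#' @export
benchmark_domain_recovery <- function(config = pipeline_config(),
                                      seed = 1L) {
  p <- sim_params(n_genes = 0, n_de = 0, rng_seed = seed)
  gg <- simulate_genome_and_genes(p)
  truth <- simulate_truth(p, gg$genome, gg$genes)
  ts <- simulate_dip_tags(gg$genome, truth, p, p$conditions[1],
                          seed = p$rng_seed)
  res <- segment_sample(ts, config, gg$genome, seed = seed + 7L)
  score_interval_recovery(res$domains, truth$domains, 0.5)
}

#' Planted-DMR recovery of the differential stage
#'
#' 1000 planted enriched regions of which 100 carry a fold-ratio-3 gain
#' in the second condition; two pools per condition; segmentation, merge,
#' chi-square testing over 5-kb units, DMR call at q < 0.01 and
#' normalized difference > 50.
#'
#' @param config A [pipeline_config()].
#' @param seed Integer seed.
#' @return [score_dmr_recovery()] output plus `n_tested`.
#' @export
benchmark_dmr_recovery <- function(config = pipeline_config(), seed = 1L) {
  p <- sim_params(n_domains = 1000, n_dmrs = 100, dmr_fold_ratio = 3,
                  n_pools = 2, n_genes = 0, n_de = 0, rng_seed = seed)
  ds <- simulate_dataset(p)
  seg <- list(); i <- 0L
  for (cond in p$conditions) for (ts in ds$dip[[cond]]) {
    i <- i + 1L
    seg[[ts$sample_id]] <-
      segment_sample(ts, config, ds$genome, seed = seed + i)$domains
  }
  merged <- merge_regions(seg, config$dmr_window_bp, ds$genome)
  tested <- test_regions(merged, ds$dip[[p$conditions[1]]],
                         ds$dip[[p$conditions[2]]], "chisq", ds$genome)
  dmrs <- call_dmrs(tested, config$dmr_q_threshold, config$dmr_min_tag_diff)
  out <- score_dmr_recovery(dmrs, ds$truth$domains[ds$truth$domains$is_dmr])
  out$n_tested <- nrow(tested)
  out
}

#' Exhaustive oracle check of the 2x2 exact and chi-square statistics
#'
#' Enumerates every 2x2 table with all margins at most `max_margin` and
#' compares (i) the package's one-sided hypergeometric overlap p against
#' a direct log-factorial enumeration of the tail and (ii) the chi-square
#' statistic against its closed form `n(ad-bc)^2 / (r1 r2 c1 c2)`.
#'
#' @param max_margin Margin bound (default 30).
#' @return List: `max_fisher_err`, `max_chisq_err`, `n_tables`.
#' @export
benchmark_table_oracles <- function(max_margin = 30) {
  g <- data.table::CJ(m1 = 0:max_margin, m2 = 0:max_margin,
                      n = 0:max_margin)
  g <- g[n <= m1 + m2 & (m1 + m2 - n) <= max_margin]
  g <- g[, .(x = max(0, n - m2):min(n, m1)), by = .(m1, m2, n)]
  # oracle: enumerate the tail sum of hypergeometric probabilities
  oracle <- vapply(seq_len(nrow(g)), function(i) {
    m1 <- g$m1[i]; m2 <- g$m2[i]; n <- g$n[i]; x <- g$x[i]
    j <- x:min(n, m1)
    sum(exp(lchoose(m1, j) + lchoose(m2, n - j) - lchoose(m1 + m2, n)))
  }, 0)
  ours <- vapply(seq_len(nrow(g)), function(i)
    overlap_fisher_p(g$x[i], g$m1[i], g$n[i], g$m1[i] + g$m2[i]), 0)
  max_fisher_err <- max(abs(ours - oracle))
  # chi-square closed form on the tables with positive margins
  t2 <- g[m1 > 0 & m2 > 0 & n > 0 & (m1 + m2 - n) > 0]
  a <- t2$x; b <- t2$m1 - t2$x; c_ <- t2$n - t2$x
  d <- t2$m2 - (t2$n - t2$x)
  N <- t2$m1 + t2$m2
  closed <- N * (a * d - b * c_)^2 /
    (t2$m1 * t2$m2 * t2$n * (N - t2$n))
  ours2 <- vapply(seq_len(nrow(t2)), function(i) {
    r <- test_region_chisq(a[i], c_[i], a[i] + b[i], c_[i] + d[i])
    r$statistic
  }, 0)
  max_chisq_err <- max(abs(ours2 - closed), na.rm = TRUE)
  list(max_fisher_err = max_fisher_err, max_chisq_err = max_chisq_err,
       n_tables = nrow(g))
}

#' Storey q-value reduction and pi0 calibration
#'
#' With pi0 forced to 1 the Storey q-values must equal BH exactly; with
#' uniform p-values the smoother pi0 estimate should be near 1.
#'
#' @param n_vectors Random p-vectors for the reduction check.
#' @param m_reduction,m_pi0 Vector lengths.
#' @param seed Integer seed.
#' @return List: `max_bh_diff`, `pi0_uniform`.
#' @export
benchmark_storey <- function(n_vectors = 10, m_reduction = 500,
                             m_pi0 = 5000, seed = 1L) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  diffs <- vapply(seq_len(n_vectors), function(i) {
    p <- runif(m_reduction)
    max(abs(storey_qvalues(p, pi0 = 1) - p.adjust(p, "BH")))
  }, 0)
  pi0 <- estimate_pi0(runif(m_pi0))
  list(max_bh_diff = max(diffs), pi0_uniform = pi0)
}

#' Expression-test calibration and power
#'
#' Null calibration: a no-effect dataset (identical condition means)
#' should give approximately uniform p-values (KS test against U(0,1)).
#' Power: planted |log2fc| = 1 at mean 100, dispersion 0.1, 4 vs 4
#' replicates, in a dense-signal benchmark (half the genes differential);
#' power is the fraction of planted genes at q < 0.05.
#'
#' @param n_genes Genes per dataset.
#' @param seed Integer seed.
#' @return List: `ks_p` (null uniformity), `power`, `fdr` (empirical,
#'   at q < 0.05).
#' @export
benchmark_expression <- function(n_genes = 2000, seed = 1L) {
  null_p <- sim_params(n_genes = n_genes, gene_length_min = 1000,
                       gene_length_max = 2000, nb_mean = 100,
                       nb_mean_sdlog = 0, nb_dispersion = 0.1, n_de = 0,
                       n_reps = 4, rng_seed = seed)
  gg <- simulate_genome_and_genes(null_p)
  truth <- simulate_truth(null_p, gg$genome, gg$genes)
  rna <- simulate_rna_counts(gg$genes, truth, null_p)
  expr <- test_expression(rna$counts, rna$conditions)
  ks_p <- suppressWarnings(ks.test(expr$p[!is.na(expr$p)], "punif"))$p.value

  pow_p <- sim_params(n_genes = n_genes, gene_length_min = 1000,
                      gene_length_max = 2000, nb_mean = 100,
                      nb_mean_sdlog = 0, nb_dispersion = 0.1,
                      n_de = n_genes / 2, de_log2fc = 1, n_reps = 4,
                      rng_seed = seed + 1L)
  gg2 <- simulate_genome_and_genes(pow_p)
  truth2 <- simulate_truth(pow_p, gg2$genome, gg2$genes)
  rna2 <- simulate_rna_counts(gg2$genes, truth2, pow_p)
  expr2 <- test_expression(rna2$counts, rna2$conditions)
  de <- expr2$gene_id %in% truth2$de_genes$gene_id
  called <- !is.na(expr2$q) & expr2$q < 0.05
  list(ks_p = ks_p, power = mean(called[de]),
       fdr = if (any(called)) mean(!de[called]) else 0)
}

# Generator settings for the coupling benchmark: 5000 short genes on a
# 25-Mb chromosome, 1200 background domains, 100 coupled genes among 300
# DE genes.
coupling_params <- function(seed, n_coupled = 100) {
  sim_params(chrom_length = 25e6, background_rate = 0.005,
             n_domains = 1200, domain_fold = 8, dmr_fold_ratio = 3,
             n_genes = 5000, gene_length_min = 1500, gene_length_max = 2500,
             n_de = 300, de_log2fc = 1,
             n_coupled = n_coupled, coupled_log2fc = 2,
             coupled_domain_frac = 0.8,
             n_pools = 2, n_reps = 4, rng_seed = seed)
}

# Metagene matrices for both conditions over an expression-sorted gene
# order, plus the per-gene intragenic difference scores.
coupling_scores <- function(ds, config = pipeline_config()) {
  expr <- test_expression(ds$rna$counts, ds$rna$conditions)
  expr <- expr[order(-statistic, gene_id, na.last = TRUE)]
  conds <- ds$params$conditions
  mats <- lapply(conds, function(cond)
    metagene_matrix(combine_tag_sets(ds$dip[[cond]], cond),
                    ds$genes, expr$gene_id,
                    ceiling_quantile = config$heatmap_quantile))
  ranked <- rank_intragenic_difference(mats[[1]], mats[[2]], Inf)
  list(expr = expr, mats = mats, ranked = ranked)
}

#' Coupled methylation-expression structure recovery
#'
#' The joint benchmark: 100 genes receive both an intragenic
#' hydroxymethylation gain and an expression gain among 5000 genes.
#' Measured quantities: (i) Fisher p of the overlap between the top
#' significantly up-regulated genes and the genes of the top-1000
#' up-regulated annotated regions, (ii) the fraction of coupled genes
#' inside the top-500 intragenic-difference ranking, and (iii) over
#' `n_reps` replicate simulations, whether the mean intragenic score of
#' the top expression decile exceeds the bottom decile (rank-sum test at
#' alpha = 0.01). All three are recomputed on an uncoupled control.
#'
#' @param config A [pipeline_config()].
#' @param seed Integer seed.
#' @param n_reps Replicates for the decile test.
#' @param coupled `TRUE` for the coupled scenario, `FALSE` for the
#'   control.
#' @return List: `overlap_p`, `top500_coupled_frac` (NA for control),
#'   `decile_signif` (count of significant replicates), `n_reps`.
#' @export
benchmark_coupling <- function(config = pipeline_config(), seed = 1L,
                               n_reps = 10, coupled = TRUE) {
  n_coupled <- if (coupled) 100 else 0
  p <- coupling_params(seed, n_coupled)
  ds <- simulate_dataset(p)
  cs <- coupling_scores(ds, config)

  # full differential path on the first replicate for the overlap test
  seg <- list(); i <- 0L
  for (cond in p$conditions) for (ts in ds$dip[[cond]]) {
    i <- i + 1L
    seg[[ts$sample_id]] <-
      segment_sample(ts, config, ds$genome, seed = seed + i)$domains
  }
  merged <- merge_regions(seg, config$dmr_window_bp, ds$genome)
  tested <- test_regions(merged, ds$dip[[p$conditions[1]]],
                         ds$dip[[p$conditions[2]]], "chisq", ds$genome)
  tested[, q := p.adjust(p, "BH")]
  expressed <- rownames(ds$rna$counts)[rowSums(ds$rna$counts) > 0]
  annotatable <- annotate_dmrs(tested, ds$genes, config$tss_max_dist_bp,
                               Inf)$gene_id
  universe <- intersect(expressed, annotatable)
  up_regions <- annotate_dmrs(tested[ndiff > 0], ds$genes,
                              config$tss_max_dist_bp, config$top_n_overlap)
  meth_set <- intersect(up_regions$gene_id, universe)
  expr_set <- intersect(top_regulated_genes(cs$expr, "up",
                                            config$expr_sig_threshold,
                                            config$top_n_overlap), universe)
  ov <- topn_overlap(meth_set, expr_set, universe)

  top500 <- head(cs$ranked$gene_id, config$top_n_intragenic)
  top500_frac <- if (coupled)
    mean(ds$truth$coupled_genes %in% top500) else NA_real_

  # expression-decile intragenic score contrast over replicate simulations
  decile_signif <- 0L
  for (r in seq_len(n_reps)) {
    pr <- coupling_params(seed + 50L * r, n_coupled)
    pr$n_pools <- 1L
    dsr <- simulate_dataset(pr)
    csr <- coupling_scores(dsr, config)
    sc <- setNames(csr$ranked$score, csr$ranked$gene_id)[csr$expr$gene_id]
    k <- floor(length(sc) / 10)
    top <- sc[seq_len(k)]; bottom <- sc[seq(length(sc) - k + 1, length(sc))]
    wp <- suppressWarnings(wilcox.test(top, bottom,
                                       alternative = "greater"))$p.value
    if (wp < 0.01) decile_signif <- decile_signif + 1L
  }
  list(overlap_p = ov$p, overlap = ov$overlap, n_meth = ov$n1,
       n_expr = ov$n2, n_universe = ov$n_universe,
       top500_coupled_frac = top500_frac,
       decile_signif = decile_signif, n_reps = n_reps)
}

#' Weighted-enrichment reduction and bias absorption
#'
#' (i) Reduction: with unit weights the Wallenius p must match the Fisher
#' p. (ii) Bias absorption: genes are sampled into the set with
#' probability proportional to a planted 4x weight on "long" genes; on
#' the long-gene category the weighted p should be at least the
#' unweighted p in nearly all replicates.
#'
#' @param n_reps Replicates for the bias check.
#' @param seed Integer seed.
#' @return List: `max_reduction_err`, `bias_absorbed_frac`.
#' @export
benchmark_weighted <- function(n_reps = 100, seed = 1L) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  universe <- sprintf("g%04d", seq_len(2000))
  long <- universe[1:500]
  cats <- list(LONG = long)
  unit_w <- setNames(rep(1, 2000), universe)
  red_err <- max(vapply(1:5, function(i) {
    gs <- sample(universe, 200)
    pf <- enrich_fisher(gs, cats, universe)$p
    pw <- enrich_weighted(gs, cats, universe, unit_w)$p
    abs(pf - pw)
  }, 0))
  bias_w <- setNames(ifelse(universe %in% long, 4, 1), universe)
  absorbed <- vapply(seq_len(n_reps), function(i) {
    gs <- sample(universe, 200, prob = bias_w)
    pf <- enrich_fisher(gs, cats, universe)$p
    pw <- enrich_weighted(gs, cats, universe, bias_w)$p
    pw >= pf
  }, TRUE)
  list(max_reduction_err = red_err, bias_absorbed_frac = mean(absorbed))
}
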