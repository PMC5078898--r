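test_that("count_windows matches direct window counts", {
  g <- Genome(c(chr1 = 2000))
  ts <- make_tags(c(100, 150, 1100), genome = g)
  wc <- count_windows(ts, g, 1000, 1000)
  expect_equal(wc$windows$count, c(2, 1))
  expect_equal(wc$windows$start, c(0, 1000))
  # overlapping windows double-count
  wc2 <- count_windows(ts, g, 1000, 500)
  expect_equal(wc2$windows$start, c(0, 500, 1000))
  expect_equal(wc2$windows$end, c(1000, 1500, 2000))
  expect_equal(wc2$windows$count, c(2, 1, 1))
  # empty tag set -> all-zero counts
  wc0 <- count_windows(make_tags(numeric(), genome = g), g, 1000, 500)
  expect_true(all(wc0$windows$count == 0))
  # non-dividing step rejected
  expect_error(count_windows(ts, g, 1000, 300), "divide")
})

test_that("window counts sum to library size when step equals window", {
  ts <- random_tagset(n = 200, seed = 6)
  wc <- count_windows(ts, ts$genome, 500, 500)
  expect_equal(sum(wc$windows$count), ts$library_size)
  # with overlap the sum can only grow
  wc2 <- count_windows(ts, ts$genome, 500, 250)
  expect_gte(sum(wc2$windows$count), ts$library_size)
})

test_that("permutation null is seeded, monotone in alpha, and validates", {
  g <- Genome(c(chr1 = 5e4))
  set.seed(1)
  ts <- make_tags(sort(floor(runif(500) * 5e4)), genome = g)
  n1 <- permutation_null(ts, g, 1000, 500, 100, 0.01, seed = 3)
  n2 <- permutation_null(ts, g, 1000, 500, 100, 0.01, seed = 3)
  expect_identical(n1$hist, n2$hist)
  # threshold is non-increasing in alpha
  alphas <- c(0.2, 0.05, 0.01, 0.001)
  thr <- vapply(alphas, function(a)
    permutation_null(ts, g, 1000, 500, 100, a, seed = 3)$threshold, 0L)
  expect_true(all(diff(thr) >= 0))
  expect_error(permutation_null(ts, g, 1000, 500, 50, 0.01, seed = 1),
               ">= 100")
  # alpha below the attainable resolution
  expect_error(permutation_null(ts, Genome(c(chr1 = 2000)), 1000, 1000,
                                100, 1e-6, seed = 1), "resolution")
})

test_that("empirical p follows the add-one rule and never reaches zero", {
  g <- Genome(c(chr1 = 5e4))
  set.seed(2)
  ts <- make_tags(floor(runif(500) * 5e4), genome = g)
  null <- permutation_null(ts, g, 1000, 500, 100, 0.01, seed = 5)
  expect_equal(empirical_p(null, 0), 1)
  big <- empirical_p(null, 1e6)  # far beyond any null count
  expect_equal(big, 1 / (null$n_null + 1))
  expect_true(all(empirical_p(null, 0:50) > 0))
  expect_true(all(diff(empirical_p(null, 0:50)) <= 0))
})

test_that("book-ended significant windows merge into one domain", {
  g <- Genome(c(chr1 = 4000))
  # step == window: windows [0,1000) and [1000,2000) hot, book-ended
  ts <- make_tags(c(seq(100, 900, by = 40), seq(1050, 1950, by = 40)),
                  genome = g)
  wc <- count_windows(ts, g, 1000, 1000)
  doms <- call_domains(wc, threshold = 10)
  expect_equal(nrow(doms), 1L)
  expect_equal(doms$start, 0)
  expect_equal(doms$end, 2000)
  expect_equal(doms$count, ts$library_size)
})

test_that("overlapping significant windows give one boundary-trimmed domain", {
  g <- Genome(c(chr1 = 4000))
  # tags concentrated in [600, 900): windows [0,1000) and [500,1500) are
  # significant; the call is a single domain trimmed to their overlap core
  ts <- make_tags(seq(600, 896, by = 4), genome = g)
  wc <- count_windows(ts, g, 1000, 500)
  doms <- call_domains(wc, threshold = 20)
  expect_equal(nrow(doms), 1L)
  expect_equal(doms$start, 500)
  expect_equal(doms$end, 1000)
  expect_equal(doms$max_window_count, 75)
})

test_that("no window above threshold gives an empty call", {
  g <- Genome(c(chr1 = 4000))
  ts <- make_tags(c(10, 1500, 3000), genome = g)
  wc <- count_windows(ts, g, 1000, 500)
  expect_equal(nrow(call_domains(wc, threshold = 5)), 0L)
})

test_that("domain calls are invariant to tag order and empty chromosomes", {
  p <- sim_params(chrom_length = 5e5, n_domains = 20, n_genes = 0,
                  n_de = 0, rng_seed = 19)
  gg <- simulate_genome_and_genes(p)
  tr <- simulate_truth(p, gg$genome, gg$genes)
  ts <- simulate_dip_tags(gg$genome, tr, p, "sham", seed = 19)
  cfg <- pipeline_config(n_permutations = 150)
  d1 <- segment_sample(ts, cfg, gg$genome, seed = 23)$domains
  # shuffle tag order
  set.seed(1)
  idx <- sample(nrow(ts$tags))
  ts_sh <- TagSet(ts$sample_id, ts$assay, ts$condition,
                  ts$tags$chrom[idx], ts$tags$pos[idx],
                  ts$tags$strand[idx], gg$genome)
  d2 <- segment_sample(ts_sh, cfg, gg$genome, seed = 23)$domains
  expect_equal(d2, d1)
  # appending an empty chromosome leaves calls unchanged
  g2 <- Genome(c(chr1 = 5e5, chrEmpty = 1e5))
  ts3 <- TagSet(ts$sample_id, ts$assay, ts$condition, ts$tags$chrom,
                ts$tags$pos, ts$tags$strand, g2)
  d3 <- segment_sample(ts3, pipeline_config(n_permutations = 150), g2,
                       seed = 23)$domains
  expect_equal(d3[, c("chrom", "start", "end")],
               d1[, c("chrom", "start", "end")])
})

test_that("window-size optimization maximizes the domain count", {
  p <- sim_params(chrom_length = 5e5, n_domains = 30, n_genes = 0,
                  n_de = 0, rng_seed = 29)
  gg <- simulate_genome_and_genes(p)
  tr <- simulate_truth(p, gg$genome, gg$genes)
  ts <- simulate_dip_tags(gg$genome, tr, p, "sham", seed = 29)
  res <- optimize_window_size(ts, gg$genome, c(500, 1000, 4000),
                              n_permutations = 150, alpha = 1e-4, seed = 31)
  tab <- res$table
  # the chosen size is exactly the argmax of its own audit table,
  # ties broken toward the smaller size
  best <- tab[order(-tab$n_domains, tab$window_bp)][1]
  expect_equal(res$window_bp, best$window_bp)
  expect_equal(nrow(tab), 3L)
  # single candidate comes back unchanged
  one <- optimize_window_size(ts, gg$genome, 1000, n_permutations = 150,
                              alpha = 1e-4, seed = 31)
  expect_equal(one$window_bp, 1000)
  # the conventional default candidate set brackets 1000 bp
  expect_true(1000 %in% eval(formals(optimize_window_size)$candidate_sizes))
})

test_that("duplicate-tag collapsing is exposed but off by default", {
  g <- Genome(c(chr1 = 2000))
  ts <- make_tags(c(5, 5, 5, 10), genome = g)
  expect_equal(ts$library_size, 4L)
  expect_equal(collapse_duplicate_tags(ts)$library_size, 2L)
  expect_false(pipeline_config()$collapse_duplicates)
})
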