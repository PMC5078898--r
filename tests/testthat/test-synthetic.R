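test_that("gene placement is disjoint, seeded, and fails cleanly when infeasible", {
  p <- sim_params(chrom_length = 1e6, n_genes = 50, gene_length_min = 10000,
                  gene_length_max = 10000, n_de = 0, rng_seed = 2)
  gm <- simulate_genome_and_genes(p)$genes
  g <- gm$genes[order(start)]
  expect_equal(nrow(g), 50L)
  expect_true(all(g$start[-1] >= g$end[-nrow(g)]))  # disjoint spans
  expect_true(all(g$end - g$start == 10000))
  # same seed -> identical annotation
  gm2 <- simulate_genome_and_genes(p)$genes
  expect_equal(gm2$genes, gm$genes)
  # infeasible packing
  bad <- sim_params(chrom_length = 10000, n_genes = 200,
                    gene_length_min = 10000, gene_length_max = 10000,
                    n_de = 0, rng_seed = 2)
  expect_error(simulate_genome_and_genes(bad), "increase the genome size")
})

test_that("DIP tag rates match the planted fold (rate arithmetic oracle)", {
  # one 1-kb domain at fold 8 over background 0.01/bp: ~80 tags in-domain
  # vs ~10 per background kb, checked as a mean over 100 replicates
  p <- sim_params(chrom_length = 1e5, background_rate = 0.01, n_domains = 1,
                  domain_length = 1000, domain_fold = 8, n_genes = 0,
                  n_de = 0, rng_seed = 7)
  gg <- simulate_genome_and_genes(p)
  tr <- simulate_truth(p, gg$genome, gg$genes)
  dom <- tr$domains
  in_dom <- bg_per_kb <- numeric(100)
  for (r in 1:100) {
    ts <- simulate_dip_tags(gg$genome, tr, p, "sham", seed = 1000 + r)
    inside <- ts$tags$pos >= dom$start & ts$tags$pos < dom$end
    in_dom[r] <- sum(inside)
    bg_per_kb[r] <- sum(!inside) / (1e5 - 1000) * 1000
  }
  # Poisson SE of the mean over 100 reps: sqrt(80/100) ~ 0.9
  expect_lt(abs(mean(in_dom) - 80), 4 * sqrt(80 / 100))
  expect_lt(abs(mean(bg_per_kb) - 10), 5 * sqrt(10 / 100))
})

test_that("background-only tags are uniform (Poisson window oracle)", {
  p <- sim_params(chrom_length = 1e6, background_rate = 0.01, n_domains = 0,
                  n_genes = 0, n_de = 0, rng_seed = 9)
  gg <- simulate_genome_and_genes(p)
  tr <- simulate_truth(p, gg$genome, gg$genes)
  ts <- simulate_dip_tags(gg$genome, tr, p, "sham", seed = 9)
  wc <- count_windows(ts, gg$genome, 1e5, 1e5)
  # every 100-kb window count within 5 Poisson SD of the expectation
  expect_true(all(abs(wc$windows$count - 1000) < 5 * sqrt(1000)))
})

test_that("library_size controls the expected tag total, zero gives empty", {
  p <- sim_params(chrom_length = 1e6, n_domains = 10, n_genes = 0, n_de = 0,
                  library_size = 0, rng_seed = 3)
  gg <- simulate_genome_and_genes(p)
  tr <- simulate_truth(p, gg$genome, gg$genes)
  ts0 <- simulate_dip_tags(gg$genome, tr, p, "sham")
  expect_equal(ts0$library_size, 0L)
  p$library_size <- 20000
  ts <- simulate_dip_tags(gg$genome, tr, p, "sham", seed = 4)
  expect_lt(abs(ts$library_size - 20000), 5 * sqrt(20000))
})

test_that("in-domain/background rate ratio converges to the planted fold", {
  folds <- vapply(c(2e4, 1e5, 5e5), function(lib) {
    p <- sim_params(chrom_length = 1e6, background_rate = 0.01,
                    n_domains = 20, domain_fold = 8, n_genes = 0, n_de = 0,
                    library_size = lib, rng_seed = 11)
    gg <- simulate_genome_and_genes(p)
    tr <- simulate_truth(p, gg$genome, gg$genes)
    ratio <- vapply(1:5, function(r) {
      ts <- simulate_dip_tags(gg$genome, tr, p, "sham", seed = 100 * r)
      gr_t <- ts$tags$pos
      dom <- tr$domains
      inside <- rep(FALSE, length(gr_t))
      for (i in seq_len(nrow(dom)))
        inside <- inside | (gr_t >= dom$start[i] & gr_t < dom$end[i])
      dlen <- sum(dom$end - dom$start)
      (sum(inside) / dlen) / (sum(!inside) / (1e6 - dlen))
    }, 0)
    mean(ratio)
  }, 0)
  err <- abs(folds - 8)
  expect_lt(err[3], 8 * 0.05)            # 5% at the largest library
  expect_lt(err[3], err[1] + 0.2)        # error shrinks with library size
})

test_that("RNA counts: null case, Poisson limit, determinism", {
  p <- sim_params(chrom_length = 1e6, n_genes = 200,
                  gene_length_min = 1000, gene_length_max = 2000,
                  nb_mean = 50, nb_mean_sdlog = 0, n_de = 0, n_reps = 4,
                  rng_seed = 13)
  gg <- simulate_genome_and_genes(p)
  tr <- simulate_truth(p, gg$genome, gg$genes)
  rna <- simulate_rna_counts(gg$genes, tr, p)
  # log2fc 0 for all genes: condition means equal in expectation
  mA <- mean(rna$counts[, rna$conditions == "sham"])
  mB <- mean(rna$counts[, rna$conditions == "IR"])
  expect_lt(abs(mA - mB) / 50, 0.1)
  # determinism
  rna2 <- simulate_rna_counts(gg$genes, tr, p)
  expect_identical(rna2$counts, rna$counts)
  # dispersion -> 0 limit: variance/mean -> 1 (moment check, >= 10k draws)
  p0 <- p; p0$nb_dispersion <- 0; p0$n_genes <- 200
  pois <- simulate_rna_counts(gg$genes, tr, p0, n_reps = 30)
  vm <- apply(pois$counts, 1, var) / rowMeans(pois$counts)
  expect_lt(abs(mean(vm) - 1), 0.05)
  # positive dispersion inflates variance well beyond Poisson
  vm1 <- apply(rna$counts, 1, var) / rowMeans(rna$counts)
  expect_gt(mean(vm1), 2)
})

test_that("whole datasets are seeded, coupled, and serialize losslessly", {
  p <- sim_params(chrom_length = 5e5, n_domains = 10, n_dmrs = 3,
                  n_genes = 30, gene_length_min = 1000,
                  gene_length_max = 2000, n_de = 10, n_coupled = 4,
                  n_categories = 3, rng_seed = 17)
  ds <- simulate_dataset(p)
  ds2 <- simulate_dataset(p)
  expect_identical(ds2$rna$counts, ds$rna$counts)
  expect_identical(ds2$dip$sham[[1]]$tags, ds$dip$sham[[1]]$tags)
  # coupled genes are a subset of up-regulated DE genes
  de_up <- ds$truth$de_genes$gene_id[ds$truth$de_genes$log2fc > 0]
  expect_true(all(ds$truth$coupled_genes %in% de_up))
  # coupled genes carry an intragenic differential domain
  cdom <- ds$truth$domains[!is.na(ds$truth$domains$coupled_gene)]
  expect_equal(sort(cdom$coupled_gene), sort(ds$truth$coupled_genes))
  expect_true(all(cdom$is_dmr & cdom$direction == "up"))
  # serialization round-trip through the standard formats
  dir <- tempfile()
  paths <- write_dataset(ds, dir)
  g2 <- read_genome(paths$genome)
  expect_equal(g2$chrom_lengths, ds$genome$chrom_lengths)
  ts <- read_tags(paths$tags_sham_pool1, p$assay, "sham", g2)
  expect_equal(ts$tags$pos, ds$dip$sham[[1]]$tags$pos)
  gm <- read_gene_models(paths$genes, g2)
  expect_equal(gm$genes$start, ds$genes$genes$start)
  expect_equal(read_counts(paths$counts), ds$rna$counts)
})
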