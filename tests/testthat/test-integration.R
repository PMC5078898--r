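big_genome <- function() Genome(c(chr1 = 1e6))

one_gene <- function(tss = 200000, strand = "+", len = 10000,
                     id = "geneA", genome = big_genome()) {
  s <- if (strand == "+") tss else tss - len + 1
  genes <- data.table::data.table(gene_id = id, chrom = "chr1",
                                  strand = strand, start = s, end = s + len)
  GeneModels(genes, genes[, .(gene_id, chrom, start, end)], genome)
}

region_at <- function(mid, width = 1000, ...) {
  data.table::data.table(chrom = "chr1", start = mid - width / 2,
                         end = mid + width / 2, ...)
}

test_that("TSS annotation: signed distance, range filter, redundancy rule", {
  gm <- one_gene(tss = 200000, strand = "+")
  # region midpoint 10 kb upstream of the only TSS in range
  ann <- annotate_dmrs(region_at(190000, p = 0.001), gm, 50000)
  expect_equal(ann$gene_id, "geneA")
  expect_equal(ann$distance, -10000)
  # same offset on a minus-strand gene: genomically left = downstream
  gmm <- one_gene(tss = 200000, strand = "-")
  annm <- annotate_dmrs(region_at(190000, p = 0.001), gmm, 50000)
  expect_equal(annm$distance, 10000)
  # 60 kb away at the 50-kb limit -> excluded
  far <- annotate_dmrs(region_at(260000, p = 0.001), gm, 50000)
  expect_equal(nrow(far), 0L)
  # two regions on one gene: only the better-ranked kept
  two <- rbind(region_at(195000, p = 0.5, q = 0.5, ndiff = 10),
               region_at(205000, p = 0.001, q = 0.01, ndiff = 100))
  ann2 <- annotate_dmrs(two, gm, 50000)
  expect_equal(nrow(ann2), 1L)
  expect_equal(ann2$start, 204500)
})

test_that("TSS annotation is deterministic under input shuffling and breaks ties lexicographically", {
  set.seed(31)
  genome <- big_genome()
  genes <- data.table::data.table(
    gene_id = sprintf("g%02d", 1:20), chrom = "chr1", strand = "+",
    start = seq(10000, 960000, length.out = 20),
    end = seq(10000, 960000, length.out = 20) + 5000)
  gm <- GeneModels(genes, genes[, .(gene_id, chrom, start, end)], genome)
  dmrs <- data.table::data.table(
    chrom = "chr1", start = s <- sort(sample(5000, 30) * 30),
    end = s + 2000, p = runif(30), q = runif(30), ndiff = rnorm(30, 0, 80))
  a1 <- annotate_dmrs(dmrs, gm, 50000)
  a2 <- annotate_dmrs(dmrs[sample(nrow(dmrs))], gm, 50000)
  data.table::setkey(a1, start); data.table::setkey(a2, start)
  expect_equal(a1, a2)
  # equidistant tie -> lexicographically smaller gene id
  tie_genes <- data.table::data.table(
    gene_id = c("gB", "gA"), chrom = "chr1", strand = "+",
    start = c(100000, 120000), end = c(105000, 125000))
  gmt <- GeneModels(tie_genes, tie_genes[, .(gene_id, chrom, start, end)],
                    genome)
  tie <- annotate_dmrs(region_at(110000, p = 0.01), gmt, 50000)
  expect_equal(tie$gene_id, "gA")
})

test_that("top-N overlap matches direct hypergeometric summation", {
  universe <- sprintf("g%05d", 1:20000)
  s1 <- universe[1:1000]
  s2 <- c(universe[1:100], universe[1101:2000])  # overlap exactly 100
  r <- topn_overlap(s1, s2, universe)
  expect_equal(r$overlap, 100L)
  j <- 100:1000
  oracle <- sum(exp(lchoose(1000, j) + lchoose(19000, 1000 - j) -
                      lchoose(20000, 1000)))
  expect_lt(abs(r$p - oracle), 1e-10)
  # sharing no genes
  expect_equal(topn_overlap(universe[1:10], universe[11:20], universe)$p, 1)
  expect_error(topn_overlap("a", "b", character()), "universe")
})

test_that("meta-gene matrix: flat coverage, orientation, degenerate input", {
  genome <- big_genome()
  gm <- one_gene(tss = 200000, strand = "+", len = 10000)
  set.seed(41)
  # 10k tags uniform over the gene body -> flat body profile
  ts <- TagSet("s", "5hmC", "x", rep("chr1", 10000),
               floor(runif(10000, 200000, 210000)), genome = genome)
  m <- metagene_matrix(ts, gm, body_bins = 10, flank_bp = 2000,
                       flank_bins = 4)
  body <- m$matrix[1, m$body_cols]
  expect_lt(max(body) / min(body), 1.2)
  expect_true(all(m$matrix[1, -m$body_cols] == 0))
  # median normalization: median positive value is 1
  expect_equal(median(m$matrix[m$matrix > 0]), 1)
  # minus-strand gene: 5' is always on the left
  gmm <- one_gene(tss = 209999, strand = "-", len = 10000)
  tsm <- TagSet("s", "5hmC", "x", rep("chr1", 1000),
                floor(runif(1000, 208000, 210000)), genome = genome)
  mm <- metagene_matrix(tsm, gmm, body_bins = 10, flank_bp = 1000,
                        flank_bins = 2)
  body_m <- mm$matrix[1, mm$body_cols]
  expect_gt(sum(body_m[1:2]), sum(body_m[9:10]))  # 5' half carries the mass
  # all-zero tags: zero matrix, no NaN from the median guard
  ts0 <- TagSet("s", "5hmC", "x", character(), numeric(), genome = genome)
  m0 <- metagene_matrix(ts0, gm, body_bins = 5, flank_bp = 1000,
                        flank_bins = 2)
  expect_true(all(m0$matrix == 0))
  expect_false(anyNA(m0$matrix))
  # flank misconfiguration
  expect_error(metagene_matrix(ts, gm, flank_bp = 0, flank_bins = 3),
               "flank_bp")
})

test_that("the colour ceiling sits at the configured quantile", {
  genome <- big_genome()
  gm <- one_gene()
  set.seed(43)
  ts <- TagSet("s", "5hmC", "x", rep("chr1", 5000),
               floor(runif(5000, 195000, 215000)), genome = genome)
  m <- metagene_matrix(ts, gm, body_bins = 20, flank_bp = 5000,
                       flank_bins = 10, ceiling_quantile = 0.8)
  expect_equal(m$ceiling, unname(quantile(m$matrix, 0.8)))
})

test_that("intragenic difference ranking: identity, antisymmetry, stability", {
  genome <- big_genome()
  genes <- data.table::data.table(
    gene_id = sprintf("g%02d", 1:5), chrom = "chr1", strand = "+",
    start = seq(1e5, 5e5, 1e5), end = seq(1e5, 5e5, 1e5) + 10000)
  gm <- GeneModels(genes, genes[, .(gene_id, chrom, start, end)], genome)
  set.seed(47)
  mk <- function(n) TagSet("s", "5hmC", "x", rep("chr1", n),
                           floor(runif(n, 1e5, 6e5)), genome = genome)
  ma <- metagene_matrix(mk(5000), gm, body_bins = 10, flank_bp = 1000,
                        flank_bins = 2)
  mb <- metagene_matrix(mk(5000), gm, body_bins = 10, flank_bp = 1000,
                        flank_bins = 2)
  # identical matrices -> all scores 0, input order preserved
  same <- rank_intragenic_difference(ma, ma, Inf)
  expect_true(all(same$score == 0))
  expect_equal(same$gene_id, ma$gene_ids)
  # antisymmetry
  ab <- rank_intragenic_difference(ma, mb, Inf)
  ba <- rank_intragenic_difference(mb, ma, Inf)
  ab <- ab[order(gene_id)]; ba <- ba[order(gene_id)]
  expect_equal(ab$score, -ba$score, tolerance = 1e-12)
  # shape mismatch
  mc <- metagene_matrix(mk(1000), gm, body_bins = 5, flank_bp = 1000,
                        flank_bins = 2)
  expect_error(rank_intragenic_difference(ma, mc), "binning")
})
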