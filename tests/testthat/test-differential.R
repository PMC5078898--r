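test_that("merge_regions unions across samples and re-tiles", {
  a <- intervals("chr1", 0, 1000)
  b <- intervals("chr1", 800, 2000)
  un <- merge_regions(list(a, b), resolution_bp = NULL)
  expect_equal(un, intervals("chr1", 0, 2000))
  # book-ended domains merge too
  un2 <- merge_regions(list(intervals("chr1", 0, 1000),
                            intervals("chr1", 1000, 1500)), NULL)
  expect_equal(nrow(un2), 1L)
  # re-tiling clips the last tile
  tiles <- merge_regions(list(intervals("chr1", 0, 12000)), 5000)
  expect_equal(tiles$start, c(0, 5000, 10000))
  expect_equal(tiles$end, c(5000, 10000, 12000))
  # empty input
  expect_equal(nrow(merge_regions(list(), 5000)), 0L)
  expect_equal(nrow(merge_regions(list(a[0]), 5000)), 0L)
})

test_that("chi-square region test: homogeneity, scaling, degenerate cases", {
  r <- test_region_chisq(10, 10, 1000, 1000)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  expect_equal(r$ndiff, 0)
  # both region counts zero -> p = 1 by convention
  r0 <- test_region_chisq(0, 0, 1000, 1000)
  expect_equal(r0$p, 1)
  # doubling all cells decreases p (statistic scales with n)
  r1 <- test_region_chisq(30, 5, 1000, 1000)
  r2 <- test_region_chisq(60, 10, 2000, 2000)
  expect_lt(r2$p, r1$p)
  expect_equal(r2$statistic, 2 * r1$statistic, tolerance = 1e-12)
  # normalized difference rescales condition B to the reference library
  r3 <- test_region_chisq(100, 50, 1000, 2000)
  expect_equal(r3$ndiff, 50 * (1000 / 2000) - 100)
})

test_that("chi-square p approximates the Fisher exact oracle", {
  # hypergeometric tail enumeration as the independent oracle
  fisher_oracle <- function(a, b, c, d) {
    m1 <- a + b; m2 <- c + d; n <- a + c
    j <- max(0, n - m2):min(n, m1)
    pj <- exp(lchoose(m1, j) + lchoose(m2, n - j) - lchoose(m1 + m2, n))
    p_obs <- pj[j == a]
    sum(pj[pj <= p_obs + 1e-12])  # two-sided by probability mass
  }
  ours <- test_region_chisq(30, 5, 1000, 1000)$p
  oracle <- fisher_oracle(30, 970, 5, 995)
  expect_lt(abs(ours - oracle) / oracle, 0.10)
})

test_that("NB region test: null behaviour and the Poisson closed-form limit", {
  cond <- rep(c("A", "B"), each = 3)
  libs <- rep(1e5, 6)
  # identical replicate vectors per condition, no difference
  r <- test_region_nb(c(50, 60, 55, 50, 60, 55), libs, cond)
  expect_gte(r$p, 0.5)
  # all counts zero
  expect_equal(test_region_nb(rep(0, 6), libs, cond)$p, 1)
  # dispersion 0 reduces to the Poisson Wald closed form:
  # z = log((kB/LB)/(kA/LA)) / sqrt(1/kA + 1/kB)
  k <- c(40, 50, 45, 80, 90, 85)
  r0 <- test_region_nb(k, libs, cond, dispersion = 0)
  kA <- sum(k[1:3]); kB <- sum(k[4:6])
  z <- log(kB / kA) / sqrt(1 / kA + 1 / kB)
  expect_equal(r0$statistic, z, tolerance = 1e-10)
  expect_equal(r0$p, 2 * pnorm(-abs(z)), tolerance = 1e-10)
  # one replicate per condition falls back to chi-square with a warning
  expect_warning(rf <- test_region_nb(c(30, 60), c(1e5, 1e5), c("A", "B")),
                 "chi-square")
  expect_equal(rf$statistic,
               test_region_chisq(30, 60, 1e5, 1e5)$statistic)
})

test_that("call_dmrs applies the q and tag-difference filters with direction", {
  tested <- data.table::data.table(
    chrom = "chr1", start = (0:9) * 5000, end = (1:10) * 5000,
    count_a = 100, count_b = 100,
    ndiff = c(60, 20, -70, rep(0, 7)),
    statistic = 0, p = c(1e-5, 1e-5, 1e-5, rep(1, 7)))
  dmrs <- call_dmrs(tested, q_threshold = 0.01, min_tag_diff = 50)
  # q for the three small p is 10/3*1e-5 < 0.01; the |ndiff|=20 region is
  # rejected by the tag-difference filter
  expect_equal(nrow(dmrs), 2L)
  expect_equal(dmrs$direction, c("up", "down"))
  expect_equal(dmrs$assay, c("5hmC", "5hmC"))
  # all p = 1 -> no DMRs
  null <- data.table::copy(tested)[, p := 1]
  expect_equal(nrow(call_dmrs(null)), 0L)
  expect_equal(nrow(call_dmrs(tested[0])), 0L)
})

test_that("BH q-values in DMR records are rank-consistent and bounded", {
  set.seed(4)
  tested <- data.table::data.table(
    chrom = "chr1", start = (0:199) * 5000, end = (1:200) * 5000,
    count_a = 100, count_b = 100, ndiff = rnorm(200, 0, 100),
    statistic = 0, p = runif(200)^2)
  dmrs <- call_dmrs(tested, q_threshold = 1.1, min_tag_diff = 0)
  o <- order(dmrs$p)
  expect_true(all(diff(dmrs$q[o]) >= -1e-12))
  expect_true(all(dmrs$q > 0 & dmrs$q <= 1))
  expect_true(all(dmrs$q >= dmrs$p - 1e-12))
  expect_true(all((dmrs$ndiff >= 0) == (dmrs$direction == "up")))
})

test_that("region tests rank regions consistently across chi-square and NB", {
  p <- sim_params(chrom_length = 2e6, n_domains = 120, n_dmrs = 30,
                  dmr_fold_ratio = 3, n_pools = 2, n_genes = 0, n_de = 0,
                  rng_seed = 37)
  ds <- simulate_dataset(p)
  regions <- merge_regions(list(ds$truth$domains), 5000, ds$genome)
  t_chi <- test_regions(regions, ds$dip$sham, ds$dip$IR, "chisq", ds$genome)
  t_nb <- test_regions(regions, ds$dip$sham, ds$dip$IR, "nb", ds$genome)
  rho <- cor(rank(t_chi$p), rank(t_nb$p), method = "spearman")
  expect_gte(rho, 0.9)
})

test_that("DMR set overlaps: combinatorial oracle and planted sharing", {
  universe <- sprintf("g%03d", 1:10)
  # identical sets of size k in universe N: p = 1 / choose(N, k)
  v <- dmr_venn(list(a = universe[1:3], b = universe[1:3]), universe)
  expect_equal(v$overlap, 3L)
  expect_equal(v$p, 1 / choose(10, 3), tolerance = 1e-12)
  # disjoint sets
  v0 <- dmr_venn(list(a = universe[1:3], b = universe[4:6]), universe)
  expect_equal(v0$overlap, 0L)
  expect_equal(v0$p, 1)
  expect_error(dmr_venn(list(a = "g", b = "g"), character()), "universe")
  # planted sharing across assays is detected
  set.seed(11)
  big <- sprintf("g%05d", 1:5000)
  shared <- sample(big, 150)
  s5mc <- c(shared, sample(setdiff(big, shared), 150))
  s5hmc <- c(shared, sample(setdiff(big, s5mc), 150))
  vs <- dmr_venn(list(mc_up = s5mc, hmc_up = s5hmc), big)
  expect_lt(vs$p, 1e-6)
})

test_that("region-median normalization recenters composition-shifted nulls", {
  # condition B has 20% more depth but identical region composition;
  # with region normalization the null regions stay centred
  set.seed(13)
  g <- Genome(c(chr1 = 1e6))
  mkts <- function(id, n) {
    pos <- floor(runif(n) * 1e6)
    TagSet(id, "5hmC", "x", rep("chr1", n), pos, genome = g)
  }
  a <- mkts("a", 5e4); b <- mkts("b", 6e4)
  regions <- intervals(rep("chr1", 100), (0:99) * 10000,
                       (0:99) * 10000 + 2000)
  tt <- test_regions(regions, list(a), list(b), "chisq", g)
  expect_lt(abs(median(tt$ndiff)), 10)
  expect_gt(mean(tt$p > 0.05), 0.85)
})
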