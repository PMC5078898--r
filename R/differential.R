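#' Merge enriched domains across samples into testing units
#'
#' Takes per-sample enriched-domain tables, forms the union of all
#' intervals (merging overlapping or book-ended domains), and optionally
#' re-tiles the merged territory into testing units of `resolution_bp`
#' (the last tile of each merged region is clipped). Re-tiling into 5-kb
#' units is the default differential testing geometry; set
#' `resolution_bp = NULL` (or `tile = FALSE`) to test whole merged
#' regions.
#'
#' @param domain_lists List of domain tables (each with `chrom`, `start`,
#'   `end`).
#' @param resolution_bp Tile width in bp, or `NULL` for whole regions.
#' @param genome Optional [Genome()].
#' @return Interval `data.table` of testing units.
#' @export
merge_regions <- function(domain_lists, resolution_bp = 5000,
                          genome = NULL) {
  all <- rbindlist(lapply(domain_lists, function(d)
    as.data.table(d)[, .(chrom, start, end)]), use.names = TRUE)
  if (nrow(all) == 0)
    return(data.table(chrom = character(), start = numeric(),
                      end = numeric()))
  red <- GenomicRanges::reduce(as_granges(all, genome), min.gapwidth = 1L)
  un <- from_granges(red)
  if (is.null(resolution_bp)) return(un[order(chrom, start)])
  tiles <- rbindlist(Map(function(cn, s0, e0) {
    s <- seq(s0, e0 - 1, by = resolution_bp)
    data.table(chrom = cn, start = s, end = pmin(s + resolution_bp, e0))
  }, un$chrom, un$start, un$end))
  setorder(tiles, chrom, start)
  tiles[]
}

#' Count tags of each sample in each region
#'
#' @param regions Interval table.
#' @param tag_sets List of [TagSet()]s.
#' @param genome A [Genome()].
#' @return Matrix of counts, one column per tag set (named by sample id).
#' @export
count_region_tags <- function(regions, tag_sets, genome = NULL) {
  gr <- as_granges(as.data.table(regions)[, .(chrom, start, end)], genome)
  m <- vapply(tag_sets, function(ts)
    GenomicRanges::countOverlaps(gr, tags_granges(ts)), numeric(length(gr)))
  if (length(gr) == 0) m <- matrix(0, 0, length(tag_sets))
  m <- matrix(m, nrow = length(gr))
  colnames(m) <- vapply(tag_sets, function(ts) ts$sample_id, "")
  m
}

#' Chi-square test of differential methylation for one region
#'
#' A 2x2 homogeneity test of region count versus remaining library count
#' across the two conditions (continuity correction off). Also returns
#' the library-size-normalized tag difference: condition-B count rescaled
#' to the reference library minus the condition-A count.
#'
#' @param count_a,count_b Pooled region tag counts per condition.
#' @param lib_a,lib_b Pooled library sizes.
#' @param correct Continuity correction (default off).
#' @return List: `statistic`, `p`, `ndiff` (normalized difference),
#'   `raw_diff`.
#' @export
test_region_chisq <- function(count_a, count_b, lib_a, lib_b,
                              correct = FALSE) {
  stopifnot(lib_a > 0, lib_b > 0)
  ndiff <- count_b * (lib_a / lib_b) - count_a
  if (count_a + count_b == 0)
    return(list(statistic = 0, p = 1, ndiff = 0, raw_diff = 0))
  tab <- matrix(c(count_a, lib_a - count_a, count_b, lib_b - count_b), 2)
  ht <- suppressWarnings(chisq.test(tab, correct = correct))
  list(statistic = unname(ht$statistic), p = unname(ht$p.value),
       ndiff = ndiff, raw_diff = count_b - count_a)
}

# Pooled method-of-moments NB dispersion from a matrix of counts
# (regions/genes x samples) given size factors and a condition factor.
# Ratio-of-sums moment estimator: E[s2 - q*mean(1/sf)] = a mu^2 and
# E[q^2 - s2/n] = mu^2, so pooling numerators and denominators over genes
# and conditions cancels the small-sample bias of per-gene ratios.
mom_dispersion <- function(counts, sf, cond, floor = 1e-8) {
  z <- sweep(counts, 2, sf, "/")
  num <- 0; den <- 0
  for (lv in unique(cond)) {
    j <- which(cond == lv)
    if (length(j) < 2) next
    q <- rowMeans(z[, j, drop = FALSE])
    s2 <- apply(z[, j, drop = FALSE], 1, var)
    minv <- mean(1 / sf[j])
    ok <- is.finite(q) & is.finite(s2)
    num <- num + sum(s2[ok] - q[ok] * minv)
    den <- den + sum(q[ok]^2 - s2[ok] / length(j))
  }
  if (den <= 0) return(floor)
  max(num / den, floor)
}

# NB Wald test of a two-group log-ratio with per-sample offsets.
# Group means are fitted by their MLE (count total / offset total); the
# Wald SE comes from the NB Fisher information sum mu_i/(1 + a mu_i).
nb_wald <- function(k, sf, cond, dispersion) {
  lv <- unique(cond)
  ka <- sum(k[cond == lv[1]]); kb <- sum(k[cond == lv[2]])
  sa <- sum(sf[cond == lv[1]]); sb <- sum(sf[cond == lv[2]])
  if (ka + kb == 0) return(list(statistic = 0, p = 1, log2fc = 0))
  # halves added when a group total is zero so the log-ratio is finite
  adj <- (ka == 0 | kb == 0) * 0.5
  mu_a <- (ka + adj) / sa; mu_b <- (kb + adj) / sb
  beta <- log(mu_b / mu_a)
  ia <- sum(sf[cond == lv[1]] * mu_a / (1 + dispersion * sf[cond == lv[1]] * mu_a))
  ib <- sum(sf[cond == lv[2]] * mu_b / (1 + dispersion * sf[cond == lv[2]] * mu_b))
  se <- sqrt(1 / ia + 1 / ib)
  z <- beta / se
  list(statistic = z, p = 2 * pnorm(-abs(z)), log2fc = beta / log(2))
}

#' Negative-binomial test of differential methylation for one region
#'
#' Replicate-aware alternative to [test_region_chisq()]: per-replicate
#' region counts are modelled as negative binomial with library-size
#' offsets and a pooled method-of-moments dispersion; the test is a Wald
#' test on the between-condition log-ratio. With fewer than 2 replicates
#' in either condition it falls back to the chi-square test on pooled
#' counts, with a warning.
#'
#' @param counts Per-replicate region counts (vector over samples).
#' @param lib_sizes Per-replicate library sizes.
#' @param cond Condition label per replicate (2 levels).
#' @param dispersion NB dispersion; normally estimated once across all
#'   regions with the internal pooled method-of-moments estimator (see
#'   [test_regions()]).
#' @return List: `statistic`, `p`, `ndiff`, `raw_diff`.
#' @export
test_region_nb <- function(counts, lib_sizes, cond, dispersion = 0.01) {
  cond <- as.character(cond)
  lv <- unique(cond)
  stopifnot(length(lv) == 2)
  if (min(table(cond)) < 2) {
    warning("fewer than 2 replicates per condition; falling back to chi-square on pooled counts")
    return(test_region_chisq(sum(counts[cond == lv[1]]),
                             sum(counts[cond == lv[2]]),
                             sum(lib_sizes[cond == lv[1]]),
                             sum(lib_sizes[cond == lv[2]])))
  }
  sf <- lib_sizes / mean(lib_sizes)
  r <- nb_wald(counts, sf, cond, dispersion)
  ka <- sum(counts[cond == lv[1]]); kb <- sum(counts[cond == lv[2]])
  la <- sum(lib_sizes[cond == lv[1]]); lb <- sum(lib_sizes[cond == lv[2]])
  list(statistic = r$statistic, p = r$p,
       ndiff = kb * (la / lb) - ka, raw_diff = kb - ka)
}

#' Test all merged regions for differential methylation
#'
#' Applies the chi-square (pooled counts) or negative-binomial
#' (replicate-aware, pooled MoM dispersion) test to every testing unit.
#'
#' @param regions Interval table from [merge_regions()].
#' @param tag_sets_a,tag_sets_b Lists of [TagSet()]s per condition.
#' @param test `"chisq"` or `"nb"`.
#' @param genome A [Genome()].
#' @param diff_mode `"normalized"` or `"raw"` tag difference.
#' @param normalization `"region"` (default): between-condition depth is
#'   estimated by median-of-ratios over the tested regions themselves,
#'   which is robust to the composition shift that differential regions
#'   induce in the total library size; `"library"`: raw library sizes.
#'   With fewer than 50 usable regions the method falls back to library
#'   sizes.
#' @return `data.table`: region columns plus `count_a`, `count_b`,
#'   `ndiff`, `statistic`, `p`.
#' @export
test_regions <- function(regions, tag_sets_a, tag_sets_b,
                         test = c("chisq", "nb"), genome = NULL,
                         diff_mode = c("normalized", "raw"),
                         normalization = c("region", "library")) {
  test <- match.arg(test)
  diff_mode <- match.arg(diff_mode)
  normalization <- match.arg(normalization)
  regions <- as.data.table(regions)[, .(chrom, start, end)]
  if (nrow(regions) == 0)
    return(cbind(regions, data.table(count_a = numeric(),
                                     count_b = numeric(),
                                     ndiff = numeric(),
                                     statistic = numeric(), p = numeric())))
  ca <- count_region_tags(regions, tag_sets_a, genome)
  cb <- count_region_tags(regions, tag_sets_b, genome)
  lib_a <- vapply(tag_sets_a, function(t) t$library_size, 0)
  lib_b <- vapply(tag_sets_b, function(t) t$library_size, 0)
  out <- data.table::copy(regions)
  out[, count_a := rowSums(ca)]
  out[, count_b := rowSums(cb)]
  la <- sum(lib_a); lb <- sum(lib_b)
  counts <- cbind(ca, cb)
  cond <- rep(c("A", "B"), c(ncol(ca), ncol(cb)))
  libs <- c(lib_a, lib_b)
  sf <- libs / mean(libs)
  lb_eff <- lb
  if (normalization == "region" && nrow(out) >= 50) {
    sf_reg <- tryCatch(size_factors(counts), error = function(e) NULL)
    if (!is.null(sf_reg)) {
      sf <- sf_reg / mean(sf_reg)
      # effective condition-B depth on the condition-A scale
      sf2 <- tryCatch(size_factors(cbind(out$count_a, out$count_b)),
                      error = function(e) NULL)
      if (!is.null(sf2)) lb_eff <- la * sf2[2] / sf2[1]
    }
  }
  if (test == "chisq") {
    res <- mapply(function(a, b) {
      r <- test_region_chisq(a, b, la, lb_eff)
      c(r$statistic, r$p, r$ndiff, r$raw_diff)
    }, out$count_a, out$count_b)
  } else {
    if (min(table(cond)) < 2) {
      res <- apply(counts, 1, function(k) {
        r <- suppressWarnings(test_region_nb(k, libs, cond))
        c(r$statistic, r$p, r$ndiff, r$raw_diff)
      })
    } else {
      disp <- mom_dispersion(counts, sf, cond)
      res <- apply(counts, 1, function(k) {
        r <- nb_wald(k, sf, cond, disp)
        ka <- sum(k[cond == "A"]); kb <- sum(k[cond == "B"])
        c(r$statistic, r$p, kb * (la / lb_eff) - ka, kb - ka)
      })
    }
  }
  out[, statistic := res[1, ]]
  out[, p := res[2, ]]
  out[, ndiff := if (diff_mode == "normalized") res[3, ] else res[4, ]]
  out[]
}

#' Call differential methylation regions
#'
#' BH-adjusts the p-values of all tested regions (of one assay) and
#' retains regions with `q < q_threshold` and an absolute (normalized)
#' tag difference above `min_tag_diff` — the q < 0.01 / difference > 50
#' tags convention over 5-kb units. Direction is the sign of the
#' difference in condition B versus A.
#'
#' @param tested Output of [test_regions()].
#' @param q_threshold BH q cut-off.
#' @param min_tag_diff Minimum absolute tag difference.
#' @param assay Assay label stamped on the records.
#' @return `data.table` of DMR records (`q`, `direction` added), one row
#'   per retained region.
#' @export
call_dmrs <- function(tested, q_threshold = 0.01, min_tag_diff = 50,
                      assay = "5hmC") {
  tested <- as.data.table(tested)
  if (nrow(tested) == 0) {
    out <- data.table::copy(tested)
    out[, `:=`(q = numeric(0), direction = character(0),
               assay = character(0))]
    return(out)
  }
  assay_label <- assay
  out <- data.table::copy(tested)
  out[, q := p.adjust(p, method = "BH")]
  out[, assay := assay_label]
  out <- out[q < q_threshold & abs(ndiff) > min_tag_diff]
  out[, direction := ifelse(ndiff >= 0, "up", "down")]
  out[]
}

#' Overlap of DMR gene sets with Fisher significance
#'
#' Pairwise overlap between DMR-derived gene sets (e.g. 5mC up/down vs
#' 5hmC up/down) against a gene universe, with a one-sided Fisher exact
#' (hypergeometric) p per pair — the Venn-diagram statistics.
#'
#' @param sets Named list of character vectors (gene ids).
#' @param universe Character vector of all eligible gene ids.
#' @return `data.table`: set1, set2, n1, n2, overlap, p.
#' @export
dmr_venn <- function(sets, universe) {
  if (length(universe) == 0) stop("empty gene universe")
  sets <- lapply(sets, function(s) intersect(unique(s), universe))
  nm <- names(sets)
  pairs <- utils::combn(seq_along(sets), 2)
  rbindlist(apply(pairs, 2, function(ij) {
    a <- sets[[ij[1]]]; b <- sets[[ij[2]]]
    ov <- length(intersect(a, b))
    data.table(set1 = nm[ij[1]], set2 = nm[ij[2]],
               n1 = length(a), n2 = length(b), overlap = ov,
               p = overlap_fisher_p(ov, length(a), length(b),
                                    length(universe)))
  }))
}

# One-sided (enrichment) hypergeometric tail P(X >= ov).
overlap_fisher_p <- function(ov, n1, n2, n_universe) {
  if (ov == 0) return(1)
  phyper(ov - 1, n1, n_universe - n1, n2, lower.tail = FALSE)
}
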