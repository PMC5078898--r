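#' Count RNA tags per gene
#'
#' A tag is counted for a gene when its position falls inside one of the
#' gene's exons (`mode = "exon"`, the default) or anywhere in the gene
#' span (`mode = "span"`). Tags assignable to more than one gene are
#' ambiguous and dropped; the number dropped is reported.
#'
#' @param rna_tags A [TagSet()] of RNA tags.
#' @param genes A [GeneModels()].
#' @param mode `"exon"` or `"span"`.
#' @return A list: `counts` (named integer vector over all genes),
#'   `n_ambiguous` (tags dropped), `n_unassigned` (intergenic/intronic
#'   tags).
#' @export
count_gene_tags <- function(rna_tags, genes, mode = c("exon", "span")) {
  mode <- match.arg(mode)
  tg <- tags_granges(rna_tags)
  feat <- if (mode == "exon") exons_granges(genes) else genes_granges(genes)
  fid <- if (mode == "exon") genes$exons$gene_id else genes$genes$gene_id
  hits <- GenomicRanges::findOverlaps(tg, feat, ignore.strand = TRUE)
  ht <- unique(data.table(tag = queryHits(hits),
                          gene = fid[subjectHits(hits)]))
  ngene <- ht[, .(n = data.table::uniqueN(gene)), by = tag]
  ambiguous <- ngene$tag[ngene$n > 1]
  ht <- ht[!tag %in% ambiguous]
  cnt <- ht[, .N, by = gene]
  ids <- gene_ids(genes)
  counts <- setNames(integer(length(ids)), ids)
  counts[cnt$gene] <- cnt$N
  list(counts = counts, n_ambiguous = length(ambiguous),
       n_unassigned = rna_tags$library_size - length(ambiguous) - sum(counts))
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization constants: the median across genes of the
#' ratio of each sample's count to the per-gene geometric mean, computed
#' over genes with nonzero geometric mean.
#'
#' @param counts Genes x samples count matrix.
#' @return Numeric vector of size factors.
#' @export
size_factors <- function(counts) {
  lg <- rowMeans(log(counts))
  use <- is.finite(lg)
  if (!any(use)) stop("no gene has all-positive counts; cannot compute size factors")
  apply(counts[use, , drop = FALSE], 2,
        function(k) exp(median(log(k) - lg[use])))
}

#' Negative-binomial differential expression
#'
#' A compact DESeq2-style test, implemented in-package so the pipeline is
#' self-contained: median-of-ratios size factors, a pooled
#' method-of-moments NB dispersion (floored at 1e-8), and a Wald test on
#' the between-condition log-ratio with size-factor offsets. No fold
#' change shrinkage is applied. Genes with all-zero counts get missing
#' p/q and are excluded from multiplicity. Multiple testing uses Storey
#' q-values.
#'
#' @param counts Genes x samples integer matrix (rownames = gene ids).
#' @param conditions Condition label per column (exactly 2 levels, >= 2
#'   replicates each).
#' @param dispersion `"pooled"` (one MoM estimate across genes, default)
#'   or a fixed numeric value.
#' @return `data.table`: `gene_id`, `base_mean`, `log2fc`, `statistic`,
#'   `p`, `q` plus `count_<sample>` columns.
#' @export
test_expression <- function(counts, conditions, dispersion = "pooled") {
  conditions <- as.character(conditions)
  lv <- unique(conditions)
  if (length(lv) != 2) stop("exactly two condition levels required")
  if (min(table(conditions)) < 2)
    stop("at least 2 replicates per condition required")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("gene%05d", seq_len(nrow(counts)))
  sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  nonzero <- rowSums(counts) > 0
  disp <- if (identical(dispersion, "pooled"))
    mom_dispersion(counts[nonzero, , drop = FALSE], sf, conditions)
  else as.numeric(dispersion)
  res <- apply(counts, 1, function(k) {
    if (sum(k) == 0) return(c(NA, NA, NA))
    r <- nb_wald(k, sf, conditions, disp)
    c(r$log2fc, r$statistic, r$p)
  })
  out <- data.table(gene_id = rownames(counts),
                    base_mean = rowMeans(norm),
                    log2fc = res[1, ], statistic = res[2, ], p = res[3, ])
  out[, q := NA_real_]
  out[!is.na(p), q := storey_qvalues(p[!is.na(p)])]
  cbind(out, as.data.table(counts))
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 with the smoother method (natural
#' cubic smoothing spline of `pi0(lambda) = #(p > lambda) / (m (1 -
#' lambda))` over the grid `lambda = 0.05, 0.10, ..., 0.95`, evaluated at
#' the largest lambda, clamped to (0, 1]) and converts p-values to
#' q-values by the step-up rule `q_(i) = min_{j >= i} pi0 m p_(j) / j`.
#' With fewer than 100 p-values the smoother is unstable and pi0 is fixed
#' at 1 (with a warning), which reduces the procedure to BH exactly; the
#' same reduction is available via `pi0 = 1`.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param pi0 Optional fixed pi0 overriding the smoother.
#' @param lambda Grid for the smoother.
#' @return Vector of q-values, same order as `p`.
#' @export
storey_qvalues <- function(p, pi0 = NULL, lambda = seq(0.05, 0.95, 0.05)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 100) {
      warning("fewer than 100 p-values; pi0 smoother unstable, using pi0 = 1")
      pi0 <- 1
    } else {
      pl <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
      fit <- smooth.spline(lambda, pl, df = 3)
      pi0 <- predict(fit, x = max(lambda))$y
      pi0 <- min(max(pi0, 1 / m), 1)
    }
  }
  o <- order(p)
  ro <- order(o)
  q <- pi0 * m * p[o] / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[ro]
}

#' Estimate Storey's pi0 (null proportion) by the smoother method
#' @inheritParams storey_qvalues
#' @return Scalar pi0 estimate in (0, 1].
#' @export
estimate_pi0 <- function(p, lambda = seq(0.05, 0.95, 0.05)) {
  m <- length(p)
  if (m < 100) stop("need at least 100 p-values for the pi0 smoother")
  pl <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
  fit <- smooth.spline(lambda, pl, df = 3)
  min(max(predict(fit, x = max(lambda))$y, 1 / m), 1)
}

#' Significantly regulated gene sets for overlap analyses
#'
#' Returns the ids of genes significant at `q < q_threshold` in the given
#' direction, ranked by p, truncated to `top_n` — the "top N
#' significantly regulated genes" convention (fewer when fewer are
#' significant).
#'
#' @param expr Result of [test_expression()].
#' @param direction `"up"`, `"down"` or `"any"`.
#' @param q_threshold Significance cut-off.
#' @param top_n Maximum set size.
#' @return Character vector of gene ids.
#' @export
top_regulated_genes <- function(expr, direction = c("up", "down", "any"),
                                q_threshold = 0.05, top_n = 1000) {
  direction <- match.arg(direction)
  x <- as.data.table(expr)[!is.na(q) & q < q_threshold]
  if (direction == "up") x <- x[log2fc > 0]
  if (direction == "down") x <- x[log2fc < 0]
  setorder(x, p)
  head(x$gene_id, top_n)
}
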