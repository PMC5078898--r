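#' Annotate differential regions to their nearest TSS
#'
#' Regions are ranked by q, then p, then decreasing absolute tag
#' difference; each region is assigned to the gene with the nearest TSS
#' within `max_dist_bp` of the region anchor (midpoint by default), the
#' list is truncated to `top_n`, and made non-redundant (one record per
#' gene, the best-ranked region kept). Distance is signed relative to
#' gene orientation: negative upstream of the TSS, positive downstream.
#' Equidistant TSS ties break toward the lexicographically smaller gene
#' id.
#'
#' @param dmrs Tested-region table (needs `chrom`, `start`, `end` and,
#'   for ranking, `p` and optionally `q`, `ndiff`).
#' @param genes A [GeneModels()].
#' @param max_dist_bp Maximum anchor-to-TSS distance (50 kb default;
#'   25 kb is the common alternate).
#' @param top_n Keep this many best-ranked annotated regions before
#'   deduplication.
#' @param anchor `"midpoint"` (default) or `"edge"` (nearest region
#'   edge).
#' @return `data.table`: region columns plus `gene_id` and `distance`.
#' @export
annotate_dmrs <- function(dmrs, genes, max_dist_bp = 50000, top_n = 2000,
                          anchor = c("midpoint", "edge")) {
  anchor <- match.arg(anchor)
  dmrs <- as.data.table(dmrs)
  if (nrow(dmrs) == 0) {
    out <- data.table::copy(dmrs)
    out[, `:=`(gene_id = character(0), distance = numeric(0))]
    return(out)
  }
  # rank key: q, then p, then |ndiff| descending
  qv <- if ("q" %in% names(dmrs)) dmrs$q else rep(NA_real_, nrow(dmrs))
  pv <- if ("p" %in% names(dmrs)) dmrs$p else rep(NA_real_, nrow(dmrs))
  nd <- if ("ndiff" %in% names(dmrs)) abs(dmrs$ndiff) else rep(0, nrow(dmrs))
  ord <- order(qv, pv, -nd, na.last = TRUE)
  dmrs <- dmrs[ord]
  mid <- floor((dmrs$start + dmrs$end) / 2)
  # one TSS record per (chrom, position): smaller gene_id wins ties there
  tss <- genes$genes[, .(gene_id, chrom, strand, tss)]
  setorder(tss, chrom, tss, gene_id)
  tss <- tss[!duplicated(paste(chrom, tss))]
  gene_id_hit <- rep(NA_character_, nrow(dmrs))
  dist_hit <- rep(NA_real_, nrow(dmrs))
  for (cn in unique(dmrs$chrom)) {
    tc <- tss[chrom == cn]
    ri <- which(dmrs$chrom == cn)
    if (nrow(tc) == 0 || !length(ri)) next
    m <- mid[ri]
    i <- findInterval(m, tc$tss)
    left <- pmax(i, 1L); right <- pmin(i + 1L, nrow(tc))
    if (anchor == "midpoint") {
      dl <- abs(m - tc$tss[left]); dr <- abs(m - tc$tss[right])
    } else {
      s <- dmrs$start[ri]; e <- dmrs$end[ri] - 1
      edge_dist <- function(tp) pmax(pmax(s - tp, tp - e), 0)
      dl <- edge_dist(tc$tss[left]); dr <- edge_dist(tc$tss[right])
    }
    dl[i < 1] <- Inf
    # tie toward smaller gene_id
    use_r <- dr < dl | (dr == dl & tc$gene_id[right] < tc$gene_id[left])
    pick <- ifelse(use_r, right, left)
    d <- pmin(dl, dr)
    ok <- d <= max_dist_bp
    g <- tc[pick]
    sgn_pos <- m - g$tss                 # genomic offset anchor - TSS
    signed <- ifelse(g$strand == "+", sgn_pos, -sgn_pos)
    gene_id_hit[ri[ok]] <- g$gene_id[ok]
    dist_hit[ri[ok]] <- signed[ok]
  }
  out <- data.table::copy(dmrs)
  out[, gene_id := gene_id_hit]
  out[, distance := dist_hit]
  out <- out[!is.na(gene_id)]
  out <- head(out, top_n)
  out <- out[!duplicated(gene_id)]
  out[]
}

#' Top-N methylation/expression overlap test
#'
#' 2x2 one-sided Fisher exact (hypergeometric) test of the overlap
#' between two gene sets within a universe — the top-1000
#' DIP-region-genes versus top-1000 regulated-genes analysis.
#'
#' @param set1,set2 Character vectors of gene ids (clipped to the
#'   universe).
#' @param universe All eligible gene ids (non-empty).
#' @return List: `n1`, `n2`, `overlap`, `n_universe`, `p`.
#' @export
topn_overlap <- function(set1, set2, universe) {
  if (length(universe) == 0) stop("empty gene universe")
  universe <- unique(universe)
  s1 <- intersect(unique(set1), universe)
  s2 <- intersect(unique(set2), universe)
  ov <- length(intersect(s1, s2))
  list(n1 = length(s1), n2 = length(s2), overlap = ov,
       n_universe = length(universe),
       p = overlap_fisher_p(ov, length(s1), length(s2), length(universe)))
}

#' Meta-gene tag-density matrix
#'
#' Rows are genes in the supplied order (typically sorted by an
#' expression statistic); columns are `flank_bins` fixed-bp bins on the
#' 5' flank, `body_bins` bins of the gene body rescaled to a common
#' length, and `flank_bins` on the 3' flank. Values are tags per bp per
#' bin, median-normalized (matrix divided by its median positive value);
#' rows of minus-strand genes are flipped so 5' is always on the left.
#' The colour ceiling for rendering is the configured quantile of the
#' normalized values.
#'
#' @param tags A [TagSet()].
#' @param genes A [GeneModels()].
#' @param gene_order Character vector of gene ids defining row order
#'   (default: annotation order).
#' @param body_bins Bins across the gene body.
#' @param flank_bp,flank_bins Flank width (bp) and bin count per flank
#'   (`flank_bins = 0` disables flanks).
#' @param ceiling_quantile Quantile for the rendering ceiling.
#' @return A `MetaGeneMatrix`: `matrix` (genes x bins), `gene_ids`,
#'   `body_cols`, `ceiling`, and the binning parameters.
#' @export
metagene_matrix <- function(tags, genes, gene_order = gene_ids(genes),
                            body_bins = 30, flank_bp = 2000,
                            flank_bins = 10, ceiling_quantile = 0.80) {
  if (flank_bins > 0 && flank_bp <= 0)
    stop("flank_bp must be positive when flank_bins > 0")
  stopifnot(body_bins >= 1, all(gene_order %in% gene_ids(genes)))
  g <- genes$genes[match(gene_order, gene_id)]
  if (any(g$end - g$start < body_bins))
    stop("all genes must be longer than body_bins bp")
  genome <- tags$genome
  ncol_total <- body_bins + 2 * flank_bins
  # per-gene bin edges in genomic coordinates, 5'->3' left to right later
  edges <- lapply(seq_len(nrow(g)), function(i) {
    s <- g$start[i]; e <- g$end[i]
    body <- s + round(seq(0, e - s, length.out = body_bins + 1))
    if (flank_bins > 0) {
      fw <- flank_bp / flank_bins
      upstream <- s - rev(seq_len(flank_bins)) * fw
      downstream <- e + seq_len(flank_bins) * fw
      c(upstream, body, downstream)
    } else body
  })
  starts <- unlist(lapply(edges, function(e) e[-length(e)]))
  ends <- unlist(lapply(edges, function(e) e[-1]))
  chroms <- rep(g$chrom, each = ncol_total)
  clen <- chrom_length(genome, chroms)
  cs <- pmax(pmin(starts, clen), 0)
  ce <- pmax(pmin(ends, clen), 0)
  width <- ce - cs
  cnt <- numeric(length(cs))
  ok <- width > 0
  if (any(ok)) {
    bins <- as_granges(data.table(chrom = chroms[ok], start = cs[ok],
                                  end = ce[ok]), genome)
    cnt[ok] <- GenomicRanges::countOverlaps(bins, tags_granges(tags))
  }
  dens <- ifelse(width > 0, cnt / width, 0)
  mat <- matrix(dens, nrow = nrow(g), ncol = ncol_total, byrow = TRUE)
  flip <- g$strand == "-"
  mat[flip, ] <- mat[flip, ncol_total:1, drop = FALSE]
  med <- median(mat[mat > 0])
  if (is.finite(med) && med > 0) mat <- mat / med
  rownames(mat) <- g$gene_id
  ceiling_val <- if (any(mat > 0)) quantile(mat, ceiling_quantile) else 0
  structure(list(matrix = mat, gene_ids = g$gene_id,
                 body_cols = (flank_bins + 1):(flank_bins + body_bins),
                 body_bins = body_bins, flank_bp = flank_bp,
                 flank_bins = flank_bins,
                 ceiling = unname(ceiling_val),
                 ceiling_quantile = ceiling_quantile),
            class = "MetaGeneMatrix")
}

#' @export
print.MetaGeneMatrix <- function(x, ...) {
  cat(sprintf("MetaGeneMatrix: %d genes x %d bins (body %d), ceiling %.3g (q%.2f)\n",
              nrow(x$matrix), ncol(x$matrix), x$body_bins, x$ceiling,
              x$ceiling_quantile))
  invisible(x)
}

#' Render a meta-gene matrix as a heatmap
#'
#' Values are clipped at the matrix's configured quantile ceiling, rows
#' drawn top-to-bottom in matrix order.
#'
#' @param x A `MetaGeneMatrix`.
#' @param main Title.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, the clipped matrix.
#' @export
plot.MetaGeneMatrix <- function(x, main = "meta-gene tag density", ...) {
  m <- pmin(x$matrix, if (x$ceiling > 0) x$ceiling else Inf)
  graphics::image(t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  axes = FALSE, main = main, ...)
  invisible(m)
}

#' Rank genes by normalized intragenic tag-density difference
#'
#' Per gene, the score is the sum over gene-body bins of the density
#' difference (condition B minus condition A) of two meta-gene matrices
#' sharing gene order and binning, each already median-normalized. Genes
#' are returned in descending score order (stable for ties); the top-500
#' convention selects the most up-regulated regions.
#'
#' @param mat_a,mat_b `MetaGeneMatrix` objects for the two conditions.
#' @param top_n How many genes to return (`Inf` for all).
#' @return `data.table`: `gene_id`, `score`, `rank`.
#' @export
rank_intragenic_difference <- function(mat_a, mat_b, top_n = 500) {
  if (!identical(dim(mat_a$matrix), dim(mat_b$matrix)) ||
      !identical(mat_a$gene_ids, mat_b$gene_ids) ||
      !identical(mat_a$body_cols, mat_b$body_cols))
    stop("matrices must share gene order and binning")
  d <- mat_b$matrix[, mat_a$body_cols, drop = FALSE] -
    mat_a$matrix[, mat_a$body_cols, drop = FALSE]
  score <- rowSums(d)
  o <- order(-score)  # stable: ties keep input order
  out <- data.table(gene_id = mat_a$gene_ids[o], score = score[o],
                    rank = seq_along(o))
  head(out, top_n)
}
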