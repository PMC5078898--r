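#' Read a category map (TSV: category, gene)
#'
#' Gene-set databases (GO, KEGG, custom) are supplied as a two-column
#' TSV; content is never bundled with the package.
#'
#' @param path TSV file with columns `category`, `gene_id` (header
#'   optional).
#' @return `data.table` with columns `category`, `gene_id`.
#' @export
read_categories <- function(path) {
  dt <- fread(path, header = "auto", sep = "\t")
  data.table::setnames(dt, seq_len(2), c("category", "gene_id"))
  dt[, .(category = as.character(category), gene_id = as.character(gene_id))]
}

category_list <- function(categories) {
  categories <- as.data.table(categories)
  split(categories$gene_id, categories$category)
}

#' Fisher exact gene-set enrichment
#'
#' One-sided (enrichment) hypergeometric test per category of the overlap
#' between `gene_set` and the category members within `universe`, with BH
#' q-values across categories. Categories empty after intersection with
#' the universe are skipped. The conventional significance call is
#' q < 0.01.
#'
#' @param gene_set Character vector of selected gene ids (subset of
#'   `universe`).
#' @param categories Category map (`data.table` category/gene_id, or a
#'   named list of id vectors).
#' @param universe All eligible gene ids.
#' @param depletion Test depletion instead of enrichment.
#' @return `data.table`: `category`, `n_category`, `n_overlap`,
#'   `odds_ratio`, `p`, `q`.
#' @export
enrich_fisher <- function(gene_set, categories, universe,
                          depletion = FALSE) {
  if (length(universe) == 0) stop("empty gene universe")
  universe <- unique(universe)
  gene_set <- intersect(unique(gene_set), universe)
  cl <- if (is.data.frame(categories)) category_list(categories)
        else categories
  cl <- lapply(cl, function(g) intersect(unique(g), universe))
  keep <- lengths(cl) > 0
  if (any(!keep))
    message(sum(!keep), " categor(ies) empty after intersecting the universe; skipped")
  cl <- cl[keep]
  N <- length(universe); n <- length(gene_set)
  out <- rbindlist(lapply(names(cl), function(nm) {
    K <- length(cl[[nm]])
    x <- length(intersect(gene_set, cl[[nm]]))
    p <- if (depletion) phyper(x, K, N - K, n)
         else overlap_fisher_p(x, K, n, N)
    or <- (x * (N - K - n + x)) / pmax((K - x) * (n - x), .Machine$double.eps)
    data.table(category = nm, n_category = K, n_overlap = x,
               odds_ratio = or, p = p)
  }))
  if (nrow(out)) out[, q := p.adjust(p, "BH")]
  out[]
}

# Wallenius noncentral hypergeometric pmf by numerical integration of
# P(X = x) = C(m1,x) C(m2,n-x) Integral_0^1 (1-t^(w/D))^x (1-t^(1/D))^(n-x) dt
# with D = w (m1 - x) + (m2 - (n - x)).
wallenius_pmf <- function(x, m1, m2, n, w) {
  lo <- max(0L, n - m2); hi <- min(n, m1)
  if (x < lo || x > hi) return(0)
  D <- w * (m1 - x) + (m2 - (n - x))
  if (D <= 0) D <- .Machine$double.eps
  lg <- lchoose(m1, x) + lchoose(m2, n - x)
  f <- function(t) {
    lt <- suppressWarnings(
      x * log1p(-t^(w / D)) + (n - x) * log1p(-t^(1 / D)))
    v <- exp(lg + lt)
    v[!is.finite(v)] <- 0
    v
  }
  val <- tryCatch(integrate(f, 0, 1, rel.tol = 1e-10,
                            subdivisions = 500L)$value,
                  error = function(e) NA_real_)
  if (is.na(val))
    val <- integrate(f, 0, 1, rel.tol = 1e-6, subdivisions = 2000L,
                     stop.on.error = FALSE)$value
  val
}

# One-sided (enrichment) Wallenius tail P(X >= x), renormalized over the
# support to absorb quadrature drift.
wallenius_tail_p <- function(x, m1, m2, n, w) {
  lo <- max(0L, n - m2); hi <- min(n, m1)
  pm <- vapply(lo:hi, wallenius_pmf, 0, m1 = m1, m2 = m2, n = n, w = w)
  tot <- sum(pm)
  if (tot <= 0) return(1)
  sum(pm[(lo:hi) >= x]) / tot
}

#' Length-bias-aware gene-set enrichment (Wallenius)
#'
#' Weighted alternative to [enrich_fisher()] correcting selection bias of
#' the kind RNA-Seq gene length induces: under the null, genes are drawn
#' into the set with probability proportional to their weight, so a
#' category of heavy (long) genes is expected to overlap the set more
#' than at random. The null is the Wallenius noncentral hypergeometric
#' distribution whose odds for a category are the mean weight of its
#' members divided by the mean weight of non-members. With all weights
#' equal it reduces exactly to the Fisher test.
#'
#' @inheritParams enrich_fisher
#' @param weights Named positive weights, one per universe gene (e.g.
#'   mappable length).
#' @return `data.table`: `category`, `n_category`, `n_overlap`, `odds`,
#'   `p`, `q`.
#' @export
enrich_weighted <- function(gene_set, categories, universe, weights) {
  if (length(universe) == 0) stop("empty gene universe")
  universe <- unique(universe)
  w <- weights[universe]
  if (anyNA(w)) stop("weights must cover every universe gene")
  if (any(w <= 0)) stop("weights must be positive")
  gene_set <- intersect(unique(gene_set), universe)
  cl <- if (is.data.frame(categories)) category_list(categories)
        else categories
  cl <- lapply(cl, function(g) intersect(unique(g), universe))
  cl <- cl[lengths(cl) > 0]
  N <- length(universe); n <- length(gene_set)
  out <- rbindlist(lapply(names(cl), function(nm) {
    memb <- universe %in% cl[[nm]]
    K <- sum(memb)
    x <- length(intersect(gene_set, cl[[nm]]))
    odds <- mean(w[memb]) / mean(w[!memb])
    if (!is.finite(odds) || K == N) odds <- 1
    p <- if (n == 0) 1 else wallenius_tail_p(x, K, N - K, n, odds)
    data.table(category = nm, n_category = K, n_overlap = x, odds = odds,
               p = p)
  }))
  if (nrow(out)) out[, q := p.adjust(p, "BH")]
  out[]
}

#' KS rank test of a gene statistic inside vs outside a category
#'
#' Two-sample Kolmogorov-Smirnov test comparing the distribution of a
#' per-gene statistic for category members against non-members.
#' Categories with fewer than 3 members in the universe are skipped
#' (`NA`). Ties are handled by the two-sample statistic itself and the
#' result does not depend on tie order.
#'
#' @param statistic Named numeric vector: the ranked statistic, one value
#'   per universe gene.
#' @param categories Category map (as in [enrich_fisher()]).
#' @return `data.table`: `category`, `n_category`, `D`, `p`, `q`.
#' @export
enrich_ks <- function(statistic, categories) {
  if (is.null(names(statistic))) stop("statistic must be named by gene id")
  universe <- names(statistic)
  cl <- if (is.data.frame(categories)) category_list(categories)
        else categories
  cl <- lapply(cl, function(g) intersect(unique(g), universe))
  out <- rbindlist(lapply(names(cl), function(nm) {
    memb <- universe %in% cl[[nm]]
    if (sum(memb) < 3 || sum(!memb) < 3)
      return(data.table(category = nm, n_category = sum(memb),
                        D = NA_real_, p = NA_real_))
    ht <- suppressWarnings(ks.test(statistic[memb], statistic[!memb]))
    data.table(category = nm, n_category = sum(memb),
               D = unname(ht$statistic), p = ht$p.value)
  }))
  if (nrow(out)) out[, q := NA_real_][!is.na(p), q := p.adjust(p, "BH")]
  out[]
}
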