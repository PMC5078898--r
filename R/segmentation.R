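# Sliding-window segmentation against a Monte-Carlo permutation background.
#
# Window counting is done on base bins of width `step_bp` (tabulate + rolling
# sum), which makes the permutation loop cheap: redrawing tags uniformly per
# chromosome is equivalent to a multinomial draw over base bins, so no
# per-tag positions are ever materialized in the null.

window_layout <- function(chrom_len, window_bp, step_bp) {
  nbins <- as.integer(ceiling(chrom_len / step_bp))
  k <- as.integer(window_bp / step_bp)
  starts <- (seq_len(nbins) - 1) * step_bp
  ends <- pmin(starts + window_bp, chrom_len)
  # windows sharing an end are suffixes of the first such window; drop them
  keep <- !duplicated(ends)
  list(nbins = nbins, k = k, starts = starts[keep], ends = ends[keep],
       sbin = which(keep) - 1L)  # 0-based index of each window's first bin
}

rolling_counts <- function(binc, layout) {
  cum <- c(0, cumsum(binc))
  ebin <- pmin(layout$sbin + layout$k, layout$nbins)
  cum[ebin + 1L] - cum[layout$sbin + 1L]
}

bin_tags <- function(pos, chrom_len, step_bp, nbins) {
  tabulate(pmin(floor(pos / step_bp), nbins - 1L) + 1L, nbins)
}

#' Count tags in sliding windows
#'
#' Tiles every chromosome with half-open windows of width `window_bp`
#' starting every `step_bp` bp (the step must divide the width) and counts
#' the tag points falling in each window. Windows are clipped at the
#' chromosome end; clipped windows wholly contained in their predecessor
#' are dropped, so with `step_bp == window_bp` the window counts sum to
#' the library size.
#'
#' @param tags A [TagSet()].
#' @param genome A [Genome()] (defaults to the TagSet's own).
#' @param window_bp Window width (bp).
#' @param step_bp Window step (bp); must divide `window_bp`.
#' @return A `WindowCounts` object: the window table plus the base-bin
#'   counts reused by [call_domains()] and [permutation_null()].
#' @export
count_windows <- function(tags, genome = tags$genome, window_bp = 1000,
                          step_bp = window_bp / 2) {
  stopifnot(step_bp >= 1, window_bp >= step_bp)
  if (window_bp %% step_bp != 0) stop("step_bp must divide window_bp")
  per_chrom <- lapply(seq_along(genome$chrom_names), function(i) {
    cn <- genome$chrom_names[i]
    len <- genome$chrom_lengths[i]
    lay <- window_layout(len, window_bp, step_bp)
    pos <- tags$tags$pos[tags$tags$chrom == cn]
    binc <- bin_tags(pos, len, step_bp, lay$nbins)
    list(chrom = cn, layout = lay, binc = binc,
         counts = rolling_counts(binc, lay))
  })
  windows <- rbindlist(lapply(per_chrom, function(pc)
    data.table(chrom = pc$chrom, start = pc$layout$starts,
               end = pc$layout$ends, count = pc$counts)))
  structure(list(window_bp = window_bp, step_bp = step_bp,
                 windows = windows, per_chrom = per_chrom, genome = genome,
                 library_size = tags$library_size,
                 sample_id = tags$sample_id),
            class = "WindowCounts")
}

#' @export
print.WindowCounts <- function(x, ...) {
  cat(sprintf("WindowCounts: %d windows of %d bp (step %d) over %d tags\n",
              nrow(x$windows), as.integer(x$window_bp),
              as.integer(x$step_bp), x$library_size))
  invisible(x)
}

#' Monte-Carlo permutation background for window counts
#'
#' Re-places all tags uniformly at random within their chromosome
#' (preserving per-chromosome totals) `n_permutations` times and pools the
#' resulting per-window counts into an empirical null distribution. The
#' enrichment threshold is the smallest count `c` whose null tail
#' probability `P(count > c)` does not exceed `alpha`.
#'
#' @param tags A [TagSet()].
#' @param genome A [Genome()].
#' @param window_bp,step_bp Window geometry as in [count_windows()].
#' @param n_permutations Number of permutations (>= 100).
#' @param alpha Tail probability for the threshold.
#' @param seed Integer seed.
#' @return A `PermutationNull` object with the pooled null histogram,
#'   `threshold`, and tail metadata.
#' @export
permutation_null <- function(tags, genome = tags$genome, window_bp = 1000,
                             step_bp = window_bp / 2, n_permutations = 500,
                             alpha = 1e-4, seed = 1L) {
  stopifnot(window_bp %% step_bp == 0)
  if (n_permutations < 100) stop("n_permutations must be >= 100")
  chroms <- genome$chrom_names
  layouts <- lapply(seq_along(chroms), function(i)
    window_layout(genome$chrom_lengths[i], window_bp, step_bp))
  n_tags <- vapply(chroms, function(cn) sum(tags$tags$chrom == cn), 0)
  # chromosomes without tags contribute no background information (their
  # observed windows are all zero) and are excluded from the pooled null,
  # so adding an empty chromosome never changes the threshold
  use <- n_tags > 0
  n_windows <- sum(vapply(layouts[use], function(l) length(l$starts), 0))
  n_null <- n_permutations * n_windows
  if (n_null > 0 && 1 / (n_null + 1) > alpha)
    stop("n_permutations too small for alpha = ", alpha,
         ": minimum resolution is 1/(n_permutations x n_windows) = ",
         format(1 / n_null, digits = 3))
  if (n_null == 0) {
    return(structure(list(hist = integer(1L), n_null = 0L, threshold = 0L,
                          alpha = alpha, n_permutations = n_permutations,
                          n_windows = 0L, window_bp = window_bp,
                          step_bp = step_bp, seed = seed),
                     class = "PermutationNull"))
  }
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  maxc <- 0L
  hist <- integer(1L)  # hist[c+1] = number of null windows with count c
  for (b in seq_len(n_permutations)) {
    for (i in which(use)) {
      pos <- floor(runif(n_tags[i]) * genome$chrom_lengths[i])
      binc <- bin_tags(pos, genome$chrom_lengths[i], step_bp,
                       layouts[[i]]$nbins)
      cnt <- rolling_counts(binc, layouts[[i]])
      m <- max(cnt)
      if (m > maxc) {
        hist <- c(hist, integer(m - maxc))
        maxc <- m
      }
      h <- tabulate(cnt + 1L, maxc + 1L)
      hist <- hist + h
    }
  }
  tail_ge <- rev(cumsum(rev(hist)))  # tail_ge[c+1] = #null >= c
  thr_idx <- which(c(tail_ge[-1], 0) / n_null <= alpha)[1]  # P(X > c)
  structure(list(hist = hist, n_null = n_null, threshold = thr_idx - 1L,
                 alpha = alpha, n_permutations = n_permutations,
                 n_windows = n_windows, window_bp = window_bp,
                 step_bp = step_bp, seed = seed),
            class = "PermutationNull")
}

#' @export
print.PermutationNull <- function(x, ...) {
  cat(sprintf(paste0("PermutationNull: %d permutations x %d windows, ",
                     "alpha %g -> count threshold %d\n"),
              x$n_permutations, x$n_windows, x$alpha, x$threshold))
  invisible(x)
}

#' Empirical tail p-value from a permutation null
#'
#' Uses the add-one rule `(r + 1) / (n + 1)` where `r` is the number of
#' pooled null window counts at least as large as the observed count, so
#' p is never zero.
#'
#' @param null A `PermutationNull`.
#' @param count Observed window count(s).
#' @return Empirical p-value(s) in (0, 1].
#' @export
empirical_p <- function(null, count) {
  tail_ge <- rev(cumsum(rev(null$hist)))  # tail_ge[c+1] = #null >= c
  maxc <- length(tail_ge) - 1L
  r <- numeric(length(count))
  inb <- count <= maxc
  r[inb] <- tail_ge[count[inb] + 1L]
  (r + 1) / (null$n_null + 1)
}

#' Call enriched domains from window counts
#'
#' Windows whose count exceeds `threshold` are merged when overlapping or
#' book-ended into enriched domains. Each domain reports its maximum
#' window count, the exact tag count within the merged interval, and the
#' minimum empirical window p from the permutation null (when supplied).
#'
#' @param wc A `WindowCounts` from [count_windows()].
#' @param threshold Count threshold, normally `null$threshold`.
#' @param null Optional `PermutationNull` for empirical p-values.
#' @return A `data.table` of domains: `chrom`, `start`, `end`,
#'   `n_windows`, `max_window_count`, `count`, `p`.
#' @export
call_domains <- function(wc, threshold, null = NULL) {
  empty <- data.table(chrom = character(), start = numeric(),
                      end = numeric(), n_windows = integer(),
                      max_window_count = numeric(), count = numeric(),
                      p = numeric())
  sig <- wc$windows[count > threshold]
  if (nrow(sig) == 0) return(empty)
  gr <- as_granges(sig[, .(chrom, start, end, count)], wc$genome)
  red <- GenomicRanges::reduce(gr, min.gapwidth = 1L)
  if (wc$step_bp < wc$window_bp) {
    # trim boundaries to the window-intersection core: positions covered
    # by >= 2 overlapping significant windows; isolated single-window
    # calls keep their full window
    core <- GenomicRanges::reduce(
      GenomicRanges::GRanges(IRanges::slice(GenomicRanges::coverage(gr),
                                            lower = 2L, rangesOnly = FALSE)),
      min.gapwidth = 1L)
    uncovered <- red[GenomicRanges::countOverlaps(red, core) == 0]
    red <- sort(c(core, uncovered))
  }
  hits <- GenomicRanges::findOverlaps(gr, red)
  agg <- data.table(dom = subjectHits(hits), count = sig$count[queryHits(hits)])
  agg <- agg[, .(n_windows = .N, max_window_count = max(count)), by = dom]
  setorder(agg, dom)
  out <- from_granges(red)
  out[, n_windows := agg$n_windows]
  out[, max_window_count := agg$max_window_count]
  # exact tag count in the merged interval from base bins (domain bounds
  # are multiples of step_bp or the chromosome end)
  out[, count := {
    cnt <- numeric(.N)
    for (pc in wc$per_chrom) {
      idx <- which(out$chrom == pc$chrom)
      if (length(idx)) {
        cum <- c(0, cumsum(pc$binc))
        sb <- out$start[idx] / wc$step_bp
        eb <- pmin(ceiling(out$end[idx] / wc$step_bp), pc$layout$nbins)
        cnt[idx] <- cum[eb + 1] - cum[sb + 1]
      }
    }
    cnt
  }]
  out[, p := if (is.null(null)) NA_real_ else {
    mp <- numeric(.N)
    hits2 <- data.table(dom = subjectHits(hits),
                        p = empirical_p(null, sig$count[queryHits(hits)]))
    mp <- hits2[, min(p), by = dom][order(dom), V1]
    mp
  }]
  out[]
}

#' Segment one sample
#'
#' Convenience wrapper: [count_windows()], [permutation_null()],
#' [call_domains()] with parameters from a [pipeline_config()].
#'
#' @param tags A [TagSet()].
#' @param config A [pipeline_config()].
#' @param genome A [Genome()].
#' @param seed Seed for the permutation null (defaults to config).
#' @return A list with `domains`, `window_counts` and `null`.
#' @export
segment_sample <- function(tags, config = pipeline_config(),
                           genome = tags$genome, seed = config$rng_seed) {
  ts <- if (config$collapse_duplicates) collapse_duplicate_tags(tags) else tags
  wc <- count_windows(ts, genome, config$window_bp, config$window_step_bp)
  null <- permutation_null(ts, genome, config$window_bp,
                           config$window_step_bp, config$n_permutations,
                           config$enrich_alpha, seed)
  domains <- call_domains(wc, null$threshold, null)
  list(domains = domains, window_counts = wc, null = null)
}

#' Drop duplicate tag coordinates
#'
#' Collapses tags sharing (chrom, position, strand) to a single tag.
#' Whether duplicate tags should be collapsed is a matter of library
#' complexity; the pipeline default keeps them.
#'
#' @param ts A [TagSet()].
#' @return A deduplicated [TagSet()].
#' @export
collapse_duplicate_tags <- function(ts) {
  u <- unique(ts$tags)
  TagSet(ts$sample_id, ts$assay, ts$condition, u$chrom, u$pos, u$strand,
         ts$genome)
}

#' Choose the sliding-window size maximizing the number of enriched regions
#'
#' Runs the full segmentation (permutation null + domain calling) for each
#' candidate window size and returns the size that yields the most
#' domains, ties broken toward the smaller size. The per-size table is
#' returned for audit.
#'
#' @param tags A [TagSet()].
#' @param genome A [Genome()].
#' @param candidate_sizes Window widths to evaluate (bp); the conventional
#'   default set brackets 1000 bp.
#' @param n_permutations,alpha,seed Passed to [permutation_null()].
#' @param step_frac Step as a fraction of the window (default 1/2).
#' @return A list: `window_bp` (chosen size) and `table`
#'   (`data.table` of size, n_domains, threshold).
#' @export
optimize_window_size <- function(tags, genome = tags$genome,
                                 candidate_sizes = c(250, 500, 1000, 2000, 4000),
                                 n_permutations = 500, alpha = 1e-4,
                                 seed = 1L, step_frac = 0.5) {
  if (length(candidate_sizes) < 1) stop("need at least one candidate size")
  tab <- rbindlist(lapply(candidate_sizes, function(w) {
    step <- max(1, w * step_frac)
    if (w %% step != 0) step <- w
    wc <- count_windows(tags, genome, w, step)
    null <- permutation_null(tags, genome, w, step, n_permutations, alpha,
                             seed)
    doms <- call_domains(wc, null$threshold, null)
    data.table(window_bp = w, n_domains = nrow(doms),
               threshold = null$threshold)
  }))
  best <- tab[order(-n_domains, window_bp)][1]
  list(window_bp = best$window_bp, table = tab[])
}

# Seed handling: temporarily set the RNG seed and restore the caller's
# generator state afterwards, so seeded stages do not perturb each other.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
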