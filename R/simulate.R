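#' Simulation parameters
#'
#' Parameters of the synthetic DIP-Seq / RNA-Seq generator. The generator
#' plants (i) enriched domains on a homogeneous Poisson tag background,
#' (ii) differential domains whose rate differs between two conditions by
#' a fold ratio, (iii) negative-binomial RNA counts with a differentially
#' expressed subset, and (iv) a coupled subset of genes that jointly
#' receive an intragenic hydroxymethylation gain and an expression gain.
#'
#' @param n_chrom,chrom_length Genome shape (default one 10-Mb chromosome).
#' @param background_rate Background tag rate, tags per bp (default 0.01,
#'   i.e. 100k tags on the default genome).
#' @param n_domains,domain_length,domain_fold Planted enriched domains:
#'   count, width (bp) and rate fold over background (fold > 1).
#' @param n_dmrs,dmr_fold_ratio,dmr_frac_up Number of planted domains that
#'   additionally change between conditions, their between-condition rate
#'   ratio (> 1), and the fraction changing upward.
#' @param library_size Optional target expected library size; rates are
#'   rescaled so the expected tag total matches. `0` gives an empty
#'   TagSet; `NULL` (default) leaves `background_rate` in charge.
#' @param n_genes,gene_length_min,gene_length_max Gene annotation:
#'   count and uniform length range (bp).
#' @param nb_mean,nb_mean_sdlog,nb_dispersion RNA counts: baseline
#'   negative-binomial mean (per-gene means are log-normal around it with
#'   `sdlog = nb_mean_sdlog`; 0 makes all means equal) and dispersion
#'   (variance = mu + dispersion * mu^2).
#' @param n_de,de_log2fc,de_frac_up Differentially expressed genes:
#'   count (includes the coupled genes), absolute log2 fold change, and
#'   fraction up-regulated among the non-coupled DE genes.
#' @param n_coupled,coupled_log2fc,coupled_domain_frac Coupled genes: each
#'   receives an up-regulated expression change of `coupled_log2fc` and an
#'   intragenic enriched domain covering the central `coupled_domain_frac`
#'   of its body whose rate rises by `dmr_fold_ratio` in the second
#'   condition.
#' @param n_reps RNA replicates per condition.
#' @param n_pools DIP pools (samples) per condition.
#' @param conditions Length-2 condition labels; the first is the
#'   reference.
#' @param assay DIP assay label.
#' @param n_categories,category_size_range Synthetic gene-category map for
#'   the enrichment stage: number of random categories and their size
#'   range; when coupled genes exist an extra category collecting them is
#'   added.
#' @param rng_seed Integer seed driving the whole generator.
#' @return A validated `SimParams` list.
#' @export
sim_params <- function(n_chrom = 1, chrom_length = 10e6,
                       background_rate = 0.01,
                       n_domains = 200, domain_length = 1000,
                       domain_fold = 8,
                       n_dmrs = 0, dmr_fold_ratio = 3, dmr_frac_up = 1,
                       library_size = NULL,
                       n_genes = 500, gene_length_min = 2000,
                       gene_length_max = 10000,
                       nb_mean = 100, nb_mean_sdlog = 0.5,
                       nb_dispersion = 0.1,
                       n_de = 50, de_log2fc = 1, de_frac_up = 0.5,
                       n_coupled = 0, coupled_log2fc = 2,
                       coupled_domain_frac = 1,
                       n_reps = 4, n_pools = 2,
                       conditions = c("sham", "IR"),
                       assay = "5hmC",
                       n_categories = 0, category_size_range = c(20, 100),
                       rng_seed = 1L) {
  p <- as.list(environment())
  p$rng_seed <- as.integer(rng_seed)
  stopifnot(n_chrom >= 1, chrom_length > 0, background_rate > 0,
            n_domains >= 0, domain_length > 0, domain_fold > 1,
            n_dmrs >= 0, n_dmrs <= n_domains, dmr_fold_ratio > 1,
            dmr_frac_up >= 0, dmr_frac_up <= 1,
            n_genes >= 0, gene_length_min > 0,
            gene_length_max >= gene_length_min,
            nb_mean > 0, nb_mean_sdlog >= 0, nb_dispersion >= 0,
            n_de >= 0, n_de <= n_genes, de_log2fc >= 0,
            n_coupled >= 0, n_coupled <= n_de,
            coupled_domain_frac > 0, coupled_domain_frac <= 1,
            n_reps >= 1, n_pools >= 1, length(conditions) == 2)
  if (!is.null(library_size) && library_size < 0)
    stop("library_size must be >= 0")
  structure(p, class = "SimParams")
}

#' Simulate a genome with non-overlapping gene models
#'
#' Genes are laid out uniformly at random without overlap: lengths are
#' drawn uniformly from the configured range, chromosomes are filled
#' proportionally to their length, and the free space between genes is cut
#' by a uniform Dirichlet stick-breaking, which makes placement exchange-
#' able and reproducible from the seed. Each gene is a single exon
#' spanning its body (multi-exon structures can be supplied externally).
#'
#' @param params A [sim_params()].
#' @param seed Seed (defaults to `params$rng_seed`).
#' @return `list(genome, genes)` with a [Genome()] and [GeneModels()].
#' @export
simulate_genome_and_genes <- function(params = sim_params(),
                                      seed = params$rng_seed) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  lens <- rep(params$chrom_length, params$n_chrom)
  genome <- Genome(setNames(lens, paste0("chr", seq_len(params$n_chrom))))
  n <- params$n_genes
  if (n == 0)
    return(list(genome = genome,
                genes = GeneModels(
                  data.table(gene_id = character(), chrom = character(),
                             strand = character(), start = numeric(),
                             end = numeric()),
                  data.table(gene_id = character(), chrom = character(),
                             start = numeric(), end = numeric()), genome)))
  glen <- floor(runif(n, params$gene_length_min, params$gene_length_max + 1))
  # apportion genes to chromosomes proportionally to length
  per_chrom <- floor(n * lens / sum(lens))
  rem <- n - sum(per_chrom)
  if (rem > 0) per_chrom[seq_len(rem)] <- per_chrom[seq_len(rem)] + 1
  idx0 <- cumsum(c(0, per_chrom))
  rows <- vector("list", params$n_chrom)
  for (i in seq_len(params$n_chrom)) {
    k <- per_chrom[i]
    if (k == 0) next
    li <- glen[(idx0[i] + 1):(idx0[i] + k)]
    free <- lens[i] - sum(li)
    if (free < 0)
      stop("cannot place ", k, " genes totalling ", sum(li), " bp on a ",
           lens[i], " bp chromosome; increase the genome size")
    cuts <- sort(runif(k)) * free
    starts <- floor(cuts) + cumsum(c(0, li[-k]))
    rows[[i]] <- data.table(
      gene_id = sprintf("gene%05d", (idx0[i] + 1):(idx0[i] + k)),
      chrom = genome$chrom_names[i],
      strand = sample(c("+", "-"), k, replace = TRUE),
      start = starts, end = starts + li)
  }
  genes <- rbindlist(rows)
  exons <- genes[, .(gene_id, chrom, start, end)]
  list(genome = genome, genes = GeneModels(genes, exons, genome))
}

#' Plant ground truth: domains, differential regions, DE and coupled genes
#'
#' Builds the `SimTruth` used by the tag and count generators and by
#' recovery scoring. Background domains are placed uniformly over the
#' genome; a subset is marked differential (rate fold ratio between
#' conditions). Coupled genes receive an additional intragenic domain,
#' always differential upward, and an upward expression change.
#'
#' @param params A [sim_params()].
#' @param genome,genes From [simulate_genome_and_genes()].
#' @param seed Seed (defaults to `params$rng_seed + 1`).
#' @return A `SimTruth`: `domains` (interval table with `fold`,
#'   `is_dmr`, `fold_ratio`, `direction`, `coupled_gene`), `de_genes`
#'   (`gene_id`, `log2fc`), `coupled_genes` (character).
#' @export
simulate_truth <- function(params, genome, genes,
                           seed = params$rng_seed + 1L) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  # expression truth first: coupled genes are a subset of up-regulated DE
  ids <- gene_ids(genes)
  if (params$n_de > length(ids)) stop("n_de exceeds number of genes")
  de_ids <- if (params$n_de) sample(ids, params$n_de) else character()
  coupled <- head(de_ids, params$n_coupled)
  rest <- setdiff(de_ids, coupled)
  n_up <- round(length(rest) * params$de_frac_up)
  sgn <- c(rep(1, n_up), rep(-1, length(rest) - n_up))
  de <- data.table(gene_id = c(coupled, rest),
                   log2fc = c(rep(params$coupled_log2fc,
                                  length(coupled)),
                              sgn * params$de_log2fc))
  # background domains, uniform over the genome
  nd <- params$n_domains
  ci <- sample.int(params$n_chrom, nd, replace = TRUE,
                   prob = genome$chrom_lengths)
  maxs <- genome$chrom_lengths[ci] - params$domain_length
  if (nd && any(maxs < 0)) stop("domain_length exceeds chromosome length")
  st <- floor(runif(nd) * (maxs + 1))
  dom <- data.table(chrom = genome$chrom_names[ci], start = st,
                    end = st + params$domain_length,
                    fold = params$domain_fold, is_dmr = FALSE,
                    fold_ratio = 1, direction = NA_character_,
                    coupled_gene = NA_character_)
  if (params$n_dmrs) {
    pick <- sample.int(nd, params$n_dmrs)
    nu <- round(params$n_dmrs * params$dmr_frac_up)
    up <- pick[seq_len(nu)]
    dn <- setdiff(pick, up)
    dom[pick, `:=`(is_dmr = TRUE, fold_ratio = params$dmr_fold_ratio)]
    dom[up, direction := "up"]
    if (length(dn)) dom[dn, direction := "down"]
  }
  if (length(coupled)) {
    g <- genes$genes[match(coupled, gene_id)]
    body <- g$end - g$start
    pad <- floor(body * (1 - params$coupled_domain_frac) / 2)
    cdom <- data.table(chrom = g$chrom, start = g$start + pad,
                       end = g$end - pad, fold = params$domain_fold,
                       is_dmr = TRUE, fold_ratio = params$dmr_fold_ratio,
                       direction = "up", coupled_gene = g$gene_id)
    dom <- rbind(dom, cdom)
  }
  structure(list(domains = dom[], de_genes = de, coupled_genes = coupled,
                 assay = params$assay, conditions = params$conditions),
            class = "SimTruth")
}

#' @export
print.SimTruth <- function(x, ...) {
  cat(sprintf("SimTruth: %d domains (%d differential), %d DE genes, %d coupled\n",
              nrow(x$domains), sum(x$domains$is_dmr), nrow(x$de_genes),
              length(x$coupled_genes)))
  invisible(x)
}

# Effective per-domain rate fold in a condition.
domain_fold_in_condition <- function(truth, condition) {
  ref <- truth$conditions[1]
  f <- truth$domains$fold
  if (!identical(condition, ref)) {
    up <- truth$domains$is_dmr & truth$domains$direction == "up"
    dn <- truth$domains$is_dmr & truth$domains$direction == "down"
    f[up] <- f[up] * truth$domains$fold_ratio[up]
    f[dn] <- f[dn] / truth$domains$fold_ratio[dn]
  }
  f
}

#' Simulate one DIP-Seq tag sample
#'
#' Homogeneous Poisson background at `background_rate` tags/bp; inside
#' each planted domain the rate is multiplied by its fold (and by the
#' between-condition fold ratio for differential domains in the
#' non-reference condition). Overlapping planted domains superpose.
#'
#' @param genome A [Genome()].
#' @param truth A [simulate_truth()] result.
#' @param params A [sim_params()].
#' @param condition One of `params$conditions`.
#' @param sample_id Sample identifier.
#' @param seed Seed.
#' @return A [TagSet()].
#' @export
simulate_dip_tags <- function(genome, truth, params, condition,
                              sample_id = paste0(condition, "_dip"),
                              seed = params$rng_seed) {
  stopifnot(condition %in% params$conditions)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  dom <- truth$domains
  f <- domain_fold_in_condition(truth, condition)
  bg_expect <- params$background_rate * genome_size(genome)
  extra_rate <- params$background_rate * (f - 1) * (dom$end - dom$start)
  scale <- 1
  if (!is.null(params$library_size)) {
    if (params$library_size == 0)
      return(TagSet(sample_id, params$assay, condition, character(),
                    numeric(), genome = genome))
    scale <- params$library_size / (bg_expect + sum(extra_rate))
  }
  n_bg <- rpois(1, bg_expect * scale)
  ci <- sample.int(length(genome$chrom_names), n_bg, replace = TRUE,
                   prob = genome$chrom_lengths)
  pos_bg <- floor(runif(n_bg) * genome$chrom_lengths[ci])
  chrom_bg <- genome$chrom_names[ci]
  n_ex <- rpois(nrow(dom), extra_rate * scale)
  pos_ex <- floor(runif(sum(n_ex)) *
                    rep(dom$end - dom$start, n_ex)) +
    rep(dom$start, n_ex)
  chrom_ex <- rep(dom$chrom, n_ex)
  TagSet(sample_id, params$assay, condition,
         chrom = c(chrom_bg, chrom_ex), pos = c(pos_bg, pos_ex),
         genome = genome)
}

#' Simulate a per-gene RNA count table
#'
#' Per-gene baseline means are log-normal around `nb_mean`; counts are
#' negative binomial with the configured dispersion (Poisson when the
#' dispersion is 0). In the non-reference condition the mean of each DE
#' gene is scaled by `2^log2fc` from the truth table.
#'
#' @param genes A [GeneModels()].
#' @param truth A [simulate_truth()] result.
#' @param params A [sim_params()].
#' @param n_reps Replicates per condition (default `params$n_reps`).
#' @param seed Seed.
#' @return A list: `counts` (genes x samples integer matrix) and
#'   `conditions` (per-column labels).
#' @export
simulate_rna_counts <- function(genes, truth, params,
                                n_reps = params$n_reps,
                                seed = params$rng_seed + 2L) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  ids <- gene_ids(genes)
  n <- length(ids)
  base <- if (params$nb_mean_sdlog > 0)
    rlnorm(n, log(params$nb_mean), params$nb_mean_sdlog)
  else rep(params$nb_mean, n)
  lfc <- truth$de_genes$log2fc[match(ids, truth$de_genes$gene_id)]
  lfc[is.na(lfc)] <- 0
  mu <- cbind(matrix(base, n, n_reps),
              matrix(base * 2^lfc, n, n_reps))
  cond <- rep(params$conditions, each = n_reps)
  draw <- function(m) {
    if (params$nb_dispersion == 0) rpois(length(m), m)
    else rnbinom(length(m), mu = m, size = 1 / params$nb_dispersion)
  }
  counts <- matrix(draw(mu), n, 2 * n_reps)
  rownames(counts) <- ids
  colnames(counts) <- paste0(cond, "_rep", rep(seq_len(n_reps), 2))
  list(counts = counts, conditions = cond)
}

#' Simulate a complete coupled DIP-Seq / RNA-Seq dataset
#'
#' Runs the full generator from one seed: genome and genes, truth,
#' `n_pools` DIP tag samples per condition, RNA counts, and (optionally) a
#' synthetic gene-category map in which one category collects the coupled
#' genes.
#'
#' @param params A [sim_params()].
#' @return A `SimDataset` list: `genome`, `genes`, `truth`, `dip` (list
#'   condition -> list of [TagSet()]), `rna` (counts + conditions),
#'   `categories` (`data.table` category/gene_id or NULL), `params`.
#' @export
simulate_dataset <- function(params = sim_params()) {
  gg <- simulate_genome_and_genes(params)
  truth <- simulate_truth(params, gg$genome, gg$genes)
  dip <- list()
  s <- params$rng_seed + 10L
  for (cond in params$conditions) {
    dip[[cond]] <- lapply(seq_len(params$n_pools), function(j) {
      simulate_dip_tags(gg$genome, truth, params, cond,
                        sample_id = sprintf("%s_pool%d", cond, j),
                        seed = s + j + 100L * match(cond, params$conditions))
    })
  }
  rna <- simulate_rna_counts(gg$genes, truth, params)
  categories <- NULL
  if (params$n_categories > 0 || length(truth$coupled_genes)) {
    old <- local_seed(params$rng_seed + 3L)
    ids <- gene_ids(gg$genes)
    cats <- lapply(seq_len(params$n_categories), function(i) {
      k <- sample(params$category_size_range[1]:params$category_size_range[2], 1)
      data.table(category = sprintf("CAT%03d", i),
                 gene_id = sample(ids, min(k, length(ids))))
    })
    if (length(truth$coupled_genes))
      cats <- c(cats, list(data.table(category = "COUPLED",
                                      gene_id = truth$coupled_genes)))
    categories <- rbindlist(cats)
    restore_seed(old)
  }
  structure(list(genome = gg$genome, genes = gg$genes, truth = truth,
                 dip = dip, rna = rna, categories = categories,
                 params = params),
            class = "SimDataset")
}

#' @export
print.SimDataset <- function(x, ...) {
  cat(sprintf("SimDataset: %d genes, %d planted domains, %d DIP samples, %d RNA samples (seed %d)\n",
              length(x$genes), nrow(x$truth$domains),
              sum(lengths(x$dip)), ncol(x$rna$counts),
              x$params$rng_seed))
  invisible(x)
}

#' Write a simulated dataset to files
#'
#' Serializes all generated components through the package's standard
#' formats: tags as BED, genes as BED12, RNA counts as TSV, truth tables
#' as TSV, categories as TSV and parameters as YAML.
#'
#' @param ds A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (cond in names(ds$dip)) for (ts in ds$dip[[cond]]) {
    p <- file.path(dir, paste0("tags_", ts$sample_id, ".bed"))
    write_tags(ts, p)
    paths[[paste0("tags_", ts$sample_id)]] <- p
  }
  paths$genes <- write_gene_models(ds$genes, file.path(dir, "genes.bed12"))
  paths$counts <- write_counts(ds$rna$counts, file.path(dir, "rna_counts.tsv"))
  paths$truth_domains <- file.path(dir, "truth_domains.tsv")
  fwrite(ds$truth$domains, paths$truth_domains, sep = "\t")
  paths$truth_de <- file.path(dir, "truth_de_genes.tsv")
  fwrite(ds$truth$de_genes, paths$truth_de, sep = "\t")
  if (!is.null(ds$categories)) {
    paths$categories <- file.path(dir, "categories.tsv")
    fwrite(ds$categories, paths$categories, sep = "\t")
  }
  paths$params <- file.path(dir, "sim_params.yaml")
  pl <- unclass(ds$params)
  pl <- pl[!vapply(pl, is.null, TRUE)]
  yaml::write_yaml(pl, paths$params)
  paths$genome <- file.path(dir, "genome.tsv")
  fwrite(data.table(chrom = ds$genome$chrom_names,
                    length = ds$genome$chrom_lengths),
         paths$genome, sep = "\t")
  invisible(paths)
}

#' Read a genome description written by [write_dataset()]
#' @param path TSV with columns chrom, length.
#' @return A [Genome()].
#' @export
read_genome <- function(path) {
  dt <- fread(path, header = TRUE, sep = "\t")
  Genome(setNames(dt$length, dt$chrom))
}
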