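#' Combine several tag sets into one
#'
#' Pools the tags of multiple samples (e.g. the pools of one condition)
#' into a single [TagSet()].
#'
#' @param tag_sets List of [TagSet()]s sharing genome/assay.
#' @param sample_id Identifier for the pooled set.
#' @param condition Condition label (defaults to the first set's).
#' @return A [TagSet()].
#' @export
combine_tag_sets <- function(tag_sets, sample_id = "pooled",
                             condition = tag_sets[[1]]$condition) {
  tg <- rbindlist(lapply(tag_sets, function(t) t$tags))
  TagSet(sample_id, tag_sets[[1]]$assay, condition, tg$chrom, tg$pos,
         tg$strand, tag_sets[[1]]$genome)
}

#' Run the full pipeline on a simulated dataset
#'
#' Orchestrates simulate, segment, diff-meth, diff-expr, integrate and
#' enrich as one reproducible run: every stage writes its tables under
#' `out_dir` and the run is summarized in a manifest (config snapshot,
#' seed, per-stage output paths, row counts and input digests). Stage
#' outputs are pure functions of (inputs, config, seed), so re-running
#' with the same manifest inputs reproduces identical tables.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param params A [sim_params()] for the simulate stage (its seed
#'   defaults to the config seed), or `NULL` with `dataset` supplied.
#' @param dataset Optionally a pre-built [simulate_dataset()] result
#'   (skips the simulate stage's generation, still serializes it).
#' @return A `RunManifest` list (also written to
#'   `out_dir/manifest.yaml`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         params = NULL, dataset = NULL) {
  validate_config(config)
  if (is.null(dataset)) {
    if (is.null(params))
      params <- sim_params(rng_seed = config$rng_seed)
    # fail fast on config conflicts before any stage runs
    if (config$dmr_test == "nb" && params$n_pools < 2)
      stop("config conflict: dmr_test = 'nb' requires >= 2 pools per condition")
    if (params$n_reps < 2)
      stop("config conflict: expression testing requires >= 2 RNA replicates")
    dataset <- simulate_dataset(params)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("dipseqr")),
                   rng_seed = config$rng_seed,
                   config = unclass(config), stages = list())
  log_stage <- function(name, paths, rows) {
    manifest$stages[[name]] <<- list(outputs = unlist(paths), rows = rows)
    message(sprintf("[%s] %s", name,
                    paste(names(rows), rows, sep = "=", collapse = ", ")))
  }

  ## simulate -------------------------------------------------------------
  sim_dir <- file.path(out_dir, "simulate")
  paths <- write_dataset(dataset, sim_dir)
  manifest$input_digests <- as.list(tools::md5sum(unlist(paths)))
  log_stage("simulate", paths,
            c(genes = length(dataset$genes),
              domains = nrow(dataset$truth$domains),
              dip_samples = sum(lengths(dataset$dip))))

  conds <- dataset$params$conditions
  genome <- dataset$genome

  ## segment --------------------------------------------------------------
  seg_dir <- file.path(out_dir, "segment")
  dir.create(seg_dir, showWarnings = FALSE)
  seg <- list(); seg_paths <- list(); i <- 0L
  for (cond in conds) for (ts in dataset$dip[[cond]]) {
    i <- i + 1L
    res <- segment_sample(ts, config, genome, seed = config$rng_seed + i)
    seg[[ts$sample_id]] <- res$domains
    p <- file.path(seg_dir, paste0("domains_", ts$sample_id, ".bed"))
    write_regions(res$domains, p)
    seg_paths[[ts$sample_id]] <- p
  }
  log_stage("segment", seg_paths,
            setNames(vapply(seg, nrow, 0L), paste0("domains_", names(seg))))

  ## diff-meth ------------------------------------------------------------
  dm_dir <- file.path(out_dir, "diff_meth")
  dir.create(dm_dir, showWarnings = FALSE)
  resolution <- if (config$dmr_tile == "tile") config$dmr_window_bp else NULL
  merged <- merge_regions(seg, resolution, genome)
  tested <- test_regions(merged, dataset$dip[[conds[1]]],
                         dataset$dip[[conds[2]]], config$dmr_test, genome,
                         config$dmr_diff_mode)
  tested[, q := p.adjust(p, "BH")]
  dmrs <- call_dmrs(tested, config$dmr_q_threshold, config$dmr_min_tag_diff,
                    dataset$params$assay)
  p_tested <- file.path(dm_dir, "tested_regions.tsv")
  fwrite(tested, p_tested, sep = "\t")
  p_dmr <- file.path(dm_dir, "dmrs.bed")
  write_regions(dmrs, p_dmr)
  log_stage("diff_meth", list(p_tested, p_dmr),
            c(merged_regions = nrow(merged), tested = nrow(tested),
              dmrs = nrow(dmrs)))

  ## diff-expr ------------------------------------------------------------
  de_dir <- file.path(out_dir, "diff_expr")
  dir.create(de_dir, showWarnings = FALSE)
  expr <- test_expression(dataset$rna$counts, dataset$rna$conditions)
  p_expr <- file.path(de_dir, "expression.tsv")
  fwrite(expr, p_expr, sep = "\t")
  log_stage("diff_expr", list(p_expr),
            c(genes = nrow(expr),
              significant = sum(expr$q < config$expr_sig_threshold,
                                na.rm = TRUE)))

  ## integrate ------------------------------------------------------------
  int_dir <- file.path(out_dir, "integrate")
  dir.create(int_dir, showWarnings = FALSE)
  annotated <- annotate_dmrs(tested, dataset$genes, config$tss_max_dist_bp,
                             config$top_n_dmrs)
  p_ann <- file.path(int_dir, "annotated_regions.tsv")
  fwrite(annotated, p_ann, sep = "\t")
  expressed <- expr$gene_id[rowSums(dataset$rna$counts) > 0]
  annotatable <- annotate_dmrs(tested, dataset$genes,
                               config$tss_max_dist_bp, Inf)$gene_id
  universe <- intersect(expressed, annotatable)
  ov <- overlap_by_direction(tested, expr, dataset$genes, config, universe)
  p_ov <- file.path(int_dir, "overlap.tsv")
  fwrite(ov, p_ov, sep = "\t")
  expr <- expr[order(-statistic, gene_id, na.last = TRUE)]
  expr_order <- expr$gene_id
  mats <- lapply(conds, function(cond) {
    pooled <- combine_tag_sets(dataset$dip[[cond]],
                               paste0(cond, "_pooled"))
    metagene_matrix(pooled, dataset$genes, expr_order,
                    ceiling_quantile = config$heatmap_quantile)
  })
  names(mats) <- conds
  mat_paths <- lapply(conds, function(cond) {
    p <- file.path(int_dir, paste0("metagene_", cond, ".tsv"))
    fwrite(as.data.table(mats[[cond]]$matrix, keep.rownames = "gene_id"),
           p, sep = "\t")
    p
  })
  ranked <- rank_intragenic_difference(mats[[1]], mats[[2]],
                                       config$top_n_intragenic)
  p_rank <- file.path(int_dir, "intragenic_ranking.tsv")
  fwrite(ranked, p_rank, sep = "\t")
  log_stage("integrate", c(list(p_ann, p_ov, p_rank), mat_paths),
            c(annotated = nrow(annotated), universe = length(universe),
              ranked = nrow(ranked)))

  ## enrich ---------------------------------------------------------------
  if (!is.null(dataset$categories)) {
    en_dir <- file.path(out_dir, "enrich")
    dir.create(en_dir, showWarnings = FALSE)
    gene_set <- ranked$gene_id
    fisher <- enrich_fisher(gene_set, dataset$categories, universe)
    weights <- setNames(dataset$genes$genes$mappable_length,
                        gene_ids(dataset$genes))
    weighted <- enrich_weighted(gene_set, dataset$categories, universe,
                                weights)
    stat <- setNames(expr$statistic, expr$gene_id)[universe]
    stat <- stat[!is.na(stat)]
    ks <- enrich_ks(stat, dataset$categories)
    p_en <- file.path(en_dir, c("enrich_fisher.tsv", "enrich_weighted.tsv",
                                "enrich_ks.tsv"))
    fwrite(fisher, p_en[1], sep = "\t")
    fwrite(weighted, p_en[2], sep = "\t")
    fwrite(ks, p_en[3], sep = "\t")
    log_stage("enrich", as.list(p_en),
              c(categories = nrow(fisher),
                significant = sum(fisher$q < 0.01, na.rm = TRUE)))
  }

  manifest_path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  manifest$path <- manifest_path
  class(manifest) <- "RunManifest"
  invisible(manifest)
}

#' @export
print.RunManifest <- function(x, ...) {
  cat("RunManifest (seed", x$rng_seed, "):",
      paste(names(x$stages), collapse = " -> "), "\n")
  invisible(x)
}

# Direction-paired overlap (methylation up/down x expression up/down).
overlap_by_direction <- function(tested, expr, genes, config, universe) {
  tested <- as.data.table(tested)
  rows <- list()
  for (mdir in c("up", "down")) {
    sub <- if (mdir == "up") tested[ndiff > 0] else tested[ndiff < 0]
    ann <- annotate_dmrs(sub, genes, config$tss_max_dist_bp,
                         config$top_n_overlap)
    mset <- intersect(ann$gene_id, universe)
    for (edir in c("up", "down")) {
      eset <- intersect(top_regulated_genes(expr, edir,
                                            config$expr_sig_threshold,
                                            config$top_n_overlap), universe)
      r <- topn_overlap(mset, eset, universe)
      rows[[paste(mdir, edir)]] <-
        data.table(meth_direction = mdir, expr_direction = edir,
                   n_meth = r$n1, n_expr = r$n2, overlap = r$overlap,
                   n_universe = r$n_universe, p = r$p)
    }
  }
  rbindlist(rows)
}
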