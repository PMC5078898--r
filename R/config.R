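#' Pipeline configuration
#'
#' Collects every numeric parameter of the pipeline in one validated list.
#' Defaults follow the analysis conventions of hippocampal DIP-Seq work:
#' 1000-bp sliding windows, differential-region filters q < 0.01 and a
#' normalized tag difference > 50 over 5-kb testing units, gene annotation
#' within 50 kb of a TSS (25 kb as the common alternate), top-2000 regions
#' for ontology work, top-1000 sets for methylation/expression overlap,
#' top-500 for intragenic-difference ranking, and heatmap colour maps
#' ceilinged at the 80% quantile.
#'
#' @param window_bp Sliding-window width for segmentation (bp).
#' @param window_step_bp Window step; defaults to `window_bp / 2` and must
#'   divide `window_bp`.
#' @param n_permutations Monte-Carlo permutations for the background model.
#' @param enrich_alpha Per-window tail probability for the enrichment
#'   threshold. The default 1e-4 is of Bonferroni order for the ~2e4
#'   windows of a 10-Mb genome at the default window size, keeping false
#'   domains rare genome-wide.
#' @param dmr_q_threshold BH q cut-off for differential regions.
#' @param dmr_min_tag_diff Minimum absolute (normalized) tag difference.
#' @param dmr_window_bp Testing-unit width when re-tiling merged
#'   enrichment territory.
#' @param tss_max_dist_bp Maximum DMR-to-TSS distance for annotation.
#' @param top_n_dmrs Regions kept after ranking for annotation.
#' @param top_n_overlap Set size for methylation/expression overlap.
#' @param top_n_intragenic Genes kept in intragenic-difference ranking.
#' @param heatmap_quantile Colour ceiling quantile for meta-gene heatmaps,
#'   in (0, 1).
#' @param rng_seed Integer seed driving every stochastic stage.
#' @param fragment_extension_bp Optional tag extension (0 = point tags).
#' @param collapse_duplicates Drop duplicate tag coordinates before
#'   counting (default keep).
#' @param dmr_test `"chisq"` (pooled counts) or `"nb"` (replicate-aware).
#' @param dmr_diff_mode `"normalized"` (library-size-scaled difference) or
#'   `"raw"`.
#' @param dmr_tile `"tile"` (5-kb testing units) or `"whole"` (test whole
#'   merged regions).
#' @param count_mode RNA counting: `"exon"` (tag must fall in an exon) or
#'   `"span"` (anywhere in the gene span).
#' @param expr_sig_threshold q threshold defining "significantly
#'   regulated" genes for overlap analyses.
#' @return A validated `PipelineConfig` list.
#' @export
pipeline_config <- function(window_bp = 1000,
                            window_step_bp = window_bp / 2,
                            n_permutations = 500,
                            enrich_alpha = 1e-4,
                            dmr_q_threshold = 0.01,
                            dmr_min_tag_diff = 50,
                            dmr_window_bp = 5000,
                            tss_max_dist_bp = 50000,
                            top_n_dmrs = 2000,
                            top_n_overlap = 1000,
                            top_n_intragenic = 500,
                            heatmap_quantile = 0.80,
                            rng_seed = 1L,
                            fragment_extension_bp = 0,
                            collapse_duplicates = FALSE,
                            dmr_test = c("chisq", "nb"),
                            dmr_diff_mode = c("normalized", "raw"),
                            dmr_tile = c("tile", "whole"),
                            count_mode = c("exon", "span"),
                            expr_sig_threshold = 0.05) {
  cfg <- list(window_bp = window_bp, window_step_bp = window_step_bp,
              n_permutations = n_permutations, enrich_alpha = enrich_alpha,
              dmr_q_threshold = dmr_q_threshold,
              dmr_min_tag_diff = dmr_min_tag_diff,
              dmr_window_bp = dmr_window_bp,
              tss_max_dist_bp = tss_max_dist_bp,
              top_n_dmrs = top_n_dmrs, top_n_overlap = top_n_overlap,
              top_n_intragenic = top_n_intragenic,
              heatmap_quantile = heatmap_quantile,
              rng_seed = as.integer(rng_seed),
              fragment_extension_bp = fragment_extension_bp,
              collapse_duplicates = isTRUE(collapse_duplicates),
              dmr_test = match.arg(dmr_test),
              dmr_diff_mode = match.arg(dmr_diff_mode),
              dmr_tile = match.arg(dmr_tile),
              count_mode = match.arg(count_mode),
              expr_sig_threshold = expr_sig_threshold)
  validate_config(cfg)
  structure(cfg, class = "PipelineConfig")
}

validate_config <- function(cfg) {
  pos <- c("window_bp", "window_step_bp", "n_permutations", "enrich_alpha",
           "dmr_q_threshold", "dmr_min_tag_diff", "dmr_window_bp",
           "tss_max_dist_bp", "top_n_dmrs", "top_n_overlap",
           "top_n_intragenic", "expr_sig_threshold")
  for (f in pos) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0)
      stop("config field '", f, "' must be a positive number")
  }
  if (cfg$heatmap_quantile <= 0 || cfg$heatmap_quantile >= 1)
    stop("config field 'heatmap_quantile' must lie in (0, 1)")
  if (cfg$window_bp %% cfg$window_step_bp != 0)
    stop("window_step_bp must divide window_bp")
  if (cfg$fragment_extension_bp < 0)
    stop("fragment_extension_bp must be >= 0")
  invisible(cfg)
}

#' Read / write a pipeline configuration as YAML
#' @param path File path.
#' @return `read_config` returns a `PipelineConfig`; `write_config` the
#'   path, invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' @rdname read_config
#' @param cfg A `PipelineConfig`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
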