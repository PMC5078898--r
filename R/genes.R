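#' Gene models
#'
#' A `GeneModels` object holds RefSeq-style gene annotation: one row per
#' gene with span, strand, transcription start site (TSS) and mappable
#' (exonic) length, plus the exon intervals. The TSS is the span start on
#' the + strand and `end - 1` on the - strand. All coordinates 0-based
#' half-open.
#'
#' @param genes `data.table` with columns `gene_id`, `chrom`, `strand`,
#'   `start`, `end`.
#' @param exons `data.table` with columns `gene_id`, `chrom`, `start`,
#'   `end`; exons of one gene must be disjoint.
#' @param genome Optional [Genome()] for bounds validation.
#' @return An object of class `GeneModels`.
#' @export
GeneModels <- function(genes, exons, genome = NULL) {
  genes <- as.data.table(genes)
  exons <- as.data.table(exons)
  validate_intervals(genes, genome)
  validate_intervals(exons, genome)
  if (!all(exons$gene_id %in% genes$gene_id))
    stop("exon refers to unknown gene_id")
  if (anyDuplicated(genes$gene_id)) stop("gene_id values must be unique")
  setorder(exons, gene_id, start)
  ov <- exons[, any(start[-1] < end[-.N]), by = gene_id]
  if (nrow(ov) && any(ov$V1)) stop("overlapping exons within a gene")
  genes <- data.table::copy(genes)
  genes[, tss := ifelse(strand == "+", start, end - 1)]
  ml <- exons[, .(mappable_length = sum(end - start)), by = gene_id]
  genes[, mappable_length := ml$mappable_length[match(gene_id, ml$gene_id)]]
  genes[is.na(mappable_length), mappable_length := 0]
  structure(list(genes = genes, exons = exons, genome = genome),
            class = "GeneModels")
}

#' @export
print.GeneModels <- function(x, ...) {
  cat("GeneModels:", nrow(x$genes), "genes,", nrow(x$exons), "exons\n")
  invisible(x)
}

#' @export
length.GeneModels <- function(x) nrow(x$genes)

#' Gene ids of a GeneModels object
#' @param gm A [GeneModels()] object.
#' @return Character vector of gene ids.
#' @export
gene_ids <- function(gm) gm$genes$gene_id

exons_granges <- function(gm) {
  as_granges(gm$exons, gm$genome)
}

genes_granges <- function(gm) {
  as_granges(gm$genes, gm$genome)
}
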