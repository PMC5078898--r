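#' Sequence-tag set
#'
#' A `TagSet` holds the uniquely-mapped sequencing tags of one sample as
#' genomic points (the 5' start of each read, 0-based), together with the
#' sample's identity, assay (`5mC`, `5hmC` or `RNA`) and condition label.
#' `library_size` always equals the number of tags. Tags are assumed to be
#' pre-filtered to unique mappers upstream.
#'
#' @param sample_id Sample identifier.
#' @param assay One of `"5mC"`, `"5hmC"`, `"RNA"`.
#' @param condition Condition label (e.g. a dose group).
#' @param chrom,pos Parallel vectors: chromosome and 0-based tag position.
#' @param strand Optional strand vector (`"+"`/`"-"`); defaults to `"+"`.
#' @param genome A [Genome()]; tag positions are validated against it.
#' @return An object of class `TagSet`.
#' @export
TagSet <- function(sample_id, assay, condition, chrom, pos, strand = NULL,
                   genome) {
  assay <- match.arg(assay, c("5mC", "5hmC", "RNA"))
  chrom <- as.character(chrom)
  pos <- as.numeric(pos)
  if (length(chrom) != length(pos)) stop("chrom and pos lengths differ")
  if (is.null(strand)) strand <- rep("+", length(pos))
  if (length(pos)) {
    len <- chrom_length(genome, chrom)  # errors on unknown chromosome
    if (any(pos < 0) || any(pos >= len))
      stop("tag position outside [0, chrom_length)")
  }
  structure(list(sample_id = sample_id, assay = assay, condition = condition,
                 tags = data.table(chrom = chrom, pos = pos,
                                   strand = as.character(strand)),
                 library_size = length(pos), genome = genome),
            class = "TagSet")
}

#' @export
print.TagSet <- function(x, ...) {
  cat(sprintf("TagSet %s [%s, %s]: %d tags\n", x$sample_id, x$assay,
              x$condition, x$library_size))
  invisible(x)
}

tags_granges <- function(ts) {
  as_granges(data.table(chrom = ts$tags$chrom, start = ts$tags$pos,
                        end = ts$tags$pos + 1, strand = ts$tags$strand),
             ts$genome)
}
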