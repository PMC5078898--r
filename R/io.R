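#' Read mapped tags from a BED file
#'
#' Each BED record contributes one tag at the record's `chromStart`
#' (0-based). Strand is taken from column 6 when present, otherwise `+`.
#' Records are validated line by line so malformed input is reported with
#' its line number.
#'
#' @param path BED3+ file of mapped tag coordinates.
#' @param assay,condition Labels stored on the resulting [TagSet()].
#' @param genome A [Genome()]; positions must fall inside it.
#' @param sample_id Sample identifier; defaults to the file base name.
#' @return A [TagSet()].
#' @export
read_tags <- function(path, assay, condition, genome,
                      sample_id = sub("\\.bed$", "", basename(path))) {
  dt <- tryCatch(
    suppressWarnings(
      fread(path, header = FALSE, sep = "\t", fill = TRUE,
            colClasses = "character", blank.lines.skip = FALSE)),
    error = function(e) stop("failed to read BED file '", path, "': ",
                             conditionMessage(e)))
  if (is.null(dt) || nrow(dt) == 0)
    return(TagSet(sample_id, assay, condition, character(), numeric(),
                  genome = genome))
  # drop trailing blank lines, track original line numbers for errors
  keep <- !(dt$V1 == "" & rowSums(dt != "") == 0)
  line_no <- which(keep)
  dt <- dt[keep]
  if (ncol(dt) < 3)
    stop("parse error in '", path, "': fewer than 3 BED columns")
  start <- suppressWarnings(as.numeric(dt$V2))
  end <- suppressWarnings(as.numeric(dt$V3))
  bad <- which(dt$V1 == "" | is.na(start) | is.na(end) | start < 0 |
                 end <= start)
  if (length(bad))
    stop("parse error in '", path, "' at line ", line_no[bad[1]],
         ": malformed BED record")
  strand <- if (ncol(dt) >= 6) ifelse(dt$V6 %in% c("+", "-"), dt$V6, "+")
            else rep("+", nrow(dt))
  TagSet(sample_id, assay, condition, chrom = dt$V1, pos = start,
         strand = strand, genome = genome)
}

#' Write tags to a BED6 file
#' @param ts A [TagSet()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tags <- function(ts, path) {
  dt <- data.table(ts$tags$chrom, format_bp(ts$tags$pos),
                   format_bp(ts$tags$pos + 1), ".", 0L, ts$tags$strand)
  fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read gene models (BED12 or refFlat)
#'
#' BED12 is parsed with `rtracklayer`; refFlat-style TSV (the 11-column
#' UCSC table: geneName, name, chrom, strand, txStart, txEnd, cdsStart,
#' cdsEnd, exonCount, exonStarts, exonEnds) is parsed directly. The format
#' is auto-detected from the column layout.
#'
#' @param path Annotation file.
#' @param genome Optional [Genome()] for validation.
#' @return A [GeneModels()] object.
#' @export
read_gene_models <- function(path, genome = NULL) {
  probe <- fread(path, header = FALSE, sep = "\t", nrows = 5L,
                 colClasses = "character")
  is_refflat <- ncol(probe) == 11 &&
    all(probe$V4 %in% c("+", "-")) &&
    !anyNA(suppressWarnings(as.numeric(probe$V5)))
  if (is_refflat) read_refflat(path, genome) else read_bed12(path, genome)
}

read_bed12 <- function(path, genome) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stop("parse error in BED12 file '",
                                          path, "': ", conditionMessage(e)))
  if (is.null(mcols(gr)$blocks))
    stop("parse error in '", path, "': BED12 block columns missing")
  n <- length(gr)
  genes <- data.table(gene_id = as.character(mcols(gr)$name),
                      chrom = as.character(GenomeInfoDb::seqnames(gr)),
                      strand = as.character(GenomicRanges::strand(gr)),
                      start = GenomicRanges::start(gr) - 1,
                      end = as.numeric(GenomicRanges::end(gr)))
  blocks <- mcols(gr)$blocks  # IRangesList, 1-based relative to span start
  nb <- S4Vectors::elementNROWS(blocks)
  flat <- unlist(blocks, use.names = FALSE)
  exons <- data.table(
    gene_id = rep(genes$gene_id, nb),
    chrom = rep(genes$chrom, nb),
    start = rep(genes$start, nb) + IRanges::start(flat) - 1,
    end = rep(genes$start, nb) + IRanges::end(flat))
  if (nrow(exons) && any(exons$end > rep(genes$end, nb)))
    stop("parse error in '", path, "': exon block extends past gene end")
  GeneModels(genes, exons, genome)
}

read_refflat <- function(path, genome) {
  dt <- fread(path, header = FALSE, sep = "\t", colClasses = "character")
  if (ncol(dt) != 11)
    stop("parse error in refFlat file '", path, "': expected 11 columns")
  genes <- data.table(gene_id = dt$V2, chrom = dt$V3, strand = dt$V4,
                      start = as.numeric(dt$V5), end = as.numeric(dt$V6))
  starts <- lapply(strsplit(dt$V10, ","), function(x) as.numeric(x[x != ""]))
  ends <- lapply(strsplit(dt$V11, ","), function(x) as.numeric(x[x != ""]))
  ecount <- as.integer(dt$V9)
  if (any(lengths(starts) != ecount) || any(lengths(ends) != ecount))
    stop("parse error in refFlat file '", path,
         "': exon count inconsistent with exon lists")
  exons <- data.table(gene_id = rep(genes$gene_id, ecount),
                      chrom = rep(genes$chrom, ecount),
                      start = unlist(starts), end = unlist(ends))
  GeneModels(genes, exons, genome)
}

#' Write gene models to BED12
#' @param gm A [GeneModels()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(gm, path) {
  g <- gm$genes
  ex <- data.table::copy(gm$exons)
  setorder(ex, gene_id, start)
  ex[, gstart := g$start[match(gene_id, g$gene_id)]]
  bl <- ex[, .(sizes = paste0(paste(format_bp(end - start), collapse = ","), ","),
               starts_rel = paste0(paste(format_bp(start - gstart),
                                         collapse = ","), ","),
               n = .N), by = gene_id]
  i <- match(g$gene_id, bl$gene_id)
  dt <- data.table(g$chrom, format_bp(g$start), format_bp(g$end), g$gene_id,
                   0L, g$strand, format_bp(g$start), format_bp(g$start),
                   "0,0,0", bl$n[i], bl$sizes[i], bl$starts_rel[i])
  fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read scored region tables
#'
#' Regions are written as BED-compatible tab-separated text: the first
#' three columns are `chrom`, `start`, `end` (0-based half-open); any
#' further columns (counts, statistics, p, q, direction, ...) follow. A
#' single `#`-prefixed header names the columns, so the file still loads
#' in standard BED tooling. Rows are sorted by (chrom, start). Writing
#' then reading returns an identical table.
#'
#' @param regions Interval `data.table` (see [intervals()]).
#' @param path Output path.
#' @return `write_regions` returns `path` invisibly; `read_regions` the
#'   region `data.table`.
#' @export
write_regions <- function(regions, path) {
  regions <- as.data.table(regions)
  if (nrow(regions)) {
    validate_intervals(regions)
    regions <- regions[order(chrom, start, end)]
  }
  cols <- if (ncol(regions)) names(regions) else c("chrom", "start", "end")
  writeLines(paste0("#", paste(cols, collapse = "\t")), path)
  if (nrow(regions)) {
    out <- data.table::copy(regions)
    out[, start := format_bp(start)]
    out[, end := format_bp(end)]
    fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE,
           append = TRUE)
  }
  invisible(path)
}

#' @rdname write_regions
#' @export
read_regions <- function(path) {
  lines <- readLines(path)
  cols <- strsplit(sub("^#", "", lines[1]), "\t")[[1]]
  dt <- if (length(lines) > 1)
    fread(path, header = FALSE, sep = "\t", skip = 1L)
  else data.table()
  if (nrow(dt) == 0)
    dt <- as.data.table(setNames(rep(list(logical()), length(cols)), cols))
  else data.table::setnames(dt, cols)
  if ("chrom" %in% names(dt)) dt[, chrom := as.character(chrom)]
  for (col in intersect(c("start", "end"), names(dt)))
    dt[[col]] <- as.numeric(dt[[col]])
  dt[]
}

#' Write / read a gene-by-sample count table (TSV with header)
#' @param counts Integer matrix, rownames = gene ids.
#' @param path File path.
#' @return `write_counts` returns `path` invisibly; `read_counts` the
#'   matrix.
#' @export
write_counts <- function(counts, path) {
  dt <- data.table(gene_id = rownames(counts))
  dt <- cbind(dt, as.data.table(counts))
  fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  dt <- fread(path, header = TRUE, sep = "\t")
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1]]
  m
}
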