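#' Genome description
#'
#' A minimal genome: an ordered set of chromosome names with lengths in base
#' pairs. All interval containers in the package are validated against a
#' `Genome`, and all coordinates are 0-based half-open (the BED convention)
#' unless a function says otherwise.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#'   Names must be unique, lengths strictly positive.
#' @return An object of class `Genome`.
#' @examples
#' g <- Genome(c(chr1 = 1e6, chr2 = 5e5))
#' genome_size(g)
#' @export
Genome <- function(chrom_lengths) {
  if (is.null(names(chrom_lengths)) || anyNA(names(chrom_lengths)) ||
      any(names(chrom_lengths) == ""))
    stop("chrom_lengths must be a named vector")
  if (anyDuplicated(names(chrom_lengths)))
    stop("chromosome names must be unique")
  if (!is.numeric(chrom_lengths) || any(chrom_lengths <= 0) ||
      anyNA(chrom_lengths))
    stop("chromosome lengths must be strictly positive")
  structure(list(chrom_names = names(chrom_lengths),
                 chrom_lengths = as.numeric(setNames(chrom_lengths,
                                                     names(chrom_lengths)))),
            class = "Genome")
}

#' @export
print.Genome <- function(x, ...) {
  cat("Genome with", length(x$chrom_names), "chromosome(s),",
      format(genome_size(x), big.mark = ","), "bp total\n")
  invisible(x)
}

#' Total genome size in bp
#' @param genome A [Genome()].
#' @return Numeric scalar.
#' @export
genome_size <- function(genome) sum(genome$chrom_lengths)

chrom_length <- function(genome, chrom) {
  i <- match(chrom, genome$chrom_names)
  if (anyNA(i)) stop("unknown chromosome(s): ",
                     paste(unique(chrom[is.na(i)]), collapse = ", "))
  genome$chrom_lengths[i]
}

as_seqinfo <- function(genome) {
  GenomeInfoDb::Seqinfo(seqnames = genome$chrom_names,
                        seqlengths = as.integer(genome$chrom_lengths))
}

#' Build an interval table
#'
#' Intervals are plain `data.table`s with columns `chrom`, `start`, `end`
#' in 0-based half-open coordinates; extra columns are carried along.
#'
#' @param chrom Character vector.
#' @param start,end 0-based half-open bounds, `0 <= start < end`.
#' @param ... Additional parallel columns.
#' @param genome Optional [Genome()] to validate bounds against.
#' @return A `data.table` of intervals.
#' @export
intervals <- function(chrom, start, end, ..., genome = NULL) {
  dt <- data.table(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), ...)
  validate_intervals(dt, genome)
  dt
}

validate_intervals <- function(dt, genome = NULL) {
  if (nrow(dt) == 0) return(invisible(dt))
  if (any(dt$start < 0) || any(dt$end <= dt$start))
    stop("intervals must satisfy 0 <= start < end")
  if (!is.null(genome)) {
    len <- chrom_length(genome, dt$chrom)
    if (any(dt$end > len))
      stop("interval end exceeds chromosome length")
  }
  invisible(dt)
}

# Convert a 0-based half-open interval table to GRanges (1-based closed).
as_granges <- function(dt, genome = NULL) {
  if (nrow(dt) == 0) {
    gr <- GenomicRanges::GRanges()
    if (!is.null(genome)) GenomeInfoDb::seqinfo(gr) <- as_seqinfo(genome)
    return(gr)
  }
  strand <- if ("strand" %in% names(dt)) dt$strand else "*"
  gr <- GenomicRanges::GRanges(
    seqnames = dt$chrom,
    ranges = IRanges::IRanges(start = dt$start + 1L, end = dt$end),
    strand = strand,
    seqinfo = if (is.null(genome)) NULL else as_seqinfo(genome))
  extra <- setdiff(names(dt), c("chrom", "start", "end", "strand"))
  for (nm in extra) S4Vectors::mcols(gr)[[nm]] <- dt[[nm]]
  gr
}

from_granges <- function(gr) {
  dt <- data.table(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = as.numeric(GenomicRanges::end(gr)))
  mc <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(mc)) dt <- cbind(dt, as.data.table(mc))
  dt
}

#' Convert between 0-based half-open and 1-based closed coordinates
#'
#' The package stores intervals 0-based half-open; these helpers convert an
#' interval table to the 1-based closed convention (e.g. for GFF-style
#' output) and back. The two are mutual inverses.
#'
#' @param dt Interval `data.table` with `start`/`end` columns.
#' @return The converted table (a copy).
#' @export
to_1based_closed <- function(dt) {
  dt <- data.table::copy(dt)
  dt[, start := start + 1]
  dt
}

#' @rdname to_1based_closed
#' @export
to_0based_halfopen <- function(dt) {
  dt <- data.table::copy(dt)
  dt[, start := start - 1]
  dt
}
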