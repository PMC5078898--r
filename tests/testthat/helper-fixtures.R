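# Small in-code fixtures shared across test files.

tiny_genome <- function() Genome(c(chr1 = 2000, chr2 = 1500))

make_tags <- function(pos, chrom = "chr1", genome = tiny_genome(),
                      strand = NULL, assay = "5hmC", condition = "sham",
                      sample_id = "s1") {
  TagSet(sample_id, assay, condition, rep(chrom, length(pos)), pos,
         strand, genome)
}

write_bed_lines <- function(lines) {
  path <- tempfile(fileext = ".bed")
  writeLines(lines, path)
  path
}

# random tag set on a tiny genome, for round-trip properties
random_tagset <- function(n = 50, genome = tiny_genome(), seed = 1) {
  set.seed(seed)
  chrom <- sample(genome$chrom_names, n, replace = TRUE)
  len <- genome$chrom_lengths[match(chrom, genome$chrom_names)]
  pos <- pmin(floor(runif(n) * len), len - 1)
  TagSet("rt", "5mC", "sham", chrom, pos,
         sample(c("+", "-"), n, TRUE), genome)
}
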