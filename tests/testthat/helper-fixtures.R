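# Shared fixtures: a hand-coordinates toy annotation and genome, plus a
# minimal SAM writer for constructing alignment cases by hand.

# Three-exon transcript with exons 1-100, 151-250, 331-430 (1-based closed),
# so introns are 101-150 (50 bp) and 251-330 (80 bp).
toy_gff3 <- function(path = tempfile(fileext = ".gff3"), strand = "+",
                     extra = character(0)) {
  lines <- c(
    "##gff-version 3",
    "##sequence-region chrT 1 600",
    sprintf("chrT\ttoy\tgene\t1\t430\t.\t%s\t.\tID=gA", strand),
    sprintf("chrT\ttoy\tmRNA\t1\t430\t.\t%s\t.\tID=gA.t1;Parent=gA", strand),
    sprintf("chrT\ttoy\texon\t1\t100\t.\t%s\t.\tID=gA.t1.e1;Parent=gA.t1", strand),
    sprintf("chrT\ttoy\texon\t151\t250\t.\t%s\t.\tID=gA.t1.e2;Parent=gA.t1", strand),
    sprintf("chrT\ttoy\texon\t331\t430\t.\t%s\t.\tID=gA.t1.e3;Parent=gA.t1", strand),
    "chrT\ttoy\tgene\t451\t550\t.\t+\t.\tID=gB",
    "chrT\ttoy\tmRNA\t451\t550\t.\t+\t.\tID=gB.t1;Parent=gB",
    "chrT\ttoy\texon\t451\t550\t.\t+\t.\tID=gB.t1.e1;Parent=gB.t1",
    extra)
  writeLines(lines, path)
  path
}

toy_fasta <- function(path = tempfile(fileext = ".fa"), seed = 99,
                      len = 600) {
  set.seed(seed)
  seq <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
  writeLines(c(">chrT", seq), path)
  path
}

toy_model <- function(strand = "+", with_genome = TRUE) {
  gff <- toy_gff3(strand = strand)
  fa <- if (with_genome) toy_fasta() else NULL
  parse_annotation(gff, fa)
}

# Write a SAM file from a data.frame(pos, cigar) on chrT (length 600).
write_toy_sam <- function(reads, path = tempfile(fileext = ".sam"),
                          chrom = "chrT", chrom_len = 600) {
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len))
  body <- if (nrow(reads) > 0) {
    seq <- vapply(reads$cigar, function(cg) {
      m <- sum(as.integer(regmatches(cg, gregexpr("[0-9]+(?=M)", cg,
                                                  perl = TRUE))[[1]]))
      paste(rep("A", m), collapse = "")
    }, character(1))
    paste(sprintf("r%03d", seq_len(nrow(reads))), 0L, chrom, reads$pos,
          255L, reads$cigar, "*", 0L, 0L, seq, "*", sep = "\t")
  } else character(0)
  writeLines(c(header, body), path)
  path
}
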