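test_that("single-exon transcripts yield zero introns", {
  model <- toy_model(with_genome = FALSE)
  expect_equal(length(model$genes), 2)
  expect_equal(sum(model$introns$gene_id == "gB"), 0)
})

test_that("introns are derived between consecutive exons with correct coordinates", {
  model <- toy_model(with_genome = FALSE)
  ir <- model$introns[model$introns$gene_id == "gA"]
  ir <- ir[order(GenomicRanges::start(ir))]
  expect_equal(GenomicRanges::start(ir), c(101, 251))
  expect_equal(GenomicRanges::end(ir), c(150, 330))
  expect_equal(GenomicRanges::width(ir), c(50, 80))
  expect_equal(ir$ordinal, c(1, 2))
  expect_equal(ir$intron_id, c("gA.t1.i1", "gA.t1.i2"))
})

test_that("minus-strand ordinals follow transcription order", {
  model <- toy_model(strand = "-", with_genome = FALSE)
  ir <- model$introns[model$introns$gene_id == "gA"]
  ord1 <- ir[ir$ordinal == 1]
  expect_equal(GenomicRanges::start(ord1), 251)
  expect_equal(GenomicRanges::end(ord1), 330)
})

test_that("exon plus intron lengths tile the transcript span", {
  cfg <- sim_config(n_genes = 15, seed = 5)
  b <- build_toy_genome(cfg, dir = withr::local_tempdir())
  m <- b$model
  for (tid in m$transcripts$transcript_id) {
    ex <- m$exons[m$exons$transcript_id == tid]
    ir <- m$introns[m$introns$transcript_id == tid]
    span <- m$transcripts[m$transcripts$transcript_id == tid]
    expect_equal(sum(GenomicRanges::width(ex)) + sum(GenomicRanges::width(ir)),
                 GenomicRanges::width(span))
  }
})

test_that("intron catalog reports stats, merges duplicate intervals, orders deterministically", {
  model <- toy_model(with_genome = FALSE)
  cat_gr <- intron_catalog(model)
  expect_equal(length(cat_gr), 2)
  expect_equal(S4Vectors::metadata(cat_gr)$mean_intron_length, 65)
  expect_equal(GenomicRanges::start(cat_gr), c(101, 251))

  # second transcript of gA sharing intron 1 merges into one entry
  extra <- c(
    "chrT\ttoy\tmRNA\t1\t250\t.\t+\t.\tID=gA.t2;Parent=gA",
    "chrT\ttoy\texon\t1\t100\t.\t+\t.\tID=gA.t2.e1;Parent=gA.t2",
    "chrT\ttoy\texon\t151\t250\t.\t+\t.\tID=gA.t2.e2;Parent=gA.t2")
  model2 <- parse_annotation(toy_gff3(extra = extra))
  cat2 <- intron_catalog(model2)
  expect_equal(length(cat2), 2)
  shared <- cat2[GenomicRanges::start(cat2) == 101]
  expect_setequal(unlist(shared$transcript_ids), c("gA.t1", "gA.t2"))

  empty <- parse_annotation(toy_gff3())
  empty$introns <- empty$introns[0]
  expect_equal(length(intron_catalog(empty)), 0)
  expect_true(is.na(S4Vectors::metadata(intron_catalog(empty))$mean_intron_length))
})

test_that("BED round trip preserves intron intervals", {
  model <- toy_model(with_genome = FALSE)
  cat_gr <- intron_catalog(model)
  bed <- file.path(withr::local_tempdir(), "introns.bed")
  write_intron_bed(cat_gr, bed)
  back <- read_intron_bed(bed)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(cat_gr))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(cat_gr))
  expect_equal(back$name, cat_gr$intron_id)
  expect_equal(back$score, cat_gr$length)
})

test_that("malformed annotations are rejected or repaired as specified", {
  overlapping <- c(
    "chrT\ttoy\tgene\t1\t200\t.\t+\t.\tID=gX",
    "chrT\ttoy\tmRNA\t1\t200\t.\t+\t.\tID=gX.t1;Parent=gX",
    "chrT\ttoy\texon\t1\t120\t.\t+\t.\tID=gX.t1.e1;Parent=gX.t1",
    "chrT\ttoy\texon\t100\t200\t.\t+\t.\tID=gX.t1.e2;Parent=gX.t1")
  expect_error(parse_annotation(toy_gff3(extra = overlapping)), "gX.t1")

  out_of_bounds <- c(
    "chrT\ttoy\tgene\t580\t650\t.\t+\t.\tID=gY",
    "chrT\ttoy\tmRNA\t580\t650\t.\t+\t.\tID=gY.t1;Parent=gY",
    "chrT\ttoy\texon\t580\t650\t.\t+\t.\tID=gY.t1.e1;Parent=gY.t1")
  expect_warning(m <- parse_annotation(toy_gff3(extra = out_of_bounds),
                                       toy_fasta()),
                 "outside chromosome bounds")
  expect_false("gY.t1" %in% m$transcripts$transcript_id)

  orphan <- "chrT\ttoy\texon\t10\t60\t.\t+\t.\tID=orphan.e1;Parent=nosuch.t1"
  expect_error(parse_annotation(toy_gff3(extra = orphan)), "unknown transcript")
})

test_that("splice-site windows carry GT/AG at the boundary positions", {
  cfg <- sim_config(n_genes = 8, seed = 17)
  b <- build_toy_genome(cfg, dir = withr::local_tempdir())
  cat_gr <- intron_catalog(b$model)
  ss <- extract_splice_sites(b$model, cat_gr)
  expect_false(any(ss$clipped))
  expect_true(all(substr(ss$five_ss, 4, 5) == "GT"))
  expect_true(all(substr(ss$three_ss, 11, 12) == "AG"))
  expect_true(all(nchar(ss$five_ss) == 11))
  expect_true(all(nchar(ss$three_ss) == 15))
})

test_that("splice-site extraction is strand symmetric", {
  # the same coding-strand gene placed on '+' and on '-' (with the genome
  # reverse-complemented) must yield identical window strings
  fa_plus <- tempfile(fileext = ".fa"); fa_minus <- tempfile(fileext = ".fa")
  set.seed(42)
  seq <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
               collapse = "")
  writeLines(c(">chrT", seq), fa_plus)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  writeLines(c(">chrT", rc), fa_minus)

  gff_plus <- toy_gff3(strand = "+")
  m_plus <- parse_annotation(gff_plus, fa_plus)
  # mirrored exon coordinates on the reverse-complemented genome
  mirror <- function(a, b, L = 600) c(L - b + 1, L - a + 1)
  ex <- list(mirror(1, 100), mirror(151, 250), mirror(331, 430))
  lines <- c("##gff-version 3", "##sequence-region chrT 1 600",
             "chrT\ttoy\tgene\t171\t600\t.\t-\t.\tID=gA",
             "chrT\ttoy\tmRNA\t171\t600\t.\t-\t.\tID=gA.t1;Parent=gA",
             vapply(seq_along(ex), function(i)
               sprintf("chrT\ttoy\texon\t%d\t%d\t.\t-\t.\tID=gA.t1.e%d;Parent=gA.t1",
                       ex[[i]][1], ex[[i]][2], i), character(1)))
  gff_minus <- tempfile(fileext = ".gff3")
  writeLines(lines, gff_minus)
  m_minus <- parse_annotation(gff_minus, fa_minus)

  cat_p <- intron_catalog(m_plus); cat_p <- cat_p[cat_p$gene_id == "gA"]
  cat_m <- intron_catalog(m_minus)
  ss_p <- extract_splice_sites(m_plus, cat_p)
  ss_m <- extract_splice_sites(m_minus, cat_m)
  expect_setequal(ss_p$five_ss, ss_m$five_ss)
  expect_setequal(ss_p$three_ss, ss_m$three_ss)
  expect_setequal(unname(interval_seqs(m_plus, cat_p)),
                  unname(interval_seqs(m_minus, cat_m)))
})

test_that("windows wider than the intron are clipped and flagged", {
  lines <- c("##gff-version 3", "##sequence-region chrT 1 600",
             "chrT\ttoy\tgene\t1\t206\t.\t+\t.\tID=gS",
             "chrT\ttoy\tmRNA\t1\t206\t.\t+\t.\tID=gS.t1;Parent=gS",
             "chrT\ttoy\texon\t1\t100\t.\t+\t.\tID=gS.t1.e1;Parent=gS.t1",
             "chrT\ttoy\texon\t107\t206\t.\t+\t.\tID=gS.t1.e2;Parent=gS.t1")
  gff <- tempfile(fileext = ".gff3")
  writeLines(lines, gff)
  model <- parse_annotation(gff, toy_fasta())
  ss <- extract_splice_sites(model, intron_catalog(model))  # intron of 6 nt
  expect_true(all(ss$clipped))
  expect_equal(nchar(ss$five_ss), 3 + 6)
})
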