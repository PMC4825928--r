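test_that("genome and read generation are deterministic under a seed", {
  cfg <- sim_config(n_genes = 6, seed = 7)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  b1 <- build_toy_genome(cfg, d1)
  b2 <- build_toy_genome(cfg, d2)
  expect_identical(readLines(b1$fasta), readLines(b2$fasta))
  expect_identical(readLines(b1$gff3), readLines(b2$gff3))
  expect_identical(b1$truth, b2$truth)

  s1 <- file.path(d1, "a.sam"); s2 <- file.path(d1, "b.sam")
  simulate_reads(b1, "MUT", "rep1", s1)
  simulate_reads(b1, "MUT", "rep1", s2)
  expect_identical(readLines(s1), readLines(s2))
  s3 <- file.path(d1, "c.sam")
  simulate_reads(b1, "MUT", "rep2", s3)
  expect_false(identical(readLines(s1), readLines(s3)))
})

test_that("every simulated intron starts GT and ends AG on the coding strand", {
  cfg <- sim_config(n_genes = 12, seed = 23)
  b <- build_toy_genome(cfg, withr::local_tempdir())
  seqs <- interval_seqs(b$model, intron_catalog(b$model))
  expect_true(all(substr(seqs, 1, 2) == "GT"))
  expect_true(all(substr(seqs, nchar(seqs) - 1, nchar(seqs)) == "AG"))
  expect_true(any(b$truth$strand == "-"))   # both strands exercised
})

test_that("closed-form expected retention matches position enumeration", {
  # spot values, pre-verified by the coordinate-level oracle
  expect_equal(expected_retention(0.5, 80, 50, 300), 64.5 / 291,
               tolerance = 1e-12)
  expect_equal(expected_retention(1, 80, 50, 300), 129 / 331,
               tolerance = 1e-12)
  expect_equal(expected_retention(0, 80, 50, 300), 0)
  expect_true(is.na(expected_retention(0.5, 80, 400, 300)))

  exons <- rbind(c(1, 150), c(231, 380))     # Le = 300, intron 80
  intr <- rbind(c(151, 230))
  for (th in c(0.2, 0.5, 1)) {
    orc <- oracle_expectations(exons, intr, th, 50)
    expect_equal(expected_retention(th, 80, 50, 300), orc$ir,
                 tolerance = 1e-12)
    expect_equal(expected_ir_enum(c(150, 150), 80, th, 50), orc$ir,
                 tolerance = 1e-12)
  }
})

test_that("multi-intron enumeration agrees with the coordinate-level oracle", {
  exons <- rbind(c(1, 120), c(201, 330), c(411, 520))
  intr <- rbind(c(121, 200), c(331, 410))
  th <- c(0.3, 0.7)
  orc <- oracle_expectations(exons, intr, th, 50)
  mine <- expected_ir_enum(c(120, 130, 110), c(80, 80), th, 50)
  expect_equal(mine, orc$ir, tolerance = 1e-12)
})

test_that("expected retention is strictly monotone in theta", {
  th <- seq(0, 1, by = 0.05)
  ir <- expected_retention(th, 80, 50, 300)
  expect_true(all(diff(ir) > 0))
  ir2 <- vapply(th, function(t)
    expected_ir_enum(c(150, 150, 150), c(80, 60), c(t, 0.3), 50)[1],
    numeric(1))
  expect_true(all(diff(ir2) > 0))
})

test_that("emitted SAM is valid and geometrically consistent", {
  cfg <- sim_config(n_genes = 8, seed = 29,
                    expression_range = c(300, 300))
  b <- build_toy_genome(cfg, withr::local_tempdir())
  sam <- file.path(withr::local_tempdir(), "s.sam")
  simulate_reads(b, "MUT", "rep1", sam)
  aln <- read_spliced_alignments(sam)       # strict parse via Rsamtools
  expect_gt(length(aln), 0)
  # CIGAR reference span equals end - start + 1
  expect_equal(GenomicAlignments::cigarWidthAlongReferenceSpace(
    GenomicAlignments::cigar(aln)),
    GenomicRanges::end(aln) - GenomicRanges::start(aln) + 1)
  # M widths sum to the read length
  expect_true(all(GenomicAlignments::cigarWidthAlongQuerySpace(
    GenomicAlignments::cigar(aln)) == cfg$read_len))
  # every N gap matches an annotated intron exactly
  gaps <- unique(unlist(GenomicAlignments::junctions(aln)))
  ir <- b$model$introns
  key <- paste(GenomeInfoDb::seqnames(ir), GenomicRanges::start(ir),
               GenomicRanges::end(ir))
  gkey <- paste(GenomeInfoDb::seqnames(gaps), GenomicRanges::start(gaps),
                GenomicRanges::end(gaps))
  expect_true(all(gkey %in% key))
})

test_that("fully spliced and fully unspliced limits hold", {
  d <- withr::local_tempdir()
  cfg0 <- sim_config(n_genes = 6, theta_wt = 0, fold_levels = 1, seed = 3)
  b0 <- build_toy_genome(cfg0, file.path(d, "g0"))
  sam0 <- file.path(d, "s0.sam")
  simulate_reads(b0, "WT", "r1", sam0)
  ct0 <- count_reads(read_spliced_alignments(sam0), b0$model)
  expect_equal(sum(ct0$introns$n_intron), 0)
  expect_gt(sum(ct0$introns$n_junction), 0)

  cfg1 <- sim_config(n_genes = 6, theta_wt = 1, fold_levels = 1, seed = 3)
  b1 <- build_toy_genome(cfg1, file.path(d, "g1"))
  sam1 <- file.path(d, "s1.sam")
  simulate_reads(b1, "WT", "r1", sam1)
  aln1 <- read_spliced_alignments(sam1)
  expect_equal(sum(GenomicAlignments::njunc(aln1)), 0)
})

test_that("empirical retention matches the analytic expectation", {
  # two (theta, geometry) draws at moderate depth; the acceptance suite
  # covers the full 20-draw sweep
  for (seed in c(41, 43)) {
    cfg <- sim_config(n_genes = 4, introns_per_gene = 1,
                      theta_wt = c(0.1, 0.8), fold_levels = 1,
                      expression_range = c(4000, 4000), seed = seed)
    b <- build_toy_genome(cfg, withr::local_tempdir())
    sam <- tempfile(fileext = ".sam")
    simulate_reads(b, "WT", "r1", sam)
    ct <- count_reads(read_spliced_alignments(sam), b$model)
    m <- merge(ct$introns, b$truth[, c("intron_id", "expected_ir_WT")],
               by = "intron_id")
    se <- sqrt(m$expected_ir_WT * (1 - m$expected_ir_WT) / m$n_transcript)
    z <- (m$n_intron / m$n_transcript - m$expected_ir_WT) / se
    expect_true(all(abs(z) < 3))
  }
})
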