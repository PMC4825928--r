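test_that("manual reads over the toy transcript are counted by the stated rules", {
  model <- toy_model(with_genome = FALSE)
  cat_gr <- intron_catalog(model)
  # intron 1 = 101-150; reads: fully exonic, 10 nt into intron 1, and a
  # junction read whose gap is exactly intron 1
  reads <- data.frame(pos = c(10, 141, 91),
                      cigar = c("50M", "50M", "10M50N40M"))
  ct <- count_reads(read_spliced_alignments(write_toy_sam(reads)), model,
                    catalog = cat_gr)
  expect_equal(ct$transcripts$n_transcript[
    ct$transcripts$transcript_id == "gA.t1"], 3)
  i1 <- ct$introns[ct$introns$intron_id == "gA.t1.i1", ]
  i2 <- ct$introns[ct$introns$intron_id == "gA.t1.i2", ]
  expect_equal(c(i1$n_intron, i1$n_junction), c(1, 1))
  expect_equal(c(i2$n_intron, i2$n_junction), c(0, 0))
  expect_equal(ct$library_size, 3)
})

test_that("junction counting requires an exact gap match", {
  model <- toy_model(with_genome = FALSE)
  reads <- data.frame(pos = 91, cigar = "10M49N40M")  # gap 101-149
  ct <- count_reads(read_spliced_alignments(write_toy_sam(reads)), model)
  i1 <- ct$introns[ct$introns$intron_id == "gA.t1.i1", ]
  expect_equal(i1$n_junction, 0)
  expect_equal(i1$n_transcript, 1)
})

test_that("empty alignment sets give zero tables and CPM refuses them", {
  model <- toy_model(with_genome = FALSE)
  ct <- count_reads(read_spliced_alignments(
    write_toy_sam(data.frame(pos = integer(0), cigar = character(0)))),
    model)
  expect_equal(ct$library_size, 0)
  expect_true(all(ct$introns$n_intron == 0))
  expect_error(compute_cpm(ct), "library size")
})

test_that("CPM arithmetic and inclusive thresholding", {
  ct <- structure(list(
    genes = data.frame(gene_id = c("g1", "g2"), n_gene = c(300L, 700L)),
    library_size = 1000L), class = "count_table")
  cpm <- compute_cpm(ct)
  expect_equal(cpm$cpm, c(3e5, 7e5))

  # CPM 9.99 fails the >= 10 filter; CPM 10.00 passes
  mk <- function(n, lib) structure(list(
    genes = data.frame(gene_id = "g", n_gene = n),
    introns = data.frame(intron_id = "g.t1.i1", gene_id = "g",
                         n_intron = 0L, n_junction = 0L,
                         n_transcript = n),
    library_size = lib), class = "count_table")
  ret_fail <- retention_level(list(s1 = mk(999L, 1e8)), cpm_threshold = 10)
  ret_pass <- retention_level(list(s1 = mk(1000L, 1e8)), cpm_threshold = 10)
  expect_false(any(ret_fail$pass_expression))
  expect_true(all(ret_pass$pass_expression))
})

test_that("counting matches the all-pairs brute-force oracle exactly", {
  set.seed(61)
  for (rep in 1:4) {
    cfg <- sim_config(n_genes = 5, seed = 100 + rep,
                      expression_range = c(30, 40))
    b <- build_toy_genome(cfg, withr::local_tempdir())
    sam <- tempfile(fileext = ".sam")
    simulate_reads(b, "MUT", "r1", sam)
    cat_gr <- intron_catalog(b$model)
    ct <- count_reads(read_spliced_alignments(sam), b$model,
                      catalog = cat_gr)
    tabs <- model_tables(b$model, cat_gr)
    orc <- oracle_count(oracle_parse_sam(sam), tabs$transcripts,
                        tabs$introns, tabs$intron_tx)
    expect_equal(ct$library_size, orc$library_size)
    expect_equal(stats::setNames(ct$transcripts$n_transcript,
                                 ct$transcripts$transcript_id),
                 orc$n_transcript[ct$transcripts$transcript_id])
    expect_equal(stats::setNames(ct$introns$n_intron, ct$introns$intron_id),
                 orc$n_intron[ct$introns$intron_id])
    expect_equal(stats::setNames(ct$introns$n_junction,
                                 ct$introns$intron_id),
                 orc$n_junction[ct$introns$intron_id])
    expect_equal(stats::setNames(ct$introns$n_transcript,
                                 ct$introns$intron_id),
                 orc$n_tx_union[ct$introns$intron_id])
  }
})

test_that("intron plus junction evidence never exceeds transcript reads", {
  cfg <- sim_config(n_genes = 10, seed = 71)
  b <- build_toy_genome(cfg, withr::local_tempdir())
  sam <- tempfile(fileext = ".sam")
  simulate_reads(b, "MUT", "r1", sam)
  ct <- count_reads(read_spliced_alignments(sam), b$model)
  expect_true(all(ct$introns$n_intron + ct$introns$n_junction <=
                    ct$introns$n_transcript))
})

test_that("retention levels follow the definition, with NA for unexpressed", {
  mk <- function(n_in, n_tx) structure(list(
    genes = data.frame(gene_id = "g", n_gene = max(n_tx, 1L)),
    introns = data.frame(intron_id = "g.t1.i1", gene_id = "g",
                         n_intron = n_in, n_junction = 0L,
                         n_transcript = n_tx),
    library_size = max(n_tx, 1L)), class = "count_table")
  expect_equal(retention_level(list(a = mk(5L, 100L)), 0)$ir, 0.05)
  expect_equal(retention_level(list(a = mk(0L, 100L)), 0)$ir, 0)
  expect_true(is.na(retention_level(list(a = mk(0L, 0L)), 0)$ir))
})

test_that("isoform retention fractions match definitions and simulation", {
  mk <- function(n_in, n_jc) structure(list(
    introns = data.frame(intron_id = "x.i4", gene_id = "x",
                         n_intron = n_in, n_junction = n_jc,
                         n_transcript = n_in + n_jc)),
    class = "count_table")
  f <- isoform_retention_fraction(mk(15L, 85L), "x.i4")
  expect_equal(f$fraction_spliced, 0.85)
  expect_equal(isoform_retention_fraction(mk(0L, 50L), "x.i4")$fraction_retained, 0)
  expect_true(is.na(isoform_retention_fraction(mk(2L, 3L), "x.i4")$fraction_retained))

  # against the coordinate-level junction/overlap expectation at theta 0.2
  cfg <- sim_config(n_genes = 1, introns_per_gene = 1,
                    exon_len_range = c(150, 150), intron_len_range = c(80, 80),
                    expression_range = c(8000, 8000), theta_wt = 0.2,
                    fold_levels = 1, seed = 83)
  b <- build_toy_genome(cfg, withr::local_tempdir())
  sam <- tempfile(fileext = ".sam")
  simulate_reads(b, "WT", "r1", sam)
  ct <- count_reads(read_spliced_alignments(sam), b$model)
  est <- isoform_retention_fraction(ct, ct$introns$intron_id[1])
  # gene-local geometry: exon 1-150, intron 151-230, exon 231-380
  orc <- oracle_expectations(rbind(c(1, 150), c(231, 380)),
                             rbind(c(151, 230)), 0.2, 50)
  # expectation of the two-isoform estimator from per-read probabilities
  p_ret <- orc$ir / (orc$ir + orc$junction)
  se <- sqrt(p_ret * (1 - p_ret) / est$n_informative)
  expect_lt(abs(est$fraction_retained - p_ret), 3 * se)
})
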