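#' Read spliced alignments from SAM or BAM
#'
#' SAM input is converted to BAM on the fly (Rsamtools) and parsed with
#' GenomicAlignments, so aligned blocks (CIGAR M runs) and skip gaps
#' (N runs) are available downstream.
#'
#' @param path SAM or BAM file.
#' @return A `GAlignments` object.
#' @export
read_spliced_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path,
                            destination = tempfile("aln"),
                            overwrite = TRUE, indexDestination = TRUE)
  } else bam <- path
  GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(what = "mapq"))
}

#' Count transcript, intron and junction reads for one sample
#'
#' Assignment rules: a read counts toward a transcript when any of its
#' aligned blocks overlaps the transcript's genomic span (exons plus
#' introns) by at least `min_overlap` nt; toward an intron when any block
#' overlaps the intron by at least `min_overlap` nt (a read may count for
#' several introns but at most once per intron); toward the junction of an
#' intron when one of its N gaps matches the intron interval exactly.
#' Reads whose gap spans an intron are junction evidence only — they never
#' count as intron reads. Library size is the number of distinct reads
#' assigned to at least one transcript.
#'
#' @param alignments A `GAlignments` (from [read_spliced_alignments()]).
#' @param model A `genome_model`.
#' @param catalog Optional intron catalog (computed from the model if
#'   missing).
#' @param min_overlap Minimum block overlap in nt (default 1).
#' @param min_mapq Minimum mapping quality (default 0; the conventional
#'   255 = "unavailable" passes any threshold up to 255).
#' @return A list of class `count_table`: `transcripts` (transcript_id,
#'   gene_id, n_transcript), `genes` (gene_id, n_gene), `introns`
#'   (intron_id, gene_id, n_intron, n_junction, n_transcript — the union of
#'   reads over the intron's transcripts), `library_size`, and
#'   `n_skipped_chrom` (reads on chromosomes absent from the model).
#' @export
count_reads <- function(alignments, model, catalog = NULL,
                        min_overlap = 1, min_mapq = 0) {
  stopifnot(inherits(model, "genome_model"))
  if (is.null(catalog)) catalog <- intron_catalog(model)

  mq <- S4Vectors::mcols(alignments)$mapq
  if (!is.null(mq)) {
    keep <- is.na(mq) | mq >= min_mapq
    alignments <- alignments[keep]
  }
  known <- as.character(GenomeInfoDb::seqnames(model$seqinfo))
  on_known <- as.character(GenomeInfoDb::seqnames(alignments)) %in% known
  n_skipped <- sum(!on_known)
  if (n_skipped > 0) {
    warning(n_skipped, " alignment(s) on chromosomes absent from the model; skipped")
    alignments <- alignments[on_known]
  }

  n_reads <- length(alignments)
  blocks <- GenomicAlignments::grglist(alignments)   # M blocks per read
  flat <- unlist(blocks, use.names = FALSE)
  read_of_block <- rep(seq_len(n_reads), S4Vectors::elementNROWS(blocks))
  # unstranded counting on plain ranges (no seqinfo clashes)
  flat <- GenomicRanges::GRanges(as.character(GenomeInfoDb::seqnames(flat)),
                                 IRanges::ranges(flat))

  tx <- model$transcripts
  tx_star <- GenomicRanges::GRanges(
    as.character(GenomeInfoDb::seqnames(tx)), IRanges::ranges(tx))
  hits <- GenomicRanges::findOverlaps(flat, tx_star,
                                      minoverlap = min_overlap)
  tx_pairs <- unique(data.frame(
    read = read_of_block[S4Vectors::queryHits(hits)],
    tx = S4Vectors::subjectHits(hits)))
  n_transcript <- tabulate(tx_pairs$tx, nbins = length(tx))
  assigned_reads <- unique(tx_pairs$read)
  library_size <- length(assigned_reads)

  gene_ids <- unique(tx$gene_id)
  gene_pairs <- unique(data.frame(
    read = tx_pairs$read,
    gene = match(tx$gene_id[tx_pairs$tx], gene_ids)))
  n_gene <- tabulate(gene_pairs$gene, nbins = length(gene_ids))

  cat_star <- GenomicRanges::GRanges(
    as.character(GenomeInfoDb::seqnames(catalog)), IRanges::ranges(catalog))
  ih <- GenomicRanges::findOverlaps(flat, cat_star, minoverlap = min_overlap)
  in_pairs <- unique(data.frame(
    read = read_of_block[S4Vectors::queryHits(ih)],
    intron = S4Vectors::subjectHits(ih)))
  n_intron <- tabulate(in_pairs$intron, nbins = length(catalog))

  gaps <- GenomicAlignments::junctions(alignments)
  gflat <- unlist(gaps, use.names = FALSE)
  if (length(gflat) > 0) {
    read_of_gap <- rep(seq_len(n_reads), S4Vectors::elementNROWS(gaps))
    gflat <- GenomicRanges::GRanges(
      as.character(GenomeInfoDb::seqnames(gflat)), IRanges::ranges(gflat))
    jh <- GenomicRanges::findOverlaps(gflat, cat_star, type = "equal")
    j_pairs <- unique(data.frame(
      read = read_of_gap[S4Vectors::queryHits(jh)],
      intron = S4Vectors::subjectHits(jh)))
    n_junction <- tabulate(j_pairs$intron, nbins = length(catalog))
  } else n_junction <- rep(0L, length(catalog))

  # per-intron transcript denominator: distinct reads assigned to any of
  # the catalog entry's transcripts
  tx_index <- stats::setNames(seq_along(tx), tx$transcript_id)
  reads_by_tx <- split(tx_pairs$read, tx_pairs$tx)
  n_tx_union <- vapply(seq_along(catalog), function(i) {
    idx <- as.character(tx_index[unlist(catalog$transcript_ids[[i]])])
    length(unique(unlist(reads_by_tx[idx], use.names = FALSE)))
  }, integer(1))

  structure(list(
    transcripts = data.frame(transcript_id = tx$transcript_id,
                             gene_id = tx$gene_id,
                             n_transcript = n_transcript,
                             stringsAsFactors = FALSE),
    genes = data.frame(gene_id = gene_ids, n_gene = n_gene,
                       stringsAsFactors = FALSE),
    introns = data.frame(intron_id = catalog$intron_id,
                         gene_id = catalog$gene_id,
                         n_intron = n_intron, n_junction = n_junction,
                         n_transcript = n_tx_union,
                         stringsAsFactors = FALSE),
    library_size = library_size,
    n_skipped_chrom = n_skipped
  ), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", x$library_size, "assigned reads,",
      nrow(x$genes), "genes,", nrow(x$introns), "introns\n")
  invisible(x)
}

#' Counts per million assigned reads, per gene
#'
#' CPM(g) = 1e6 * n_gene(g) / library_size, where n_gene counts each read
#' once however many of the gene's transcripts it overlaps.
#'
#' @param count_table A `count_table`.
#' @return data.frame(gene_id, n_gene, cpm).
#' @export
compute_cpm <- function(count_table) {
  stopifnot(inherits(count_table, "count_table"))
  if (count_table$library_size < 1) stop("library size is zero")
  g <- count_table$genes
  g$cpm <- 1e6 * g$n_gene / count_table$library_size
  g
}

#' Per-intron retention levels across samples, with the expression filter
#'
#' The intron retention level is the number of reads aligned within the
#' intron divided by the number of reads aligned to the corresponding
#' transcript (union of transcripts sharing the intron). An intron's gene
#' passes the expression filter when its CPM reaches `cpm_threshold`
#' (inclusive) in every sample (or any sample, when
#' `require_all_samples = FALSE`).
#'
#' @param count_tables Named list of `count_table`s, one per sample.
#' @param cpm_threshold CPM cutoff (default 10; 1 is the permissive
#'   alternative).
#' @param require_all_samples Expression must pass in every sample.
#' @return data.frame with one row per (intron, sample): `intron_id`,
#'   `gene_id`, `sample`, `n_intron`, `n_junction`, `n_transcript`, `ir`
#'   (NA when the transcript has no reads), `cpm`, `pass_expression`.
#' @export
retention_level <- function(count_tables, cpm_threshold = 10,
                            require_all_samples = TRUE) {
  stopifnot(length(count_tables) > 0)
  samples <- names(count_tables)
  if (is.null(samples)) stop("count_tables must be a named list")
  rows <- lapply(samples, function(s) {
    ct <- count_tables[[s]]
    cpm <- compute_cpm(ct)
    d <- ct$introns
    d$sample <- s
    d$ir <- ifelse(d$n_transcript >= 1, d$n_intron / d$n_transcript, NA_real_)
    d$cpm <- cpm$cpm[match(d$gene_id, cpm$gene_id)]
    d
  })
  out <- do.call(rbind, rows)
  pass_by_gene <- tapply(out$cpm >= cpm_threshold, out$gene_id,
                         if (require_all_samples) all else any)
  out$pass_expression <- as.logical(pass_by_gene[out$gene_id])
  rownames(out) <- NULL
  out
}

#' Two-isoform retention fraction for a single intron
#'
#' The PSI-like estimator distinguishing the intron-retaining isoform from
#' the spliced isoform: fraction_retained = n_intron / (n_intron +
#' n_junction).
#'
#' @param count_table A `count_table`.
#' @param intron_id Catalog intron id.
#' @param min_informative Minimum informative (intron + junction) reads;
#'   below it the estimate is NA.
#' @return list(fraction_retained, fraction_spliced, n_informative).
#' @export
isoform_retention_fraction <- function(count_table, intron_id,
                                       min_informative = 10) {
  stopifnot(inherits(count_table, "count_table"))
  row <- count_table$introns[count_table$introns$intron_id == intron_id, ]
  if (nrow(row) != 1) stop("intron ", intron_id, " not in catalog")
  n_inf <- row$n_intron + row$n_junction
  if (n_inf < min_informative) {
    return(list(fraction_retained = NA_real_, fraction_spliced = NA_real_,
                n_informative = n_inf))
  }
  fr <- row$n_intron / n_inf
  list(fraction_retained = fr, fraction_spliced = 1 - fr,
       n_informative = n_inf)
}
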