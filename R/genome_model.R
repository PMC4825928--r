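#' @importFrom methods is as
NULL

#' Parse a GFF3 annotation (and optionally a genome FASTA) into an
#' intron-aware gene model
#'
#' Builds a gene -> transcript -> exon hierarchy from a GFF3 file and derives
#' the introns of every multi-exon transcript as the gaps between consecutive
#' exons. GFF3 coordinates (1-based, closed) are converted once, at this
#' parser, into the GRanges representation used throughout the package.
#'
#' Intron ordinals follow transcription order: for a minus-strand transcript,
#' intron 1 is the intron closest to the transcription start site, not the
#' one with the lowest genomic coordinate.
#'
#' @param gff3_path Path to a GFF3 file with gene/mRNA/exon features linked
#'   by `ID`/`Parent` attributes.
#' @param fasta_path Optional path to the genome FASTA. Sequences can also be
#'   attached later with [attach_genome()].
#' @return An object of class `genome_model`: a list with `seqinfo`
#'   (chromosome lengths), `genes`, `transcripts`, `exons` and `introns`
#'   (GRanges), and `genome` (a `DNAStringSet`, or `NULL`).
#'
#' Exons falling outside their chromosome bounds are dropped with a warning;
#' a transcript with overlapping exons, or an exon without a parent
#' transcript, is a hard error.
#' @export
parse_annotation <- function(gff3_path, fasta_path = NULL) {
  gff <- rtracklayer::import(gff3_path, format = "gff3")
  genome <- NULL
  if (!is.null(fasta_path)) {
    genome <- Biostrings::readDNAStringSet(fasta_path)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }

  chrlen <- chrom_lengths(gff, genome)

  is_gene <- gff$type == "gene"
  is_tx   <- gff$type %in% c("mRNA", "transcript")
  is_exon <- gff$type == "exon"
  if (!any(is_tx)) stop("no mRNA/transcript features in ", gff3_path)
  if (!any(is_exon)) stop("no exon features in ", gff3_path)

  gene_gr <- gff[is_gene]
  tx_gr   <- gff[is_tx]
  exon_gr <- gff[is_exon]

  tx_parent <- first_parent(tx_gr$Parent)
  if (anyNA(tx_parent)) {
    stop("transcript(s) without a gene Parent: ",
         paste(stats::na.omit(tx_gr$ID[is.na(tx_parent)]), collapse = ", "))
  }
  exon_parent <- first_parent(exon_gr$Parent)
  if (anyNA(exon_parent)) stop("exon(s) without a Parent transcript link")
  unknown <- setdiff(exon_parent, tx_gr$ID)
  if (length(unknown) > 0) {
    stop("exon Parent(s) reference unknown transcripts: ",
         paste(unknown, collapse = ", "))
  }

  # Exon bounds check against chromosome lengths (when known).
  len_of <- chrlen[as.character(GenomeInfoDb::seqnames(exon_gr))]
  bad <- !is.na(len_of) &
    (GenomicRanges::start(exon_gr) < 1 | GenomicRanges::end(exon_gr) > len_of)
  if (any(bad)) {
    warning(sum(bad), " exon record(s) outside chromosome bounds; dropped")
    exon_gr <- exon_gr[!bad]
    exon_parent <- exon_parent[!bad]
  }

  tx2gene <- setNames(tx_parent, tx_gr$ID)

  exons_by_tx <- split(seq_along(exon_gr), exon_parent)
  exon_rows <- list(); intron_rows <- list()
  for (tx_id in names(exons_by_tx)) {
    idx <- exons_by_tx[[tx_id]]
    ex <- exon_gr[idx]
    ord <- order(GenomicRanges::start(ex))
    ex <- ex[ord]
    st <- GenomicRanges::start(ex); en <- GenomicRanges::end(ex)
    if (length(ex) > 1 && any(st[-1] <= en[-length(en)])) {
      stop("transcript ", tx_id, " has overlapping exons")
    }
    strand <- as.character(GenomicRanges::strand(ex))[1]
    chrom <- as.character(GenomeInfoDb::seqnames(ex))[1]
    n <- length(ex)
    exon_rows[[tx_id]] <- data.frame(
      chrom = chrom, start = st, end = en, strand = strand,
      transcript_id = tx_id, gene_id = unname(tx2gene[tx_id]),
      exon_rank = if (strand == "-") rev(seq_len(n)) else seq_len(n),
      stringsAsFactors = FALSE)
    if (n > 1) {
      i_st <- en[-n] + 1L; i_en <- st[-1] - 1L
      keep <- i_en >= i_st
      if (!all(keep)) warning("transcript ", tx_id,
                              " has abutting exons; zero-length gap dropped")
      i_st <- i_st[keep]; i_en <- i_en[keep]
      if (length(i_st) > 0) {
        k <- length(i_st)
        ordinal <- if (strand == "-") rev(seq_len(k)) else seq_len(k)
        intron_rows[[tx_id]] <- data.frame(
          chrom = chrom, start = i_st, end = i_en, strand = strand,
          transcript_id = tx_id, gene_id = unname(tx2gene[tx_id]),
          ordinal = ordinal,
          intron_id = paste0(tx_id, ".i", ordinal),
          stringsAsFactors = FALSE)
      }
    }
  }

  seqinfo <- GenomeInfoDb::Seqinfo(seqnames = names(chrlen),
                                   seqlengths = unname(chrlen))

  df2gr <- function(df) {
    if (length(df) == 0 || nrow(df) == 0) {
      return(GenomicRanges::GRanges(seqinfo = seqinfo))
    }
    gr <- GenomicRanges::GRanges(
      seqnames = df$chrom,
      ranges = IRanges::IRanges(df$start, df$end),
      strand = df$strand, seqinfo = seqinfo)
    S4Vectors::mcols(gr) <- df[, setdiff(names(df),
                                         c("chrom", "start", "end", "strand")),
                               drop = FALSE]
    gr
  }

  exon_df <- do.call(rbind, exon_rows)
  intron_df <- if (length(intron_rows)) do.call(rbind, intron_rows) else NULL
  exons <- df2gr(exon_df)

  # Transcript and gene spans derived from their exons.
  tx_span <- range_by(exons, exons$transcript_id, seqinfo)
  tx_span$transcript_id <- names(tx_span)
  tx_span$gene_id <- unname(tx2gene[tx_span$transcript_id])
  tx_span$n_exons <- as.integer(table(exon_df$transcript_id)[tx_span$transcript_id])
  names(tx_span) <- NULL

  gene_span <- range_by(exons, exons$gene_id, seqinfo)
  gene_span$gene_id <- names(gene_span)
  names(gene_span) <- NULL

  model <- structure(list(
    seqinfo = seqinfo,
    genes = gene_span,
    transcripts = tx_span,
    exons = exons,
    introns = df2gr(intron_df),
    genome = genome
  ), class = "genome_model")
  model
}

# Single-interval genomic span per group (groups never span chromosomes).
range_by <- function(gr, f, seqinfo) {
  st <- tapply(GenomicRanges::start(gr), f, min)
  en <- tapply(GenomicRanges::end(gr), f, max)
  first <- !duplicated(f)
  ord <- match(names(st), f[first])
  out <- GenomicRanges::GRanges(
    seqnames = as.character(GenomeInfoDb::seqnames(gr))[first][ord],
    ranges = IRanges::IRanges(as.integer(st), as.integer(en)),
    strand = as.character(GenomicRanges::strand(gr))[first][ord],
    seqinfo = seqinfo)
  names(out) <- names(st)
  out
}

first_parent <- function(parent) {
  if (is.null(parent)) return(NA_character_)
  vapply(as.list(parent), function(p) {
    if (length(p) == 0) NA_character_ else p[[1]]
  }, character(1))
}

chrom_lengths <- function(gff, genome) {
  if (!is.null(genome)) {
    return(setNames(Biostrings::width(genome), names(genome)))
  }
  si <- GenomeInfoDb::seqinfo(gff)
  setNames(GenomeInfoDb::seqlengths(si), GenomeInfoDb::seqnames(si))
}

#' Attach genome sequence to a parsed gene model
#'
#' @param model A `genome_model`.
#' @param fasta_path Path to the genome FASTA.
#' @return The model with `genome` populated.
#' @export
attach_genome <- function(model, fasta_path) {
  stopifnot(inherits(model, "genome_model"))
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  model$genome <- genome
  model
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", length(x$genes), "genes,",
      length(x$transcripts), "transcripts,",
      length(x$exons), "exons,",
      length(x$introns), "introns",
      if (is.null(x$genome)) "(no genome attached)" else "(genome attached)",
      "\n")
  invisible(x)
}

#' Deduplicated intron catalog of a gene model
#'
#' Introns are defined per transcript; transcripts of the same gene that
#' imply an identical genomic interval are merged into one catalog entry
#' carrying all their transcript ids. Entries are deterministically ordered
#' by (chromosome, start, end, first transcript id). Mean intron length and
#' the introns-per-gene distribution are stored in `S4Vectors::metadata()`.
#'
#' @param model A `genome_model`.
#' @return A GRanges with metadata columns `intron_id`, `gene_id`,
#'   `ordinal`, `transcript_ids` (CharacterList) and `length`.
#' @export
intron_catalog <- function(model) {
  stopifnot(inherits(model, "genome_model"))
  ir <- model$introns
  if (length(ir) == 0) {
    out <- GenomicRanges::GRanges(seqinfo = model$seqinfo)
    S4Vectors::metadata(out) <- list(mean_intron_length = NA_real_,
                                     introns_per_gene = integer(0))
    return(out)
  }
  key <- paste(GenomeInfoDb::seqnames(ir), GenomicRanges::start(ir),
               GenomicRanges::end(ir), GenomicRanges::strand(ir),
               ir$gene_id, sep = "\r")
  ord <- order(ir$transcript_id)
  ir <- ir[ord]; key <- key[ord]
  first <- !duplicated(key)
  tx_ids <- split(ir$transcript_id, key)
  cat_gr <- ir[first]
  cat_gr$transcript_ids <- IRanges::CharacterList(
    tx_ids[key[first]])
  cat_gr$transcript_id <- NULL
  cat_gr$length <- GenomicRanges::width(cat_gr)
  o <- order(as.character(GenomeInfoDb::seqnames(cat_gr)),
             GenomicRanges::start(cat_gr), GenomicRanges::end(cat_gr),
             cat_gr$intron_id)
  cat_gr <- cat_gr[o]

  per_gene <- table(factor(cat_gr$gene_id, levels = model$genes$gene_id))
  S4Vectors::metadata(cat_gr) <- list(
    mean_intron_length = mean(cat_gr$length),
    introns_per_gene = as.integer(per_gene))
  names(S4Vectors::metadata(cat_gr)$introns_per_gene) <- names(per_gene)
  cat_gr
}

#' Coding-strand nucleotide sequences for a set of intervals
#'
#' @param model A `genome_model` with genome attached.
#' @param gr GRanges of intervals (minus-strand intervals are
#'   reverse-complemented).
#' @return A named character vector (names taken from `gr$intron_id` when
#'   present).
#' @export
interval_seqs <- function(model, gr) {
  stopifnot(inherits(model, "genome_model"))
  if (is.null(model$genome)) stop("no genome attached to model")
  seqs <- character(length(gr))
  chrom <- as.character(GenomeInfoDb::seqnames(gr))
  st <- GenomicRanges::start(gr); en <- GenomicRanges::end(gr)
  neg <- as.character(GenomicRanges::strand(gr)) == "-"
  for (i in seq_along(gr)) {
    s <- Biostrings::subseq(model$genome[[chrom[i]]], st[i], en[i])
    if (neg[i]) s <- Biostrings::reverseComplement(s)
    seqs[i] <- as.character(s)
  }
  if (!is.null(gr$intron_id)) names(seqs) <- gr$intron_id
  seqs
}

#' Extract splice-site windows around intron boundaries
#'
#' Returns coding-strand-oriented windows centered on the exon|intron
#' boundaries: the 5' splice site window spans `exonic5` exonic plus
#' `intronic5` intronic nucleotides, and the 3' splice site window
#' `intronic3` intronic plus `exonic3` exonic nucleotides. Minus-strand
#' windows are reverse-complemented. A window whose intronic part exceeds
#' the intron, or that runs off the chromosome, is clipped and flagged.
#'
#' @param model A `genome_model` with genome attached.
#' @param introns GRanges of introns (e.g. from [intron_catalog()]).
#' @param exonic5,intronic5 5'ss window sizes in nt (defaults 3 + 8).
#' @param intronic3,exonic3 3'ss window sizes in nt (defaults 12 + 3).
#' @return data.frame with `intron_id`, `five_ss`, `three_ss`, `clipped`.
#' @export
extract_splice_sites <- function(model, introns,
                                 exonic5 = 3, intronic5 = 8,
                                 intronic3 = 12, exonic3 = 3) {
  stopifnot(inherits(model, "genome_model"))
  if (is.null(model$genome)) stop("no genome attached to model")
  chrlen <- setNames(GenomeInfoDb::seqlengths(model$seqinfo),
                     GenomeInfoDb::seqnames(model$seqinfo))
  n <- length(introns)
  five <- character(n); three <- character(n); clipped <- logical(n)
  chrom <- as.character(GenomeInfoDb::seqnames(introns))
  st <- GenomicRanges::start(introns); en <- GenomicRanges::end(introns)
  neg <- as.character(GenomicRanges::strand(introns)) == "-"
  ilen <- GenomicRanges::width(introns)

  fetch <- function(chr, a, b, revcomp) {
    L <- chrlen[chr]
    clip <- a < 1 || (!is.na(L) && b > L)
    a2 <- max(a, 1L); b2 <- if (is.na(L)) b else min(b, L)
    s <- Biostrings::subseq(model$genome[[chr]], a2, b2)
    if (revcomp) s <- Biostrings::reverseComplement(s)
    list(seq = as.character(s), clip = clip)
  }

  for (i in seq_len(n)) {
    in5 <- min(intronic5, ilen[i])
    in3 <- min(intronic3, ilen[i])
    cl <- in5 < intronic5 || in3 < intronic3
    if (!neg[i]) {
      f <- fetch(chrom[i], st[i] - exonic5, st[i] + in5 - 1L, FALSE)
      t <- fetch(chrom[i], en[i] - in3 + 1L, en[i] + exonic3, FALSE)
    } else {
      f <- fetch(chrom[i], en[i] - in5 + 1L, en[i] + exonic5, TRUE)
      t <- fetch(chrom[i], st[i] - exonic3, st[i] + in3 - 1L, TRUE)
    }
    five[i] <- f$seq; three[i] <- t$seq
    clipped[i] <- cl || f$clip || t$clip
  }
  ids <- if (!is.null(introns$intron_id)) introns$intron_id
         else as.character(seq_len(n))
  data.frame(intron_id = ids, five_ss = five, three_ss = three,
             clipped = clipped, stringsAsFactors = FALSE)
}

#' Write an intron catalog as BED6
#'
#' BED name is the intron id and score the intron length; BED uses 0-based
#' half-open coordinates on disk (conversion handled by rtracklayer).
#'
#' @param catalog GRanges from [intron_catalog()].
#' @param path Output path.
#' @export
write_intron_bed <- function(catalog, path) {
  gr <- catalog
  gr$name <- gr$intron_id
  gr$score <- GenomicRanges::width(gr)
  S4Vectors::mcols(gr) <- S4Vectors::mcols(gr)[, c("name", "score")]
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read an intron BED file back as GRanges
#' @param path Path to a BED6 file written by [write_intron_bed()].
#' @export
read_intron_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}
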