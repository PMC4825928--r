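#' Configuration for the spliced-read simulator
#'
#' The simulator emulates a two-condition, two-replicate RNA-seq design over
#' a toy genome: every intron has canonical GT..AG boundaries and one
#' embedded branch-point consensus at a recorded distance from the 3' end;
#' per-intron retention fractions (theta, the fraction of unspliced
#' molecules) are near zero in the wild-type condition and elevated in the
#' mutant by a per-intron fold factor.
#'
#' @param n_genes Number of genes.
#' @param introns_per_gene Integer vector sampled uniformly per gene
#'   (default 0:4 introns).
#' @param exon_len_range,intron_len_range Length ranges in bp; the intron
#'   default is centered near the fungal genome-wide average of ~83 bp.
#' @param expression_range Expected reads per gene per sample, drawn
#'   log-uniformly.
#' @param read_len Read length in bp; must not exceed the minimum exon
#'   length so that intron flanks always accommodate a full read.
#' @param theta_wt Wild-type per-intron retention fraction (scalar, or
#'   range of length 2 sampled uniformly).
#' @param fold_levels,fold_probs Mutant retention fold factors per intron
#'   and their sampling probabilities; theta_mut = min(1, theta_wt * fold).
#' @param conditions,replicates Condition names (first = reference) and
#'   replicates per condition.
#' @param bp_dist_range Distance range (nt) from the embedded branch A to
#'   the intron 3' end.
#' @param intergenic Intergenic spacer length in bp.
#' @param balanced_folds Assign `fold_levels` to introns cyclically instead
#'   of at random, giving (near-)equal group sizes.
#' @param seed Master seed; every downstream draw is derived from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 60,
                       introns_per_gene = 0:4,
                       exon_len_range = c(120, 300),
                       intron_len_range = c(60, 110),
                       expression_range = c(50, 1500),
                       read_len = 50,
                       theta_wt = 0.02,
                       fold_levels = c(1, 3, 6, 16),
                       fold_probs = NULL,
                       conditions = c("WT", "MUT"),
                       replicates = 2,
                       bp_dist_range = c(10, 50),
                       intergenic = 500,
                       balanced_folds = FALSE,
                       seed = 1) {
  if (any(theta_wt < 0) || any(theta_wt > 1)) stop("theta_wt must be in [0,1]")
  if (exon_len_range[1] < read_len) {
    stop("minimum exon length must be >= read_len so every molecule form ",
         "offers valid read start positions")
  }
  if (intron_len_range[1] < 20) stop("introns must be long enough for GT/AG ",
                                     "boundaries and a branch-point motif")
  if (is.null(fold_probs)) fold_probs <- rep(1 / length(fold_levels),
                                             length(fold_levels))
  structure(list(
    n_genes = n_genes, introns_per_gene = introns_per_gene,
    exon_len_range = exon_len_range, intron_len_range = intron_len_range,
    expression_range = expression_range, read_len = read_len,
    theta_wt = theta_wt, fold_levels = fold_levels, fold_probs = fold_probs,
    conditions = conditions, replicates = replicates,
    bp_dist_range = bp_dist_range, intergenic = intergenic,
    balanced_folds = balanced_folds, seed = seed
  ), class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

rand_bases <- function(n) sample(BASES, n, replace = TRUE)

# sample() without the scalar-x surprise (sample(5, 1) drawing from 1:5)
sample_vec <- function(x, n, prob = NULL) {
  x[sample.int(length(x), n, replace = TRUE, prob = prob)]
}

# Branch-point motif embedded by the generator: a concrete realization of
# the CTRAC consensus, branch A at position 4.
BP_MOTIF <- c("C", "T", "A", "A", "C")

# Generate one intron sequence in coding orientation: GT...AG with the BP
# motif planted so its branch A sits `bp_dist` nt from the 3' end. Rejection
# sampling guarantees the planted site is the unique call the consensus scan
# reports (no competing match displaces it under the tie-break), so the
# recorded position is exact ground truth.
make_intron_seq <- function(len, bp_dist, bp_window = c(5, 60),
                            max_tries = 100) {
  a_pos <- len - bp_dist            # 1-based branch A position
  m_start <- a_pos - 3
  stopifnot(m_start >= 3, a_pos + 1 <= len - 2)
  for (try in seq_len(max_tries)) {
    s <- rand_bases(len)
    s[1:2] <- c("G", "T"); s[(len - 1):len] <- c("A", "G")
    s[m_start:(m_start + 4)] <- BP_MOTIF
    seq <- paste(s, collapse = "")
    hit <- find_branch_point(stats::setNames(seq, "x"), bp_window = bp_window)
    if (isTRUE(hit$found[1]) && hit$bp_pos[1] == a_pos - 1) {
      return(list(seq = seq, bp_pos0 = a_pos - 1L))
    }
  }
  stop("failed to embed a uniquely recoverable branch point (len=", len, ")")
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Build a toy genome with known per-intron retention fractions
#'
#' Writes a FASTA and GFF3 for a simulated genome whose gene structures,
#' intron sequences (canonical GT/AG, embedded branch point, both strands)
#' and per-intron retention fractions are all recorded as ground truth. The
#' written files are parsed back through [parse_annotation()], so the
#' returned model has round-tripped through the package's own I/O.
#' Byte-identical output under a fixed seed.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if missing).
#' @return A list of class `sim_bundle`: `model` (genome_model), `truth`
#'   (per-intron data.frame with theta per condition and analytic expected
#'   IR), `genes` (per-gene expected depth), `fasta`, `gff3`, `config`.
#' @export
build_toy_genome <- function(config, dir = tempfile("simgenome")) {
  stopifnot(inherits(config, "sim_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(config$seed)

  n_chrom <- max(1L, min(4L, ceiling(config$n_genes / 25)))
  chrom_names <- paste0("chr", seq_len(n_chrom))
  chrom_of <- rep_len(chrom_names, config$n_genes)
  chrom_seq <- stats::setNames(vector("list", n_chrom), chrom_names)
  chrom_pos <- stats::setNames(rep(0L, n_chrom), chrom_names)

  gene_rows <- list(); truth_rows <- list()
  gff <- list("##gff-version 3")
  intron_counter <- 0L                 # drives cyclic fold assignment

  for (g in seq_len(config$n_genes)) {
    gid <- sprintf("g%03d", g); tid <- paste0(gid, ".t1")
    chrom <- chrom_of[g]
    k <- sample_vec(config$introns_per_gene, 1)
    exon_len <- sample_vec(config$exon_len_range[1]:config$exon_len_range[2],
                           k + 1)
    intron_len <- if (k > 0)
      sample_vec(config$intron_len_range[1]:config$intron_len_range[2], k)
    else integer(0)
    strand <- sample(c("+", "-"), 1)

    piece <- list(paste(rand_bases(config$intergenic), collapse = ""))
    gstart <- chrom_pos[[chrom]] + config$intergenic + 1L
    offset <- gstart
    ex_start <- integer(k + 1); ex_end <- integer(k + 1)
    in_start <- integer(k); in_end <- integer(k)
    bp_pos0 <- integer(k); bp_dist <- integer(k)
    for (j in seq_len(k + 1)) {
      ex_start[j] <- offset; ex_end[j] <- offset + exon_len[j] - 1L
      piece <- c(piece, list(paste(rand_bases(exon_len[j]), collapse = "")))
      offset <- ex_end[j] + 1L
      if (j <= k) {
        d <- sample_vec(config$bp_dist_range[1]:config$bp_dist_range[2], 1)
        d <- min(d, intron_len[j] - 10L)
        isq <- make_intron_seq(intron_len[j], d)
        # the genome stores the plus strand; minus-strand genes carry the
        # reverse complement of the coding-orientation intron sequence
        gseq <- if (strand == "-") revcomp_chr(isq$seq) else isq$seq
        in_start[j] <- offset; in_end[j] <- offset + intron_len[j] - 1L
        piece <- c(piece, list(gseq))
        bp_pos0[j] <- isq$bp_pos0; bp_dist[j] <- d
        offset <- in_end[j] + 1L
      }
    }
    chrom_seq[[chrom]] <- c(chrom_seq[[chrom]], piece)
    chrom_pos[[chrom]] <- ex_end[k + 1]

    expected_reads <- exp(stats::runif(1, log(config$expression_range[1]),
                                       log(config$expression_range[2])))

    gff[[length(gff) + 1]] <- c(
      sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              chrom, gstart, ex_end[k + 1], strand, gid),
      sprintf("%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              chrom, gstart, ex_end[k + 1], strand, tid, gid),
      sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
              chrom, ex_start, ex_end, strand, tid, seq_len(k + 1), tid))

    if (k > 0) {
      tw <- if (length(config$theta_wt) == 2)
        stats::runif(k, config$theta_wt[1], config$theta_wt[2])
      else rep(config$theta_wt, k)
      fold <- if (isTRUE(config$balanced_folds)) {
        config$fold_levels[(intron_counter + seq_len(k) - 1L) %%
                             length(config$fold_levels) + 1L]
      } else sample_vec(config$fold_levels, k, prob = config$fold_probs)
      intron_counter <- intron_counter + k
      tm <- pmin(1, tw * fold)
      ordinal <- if (strand == "-") rev(seq_len(k)) else seq_len(k)
      truth_rows[[gid]] <- data.frame(
        intron_id = paste0(tid, ".i", ordinal),
        gene_id = gid, transcript_id = tid,
        chrom = chrom, start = in_start, end = in_end, strand = strand,
        length = intron_len, ordinal = ordinal,
        bp_pos = bp_pos0, bp_dist_3ss = bp_dist,
        theta_WT = tw, theta_MUT = tm, fold = fold,
        stringsAsFactors = FALSE)
    }
    gene_rows[[gid]] <- data.frame(
      gene_id = gid, transcript_id = tid, chrom = chrom, strand = strand,
      n_introns = k, expected_reads = expected_reads,
      stringsAsFactors = FALSE)
  }

  genome <- Biostrings::DNAStringSet(vapply(chrom_seq, function(p)
    paste(unlist(p), collapse = ""), character(1)))
  fasta <- file.path(dir, "genome.fa")
  gff3 <- file.path(dir, "genes.gff3")
  Biostrings::writeXStringSet(genome, fasta, width = 80)
  writeLines(unlist(gff), gff3)

  model <- parse_annotation(gff3, fasta)
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(intron_id = character(0))
  rownames(truth) <- NULL
  genes <- do.call(rbind, gene_rows); rownames(genes) <- NULL

  bundle <- structure(list(model = model, truth = truth, genes = genes,
                           fasta = fasta, gff3 = gff3, config = config),
                      class = "sim_bundle")
  if (nrow(truth) > 0) {
    for (cond in c("WT", "MUT")) {
      bundle$truth[[paste0("expected_ir_", cond)]] <-
        truth_expected_ir(bundle, paste0("theta_", cond))
    }
  }
  bundle
}

# Analytic expected IR for every intron in the truth table, by molecule-form
# enumeration on each gene's geometry (exon lengths from the parsed model).
truth_expected_ir <- function(bundle, theta_col) {
  truth <- bundle$truth
  exons <- bundle$model$exons
  out <- numeric(nrow(truth))
  for (gid in unique(truth$gene_id)) {
    sel <- which(truth$gene_id == gid)
    o <- order(truth$start[sel]); sel <- sel[o]
    ex <- exons[exons$gene_id == gid]
    exon_lens <- GenomicRanges::width(ex)[order(GenomicRanges::start(ex))]
    out[sel] <- expected_ir_enum(exon_lens, truth$length[sel],
                                 truth[[theta_col]][sel],
                                 bundle$config$read_len)
  }
  out
}

#' Analytic expected intron retention level (single-intron closed form)
#'
#' For a transcript with one intron of length `m`, spliced exonic length
#' `Le`, read length `r` and unspliced-molecule fraction `theta`, the
#' expected retention level (intron-overlapping reads over transcript reads)
#' under uniform per-nucleotide read sampling is
#' \deqn{\theta (m + r - 1) / [\theta (L_u - r + 1) + (1-\theta)(L_e - r + 1)]}
#' with `Lu = Le + m`, assuming both intron flanks are at least `r` long.
#'
#' @param theta Unspliced-molecule fraction in `[0,1]` (vectorized).
#' @param m Intron length (bp).
#' @param r Read length (bp).
#' @param Le Spliced transcript length (bp).
#' @return Expected IR; `NA` when `r > Le` (no valid spliced read exists).
#' @export
expected_retention <- function(theta, m, r, Le) {
  stopifnot(all(theta >= 0 & theta <= 1))
  if (r > Le) return(rep(NA_real_, length(theta)))
  Lu <- Le + m
  num <- theta * (m + r - 1)
  den <- theta * (Lu - r + 1) + (1 - theta) * (Le - r + 1)
  num / den
}

#' Expected IR for a multi-intron transcript by molecule-form enumeration
#'
#' Enumerates all 2^k splicing forms (each intron retained independently
#' with its theta), weights each form by abundance times its number of
#' valid read start positions, and counts the start positions whose read
#' overlaps each intron by at least one nucleotide — the exact expectation
#' of the retention statistic under the simulator's sampling scheme.
#'
#' @param exon_lens Exon lengths in genomic order (k+1 values).
#' @param intron_lens Intron lengths in genomic order (k values).
#' @param thetas Per-intron retention fractions (k values).
#' @param r Read length.
#' @return Numeric vector of expected IR, one per intron (genomic order).
#' @export
expected_ir_enum <- function(exon_lens, intron_lens, thetas, r) {
  k <- length(intron_lens)
  stopifnot(length(exon_lens) == k + 1, length(thetas) == k)
  if (k == 0) return(numeric(0))
  forms <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), k)))
  Z <- 0; num <- numeric(k)
  for (f in seq_len(nrow(forms))) {
    keep <- forms[f, ]
    p <- prod(ifelse(keep, thetas, 1 - thetas))
    if (p == 0) next
    lens <- exon_lens[1]
    pos_of_intron <- rep(NA_real_, k)
    for (j in seq_len(k)) {
      if (keep[j]) {
        pos_of_intron[j] <- sum(lens)      # 0-based molecule offset
        lens <- c(lens, intron_lens[j])
      }
      lens <- c(lens, exon_lens[j + 1])
    }
    L <- sum(lens)
    npos <- L - r + 1
    if (npos < 1) next                     # form too short to host a read
    Z <- Z + p * npos
    for (j in which(keep)) {
      a <- pos_of_intron[j]; m <- intron_lens[j]
      ov <- min(a + m - 1, L - r) - max(a - r + 1, 0) + 1
      num[j] <- num[j] + p * max(0, ov)
    }
  }
  if (Z == 0) return(rep(NA_real_, k))
  num / Z
}

# Deterministic small-integer seed derived from the master seed and a
# sample id (kept below 2^31).
derive_seed <- function(seed, sample_id) {
  h <- 0
  for (ch in utf8ToInt(sample_id)) h <- (h * 131 + ch) %% 1000003
  as.integer(((seed %% 1000003) * 1009 + h) %% 2147483647)
}

#' Simulate spliced/unspliced read alignments for one sample
#'
#' For each gene, reads are drawn from the gene's splicing forms (every
#' subset of its introns retained): a form is chosen with probability
#' proportional to abundance times its number of valid read start positions,
#' and the start is uniform over those positions. Alignments are emitted as
#' a coordinate-sorted SAM with M blocks and N gaps at skipped introns
#' (junction reads), MAPQ 255, no mismatches. Deterministic under
#' (config seed, condition, sample id).
#'
#' @param bundle A `sim_bundle` from [build_toy_genome()].
#' @param condition Condition name; theta per intron is taken from the
#'   truth column `theta_<condition>`.
#' @param sample_id Sample identifier (also seeds the sample's draws).
#' @param out_sam Output SAM path.
#' @param depth_scale Multiplier on per-gene expected read counts.
#' @return Invisibly, the SAM path; attribute `n_reads` carries the count.
#' @export
simulate_reads <- function(bundle, condition, sample_id, out_sam,
                           depth_scale = 1) {
  stopifnot(inherits(bundle, "sim_bundle"))
  theta_col <- paste0("theta_", condition)
  if (nrow(bundle$truth) > 0 && !theta_col %in% names(bundle$truth)) {
    stop("no theta column for condition ", condition)
  }
  set.seed(derive_seed(bundle$config$seed, paste0(condition, ":", sample_id)))
  r <- bundle$config$read_len
  model <- bundle$model
  chrom_str <- lapply(as.list(model$genome), as.character)

  recs <- list()
  for (gi in seq_len(nrow(bundle$genes))) {
    grow <- bundle$genes[gi, ]
    gid <- grow$gene_id
    n <- stats::rpois(1, grow$expected_reads * depth_scale)
    if (n == 0) next
    tr <- bundle$truth[bundle$truth$gene_id == gid, , drop = FALSE]
    tr <- tr[order(tr$start), , drop = FALSE]
    tx <- model$transcripts[model$transcripts$transcript_id ==
                              grow$transcript_id]
    span <- c(GenomicRanges::start(tx), GenomicRanges::end(tx))
    segs <- gene_segments(span, tr)
    thetas <- if (nrow(tr)) tr[[theta_col]] else numeric(0)
    reads <- draw_gene_reads(segs, thetas, n, r, chrom_str[[grow$chrom]])
    if (is.null(reads)) next
    reads$chrom <- grow$chrom
    reads$gene <- gid
    recs[[length(recs) + 1]] <- reads
  }
  df <- if (length(recs) == 0) {
    data.frame(pos = integer(0), cigar = character(0), seq = character(0),
               chrom = character(0), gene = character(0))
  } else do.call(rbind, recs)

  df <- df[order(df$chrom, df$pos, df$cigar), , drop = FALSE]
  n_reads <- nrow(df)

  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d",
                      GenomeInfoDb::seqnames(model$seqinfo),
                      GenomeInfoDb::seqlengths(model$seqinfo)),
              paste0("@PG\tID:spliceff\tPN:spliceff\tVN:",
                     as.character(utils::packageVersion("spliceff"))))
  body <- character(0)
  if (n_reads > 0) {
    qname <- sprintf("%s_%s_%s_%06d", df$gene, condition, sample_id,
                     seq_len(n_reads))
    body <- paste(qname, 0L, df$chrom, df$pos, 255L, df$cigar,
                  "*", 0L, 0L, df$seq, "*", sep = "\t")
  }
  writeLines(c(header, body), out_sam)
  attr(out_sam, "n_reads") <- n_reads
  invisible(out_sam)
}

# Genomic segments of a gene: exons and introns in order, with intron index
# (NA for exonic segments).
gene_segments <- function(span, tr) {
  if (nrow(tr) == 0) {
    return(data.frame(start = span[1], end = span[2], intron = NA_integer_))
  }
  st <- span[1]; rows <- list()
  for (j in seq_len(nrow(tr))) {
    rows[[length(rows) + 1]] <- data.frame(start = st, end = tr$start[j] - 1L,
                                           intron = NA_integer_)
    rows[[length(rows) + 1]] <- data.frame(start = tr$start[j],
                                           end = tr$end[j], intron = j)
    st <- tr$end[j] + 1L
  }
  rows[[length(rows) + 1]] <- data.frame(start = st, end = span[2],
                                         intron = NA_integer_)
  do.call(rbind, rows)
}

# Draw n reads for one gene. Returns data.frame(pos, cigar, seq) in 1-based
# genomic coordinates, or NULL when no form can host a read.
draw_gene_reads <- function(segs, thetas, n, r, chr) {
  k <- length(thetas)
  forms <- if (k == 0) matrix(FALSE, 1, 0) else
    as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), k)))
  nf <- nrow(forms)
  weight <- numeric(nf)
  layout <- vector("list", nf)
  for (f in seq_len(nf)) {
    keep_row <- is.na(segs$intron)
    if (k > 0) keep_row[!keep_row] <- forms[f, segs$intron[!keep_row]]
    sub <- segs[keep_row, , drop = FALSE]
    sb <- merge_contiguous(sub)
    L <- sum(sb$end - sb$start + 1)
    npos <- L - r + 1
    p <- if (k == 0) 1 else prod(ifelse(forms[f, ], thetas, 1 - thetas))
    if (npos < 1) {
      if (p > 0) warning("molecule form shorter than read length; skipped")
      next
    }
    weight[f] <- p * npos
    sb$m0 <- cumsum(c(0, utils::head(sb$end - sb$start + 1, -1)))
    layout[[f]] <- list(sb = sb, L = L)
  }
  if (sum(weight) == 0) return(NULL)
  fidx <- sample.int(nf, n, replace = TRUE, prob = weight)
  out <- vector("list", nf)
  for (f in unique(fidx)) {
    m <- sum(fidx == f)
    lay <- layout[[f]]
    s <- sample.int(lay$L - r + 1, m, replace = TRUE) - 1L  # 0-based starts
    out[[f]] <- reads_from_starts(lay$sb, s, r, chr)
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

# Collapse genomically contiguous segments (exon + retained intron runs)
# into superblocks; N gaps arise only between superblocks.
merge_contiguous <- function(sub) {
  sub <- sub[order(sub$start), , drop = FALSE]
  run <- cumsum(c(TRUE, sub$start[-1] != sub$end[-nrow(sub)] + 1L))
  starts <- integer(max(run)); ends <- integer(max(run))
  for (i in seq_len(nrow(sub))) {
    if (starts[run[i]] == 0L) starts[run[i]] <- sub$start[i]
    ends[run[i]] <- max(ends[run[i]], sub$end[i])
  }
  data.frame(start = starts, end = ends)
}

# Map 0-based molecule starts to genomic positions, CIGAR strings and read
# sequences given superblocks (genomic intervals with molecule offsets m0)
# and the chromosome sequence. Continuous and single-junction reads are
# vectorized; reads spanning two or more gaps take the general path.
reads_from_starts <- function(sb, s, r, chr) {
  m0 <- sb$m0
  i1 <- findInterval(s, m0)
  i2 <- findInterval(s + r - 1, m0)
  pos <- sb$start[i1] + (s - m0[i1])            # 1-based genomic start
  n <- length(s)
  cigar <- character(n); seq <- character(n)

  simple <- i1 == i2
  if (any(simple)) {
    cigar[simple] <- paste0(r, "M")
    seq[simple] <- substring(chr, pos[simple], pos[simple] + r - 1)
  }
  one_gap <- i2 == i1 + 1L
  if (any(one_gap)) {
    a <- i1[one_gap]; b <- i2[one_gap]
    p1 <- m0[a + 1] - s[one_gap]
    p2 <- s[one_gap] + r - m0[b]
    gap <- sb$start[b] - sb$end[a] - 1L
    cigar[one_gap] <- paste0(p1, "M", gap, "N", p2, "M")
    seq[one_gap] <- paste0(
      substring(chr, pos[one_gap], pos[one_gap] + p1 - 1),
      substring(chr, sb$start[b], sb$start[b] + p2 - 1))
  }
  for (w in which(!simple & !one_gap)) {
    a <- i1[w]; b <- i2[w]
    pieces <- c(m0[a + 1] - s[w],
                sb$end[(a + 1):(b - 1)] - sb$start[(a + 1):(b - 1)] + 1L,
                s[w] + r - m0[b])
    gaps <- sb$start[(a + 1):b] - sb$end[a:(b - 1)] - 1L
    cig <- paste0(pieces[1], "M")
    for (j in seq_along(gaps)) {
      cig <- paste0(cig, gaps[j], "N", pieces[j + 1], "M")
    }
    cigar[w] <- cig
    bst <- c(pos[w], sb$start[(a + 1):b])
    seq[w] <- paste(substring(chr, bst, bst + pieces - 1), collapse = "")
  }
  data.frame(pos = pos, cigar = cigar, seq = seq, stringsAsFactors = FALSE)
}

#' Add a suppressor condition to a simulation truth table
#'
#' Emulates a spontaneous suppressor strain: introns whose mutant retention
#' fold exceeds `deficiency_fold` are "recovered" (theta reset to wild type)
#' with probability `recover_frac`; all other introns keep the mutant theta.
#' The recovered set is recorded as ground truth.
#'
#' @param bundle A `sim_bundle`.
#' @param name Condition name (e.g. "S2"); adds columns
#'   `theta_<name>`, `recovered_<name>` and `expected_ir_<name>`.
#' @param recover_frac Fraction of deficient introns that recover.
#' @param deficiency_fold Fold threshold defining the deficient set.
#' @param seed Seed for the recovery draw (default derived from the config).
#' @return The bundle with augmented truth.
#' @export
add_suppressor_condition <- function(bundle, name, recover_frac,
                                     deficiency_fold = 8, seed = NULL) {
  stopifnot(inherits(bundle, "sim_bundle"))
  tr <- bundle$truth
  if (is.null(seed)) seed <- derive_seed(bundle$config$seed,
                                         paste0("supp:", name))
  set.seed(seed)
  deficient <- tr$fold > deficiency_fold
  rec <- deficient & stats::runif(nrow(tr)) < recover_frac
  tr[[paste0("theta_", name)]] <- ifelse(rec, tr$theta_WT, tr$theta_MUT)
  tr[[paste0("recovered_", name)]] <- rec
  bundle$truth <- tr
  bundle$truth[[paste0("expected_ir_", name)]] <-
    truth_expected_ir(bundle, paste0("theta_", name))
  bundle
}
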