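# Independent brute-force oracles. These deliberately avoid the package's
# interval machinery: SAM text is parsed by hand, overlaps are enumerated
# pairwise, and expectations are computed by explicit (form, start)
# enumeration over genomic coordinate vectors.

# Parse SAM text into a list of reads, each with block and gap intervals
# (1-based closed) derived from the CIGAR.
oracle_parse_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    pos <- as.integer(f[4]); cg <- f[6]
    lens <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
    ops <- regmatches(cg, gregexpr("[A-Z]", cg))[[1]]
    cur <- pos
    blocks <- NULL; gaps <- NULL
    for (i in seq_along(ops)) {
      if (ops[i] == "M") blocks <- rbind(blocks, c(cur, cur + lens[i] - 1L))
      if (ops[i] == "N") gaps <- rbind(gaps, c(cur, cur + lens[i] - 1L))
      cur <- cur + lens[i]
    }
    list(chrom = f[3], blocks = blocks, gaps = gaps)
  })
}

ivl_overlap <- function(a1, a2, b1, b2) max(0L, min(a2, b2) - max(a1, b1) + 1L)

# All-pairs enumeration of the counting rules over parsed reads and plain
# interval tables (data.frames with chrom, start, end, id columns).
oracle_count <- function(reads, transcripts, introns, intron_tx,
                         min_overlap = 1) {
  n_tx <- stats::setNames(rep(0L, nrow(transcripts)), transcripts$id)
  n_in <- stats::setNames(rep(0L, nrow(introns)), introns$id)
  n_jc <- stats::setNames(rep(0L, nrow(introns)), introns$id)
  reads_of_tx <- stats::setNames(vector("list", nrow(transcripts)),
                                 transcripts$id)
  assigned <- logical(length(reads))
  for (ri in seq_along(reads)) {
    rd <- reads[[ri]]
    for (ti in seq_len(nrow(transcripts))) {
      tx <- transcripts[ti, ]
      if (rd$chrom != tx$chrom) next
      hit <- FALSE
      for (bi in seq_len(nrow(rd$blocks))) {
        if (ivl_overlap(rd$blocks[bi, 1], rd$blocks[bi, 2],
                        tx$start, tx$end) >= min_overlap) hit <- TRUE
      }
      if (hit) {
        n_tx[tx$id] <- n_tx[tx$id] + 1L
        reads_of_tx[[tx$id]] <- c(reads_of_tx[[tx$id]], ri)
        assigned[ri] <- TRUE
      }
    }
    for (ii in seq_len(nrow(introns))) {
      iv <- introns[ii, ]
      if (rd$chrom != iv$chrom) next
      hit <- FALSE
      for (bi in seq_len(nrow(rd$blocks))) {
        if (ivl_overlap(rd$blocks[bi, 1], rd$blocks[bi, 2],
                        iv$start, iv$end) >= min_overlap) hit <- TRUE
      }
      if (hit) n_in[iv$id] <- n_in[iv$id] + 1L
      if (!is.null(rd$gaps)) {
        for (gi in seq_len(nrow(rd$gaps))) {
          if (rd$gaps[gi, 1] == iv$start && rd$gaps[gi, 2] == iv$end) {
            n_jc[iv$id] <- n_jc[iv$id] + 1L
          }
        }
      }
    }
  }
  n_tx_union <- vapply(seq_len(nrow(introns)), function(ii) {
    txs <- intron_tx[[introns$id[ii]]]
    length(unique(unlist(reads_of_tx[txs])))
  }, integer(1))
  list(n_transcript = n_tx, n_intron = n_in, n_junction = n_jc,
       n_tx_union = stats::setNames(n_tx_union, introns$id),
       library_size = sum(assigned))
}

# Expected per-intron overlap and junction read fractions by explicit
# enumeration of every (splicing form, start position) as genomic
# coordinate vectors.
oracle_expectations <- function(exon_ivls, intron_ivls, thetas, r) {
  k <- nrow(intron_ivls)
  forms <- expand.grid(rep(list(c(FALSE, TRUE)), k))
  Z <- 0
  ov <- numeric(k); jc <- numeric(k)
  for (f in seq_len(nrow(forms))) {
    keep <- as.logical(forms[f, ])
    p <- prod(ifelse(keep, thetas, 1 - thetas))
    if (p == 0) next
    coords <- integer(0)
    for (e in seq_len(nrow(exon_ivls))) {
      coords <- c(coords, exon_ivls[e, 1]:exon_ivls[e, 2])
      if (e <= k && keep[e]) {
        coords <- c(coords, intron_ivls[e, 1]:intron_ivls[e, 2])
      }
    }
    coords <- sort(coords)
    L <- length(coords)
    if (L < r) next
    Z <- Z + p * (L - r + 1)
    for (s in 0:(L - r)) {
      cc <- coords[(s + 1):(s + r)]
      for (j in seq_len(k)) {
        if (any(cc >= intron_ivls[j, 1] & cc <= intron_ivls[j, 2])) {
          ov[j] <- ov[j] + p
        }
        d <- diff(cc)
        skip <- which(d > 1)
        for (t in skip) {
          if (cc[t] == intron_ivls[j, 1] - 1 &&
              cc[t + 1] == intron_ivls[j, 2] + 1) jc[j] <- jc[j] + p
        }
      }
    }
  }
  list(ir = ov / Z, junction = jc / Z)
}

# Brute-force branch-point scoring of every window, via per-position IUPAC
# regular-expression classes.
oracle_bp <- function(seq, consensus = "CTRAC", bp_window = c(5, 60),
                      min_score = 0.8) {
  map <- Biostrings::IUPAC_CODE_MAP
  cons <- strsplit(consensus, "")[[1]]
  anchor <- which(cons == "A")
  W <- length(cons)
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  best_score <- -1; best_b <- NA_integer_
  if (L >= W) {
    for (o in 1:(L - W + 1)) {
      b <- o + anchor - 1
      dist <- L - b
      if (dist < bp_window[1] || dist > bp_window[2]) next
      if (ch[b] != "A") next
      sc <- 0
      for (j in 1:W) {
        if (grepl(paste0("[", map[[cons[j]]], "]"), ch[o + j - 1])) {
          sc <- sc + 1
        }
      }
      sc <- sc / W
      if (sc > best_score || (sc == best_score && b > best_b)) {
        best_score <- sc; best_b <- b
      }
    }
  }
  if (best_score < 0) {
    return(list(found = FALSE, bp_pos = NA_integer_, score = NA_real_))
  }
  list(found = best_score >= min_score, bp_pos = best_b - 1L,
       score = best_score)
}

# Intervals of a model's catalog and transcripts as plain data.frames for
# the oracle counter.
model_tables <- function(model, catalog) {
  tx <- data.frame(
    id = model$transcripts$transcript_id,
    chrom = as.character(GenomeInfoDb::seqnames(model$transcripts)),
    start = GenomicRanges::start(model$transcripts),
    end = GenomicRanges::end(model$transcripts),
    stringsAsFactors = FALSE)
  introns <- data.frame(
    id = catalog$intron_id,
    chrom = as.character(GenomeInfoDb::seqnames(catalog)),
    start = GenomicRanges::start(catalog),
    end = GenomicRanges::end(catalog),
    stringsAsFactors = FALSE)
  intron_tx <- stats::setNames(
    lapply(seq_along(catalog), function(i)
      unlist(catalog$transcript_ids[[i]])),
    catalog$intron_id)
  list(transcripts = tx, introns = introns, intron_tx = intron_tx)
}

# Retention table scaffold for classification tests: one intron per row of
# `ir`, whose columns are samples.
make_retention <- function(ir, gene_id = NULL, pass = TRUE) {
  ids <- rownames(ir)
  if (is.null(ids)) ids <- paste0("i", seq_len(nrow(ir)))
  if (is.null(gene_id)) gene_id <- paste0("g_", ids)
  out <- do.call(rbind, lapply(colnames(ir), function(s) {
    data.frame(intron_id = ids, gene_id = gene_id, sample = s,
               ir = ir[, s], pass_expression = pass,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

two_cond_design <- function(n_rep = 2, test = "MUT", ref = "WT") {
  data.frame(sample = c(paste0(ref, "_", seq_len(n_rep)),
                        paste0(test, "_", seq_len(n_rep))),
             condition = rep(c(ref, test), each = n_rep),
             replicate = rep(seq_len(n_rep), 2),
             stringsAsFactors = FALSE)
}
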