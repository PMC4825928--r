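#' Feature table for affected vs. unaffected introns
#'
#' One row per classified intron: class label ("affected" = binned above
#' `affected_fold`, "unaffected" = below the first threshold, others
#' dropped), intron length, branch-point distances (0-based offsets of the
#' branch adenosine: `dist_5ss_bp` from the intron start, `dist_bp_3ss` to
#' the last intronic base, so dist_5ss_bp + dist_bp_3ss = length - 1), and
#' the number of catalog introns in the host gene. Introns without a
#' branch-point call keep their length but have NA distances.
#'
#' @param diff A `diff_result` from [classify_introns()].
#' @param catalog Intron catalog GRanges.
#' @param bp_calls data.frame from [find_branch_point()].
#' @param affected_fold Minimum fold (strict) for the affected class
#'   (default 4, the "over 4-fold" reading).
#' @param unaffected_fold Fold below which an intron is unaffected
#'   (default 2).
#' @return data.frame(intron_id, class, length, dist_5ss_bp, dist_bp_3ss,
#'   introns_in_gene, gene_id).
#' @export
feature_table <- function(diff, catalog, bp_calls,
                          affected_fold = 4, unaffected_fold = 2) {
  stopifnot(inherits(diff, "diff_result"))
  rec <- diff$records
  cls <- ifelse(rec$min_fc > affected_fold, "affected",
                ifelse(rec$min_fc < unaffected_fold, "unaffected", NA))
  keep <- !is.na(cls)
  rec <- rec[keep, ]; cls <- cls[keep]

  idx <- match(rec$intron_id, catalog$intron_id)
  if (anyNA(idx)) stop("classified introns missing from catalog")
  len <- catalog$length[idx]
  per_gene <- table(catalog$gene_id)
  bp_idx <- match(rec$intron_id, bp_calls$intron_id)
  bp_found <- !is.na(bp_idx) & bp_calls$found[bp_idx]
  d5 <- ifelse(bp_found, bp_calls$bp_pos[bp_idx], NA_integer_)
  d3 <- ifelse(bp_found, len - 1L - bp_calls$bp_pos[bp_idx], NA_integer_)

  data.frame(intron_id = rec$intron_id, class = cls, length = len,
             dist_5ss_bp = d5, dist_bp_3ss = d3,
             introns_in_gene = as.integer(per_gene[catalog$gene_id[idx]]),
             gene_id = catalog$gene_id[idx],
             stringsAsFactors = FALSE)
}

#' Compare a feature between affected and unaffected introns
#'
#' Two-sided location test (Welch t or Mann-Whitney) on a feature column of
#' the [feature_table()].
#'
#' @param rows A feature table.
#' @param feature Column name (`length`, `dist_5ss_bp`, `dist_bp_3ss` or
#'   `introns_in_gene`).
#' @param test "welch_t" (default) or "mann_whitney".
#' @return list(statistic, p_value, means, medians, n, test).
#' @export
compare_feature <- function(rows, feature = "length",
                            test = c("welch_t", "mann_whitney")) {
  test <- match.arg(test)
  stopifnot(feature %in% names(rows))
  a <- rows[[feature]][rows$class == "affected"]
  u <- rows[[feature]][rows$class == "unaffected"]
  a <- a[!is.na(a)]; u <- u[!is.na(u)]
  if (length(a) < 2 || length(u) < 2) {
    stop("need at least 2 defined values per class for feature ", feature)
  }
  ht <- if (test == "welch_t") stats::t.test(a, u) else
    stats::wilcox.test(a, u, exact = FALSE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       means = c(affected = mean(a), unaffected = mean(u)),
       medians = c(affected = stats::median(a), unaffected = stats::median(u)),
       n = c(affected = length(a), unaffected = length(u)),
       test = test)
}

#' Position frequency matrix with per-column information content
#'
#' Builds per-position base frequencies from equal-length sequences over
#' ACGT; `N` bases are excluded from their column's weight. Information
#' content per column is 2 minus the Shannon entropy in bits.
#'
#' @param sequences Character vector (or DNAStringSet) of equal-length
#'   sequences.
#' @return list of class `pfm`: `freq` (4 x W), `counts` (4 x W),
#'   `n_sequences`, `ic` (per-column bits).
#' @export
build_pfm <- function(sequences) {
  if (methods::is(sequences, "XStringSet")) sequences <- as.character(sequences)
  if (length(sequences) == 0) stop("no sequences")
  w <- unique(nchar(sequences))
  if (length(w) != 1) stop("sequences must have equal length")
  mat <- do.call(rbind, strsplit(toupper(sequences), ""))
  counts <- apply(mat, 2, function(col)
    table(factor(col, levels = BASES)))
  counts <- matrix(as.integer(counts), nrow = 4,
                   dimnames = list(BASES, NULL))
  tot <- colSums(counts)
  if (any(tot == 0)) stop("column with no ACGT bases")
  freq <- sweep(counts, 2, tot, "/")
  ic <- apply(freq, 2, function(p) {
    p <- p[p > 0]
    2 - sum(-p * log2(p))
  })
  structure(list(freq = freq, counts = counts,
                 n_sequences = length(sequences), ic = ic),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat("pfm:", ncol(x$freq), "positions,", x$n_sequences, "sequences\n")
  print(round(x$freq, 3))
  invisible(x)
}

#' Compare two position frequency matrices column by column
#'
#' Per column: Jensen-Shannon divergence (base-2 logarithm, in bits) of the
#' frequency vectors and a chi-square test on the base counts, with
#' Bonferroni correction across columns. The summary flag `no_difference`
#' is TRUE when every adjusted p-value exceeds `alpha`.
#'
#' @param pfm_a,pfm_b `pfm` objects of equal width.
#' @param alpha Significance level after Bonferroni (default 0.05).
#' @return list: `columns` (data.frame with jsd, chisq_p, p_adj),
#'   `no_difference`.
#' @export
compare_pfms <- function(pfm_a, pfm_b, alpha = 0.05) {
  stopifnot(inherits(pfm_a, "pfm"), inherits(pfm_b, "pfm"))
  if (ncol(pfm_a$freq) != ncol(pfm_b$freq)) stop("PFM widths differ")
  W <- ncol(pfm_a$freq)
  jsd <- numeric(W); pval <- numeric(W)
  for (j in seq_len(W)) {
    jsd[j] <- js_divergence(pfm_a$freq[, j], pfm_b$freq[, j])
    tab <- rbind(pfm_a$counts[, j], pfm_b$counts[, j])
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    pval[j] <- if (ncol(tab) < 2 || min(rowSums(tab)) == 0) 1 else
      suppressWarnings(stats::chisq.test(tab)$p.value)
  }
  p_adj <- stats::p.adjust(pval, method = "bonferroni")
  list(columns = data.frame(position = seq_len(W), jsd = jsd,
                            chisq_p = pval, p_adj = p_adj),
       no_difference = all(p_adj > alpha))
}

js_divergence <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  kl(p, m) / 2 + kl(q, m) / 2
}
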