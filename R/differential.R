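#' Retention fold change between two samples, with a pseudocount
#'
#' FC = (IR_test + epsilon) / (IR_ref + epsilon). The pseudocount guards
#' against zero reference retention; it is applied to the IR ratio, not to
#' raw counts.
#'
#' @param ir_test,ir_ref Retention levels (vectorized); NA propagates.
#' @param epsilon Pseudocount (default 0.001).
#' @return Fold change(s).
#' @export
fold_change <- function(ir_test, ir_ref, epsilon = 0.001) {
  (ir_test + epsilon) / (ir_ref + epsilon)
}

#' Classify introns by retention fold change with replicate concordance
#'
#' For every intron passing the expression filter (and with defined IR in
#' all samples), a fold change is computed per replicate pair (test
#' replicate i over reference replicate i) and the intron is binned by the
#' MINIMUM fold change across replicates — a threshold counts only when met
#' in every replicate. Assigned bins partition the introns: `"<2"`
#' (minFC < 2), `"2-4"` (2 <= minFC <= 4), `">4"` (4 < minFC <= 8), `">8"`
#' (minFC > 8); introns labelled `">8"` also satisfy `">4"` in the nested
#' reading used for threshold fractions. The direction flag marks
#' concordant decreases symmetrically. A global Welch two-sample t-test
#' compares the pooled IR distributions of the two conditions (the box-plot
#' comparison).
#'
#' @param retention Output of [retention_level()].
#' @param design data.frame(sample, condition, replicate).
#' @param test,ref Condition names (test = mutant, ref = wild type).
#' @param thresholds Fold thresholds (increasing; default `c(2, 4, 8)`).
#' @param epsilon Pseudocount for [fold_change()].
#' @return list of class `diff_result`: `records` (one row per classified
#'   intron: per-sample IRs, per-replicate FCs, `min_fc`, `bin`,
#'   `concordant`, `direction`), `t_test` (htest), `n_filtered` counts.
#' @export
classify_introns <- function(retention, design, test = "MUT", ref = "WT",
                             thresholds = c(2, 4, 8), epsilon = 0.001) {
  stopifnot(all(c("sample", "condition", "replicate") %in% names(design)))
  stopifnot(all(diff(thresholds) > 0))
  d_test <- design[design$condition == test, ]
  d_ref <- design[design$condition == ref, ]
  if (nrow(d_test) == 0 || nrow(d_ref) == 0) {
    stop("design lacks samples for one of the conditions")
  }
  d_test <- d_test[order(d_test$replicate), ]
  d_ref <- d_ref[order(d_ref$replicate), ]
  if (nrow(d_test) != nrow(d_ref)) {
    stop("replicate layouts mismatched between conditions (",
         nrow(d_test), " vs ", nrow(d_ref), ")")
  }
  n_rep <- nrow(d_test)

  ir_wide <- ir_matrix(retention, c(d_ref$sample, d_test$sample))
  pass <- pass_matrix(retention, c(d_ref$sample, d_test$sample))
  n_total <- nrow(ir_wide)
  ok <- pass & rowSums(is.na(ir_wide)) == 0
  rec <- ir_wide[ok, , drop = FALSE]
  gene_of <- attr(ir_wide, "gene_id")[ok]

  fcs <- sapply(seq_len(n_rep), function(i) {
    fold_change(rec[, n_rep + i], rec[, i], epsilon)
  })
  if (is.null(dim(fcs))) fcs <- matrix(fcs, ncol = n_rep)
  min_fc <- apply(fcs, 1, min)
  max_fc <- apply(fcs, 1, max)
  min_fc_down <- 1 / max_fc              # concordant decrease fold

  bin <- cut_fold(min_fc, thresholds)
  direction <- ifelse(min_fc >= thresholds[1], "increase",
                      ifelse(min_fc_down >= thresholds[1], "decrease",
                             "none"))
  records <- data.frame(intron_id = rownames(rec), gene_id = gene_of,
                        stringsAsFactors = FALSE)
  for (i in seq_len(n_rep)) {
    records[[paste0("ir_", ref, "_", i)]] <- rec[, i]
    records[[paste0("ir_", test, "_", i)]] <- rec[, n_rep + i]
  }
  for (i in seq_len(n_rep)) records[[paste0("fc_rep", i)]] <- fcs[, i]
  records$min_fc <- min_fc
  records$bin <- bin
  records$concordant <- min_fc >= thresholds[1]
  records$direction <- direction
  rownames(records) <- NULL

  ir_ref_all <- as.vector(rec[, seq_len(n_rep)])
  ir_test_all <- as.vector(rec[, n_rep + seq_len(n_rep)])
  # essentially-constant data (degenerate toy inputs) yield no test
  tt <- tryCatch(stats::t.test(ir_test_all, ir_ref_all),
                 error = function(e) NULL)

  structure(list(records = records, t_test = tt,
                 n_filtered = c(total = n_total, classified = sum(ok)),
                 thresholds = thresholds, test = test, ref = ref),
            class = "diff_result")
}

# wide intron x sample IR matrix with gene ids attached
ir_matrix <- function(retention, samples) {
  ids <- unique(retention$intron_id)
  m <- matrix(NA_real_, length(ids), length(samples),
              dimnames = list(ids, samples))
  for (s in samples) {
    sub <- retention[retention$sample == s, ]
    m[match(sub$intron_id, ids), s] <- sub$ir
  }
  attr(m, "gene_id") <- retention$gene_id[match(ids, retention$intron_id)]
  m
}

# pass_expression is aggregated across samples by retention_level(), so any
# row of the intron carries the flag
pass_matrix <- function(retention, samples) {
  ids <- unique(retention$intron_id)
  p <- retention$pass_expression[match(ids, retention$intron_id)]
  p & !is.na(p)
}

cut_fold <- function(min_fc, thresholds) {
  t2 <- thresholds[1]; t4 <- thresholds[2]; t8 <- thresholds[3]
  ifelse(min_fc > t8, paste0(">", t8),
         ifelse(min_fc > t4, paste0(">", t4),
                ifelse(min_fc >= t2, paste0(t2, "-", t4),
                       paste0("<", t2))))
}

#' @export
print.diff_result <- function(x, ...) {
  cat("diff_result:", nrow(x$records), "classified introns (",
      x$test, "vs", x$ref, ")\n")
  print(table(x$records$bin))
  invisible(x)
}

#' Gene-level summary of differential retention
#'
#' Fractions of introns affected at each fold threshold (minimum FC across
#' replicates strictly above the threshold) and the fraction of genes with
#' at least one affected intron. Denominators are the introns/genes that
#' passed the expression filter and were classified.
#'
#' @param diff A `diff_result` from [classify_introns()].
#' @param gene_threshold Fold threshold defining an affected gene
#'   (default the first classification threshold, 2).
#' @return list: `genes` (gene_id, n_introns, n_affected, affected),
#'   `fractions` (named list with explicit numerators/denominators).
#' @export
summarize_genes <- function(diff, gene_threshold = NULL) {
  stopifnot(inherits(diff, "diff_result"))
  rec <- diff$records
  thr <- diff$thresholds
  if (is.null(gene_threshold)) gene_threshold <- thr[1]
  n_introns <- tapply(rec$intron_id, rec$gene_id, length)
  n_aff <- tapply(rec$min_fc > gene_threshold, rec$gene_id, sum)
  genes <- data.frame(gene_id = names(n_introns),
                      n_introns = as.integer(n_introns),
                      n_affected = as.integer(n_aff),
                      affected = as.integer(n_aff) >= 1,
                      stringsAsFactors = FALSE)
  rownames(genes) <- NULL
  fr <- list(n_introns = nrow(rec), n_genes = nrow(genes))
  for (t in thr) {
    fr[[paste0("frac_introns_over_", t, "fold")]] <-
      mean(rec$min_fc > t)
  }
  fr$frac_genes_affected <- mean(genes$affected)
  fr$gene_threshold <- gene_threshold
  list(genes = genes, fractions = fr)
}

#' Suppressor recovery analysis
#'
#' The deficient set D comprises introns whose retention increased more
#' than `deficiency_fold`-fold in the mutant relative to wild type in every
#' replicate (minimum FC rule). An intron is recovered in the suppressor
#' when its fold change versus the mean wild-type IR is below
#' `recovered_fold` in every suppressor sample. Returns
#' 100 * |recovered| / |D|.
#'
#' @param ir_wt,ir_mut Numeric matrices (introns x replicates) of retention
#'   levels, same rownames; a vector is treated as a single replicate.
#' @param ir_supp Matrix (introns x suppressor samples) of suppressor IRs.
#' @param deficiency_fold Fold defining deficiency (default 8).
#' @param recovered_fold Fold below which the suppressor is called
#'   recovered (default 2).
#' @param epsilon Pseudocount for [fold_change()].
#' @return list: `percent_recovered` (NA when D is empty), `n_deficient`,
#'   `n_recovered`, `deficient_ids`, `recovered_ids`.
#' @export
recovery_analysis <- function(ir_wt, ir_mut, ir_supp,
                              deficiency_fold = 8, recovered_fold = 2,
                              epsilon = 0.001) {
  ir_wt <- as_ir_matrix(ir_wt); ir_mut <- as_ir_matrix(ir_mut)
  ir_supp <- as_ir_matrix(ir_supp)
  stopifnot(nrow(ir_wt) == nrow(ir_mut), nrow(ir_wt) == nrow(ir_supp),
            ncol(ir_wt) == ncol(ir_mut))
  ids <- rownames(ir_wt)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(ir_wt)))

  fc_mut <- fold_change(ir_mut, ir_wt, epsilon)
  complete <- rowSums(is.na(cbind(ir_wt, ir_mut, ir_supp))) == 0
  deficient <- complete & apply(fc_mut, 1, min) > deficiency_fold

  wt_mean <- rowMeans(ir_wt)
  fc_supp <- fold_change(ir_supp, matrix(wt_mean, nrow(ir_supp),
                                         ncol(ir_supp)), epsilon)
  recovered <- deficient & apply(fc_supp, 1, max) < recovered_fold

  nD <- sum(deficient)
  list(percent_recovered = if (nD == 0) NA_real_ else 100 * sum(recovered) / nD,
       n_deficient = nD, n_recovered = sum(recovered),
       deficient_ids = ids[deficient], recovered_ids = ids[recovered])
}

as_ir_matrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1, dimnames = list(names(x)))
  as.matrix(x)
}
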