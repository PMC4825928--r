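#' End-to-end retention analysis: count, filter, classify, characterize
#'
#' Orchestrates the full analysis downstream of alignment: per-sample
#' counting, CPM expression filtering, retention levels, differential
#' classification with replicate concordance, gene-level summary, intron
#' feature comparison (lengths, branch-point distances, introns per gene)
#' and splice-site/branch-point position frequency matrices. Writes
#' tab-separated tables plus a JSON run summary; every output carries a
#' header naming the package version and the resolved configuration, and
#' the filter funnel (genes detected, genes with introns, introns
#' classified) is logged via `message()`.
#'
#' @param model A `genome_model` with genome attached (for sequence
#'   features; pass one without a genome to skip them).
#' @param sam_paths Named character vector of SAM/BAM paths (names =
#'   sample ids).
#' @param design data.frame(sample, condition, replicate).
#' @param test,ref Condition names compared (default MUT vs WT).
#' @param out_dir Output directory (created if missing); NULL writes
#'   nothing.
#' @param cpm_threshold Expression filter (default 10).
#' @param thresholds Fold-change bins (default c(2, 4, 8)).
#' @param epsilon Pseudocount for IR fold changes.
#' @param bp_consensus,bp_window,bp_min_score Branch-point scan settings.
#' @return list of class `spliceff_run`: `counts`, `retention`, `diff`,
#'   `gene_summary`, `features`, `feature_tests`, `pfms`, `pfm_comparison`,
#'   `bp_calls`, `config`.
#' @export
run_pipeline <- function(model, sam_paths, design, test = "MUT", ref = "WT",
                         out_dir = NULL, cpm_threshold = 10,
                         thresholds = c(2, 4, 8), epsilon = 0.001,
                         bp_consensus = "CTRAC", bp_window = c(5, 60),
                         bp_min_score = 0.8) {
  stopifnot(inherits(model, "genome_model"))
  if (is.null(names(sam_paths)) || any(names(sam_paths) == "")) {
    stop("sam_paths must be named by sample id")
  }
  if (nrow(design) == 0) stop("empty sample sheet")
  missing <- setdiff(design$sample, names(sam_paths))
  if (length(missing) > 0) stop("no alignment file for sample(s): ",
                                paste(missing, collapse = ", "))
  config <- list(test = test, ref = ref, cpm_threshold = cpm_threshold,
                 thresholds = thresholds, epsilon = epsilon,
                 bp_consensus = bp_consensus, bp_window = bp_window,
                 bp_min_score = bp_min_score)

  catalog <- intron_catalog(model)
  message("genes in model: ", length(model$genes),
          "; genes with introns: ", length(unique(catalog$gene_id)),
          "; catalog introns: ", length(catalog))

  counts <- lapply(stats::setNames(design$sample, design$sample),
                   function(s) {
    aln <- read_spliced_alignments(sam_paths[[s]])
    count_reads(aln, model, catalog = catalog)
  })
  retention <- retention_level(counts, cpm_threshold = cpm_threshold)
  n_pass <- length(unique(retention$gene_id[retention$pass_expression]))
  message("genes passing CPM >= ", cpm_threshold, " in all samples: ",
          n_pass, " of ", length(unique(retention$gene_id)))

  diff <- classify_introns(retention, design, test = test, ref = ref,
                           thresholds = thresholds, epsilon = epsilon)
  message("introns classified: ", diff$n_filtered[["classified"]],
          " of ", diff$n_filtered[["total"]])
  gene_summary <- summarize_genes(diff)

  features <- NULL; feature_tests <- NULL; pfms <- NULL
  pfm_comparison <- NULL; bp_calls <- NULL
  if (!is.null(model$genome)) {
    seqs <- interval_seqs(model, catalog)
    bp_calls <- find_branch_point(seqs, consensus = bp_consensus,
                                  bp_window = bp_window,
                                  min_score = bp_min_score)
    features <- feature_table(diff, catalog, bp_calls,
                              affected_fold = thresholds[2],
                              unaffected_fold = thresholds[1])
    feature_tests <- lapply(
      stats::setNames(nm = c("length", "dist_5ss_bp", "dist_bp_3ss",
                             "introns_in_gene")),
      function(f) try_compare(features, f))
    pfms <- pfms_by_class(model, catalog, features)
    pfm_comparison <- list()
    for (site in intersect(names(pfms$affected), names(pfms$unaffected))) {
      pfm_comparison[[site]] <-
        compare_pfms(pfms$affected[[site]], pfms$unaffected[[site]])
    }
  }

  run <- structure(list(counts = counts, retention = retention, diff = diff,
                        gene_summary = gene_summary, features = features,
                        feature_tests = feature_tests, pfms = pfms,
                        pfm_comparison = pfm_comparison,
                        bp_calls = bp_calls, config = config),
                   class = "spliceff_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

try_compare <- function(features, f) {
  tryCatch(compare_feature(features, f), error = function(e) NULL)
}

# splice-site PFMs per class from unclipped windows
pfms_by_class <- function(model, catalog, features) {
  ss <- extract_splice_sites(model, catalog)
  ss <- ss[!ss$clipped, ]
  out <- list()
  for (cls in c("affected", "unaffected")) {
    ids <- features$intron_id[features$class == cls]
    sub <- ss[ss$intron_id %in% ids, ]
    out[[cls]] <- if (nrow(sub) >= 2) {
      list(five_ss = build_pfm(sub$five_ss),
           three_ss = build_pfm(sub$three_ss))
    } else list()
  }
  out
}

#' Write the tables and JSON summary of a pipeline run
#'
#' @param run A `spliceff_run`.
#' @param out_dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_run <- function(run, out_dir) {
  stopifnot(inherits(run, "spliceff_run"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  hdr <- c(paste0("# spliceff ",
                  as.character(utils::packageVersion("spliceff"))),
           paste0("# config: ",
                  jsonlite::toJSON(run$config, auto_unbox = TRUE)))
  paths <- character(0)

  write_tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    con <- file(p, "w")
    writeLines(hdr, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    p
  }
  paths <- c(paths, write_tsv(run$retention, "retention.tsv"))
  paths <- c(paths, write_tsv(run$diff$records, "differential.tsv"))
  paths <- c(paths, write_tsv(run$gene_summary$genes, "gene_summary.tsv"))
  if (!is.null(run$features)) {
    paths <- c(paths, write_tsv(run$features, "intron_features.tsv"))
  }

  summary <- list(
    config = run$config,
    n_classified = nrow(run$diff$records),
    bin_counts = as.list(table(run$diff$records$bin)),
    fractions = run$gene_summary$fractions,
    t_test_p = if (is.null(run$diff$t_test)) NULL else
      run$diff$t_test$p.value,
    feature_p = lapply(run$feature_tests, function(x)
      if (is.null(x)) NULL else x$p_value),
    pfm_no_difference = lapply(run$pfm_comparison, function(x)
      if (is.null(x)) NULL else x$no_difference))
  jp <- file.path(out_dir, "run_summary.json")
  jsonlite::write_json(summary, jp, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(c(paths, jp))
}

#' Simulate a full two-condition study and write its sample sheet
#'
#' Convenience wrapper used by the analysis scripts and the acceptance
#' tests: builds a toy genome, simulates every (condition, replicate)
#' sample to SAM, and writes the design as TSV.
#'
#' @param config A [sim_config()].
#' @param dir Output directory.
#' @param conditions Conditions to simulate (default those in the config).
#' @return list: `bundle`, `sam_paths` (named), `design`, `dir`.
#' @export
simulate_study <- function(config, dir = tempfile("study"),
                           conditions = NULL) {
  bundle <- build_toy_genome(config, dir = file.path(dir, "genome"))
  if (is.null(conditions)) conditions <- config$conditions
  design <- expand.grid(replicate = seq_len(config$replicates),
                        condition = conditions,
                        stringsAsFactors = FALSE)[, 2:1]
  design$sample <- paste0(design$condition, "_rep", design$replicate)
  sam_dir <- file.path(dir, "sam")
  if (!dir.exists(sam_dir)) dir.create(sam_dir, recursive = TRUE)
  sam_paths <- stats::setNames(
    file.path(sam_dir, paste0(design$sample, ".sam")), design$sample)
  for (i in seq_len(nrow(design))) {
    simulate_reads(bundle, design$condition[i], design$sample[i],
                   sam_paths[[i]])
  }
  utils::write.table(design, file.path(dir, "design.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(bundle = bundle, sam_paths = sam_paths, design = design, dir = dir)
}
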