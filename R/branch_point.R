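#' Locate the branch point of each intron by IUPAC consensus scan
#'
#' Scans each intron sequence (coding-strand orientation) for the best match
#' to a branch-point consensus. The consensus is an IUPAC string with exactly
#' one literal `A`, the branch adenosine anchor (default `"CTRAC"`, anchor at
#' position 4). A candidate placement must fit entirely inside the intron,
#' its anchor position must be an `A`, and the distance from the branch
#' adenosine to the intron's 3' end must lie within `bp_window`. The score of
#' a placement is the fraction of consensus positions satisfied; the
#' highest-scoring placement wins, with ties broken toward the 3' splice
#' site. A call is reported as found only when the best score reaches
#' `min_score`.
#'
#' @param seqs Named character vector (or DNAStringSet) of intron sequences,
#'   names taken as intron ids.
#' @param consensus IUPAC consensus with a single literal `A` anchor.
#' @param bp_window Allowed range (nt) of distances from the branch A to the
#'   3' end of the intron, counted as the number of intronic nucleotides
#'   downstream of the branch A.
#' @param min_score Minimum score for a call to be reported found.
#' @return data.frame with one row per intron: `intron_id`, `bp_pos`
#'   (0-based offset of the branch A within the intron), `score`, `found`,
#'   `dist_bp_3ss`.
#' @export
find_branch_point <- function(seqs, consensus = "CTRAC",
                              bp_window = c(5, 60), min_score = 0.8) {
  if (methods::is(seqs, "XStringSet")) seqs <- as.character(seqs)
  ids <- names(seqs)
  if (is.null(ids)) ids <- as.character(seq_along(seqs))

  cons <- strsplit(toupper(consensus), "")[[1]]
  anchor <- which(cons == "A")
  if (length(anchor) != 1) {
    stop("consensus must contain exactly one literal 'A' anchor")
  }
  allowed <- lapply(cons, iupac_bases)
  W <- length(cons)

  out <- data.frame(intron_id = ids, bp_pos = NA_integer_,
                    score = NA_real_, found = FALSE,
                    dist_bp_3ss = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_along(seqs)) {
    ch <- strsplit(toupper(seqs[[i]]), "")[[1]]
    L <- length(ch)
    if (L < W) next
    starts <- seq_len(L - W + 1)
    b <- starts + anchor - 1          # 1-based branch A position
    dist <- L - b                     # nt downstream of the branch A
    ok <- dist >= bp_window[1] & dist <= bp_window[2] & ch[b] == "A"
    starts <- starts[ok]; b <- b[ok]
    if (length(starts) == 0) next
    score <- vapply(starts, function(s) {
      mean(vapply(seq_len(W),
                  function(j) ch[s + j - 1] %in% allowed[[j]], logical(1)))
    }, numeric(1))
    best <- max(score)
    # ties broken toward the 3'ss: the largest offset among the best
    pick <- max(which(score == best))
    out$bp_pos[i] <- b[pick] - 1L
    out$score[i] <- best
    out$found[i] <- best >= min_score
    out$dist_bp_3ss[i] <- L - b[pick]
  }
  out
}

iupac_bases <- function(code) {
  map <- Biostrings::IUPAC_CODE_MAP
  if (!code %in% names(map)) stop("invalid IUPAC code: ", code)
  strsplit(map[[code]], "")[[1]]
}
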