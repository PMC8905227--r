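# At/Dt subgenome homolog pairing: reciprocal best-hit local alignment,
# a simplified collinearity (synteny) filter over flanking anchor genes,
# and the paired test of subgenome expression bias under infestation.

default_nt_scoring <- function() {
  list(match = 2, mismatch = -3, gap_opening = 5, gap_extension = 2)
}

align_pair <- function(a, b, scoring, score_only = FALSE) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = TRUE)
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = sm, gapOpening = scoring$gap_opening,
    gapExtension = scoring$gap_extension, scoreOnly = score_only)
}

align_scores_vs <- function(patterns, subject, scoring) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = TRUE)
  Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(patterns), Biostrings::DNAString(subject),
    type = "local", substitutionMatrix = sm,
    gapOpening = scoring$gap_opening, gapExtension = scoring$gap_extension,
    scoreOnly = TRUE)
}

#' Reciprocal best-hit homolog pairs between subgenomes
#'
#' All-vs-all Smith-Waterman local alignment (match 2, mismatch -3, gap
#' open 5, extend 2 by default); a pair (a, d) is reported iff d is a's
#' best-scoring hit and a is d's best-scoring hit, with score ties broken
#' by lexicographic id, and the alignment passes the identity and coverage
#' thresholds. Identity is matches / alignment columns; coverage is the
#' aligned span of the shorter sequence / its length.
#'
#' @param at_seqs,dt_seqs named character vectors of lncRNA sequences from
#'   the At and Dt subgenome respectively.
#' @param min_identity minimum identity (default 0.85).
#' @param min_coverage minimum coverage (default 0.8).
#' @param scoring list(match, mismatch, gap_opening, gap_extension).
#' @return data.frame (at_id, dt_id, score, identity, coverage), sorted by
#'   at_id; zero rows when either input set is empty.
#' @export
reciprocal_best_pairs <- function(at_seqs, dt_seqs, min_identity = 0.85,
                                  min_coverage = 0.8,
                                  scoring = default_nt_scoring()) {
  empty <- data.frame(at_id = character(0), dt_id = character(0),
                      score = numeric(0), identity = numeric(0),
                      coverage = numeric(0), stringsAsFactors = FALSE)
  if (length(at_seqs) == 0 || length(dt_seqs) == 0) return(empty)
  at_ids <- sort(names(at_seqs))
  dt_ids <- sort(names(dt_seqs))
  scores <- matrix(NA_real_, length(at_ids), length(dt_ids),
                   dimnames = list(at_ids, dt_ids))
  for (a in at_ids) {
    scores[a, ] <- align_scores_vs(dt_seqs[dt_ids], at_seqs[[a]], scoring)
  }
  # ids are sorted, so which.max resolves ties lexicographically
  best_dt_for_at <- dt_ids[apply(scores, 1, which.max)]
  best_at_for_dt <- at_ids[apply(scores, 2, which.max)]
  names(best_dt_for_at) <- at_ids
  names(best_at_for_dt) <- dt_ids
  rows <- list()
  for (a in at_ids) {
    d <- best_dt_for_at[[a]]
    if (best_at_for_dt[[d]] != a) next
    aln <- align_pair(at_seqs[[a]], dt_seqs[[d]], scoring)
    ap <- as.character(Biostrings::alignedPattern(aln))
    as_ <- as.character(Biostrings::alignedSubject(aln))
    alen <- nchar(ap)
    ident <- Biostrings::nmatch(aln) / alen
    wp <- nchar(gsub("-", "", ap))
    ws <- nchar(gsub("-", "", as_))
    shorter <- which.min(c(nchar(at_seqs[[a]]), nchar(dt_seqs[[d]])))
    cov <- c(wp, ws)[shorter] / min(nchar(at_seqs[[a]]), nchar(dt_seqs[[d]]))
    if (ident >= min_identity && cov >= min_coverage) {
      rows[[length(rows) + 1L]] <- data.frame(
        at_id = a, dt_id = d, score = unname(scores[a, d]),
        identity = ident, coverage = cov, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty)
  res <- do.call(rbind, rows)
  res[order(res$at_id), , drop = FALSE]
}

flank_anchor_ids <- function(order_tbl, id, flank_k) {
  row <- order_tbl[order_tbl$id == id, , drop = FALSE]
  if (nrow(row) == 0) return(NULL)
  oc <- order_tbl[order_tbl$chrom == row$chrom[1], , drop = FALSE]
  oc <- oc[order(oc$rank), ]
  pos <- which(oc$id == id)
  genes_left <- oc[seq_len(pos - 1L), , drop = FALSE]
  genes_left <- genes_left[genes_left$kind == "gene", , drop = FALSE]
  genes_right <- oc[-seq_len(pos), , drop = FALSE]
  genes_right <- genes_right[genes_right$kind == "gene", , drop = FALSE]
  left <- rev(genes_left$anchor_id)  # nearest first
  right <- genes_right$anchor_id
  list(left = head(left, flank_k), right = head(right, flank_k))
}

shared_in_order <- function(x, y) {
  sh <- x[x %in% y]
  if (length(sh) < 2) return(length(sh))
  if (all(diff(match(sh, y)) > 0)) length(sh) else sum(x %in% y & FALSE)
}

#' Flag homolog pairs as syntenic by flanking-anchor agreement
#'
#' A pair is syntenic iff, among the `flank_k` nearest anchor genes on each
#' side of each member, at least `min_shared` anchors are homologous
#' between the two loci and appear in preserved order. `flank_k = 0` makes
#' the criterion vacuous (every pair syntenic).
#'
#' @param pairs data.frame from [reciprocal_best_pairs()].
#' @param at_gene_order,dt_gene_order per-chromosome order tables with
#'   columns chrom, id, kind ("gene"/"lnc"), anchor_id, rank; anchors are
#'   homologous across subgenomes iff they share `anchor_id`.
#' @param flank_k anchors examined on each side.
#' @param min_shared homologous anchors required per side (effectively
#'   capped at `flank_k`).
#' @return `pairs` with a logical `syntenic` column.
#' @export
synteny_filter <- function(pairs, at_gene_order, dt_gene_order,
                           flank_k = 5L, min_shared = 2L) {
  need <- min(min_shared, flank_k)
  pairs$syntenic <- vapply(seq_len(nrow(pairs)), function(i) {
    fa <- flank_anchor_ids(at_gene_order, pairs$at_id[i], flank_k)
    fd <- flank_anchor_ids(dt_gene_order, pairs$dt_id[i], flank_k)
    if (is.null(fa) || is.null(fd)) {
      warning("pair member missing from gene order: ",
              pairs$at_id[i], " / ", pairs$dt_id[i])
      return(FALSE)
    }
    shared_in_order(fa$left, fd$left) >= need &&
      shared_in_order(fa$right, fd$right) >= need
  }, logical(1))
  pairs
}

#' Subgenome expression bias of homolog pairs
#'
#' Collects each member's log2 fold change under a contrast and tests the
#' At-vs-Dt shift with a two-sided Wilcoxon signed-rank test on the
#' per-pair differences (Dt minus At).
#'
#' @param pairs data.frame with at_id, dt_id.
#' @param de_results a [call_de()] result providing log2_fold_change per
#'   feature.
#' @return list with `pairs` (per-pair lfc values and difference),
#'   `median_at`, `median_dt`, `median_diff`, `p_value` (NA with a notice
#'   when fewer than 2 complete pairs) and `n_pairs`.
#' @export
pair_expression_bias <- function(pairs, de_results) {
  lfc <- setNames(de_results$log2_fold_change, de_results$feature_id)
  at <- lfc[pairs$at_id]
  dt <- lfc[pairs$dt_id]
  ok <- !is.na(at) & !is.na(dt)
  if (!any(ok)) stop("no pair has complete DE results for this contrast")
  at <- unname(at[ok])
  dt <- unname(dt[ok])
  d <- dt - at
  p <- NA_real_
  if (sum(ok) < 2) {
    message("signed-rank test skipped: fewer than 2 complete pairs")
  } else if (all(d == 0)) {
    p <- 1  # no shift whatsoever
  } else {
    p <- suppressWarnings(wilcox.test(dt, at, paired = TRUE)$p.value)
  }
  list(pairs = data.frame(at_id = pairs$at_id[ok], dt_id = pairs$dt_id[ok],
                          log2fc_at = at, log2fc_dt = dt, diff = d,
                          stringsAsFactors = FALSE),
       median_at = median(at), median_dt = median(dt),
       median_diff = median(d), p_value = p, n_pairs = sum(ok))
}
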