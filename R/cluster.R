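# Expression-profile clustering (k-means on z-scored rows), Fisher-exact
# term enrichment per cluster, and guilt-by-association function transfer
# from protein-coding genes to co-clustered lncRNAs.

#' Row z-scoring of an expression matrix
#'
#' @param m matrix; constant rows are dropped with a notice.
#' @return z-scored matrix (rows mean 0, sd 1).
#' @export
zscore_rows <- function(m) {
  m <- as.matrix(m)
  s <- apply(m, 1, sd)
  if (any(s == 0)) {
    message("excluding ", sum(s == 0), " constant feature(s) from clustering")
    m <- m[s > 0, , drop = FALSE]
    s <- s[s > 0]
  }
  (m - rowMeans(m)) / s
}

#' k-means clustering of expression profiles
#'
#' Rows are z-scored first; Lloyd's algorithm with `n_init` random restarts
#' keeps the solution with the lowest within-cluster sum of squares.
#' Deterministic under a fixed seed.
#'
#' @param expr `expr_matrix` or matrix (features x samples).
#' @param k number of clusters (default 10).
#' @param seed RNG seed.
#' @param n_init random restarts.
#' @param max_iter Lloyd iterations per restart.
#' @return list with `assignments` (data.frame feature_id, cluster),
#'   `centers`, `inertia` (total within-cluster sum of squares), `k`,
#'   and `profiles` (the z-scored matrix).
#' @export
kmeans_profiles <- function(expr, k = 10L, seed = 1L, n_init = 10L,
                            max_iter = 100L) {
  m <- if (methods::is(expr, "expr_matrix")) expr$values else as.matrix(expr)
  z <- zscore_rows(m)
  if (k > nrow(z)) stop("k (", k, ") exceeds number of features (",
                        nrow(z), ")")
  km <- with_seed(seed, kmeans(z, centers = k, nstart = n_init,
                               iter.max = max_iter, algorithm = "Lloyd"))
  list(assignments = data.frame(feature_id = rownames(z),
                                cluster = unname(km$cluster),
                                stringsAsFactors = FALSE),
       centers = km$centers, inertia = km$tot.withinss, k = k,
       profiles = z)
}

#' Fisher-exact term enrichment
#'
#' One-sided (enrichment) Fisher exact test per term on the 2x2 table of
#' set membership vs term annotation, with Benjamini-Hochberg FDR across
#' the tested terms. Terms annotating fewer than `min_term_size` universe
#' features are skipped.
#'
#' @param feature_set character vector, subset of `universe`.
#' @param universe character vector of all considered features.
#' @param annotation data.frame (feature_id, term_id); features outside
#'   the universe are ignored.
#' @param alpha significance level recorded in the `significant` column.
#'   Presets used in the surrounding analyses: 0.01 on raw p for profile
#'   clusters, 0.05 on raw p for network neighbourhoods, FDR < 1e-4 for
#'   knock-out line gene sets (`use_fdr = TRUE`).
#' @param min_term_size minimum universe annotation count per term.
#' @param use_fdr test `fdr` instead of raw p against `alpha`.
#' @return data.frame (term_id, a, b, c, d, odds_ratio, p_value, fdr,
#'   significant) sorted by p; a = in-set annotated, b = in-set not,
#'   c = out-set annotated, d = out-set not.
#' @export
fisher_enrichment <- function(feature_set, universe, annotation,
                              alpha = 0.05, min_term_size = 2L,
                              use_fdr = FALSE) {
  if (length(universe) == 0) stop("empty universe")
  if (!all(feature_set %in% universe)) {
    stop("feature_set must be a subset of the universe")
  }
  ann <- annotation[annotation$feature_id %in% universe, , drop = FALSE]
  terms <- split(unique(ann)[, "feature_id"],
                 unique(ann)[, "term_id"])
  terms <- terms[vapply(terms, length, 1L) >= min_term_size]
  if (length(terms) == 0) {
    return(data.frame(term_id = character(0), a = integer(0), b = integer(0),
                      c = integer(0), d = integer(0), odds_ratio = numeric(0),
                      p_value = numeric(0), fdr = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE))
  }
  n_set <- length(feature_set)
  n_uni <- length(universe)
  rows <- lapply(names(terms), function(t) {
    tg <- terms[[t]]
    a <- length(intersect(feature_set, tg))
    b <- n_set - a
    cc <- length(tg) - a
    d <- n_uni - n_set - cc
    ft <- fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE),
                      alternative = "greater")
    data.frame(term_id = t, a = a, b = b, c = cc, d = d,
               odds_ratio = unname(ft$estimate), p_value = ft$p.value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$fdr <- p.adjust(res$p_value, method = "BH")
  res$significant <- if (use_fdr) res$fdr < alpha else res$p_value < alpha
  res <- res[order(res$p_value, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Transfer putative function to lncRNAs by co-clustering
#'
#' Each lncRNA inherits the significantly enriched terms of its cluster
#' (computed over the cluster's protein-coding genes against the
#' protein-coding universe). Associations are labelled "associated" —
#' guilt by association, never demonstrated function.
#'
#' @param assignments clustering result data.frame (feature_id, cluster)
#'   covering lncRNAs and protein-coding genes.
#' @param feature_kind named character vector ("lncRNA"/"PCG").
#' @param annotation feature-to-term table for the protein-coding genes.
#' @param alpha,min_term_size,use_fdr passed to [fisher_enrichment()].
#' @return list with `associations` (lncRNA_id, cluster, term_id,
#'   p_value, evidence) and `cluster_enrichment` (per-cluster tables).
#' @export
transfer_function <- function(assignments, feature_kind, annotation,
                              alpha = 0.01, min_term_size = 2L,
                              use_fdr = FALSE) {
  kinds <- feature_kind[assignments$feature_id]
  pcg_ids <- assignments$feature_id[kinds == "PCG"]
  lnc_ids <- assignments$feature_id[kinds == "lncRNA"]
  per_cluster <- list()
  assoc <- list()
  for (cl in sort(unique(assignments$cluster))) {
    members <- assignments$feature_id[assignments$cluster == cl]
    pcg_in <- intersect(members, pcg_ids)
    enr <- fisher_enrichment(pcg_in, pcg_ids, annotation, alpha = alpha,
                             min_term_size = min_term_size,
                             use_fdr = use_fdr)
    per_cluster[[as.character(cl)]] <- enr
    sig <- enr[enr$significant, , drop = FALSE]
    lnc_in <- intersect(members, lnc_ids)
    if (nrow(sig) > 0 && length(lnc_in) > 0) {
      assoc[[length(assoc) + 1L]] <- do.call(rbind, lapply(lnc_in,
        function(l) {
          data.frame(lncRNA_id = l, cluster = cl, term_id = sig$term_id,
                     p_value = sig$p_value, evidence = "associated",
                     stringsAsFactors = FALSE)
        }))
    }
  }
  associations <- if (length(assoc)) do.call(rbind, assoc) else
    data.frame(lncRNA_id = character(0), cluster = integer(0),
               term_id = character(0), p_value = numeric(0),
               evidence = character(0), stringsAsFactors = FALSE)
  associations <- associations[order(associations$lncRNA_id,
                                     associations$term_id), , drop = FALSE]
  rownames(associations) <- NULL
  list(associations = associations, cluster_enrichment = per_cluster)
}
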