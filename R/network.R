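# Weighted co-expression network: soft-threshold (scale-free fit)
# selection, unsigned adjacency |cor|^beta, edge export and hub detection.

#' Pick a soft-threshold power by scale-free topology fit
#'
#' For each candidate power, adjacency = |Pearson correlation|^power; the
#' scale-free fit R^2 is the squared correlation of log10(frequency) vs
#' log10(k) over a 10-bin histogram of connectivity k (row sums of
#' adjacency minus the diagonal; empty bins dropped). The selected beta is
#' the smallest power whose R^2 reaches `r2_target`; when none does, the
#' power maximizing R^2 is returned with a warning.
#'
#' @param expr `expr_matrix` or matrix (features x samples).
#' @param candidate_powers integer powers to try.
#' @param r2_target scale-free fit target (default 0.9).
#' @return list with `beta` and `fit` (data.frame power, r_squared,
#'   mean_connectivity).
#' @export
pick_soft_threshold <- function(expr, candidate_powers = 1:20,
                                r2_target = 0.9) {
  m <- if (methods::is(expr, "expr_matrix")) expr$values else as.matrix(expr)
  if (ncol(m) < 8) stop("need >= 8 samples for soft-threshold selection")
  v <- apply(m, 1, var)
  if (any(v == 0)) {
    message("dropping ", sum(v == 0), " constant-expression feature(s)")
    m <- m[v > 0, , drop = FALSE]
  }
  ac <- abs(cor(t(m)))
  diag(ac) <- 0
  fit <- do.call(rbind, lapply(candidate_powers, function(p) {
    adj <- ac^p
    k <- rowSums(adj)
    data.frame(power = p, r_squared = scale_free_r2(k),
               mean_connectivity = mean(k))
  }))
  ok <- which(fit$r_squared >= r2_target)
  if (length(ok) > 0) {
    beta <- fit$power[ok[1]]
  } else {
    beta <- fit$power[which.max(fit$r_squared)]
    warning("no candidate power reached r2_target = ", r2_target,
            "; using power with maximal fit (", beta, ")")
  }
  list(beta = beta, fit = fit)
}

# Scale-free topology fit: R^2 of log10(freq) ~ log10(k) over binned k.
scale_free_r2 <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < 3) return(0)
  br <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  freq <- as.numeric(table(bin))
  mid <- (br[-1] + br[-length(br)]) / 2
  keep <- freq > 0 & mid > 0
  if (sum(keep) < 3) return(0)
  cor(log10(mid[keep]), log10(freq[keep]))^2
}

#' Build the weighted co-expression network
#'
#' Unsigned adjacency a_ij = |cor(x_i, x_j)|^beta; an edge is exported for
#' every unordered pair with adjacency >= edge_cutoff.
#'
#' @param expr `expr_matrix` or matrix (features x samples).
#' @param beta soft-threshold power (>= 1).
#' @param edge_cutoff adjacency threshold in \[0, 1\] (default 0.9).
#' @param kind named character vector labelling nodes ("lncRNA"/"PCG");
#'   taken from the `expr_matrix` when present.
#' @return object of class `coexp_network`: list with `nodes` (id, kind,
#'   degree), `edges` (node_a, node_b, weight, kinds), `adjacency`, `beta`,
#'   `edge_cutoff`.
#' @export
build_network <- function(expr, beta = 8, edge_cutoff = 0.9, kind = NULL) {
  if (beta < 1) stop("beta must be >= 1")
  if (edge_cutoff < 0 || edge_cutoff > 1) {
    stop("edge_cutoff must be in [0, 1]")
  }
  m <- if (methods::is(expr, "expr_matrix")) expr$values else as.matrix(expr)
  if (is.null(rownames(m))) stop("expression matrix needs feature rownames")
  if (is.null(kind) && methods::is(expr, "expr_matrix") &&
      !is.null(expr$feature_kind)) {
    kind <- expr$feature_kind
  }
  v <- apply(m, 1, var)
  if (any(v == 0)) {
    message("dropping ", sum(v == 0), " constant-expression feature(s)")
    m <- m[v > 0, , drop = FALSE]
  }
  adj <- abs(cor(t(m)))^beta
  diag(adj) <- 0
  ids <- rownames(m)
  node_kind <- if (is.null(kind)) setNames(rep("feature", length(ids)), ids)
               else kind[ids]
  ut <- which(upper.tri(adj) & adj >= edge_cutoff, arr.ind = TRUE)
  edges <- data.frame(
    node_a = ids[ut[, 1]], node_b = ids[ut[, 2]],
    weight = adj[ut],
    kind_a = unname(node_kind[ids[ut[, 1]]]),
    kind_b = unname(node_kind[ids[ut[, 2]]]),
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
  rownames(edges) <- NULL
  degree <- setNames(integer(length(ids)), ids)
  tb <- table(c(edges$node_a, edges$node_b))
  degree[names(tb)] <- as.integer(tb)
  nodes <- data.frame(id = ids, kind = unname(node_kind),
                      degree = unname(degree), stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, adjacency = adj,
                 beta = beta, edge_cutoff = edge_cutoff),
            class = "coexp_network")
}

#' @export
print.coexp_network <- function(x, ...) {
  cat(sprintf("coexp_network: %d nodes, %d edges (beta = %g, cutoff = %g)\n",
              nrow(x$nodes), nrow(x$edges), x$beta, x$edge_cutoff))
  invisible(x)
}

#' Nominate hub lncRNAs by network degree
#'
#' Ranks lncRNA nodes by degree (optionally counting only protein-coding
#' neighbours), ties broken by id.
#'
#' @param network a `coexp_network`.
#' @param top_n number of hubs to return (all ranked when NULL and
#'   `min_degree` given).
#' @param min_degree keep only nodes with at least this degree.
#' @param hub_kind node kind eligible as hub (default "lncRNA").
#' @param neighbor_kind when non-NULL, degree counts only neighbours of
#'   this kind (e.g. "PCG").
#' @return data.frame (id, degree, pcg_neighbors) sorted by the ranking
#'   degree, descending.
#' @export
find_hubs <- function(network, top_n = 3L, min_degree = NULL,
                      hub_kind = "lncRNA", neighbor_kind = "PCG") {
  nodes <- network$nodes
  edges <- network$edges
  cand <- nodes$id[nodes$kind == hub_kind]
  if (nrow(edges) == 0 || length(cand) == 0) {
    return(data.frame(id = character(0), degree = integer(0),
                      pcg_neighbors = integer(0), stringsAsFactors = FALSE))
  }
  count_nb <- function(id, want_kind = NULL) {
    nb_a <- edges$node_b[edges$node_a == id]
    nb_k_a <- edges$kind_b[edges$node_a == id]
    nb_b <- edges$node_a[edges$node_b == id]
    nb_k_b <- edges$kind_a[edges$node_b == id]
    k <- c(nb_k_a, nb_k_b)
    if (is.null(want_kind)) length(c(nb_a, nb_b)) else sum(k == want_kind)
  }
  res <- data.frame(
    id = cand,
    degree = vapply(cand, count_nb, integer(1)),
    pcg_neighbors = vapply(cand, count_nb, integer(1),
                           want_kind = neighbor_kind),
    stringsAsFactors = FALSE)
  rank_by <- if (is.null(neighbor_kind)) res$degree else res$pcg_neighbors
  res <- res[order(-rank_by, res$id), , drop = FALSE]
  if (!is.null(min_degree)) res <- res[res$degree >= min_degree, ]
  if (!is.null(top_n)) res <- head(res, top_n)
  rownames(res) <- NULL
  res
}

#' Write a network edge list as TSV
#' @param network `coexp_network`.
#' @param path output file.
#' @export
write_edge_list <- function(network, path) {
  e <- network$edges
  names(e) <- c("source", "target", "weight", "source_kind", "target_kind")
  write_tsv(e, path)
}
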