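# Expression container, FPKM normalization and negative-binomial
# differential expression.
#
# The DE caller is a self-contained NB Wald test: median-of-ratios size
# factors, method-of-moments per-feature dispersion shrunk toward a fitted
# mean-dispersion trend, and a pseudocount-stabilized log2 fold change.
# Two threshold regimes are used in the surrounding analyses:
# |log2FC| > 2 with p < 0.05 for infestation lncRNA calls, and
# |log2FC| > 1 with p < 0.05 for knock-out-line gene calls.

#' Construct an expression matrix with its sample design
#'
#' @param values numeric matrix, features x samples; rownames are feature
#'   ids, colnames are sample ids.
#' @param design data.frame with one row per sample (columns such as
#'   genotype, timepoint_h, replicate, sample_id); `sample_id` must match
#'   `colnames(values)`.
#' @param feature_length named integer vector of transcript lengths (nt).
#' @param feature_kind named character vector (e.g. "lncRNA"/"PCG").
#' @param type "counts" or "fpkm".
#' @return object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, design = NULL, feature_length = NULL,
                              feature_kind = NULL, type = c("counts", "fpkm")) {
  type <- match.arg(type)
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("values must have feature rownames")
  if (anyDuplicated(rownames(values))) stop("duplicate feature ids")
  if (type == "counts") {
    if (any(values < 0) || any(values != round(values))) {
      stop("counts must be non-negative integers")
    }
  }
  if (!is.null(design)) {
    if (is.null(design$sample_id)) stop("design needs a sample_id column")
    if (!identical(as.character(design$sample_id), colnames(values))) {
      stop("design sample_id must match matrix columns in order")
    }
  }
  structure(list(values = values, design = design,
                 feature_length = feature_length,
                 feature_kind = feature_kind, type = type),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix (%s): %d features x %d samples\n", x$type,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Convert raw counts to FPKM
#'
#' FPKM = counts x 10^9 / (length_nt x library_size).
#'
#' @param counts `expr_matrix` of counts, or a bare counts matrix.
#' @param feature_lengths named lengths (nt); taken from the `expr_matrix`
#'   when omitted.
#' @param library_sizes per-sample totals; defaults to column sums.
#' @return `expr_matrix` of type "fpkm".
#' @export
counts_to_fpkm <- function(counts, feature_lengths = NULL,
                           library_sizes = NULL) {
  em <- if (methods::is(counts, "expr_matrix")) counts else
    expression_matrix(counts, type = "counts")
  m <- em$values
  feature_lengths <- feature_lengths %||% em$feature_length
  if (is.null(feature_lengths)) stop("feature lengths required")
  len <- feature_lengths[rownames(m)]
  if (any(is.na(len))) stop("missing length for some features")
  if (any(len <= 0)) stop("zero-length feature")
  library_sizes <- library_sizes %||% colSums(m)
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  fpkm <- sweep(m / len, 2, library_sizes, "/") * 1e9
  expression_matrix(fpkm, design = em$design, feature_length = em$feature_length,
                    feature_kind = em$feature_kind, type = "fpkm")
}

#' Median-of-ratios size factors
#'
#' Per-sample median of count ratios to the per-feature geometric mean,
#' computed over features with all-positive counts.
#'
#' @param counts counts matrix (features x samples).
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  log_gm <- rowMeans(log(counts))
  use <- is.finite(log_gm)
  if (!any(use)) stop("no feature has positive counts in every sample")
  sf <- apply(counts[use, , drop = FALSE], 2, function(col) {
    exp(median(log(col) - log_gm[use]))
  })
  sf
}

#' Negative-binomial Wald test for differential expression
#'
#' @param counts counts matrix or `expr_matrix` (type "counts").
#' @param groups factor/character over samples with exactly two levels;
#'   the first level is the control (denominator of the fold change).
#' @param lfc_threshold |log2FC| required for significance (2 for the
#'   infestation lncRNA regime, 1 for the knock-out regime).
#' @param alpha p-value threshold (0.05 in both regimes).
#' @param shrink_pseudocount pseudocount added to normalized group means
#'   before taking the fold-change log (stabilizes zeros).
#' @param fdr if TRUE, significance uses Benjamini-Hochberg adjusted
#'   p-values; the calling convention of the analyses here is raw p.
#' @param prior_df weight (in residual degrees of freedom) given to the
#'   mean-dispersion trend when shrinking per-feature dispersions.
#' @return data.frame with feature_id, base_mean, mean_control,
#'   mean_treatment, log2_fold_change, dispersion, stat, p_value, padj,
#'   significant, direction.
#' @export
call_de <- function(counts, groups, lfc_threshold = 2, alpha = 0.05,
                    shrink_pseudocount = 1, fdr = FALSE, prior_df = 6) {
  m <- if (methods::is(counts, "expr_matrix")) counts$values else
    as.matrix(counts)
  groups <- as.factor(groups)
  if (length(groups) != ncol(m)) stop("groups must match sample columns")
  if (nlevels(groups) != 2) stop("exactly two groups required")
  n_per <- table(groups)
  if (any(n_per < 2)) {
    stop("each group needs >= 2 replicates (got ",
         paste(n_per, collapse = ", "), ")")
  }
  ctrl <- levels(groups)[1]
  trt <- levels(groups)[2]

  sf <- size_factors(m)
  norm <- sweep(m, 2, sf, "/")
  idx_c <- which(groups == ctrl)
  idx_t <- which(groups == trt)
  mu_c <- rowMeans(norm[, idx_c, drop = FALSE])
  mu_t <- rowMeans(norm[, idx_t, drop = FALSE])
  mu0 <- rowMeans(norm)

  # method-of-moments dispersion from pooled within-group variance
  n_tot <- length(groups)
  resid_df <- n_tot - 2L
  ss <- rowSums((norm[, idx_c, drop = FALSE] - mu_c)^2) +
    rowSums((norm[, idx_t, drop = FALSE] - mu_t)^2)
  var_w <- ss / resid_df
  disp_mom <- pmax((var_w - mu0) / mu0^2, 1e-8)
  disp_mom[mu0 == 0] <- NA

  # mean-dispersion trend a0 + a1/mu, fitted by least squares on features
  # with informative moments, then moderated toward it
  ok <- is.finite(disp_mom) & mu0 > 0 & disp_mom > 1e-8
  trend <- rep(median(disp_mom[is.finite(disp_mom)], na.rm = TRUE),
               nrow(m))
  if (sum(ok) >= 10) {
    fit <- tryCatch(lm(disp_mom[ok] ~ I(1 / mu0[ok])), error = function(e) NULL)
    if (!is.null(fit)) {
      a0 <- max(coef(fit)[1], 1e-8)
      a1 <- max(coef(fit)[2], 0)
      trend <- a0 + a1 / pmax(mu0, 1e-8)
    }
  }
  disp <- (resid_df * ifelse(is.finite(disp_mom), disp_mom, trend) +
             prior_df * trend) / (resid_df + prior_df)
  disp <- pmax(disp, 1e-8)

  ps <- shrink_pseudocount
  lfc <- log2((mu_t + ps) / (mu_c + ps))

  var_mean_c <- rowSums(outer(mu_c, 1 / sf[idx_c]) +
                          disp * mu_c^2) / length(idx_c)^2
  var_mean_t <- rowSums(outer(mu_t, 1 / sf[idx_t]) +
                          disp * mu_t^2) / length(idx_t)^2
  se <- sqrt(var_mean_c / (mu_c + ps)^2 + var_mean_t / (mu_t + ps)^2) / log(2)
  stat <- ifelse(se > 0, lfc / se, 0)
  # reference distribution: t with residual df augmented by the prior df
  # contributed by dispersion moderation (Smyth-style moderated test)
  p <- 2 * pt(-abs(stat), df = resid_df + prior_df)
  p[mu_c == 0 & mu_t == 0] <- 1
  padj <- p.adjust(p, method = "BH")
  p_eff <- if (fdr) padj else p
  res <- data.frame(
    feature_id = rownames(m),
    base_mean = mu0,
    mean_control = mu_c,
    mean_treatment = mu_t,
    log2_fold_change = lfc,
    dispersion = disp,
    stat = stat,
    p_value = p,
    padj = padj,
    significant = abs(lfc) > lfc_threshold & p_eff < alpha,
    direction = ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", "none")),
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  attr(res, "contrast") <- c(control = ctrl, treatment = trt)
  res
}

#' Summarize differential-expression calls across contrasts
#'
#' Computes the DE ratio within a feature class (e.g. the fraction of
#' lncRNAs called differentially expressed versus the same fraction for
#' mRNAs), per-contrast up/down counts, and pairwise overlaps of the
#' significant sets across contrasts.
#'
#' @param de_results named list of [call_de()] results, one per contrast.
#' @param universes named list of feature-id vectors (e.g. list(lncRNA =
#'   ..., mRNA = ...)); ratios are computed per universe.
#' @return list with `ratios` (data.frame class/n_universe/n_sig/ratio),
#'   `per_contrast` (up/down counts) and `overlap` (square matrix of
#'   significant-set intersections across contrasts).
#' @export
summarize_del <- function(de_results, universes) {
  if (any(vapply(universes, length, 1L) == 0)) stop("empty universe")
  sig_sets <- lapply(de_results, function(r) r$feature_id[r$significant])
  all_sig <- unique(unlist(sig_sets))
  ratios <- do.call(rbind, lapply(names(universes), function(cl) {
    u <- universes[[cl]]
    ns <- length(intersect(all_sig, u))
    data.frame(class = cl, n_universe = length(u), n_significant = ns,
               ratio = ns / length(u), stringsAsFactors = FALSE)
  }))
  per_contrast <- do.call(rbind, lapply(names(de_results), function(nm) {
    r <- de_results[[nm]]
    data.frame(contrast = nm,
               n_up = sum(r$significant & r$direction == "up"),
               n_down = sum(r$significant & r$direction == "down"),
               stringsAsFactors = FALSE)
  }))
  k <- length(sig_sets)
  overlap <- matrix(0L, k, k, dimnames = list(names(de_results),
                                              names(de_results)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      overlap[i, j] <- length(intersect(sig_sets[[i]], sig_sets[[j]]))
    }
  }
  list(ratios = ratios, per_contrast = per_contrast, overlap = overlap)
}
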