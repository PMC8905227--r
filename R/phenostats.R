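# Small-sample statistics for qRT-PCR, insect-count and hormone assays:
# 2^-dCt / 2^-ddCt relative expression, Student's t, one-way ANOVA with
# Fisher's LSD pairwise comparisons, and significance-star labelling.

#' Significance stars
#'
#' p >= 0.05 -> "ns"; < 0.05 -> "*"; < 0.01 -> "**"; < 0.001 -> "***";
#' < 0.0001 -> "****" (strict inequalities; p = 0.05 is "ns").
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @export
star_label <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  vapply(p, function(x) {
    if (is.na(x)) NA_character_
    else if (x < 0.0001) "****"
    else if (x < 0.001) "***"
    else if (x < 0.01) "**"
    else if (x < 0.05) "*"
    else "ns"
  }, character(1))
}

#' qRT-PCR relative expression (2^-dCt / 2^-ddCt)
#'
#' dCt = target Ct - reference Ct. Method "dct" reports 2^(-dCt); method
#' "ddct" reports 2^(-(dCt - dCt_calibrator)), so the calibrator sample
#' itself gets relative expression exactly 1.
#'
#' @param records data.frame with columns sample, target_ct, reference_ct.
#' @param method "dct" or "ddct".
#' @param calibrator sample name used as calibrator (required for "ddct").
#' @return `records` with delta_ct and rel_expression columns (and
#'   delta_delta_ct for "ddct").
#' @export
rel_expression <- function(records, method = c("dct", "ddct"),
                           calibrator = NULL) {
  method <- match.arg(method)
  stopifnot(all(c("sample", "target_ct", "reference_ct") %in% names(records)))
  records$delta_ct <- records$target_ct - records$reference_ct
  if (method == "dct") {
    records$rel_expression <- 2^(-records$delta_ct)
  } else {
    if (is.null(calibrator) || !(calibrator %in% records$sample)) {
      stop("ddct method requires a calibrator sample present in records")
    }
    cal_dct <- mean(records$delta_ct[records$sample == calibrator])
    records$delta_delta_ct <- records$delta_ct - cal_dct
    records$rel_expression <- 2^(-records$delta_delta_ct)
  }
  records
}

#' Two-group Student's t test with star labelling
#'
#' Two-sided; pooled-variance (classic Student) by default, Welch on
#' request. When both groups have zero variance and equal means, p = 1 by
#' convention.
#'
#' @param x,y numeric samples (n >= 2 each).
#' @param welch use the Welch unequal-variance test.
#' @return list with means, sds, n, statistic, df, p_value, star.
#' @export
two_group_t <- function(x, y, welch = FALSE) {
  if (length(x) < 2 || length(y) < 2) stop("need n >= 2 per group")
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(means = c(mean(x), mean(y)), sds = c(0, 0),
                  n = c(length(x), length(y)), statistic = 0,
                  df = length(x) + length(y) - 2, p_value = 1, star = "ns"))
    }
    stop("zero variance in both groups with different means")
  }
  tt <- stats::t.test(x, y, var.equal = !welch)
  list(means = c(mean(x), mean(y)), sds = c(sd(x), sd(y)),
       n = c(length(x), length(y)),
       statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, star = star_label(tt$p.value))
}

#' One-way ANOVA with Fisher's LSD pairwise comparisons
#'
#' Computes the one-way ANOVA F test, then all pairwise least significant
#' difference tests: t_ij = (m_i - m_j) / sqrt(MSE (1/n_i + 1/n_j)) with
#' the residual degrees of freedom. By default the LSD step is protected
#' (only run when the ANOVA p-value is below `alpha`); unprotected mode
#' always runs it. A compact letter display groups means that are not
#' significantly different.
#'
#' @param groups named list of numeric vectors (>= 2 observations each;
#'   >= 2 groups).
#' @param alpha significance level for the LSD tests and protection gate.
#' @param protected require ANOVA p < alpha before pairwise testing.
#' @return list with group_stats (group, n, mean, sd, letters), f_value,
#'   df, p_value, star, lsd (pairwise table; NULL when protected and the
#'   ANOVA is not significant), mse.
#' @export
anova_lsd <- function(groups, alpha = 0.05, protected = TRUE) {
  if (length(groups) < 2) stop("need >= 2 groups")
  if (is.null(names(groups))) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  ns <- vapply(groups, length, 1L)
  if (any(ns < 2)) {
    stop("every group needs >= 2 observations (", names(groups)[ns < 2][1],
         " has ", min(ns), ")")
  }
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(names(groups), ns), levels = names(groups))
  n_tot <- length(values)
  k <- length(groups)
  gm <- vapply(groups, mean, numeric(1))
  ss_between <- sum(ns * (gm - mean(values))^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                          numeric(1)))
  df1 <- k - 1
  df2 <- n_tot - k
  mse <- ss_within / df2
  f <- if (ss_within == 0) {
    if (ss_between == 0) 0 else Inf
  } else {
    (ss_between / df1) / mse
  }
  p <- if (is.infinite(f)) 0 else stats::pf(f, df1, df2, lower.tail = FALSE)

  lsd <- NULL
  letters_vec <- setNames(rep("a", k), names(groups))
  run_lsd <- !protected || p < alpha
  if (run_lsd && mse > 0) {
    combos <- utils::combn(names(groups), 2)
    lsd <- do.call(rbind, lapply(seq_len(ncol(combos)), function(j) {
      g1 <- combos[1, j]; g2 <- combos[2, j]
      tstat <- (gm[[g1]] - gm[[g2]]) /
        sqrt(mse * (1 / ns[[g1]] + 1 / ns[[g2]]))
      pp <- 2 * pt(-abs(tstat), df2)
      data.frame(group1 = g1, group2 = g2, diff = gm[[g1]] - gm[[g2]],
                 t = tstat, p_value = pp, star = star_label(pp),
                 stringsAsFactors = FALSE)
    }))
    letters_vec <- lsd_letters(names(groups), gm, lsd, alpha)
  }
  list(group_stats = data.frame(group = names(groups), n = as.integer(ns),
                                mean = unname(gm),
                                sd = vapply(groups, sd, numeric(1)),
                                letters = unname(letters_vec[names(groups)]),
                                stringsAsFactors = FALSE),
       f_value = f, df = c(df1, df2), p_value = p, star = star_label(p),
       lsd = lsd, mse = mse)
}

# Compact letter display by insert-and-absorb over the non-significant
# pairs, means sorted descending.
lsd_letters <- function(group_names, means, lsd, alpha) {
  ord <- group_names[order(-means[group_names])]
  not_sig <- function(a, b) {
    row <- lsd[(lsd$group1 == a & lsd$group2 == b) |
                 (lsd$group1 == b & lsd$group2 == a), ]
    nrow(row) > 0 && row$p_value[1] >= alpha
  }
  sets <- list()
  for (g in ord) {
    placed <- FALSE
    for (i in seq_along(sets)) {
      if (all(vapply(sets[[i]], not_sig, logical(1), b = g))) {
        sets[[i]] <- c(sets[[i]], g)
        placed <- TRUE
      }
    }
    if (!placed) sets[[length(sets) + 1L]] <- g
  }
  lab <- setNames(rep("", length(group_names)), group_names)
  for (i in seq_along(sets)) {
    for (g in sets[[i]]) lab[g] <- paste0(lab[g], letters[i])
  }
  lab
}
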