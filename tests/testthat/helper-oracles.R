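# Independent reference implementations used as test oracles. These are
# deliberately naive (quadratic DP, brute-force enumeration, closed-form
# tail sums) and share no code with the package internals they check.

# Gotoh local alignment (affine gaps; a gap of length L costs
# open + L * ext), score only.
oracle_sw_score <- function(a, b, submat, open, ext) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      s <- submat[a[i - 1], b[j - 1]]
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

oracle_sw_nt <- function(a, b, match = 2, mismatch = -3, open = 5, ext = 2) {
  bases <- c("A", "C", "G", "T")
  sm <- matrix(mismatch, 4, 4, dimnames = list(bases, bases))
  diag(sm) <- match
  oracle_sw_score(a, b, sm, open, ext)
}

oracle_sw_aa <- function(a, b, open = 11, ext = 1) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  oracle_sw_score(a, b, BLOSUM62, open, ext)
}

# Brute-force ORF enumeration: every in-frame ATG..stop span, collapsed to
# the longest ORF per (frame, stop).
oracle_orfs <- function(seq, min_aa) {
  seq <- toupper(seq)
  n <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  hits <- list()
  for (frame in 0:2) {
    for (s0 in seq(frame, n - 3, by = 3)) {
      if (substr(seq, s0 + 1, s0 + 3) != "ATG") next
      j <- s0
      found <- NULL
      while (j + 3 <= n) {
        cod <- substr(seq, j + 1, j + 3)
        if (grepl("N", cod, fixed = TRUE)) break
        if (cod %in% stops && j > s0) { found <- j + 3; break }
        if (cod %in% stops && j == s0) break
        j <- j + 3
      }
      if (!is.null(found)) {
        aa_len <- (found - s0) / 3 - 1
        if (aa_len >= min_aa) {
          hits[[length(hits) + 1L]] <- data.frame(frame = frame, start = s0,
                                                  end = found,
                                                  peptide_length = aa_len)
        }
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(frame = integer(0), start = integer(0),
                      end = integer(0), peptide_length = integer(0)))
  }
  h <- do.call(rbind, hits)
  # longest per (frame, stop) = smallest start per (frame, end)
  h <- h[order(h$frame, h$end, h$start), ]
  h <- h[!duplicated(h[, c("frame", "end")]), ]
  h[order(-h$peptide_length, h$frame, h$start), ]
}

# Hypergeometric upper-tail P(X >= a) for the 2x2 table (a,b,c,d).
oracle_fisher_p <- function(a, b, cc, d) {
  N <- a + b + cc + d
  K <- a + cc      # annotated in universe
  n <- a + b       # set size
  x <- a:min(K, n)
  sum(stats::dhyper(x, K, N - K, n))
}

# Exact two-sided Wilcoxon rank-sum p by full enumeration of group
# assignments (no-ties case).
oracle_wilcox_exact <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  W_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  Ws <- apply(combs, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- nx * ny / 2
  mean(abs(Ws - mu) >= abs(W_obs - mu) - 1e-12)
}

# Pooled two-sample t-test, closed form.
oracle_pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  p <- 2 * stats::pt(-abs(t), nx + ny - 2)
  list(t = t, p = p)
}

random_seq <- function(len, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, len, replace = TRUE), collapse = "")
}
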