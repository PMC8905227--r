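# Shared internal helpers.

# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' GC content of a nucleotide sequence
#'
#' Fraction (G + C) / (A + C + G + T); other letters (e.g. N) are excluded
#' from the denominator.
#'
#' @param x character vector of nucleotide sequences.
#' @return numeric vector in \[0, 1\]; NaN for sequences with no ACGT letters.
#' @examples
#' gc_content("ATGC")  # 0.5
#' @export
gc_content <- function(x) {
  xs <- Biostrings::DNAStringSet(toupper(as.character(x)))
  fr <- Biostrings::letterFrequency(xs, letters = c("A", "C", "G", "T"))
  tot <- rowSums(fr)
  unname((fr[, "C"] + fr[, "G"]) / tot)
}

# Random DNA with a target GC fraction.
random_dna <- function(n, length, gc = 0.4) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(seq_len(n), function(i) {
    paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
  }, character(1))
}

# Apportion n into counts proportional to p, exactly summing to n
# (largest-remainder method; deterministic ties by index order).
apportion <- function(n, p) {
  stopifnot(all(p >= 0), sum(p) > 0)
  q <- n * p / sum(p)
  k <- floor(q)
  left <- n - sum(k)
  if (left > 0) {
    ord <- order(q - k, decreasing = TRUE)
    k[ord[seq_len(left)]] <- k[ord[seq_len(left)]] + 1
  }
  as.integer(k)
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Stable TSV writers: never quote, never write row names, LF endings.
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, eol = "\n")
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
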