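# Coding-potential evaluation: ORF enumeration, a trained hexamer
# composition score combined with ORF coverage, and local protein-database
# alignment as independent coding evidence.

DNA_BASES <- c("A", "C", "G", "T")
ALL_HEXAMERS <- local({
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, b, b, b, stringsAsFactors = FALSE)[, 6:1]
  apply(g, 1, paste, collapse = "")
})

codon_to_aa <- function(codons) {
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

#' Enumerate open reading frames
#'
#' Scans the three forward frames (optionally all six) for ATG..stop spans.
#' Nested starts sharing a stop are collapsed to the longest ORF per
#' (frame, stop). Codons containing N never start or extend an ORF. ORFs
#' reaching the 3' end without a stop codon are reported only in
#' permissive mode.
#'
#' @param sequence nucleotide string over A/C/G/T/N.
#' @param min_peptide_aa minimum peptide length (aa, start codon included,
#'   stop excluded). Default 20 keeps short-peptide ORFs reportable while
#'   suppressing micro-ORFs.
#' @param both_strands also scan the three reverse-complement frames
#'   (reported with strand "-" and coordinates on the forward sequence of
#'   the reverse complement).
#' @param open_ended report stop-less ORFs that run into the sequence end.
#' @return data.frame (frame, strand, start, end, peptide, peptide_length)
#'   with 0-based half-open transcript coordinates, `end` covering the stop
#'   codon, sorted by peptide length (desc), then frame, then start.
#' @export
find_orfs <- function(sequence, min_peptide_aa = 20L, both_strands = FALSE,
                      open_ended = FALSE) {
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) == 0) return(empty_orf_table())
  if (grepl("[^ACGTN]", sequence)) {
    stop("sequence contains letters outside A/C/G/T/N")
  }
  res <- scan_orfs_one_strand(sequence, min_peptide_aa, open_ended, "+")
  if (both_strands) {
    rc <- reverse_complement(sequence)
    res <- rbind(res, scan_orfs_one_strand(rc, min_peptide_aa, open_ended,
                                           "-"))
  }
  res[order(-res$peptide_length, res$frame, res$start), , drop = FALSE]
}

empty_orf_table <- function() {
  data.frame(frame = integer(0), strand = character(0), start = integer(0),
             end = integer(0), peptide = character(0),
             peptide_length = integer(0), stringsAsFactors = FALSE)
}

scan_orfs_one_strand <- function(seq, min_aa, open_ended, strand) {
  n <- nchar(seq)
  out <- list()
  for (frame in 0:2) {
    n_cod <- (n - frame) %/% 3
    if (n_cod < 2) next
    starts <- frame + 3 * (seq_len(n_cod) - 1)  # 0-based codon starts
    codons <- substring(seq, starts + 1, starts + 3)
    open_at <- NA_integer_  # 0-based start of first ATG since last stop
    for (ci in seq_len(n_cod)) {
      cod <- codons[ci]
      if (grepl("N", cod, fixed = TRUE)) {
        open_at <- NA_integer_  # N codons never start or extend an ORF
        next
      }
      if (cod %in% STOP_CODONS) {
        if (!is.na(open_at)) {
          end <- starts[ci] + 3L
          aa_len <- as.integer((end - open_at) / 3 - 1)
          if (aa_len >= min_aa) {
            pep <- paste(codon_to_aa(
              substring(seq, seq(open_at + 1, starts[ci] - 2, by = 3),
                        seq(open_at + 3, starts[ci], by = 3))), collapse = "")
            out[[length(out) + 1L]] <- data.frame(
              frame = frame, strand = strand, start = open_at, end = end,
              peptide = pep, peptide_length = aa_len,
              stringsAsFactors = FALSE)
          }
          open_at <- NA_integer_
        }
      } else if (cod == "ATG" && is.na(open_at)) {
        open_at <- starts[ci]
      }
    }
    if (open_ended && !is.na(open_at)) {
      end <- starts[n_cod] + 3L
      aa_len <- as.integer((end - open_at) / 3)
      if (aa_len >= min_aa) {
        pep <- paste(codon_to_aa(
          substring(seq, seq(open_at + 1, end - 2, by = 3),
                    seq(open_at + 3, end, by = 3))), collapse = "")
        out[[length(out) + 1L]] <- data.frame(
          frame = frame, strand = strand, start = open_at, end = end,
          peptide = pep, peptide_length = aa_len, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) return(empty_orf_table())
  do.call(rbind, out)
}

count_hexamers <- function(seqs, pseudocount) {
  counts <- setNames(numeric(4096), ALL_HEXAMERS)
  for (s in seqs) {
    s <- toupper(s)
    n <- nchar(s)
    if (n < 6) next
    hx <- substring(s, 1:(n - 5), 6:n)
    hx <- hx[!grepl("N", hx, fixed = TRUE)]
    tb <- table(hx)
    counts[names(tb)] <- counts[names(tb)] + as.numeric(tb)
  }
  (counts + pseudocount) / (sum(counts) + pseudocount * 4096)
}

#' Train the hexamer coding-potential model
#'
#' Builds per-class hexamer frequencies (additive pseudocount over all 4096
#' hexamers, step-1 sliding window) and their log-ratio table, then records
#' the pooled mean/sd of the two classifier features (ORF coverage and
#' hexamer log-ratio) over both training sets for z-standardization.
#'
#' @param coding_seqs,noncoding_seqs character vectors of training
#'   sequences (A/C/G/T/N).
#' @param pseudocount additive smoothing count.
#' @return object of class `hexamer_model`.
#' @export
train_hexamer_model <- function(coding_seqs, noncoding_seqs,
                                pseudocount = 1) {
  if (length(coding_seqs) == 0 || length(noncoding_seqs) == 0) {
    stop("both training sets must be non-empty")
  }
  all_seq <- toupper(c(coding_seqs, noncoding_seqs))
  if (any(grepl("[^ACGTN]", all_seq))) {
    stop("training sequences contain letters outside A/C/G/T/N")
  }
  f_cod <- count_hexamers(toupper(coding_seqs), pseudocount)
  f_non <- count_hexamers(toupper(noncoding_seqs), pseudocount)
  model <- structure(list(logratio = log(f_cod / f_non),
                          freq_coding = f_cod, freq_noncoding = f_non,
                          pseudocount = pseudocount, trained = TRUE,
                          z = NULL),
                     class = "hexamer_model")
  feats <- t(vapply(all_seq, function(s) {
    unlist(coding_features(s, model))
  }, numeric(2)))
  model$z <- list(mean = colMeans(feats),
                  sd = pmax(apply(feats, 2, sd), 1e-8))
  model
}

# Raw classifier features for one sequence: ORF coverage (longest ORF nt /
# sequence nt) and the mean hexamer log-ratio over the in-frame hexamers of
# the longest ORF body (start codon and stop codon excluded; 0 without an
# ORF or with a body shorter than one hexamer).
coding_features <- function(sequence, model) {
  orfs <- find_orfs(sequence, min_peptide_aa = 2L)
  if (nrow(orfs) == 0) {
    return(list(orf_coverage = 0, hexamer_log_ratio = 0))
  }
  o <- orfs[1, ]
  cov <- (o$end - o$start) / nchar(sequence)
  body_start <- o$start + 3L   # 0-based, skip ATG
  body_end <- o$end - 3L       # exclude stop codon
  offs <- if (body_end - body_start >= 6L) {
    seq(body_start, body_end - 6L, by = 3L)
  } else {
    integer(0)
  }
  hlr <- if (length(offs) == 0) 0 else {
    hx <- substring(sequence, offs + 1L, offs + 6L)
    hx <- hx[!grepl("N", hx, fixed = TRUE)]
    if (length(hx) == 0) 0 else mean(model$logratio[hx])
  }
  list(orf_coverage = cov, hexamer_log_ratio = hlr)
}

#' Score the coding potential of a transcript
#'
#' combined_score = w1 * z(ORF coverage) + w2 * z(hexamer log-ratio), with
#' z-standardization parameters taken from the training step; label is
#' "coding" iff combined_score > threshold.
#'
#' @param sequence nucleotide string.
#' @param hexamer_model a trained [train_hexamer_model()].
#' @param threshold decision threshold on the combined score.
#' @param weights length-2 weights for (ORF coverage, hexamer log-ratio).
#' @return data.frame with orf_coverage, hexamer_log_ratio,
#'   combined_score, label.
#' @export
score_coding <- function(sequence, hexamer_model, threshold = 0,
                         weights = c(1, 1)) {
  if (!methods::is(hexamer_model, "hexamer_model") ||
      !isTRUE(hexamer_model$trained) || is.null(hexamer_model$z)) {
    stop("hexamer_model is not trained")
  }
  f <- coding_features(toupper(as.character(sequence)), hexamer_model)
  z <- hexamer_model$z
  z1 <- (f$orf_coverage - z$mean[["orf_coverage"]]) / z$sd[["orf_coverage"]]
  z2 <- (f$hexamer_log_ratio - z$mean[["hexamer_log_ratio"]]) /
    z$sd[["hexamer_log_ratio"]]
  score <- weights[1] * z1 + weights[2] * z2
  data.frame(orf_coverage = f$orf_coverage,
             hexamer_log_ratio = f$hexamer_log_ratio,
             combined_score = score,
             label = if (score > threshold) "coding" else "noncoding",
             stringsAsFactors = FALSE)
}

#' Local protein-database alignment of predicted peptides
#'
#' Smith-Waterman with BLOSUM62 and affine gaps (open 11, extend 1) of each
#' peptide against each database protein; a peptide is a hit when its best
#' local score reaches `min_score`. A transcript with any hit carries
#' independent coding evidence.
#'
#' @param peptides named character vector of peptide sequences (or a
#'   [find_orfs()] table, in which case peptides are taken from it).
#' @param protein_db named character vector of protein sequences.
#' @param min_score score at or above which a pair is a hit.
#' @return data.frame (peptide_id, protein_id, score, hit).
#' @export
protein_hits <- function(peptides, protein_db, min_score = 50) {
  if (is.data.frame(peptides)) {
    pep <- peptides$peptide
    names(pep) <- sprintf("orf%03d", seq_along(pep))
    peptides <- pep
  }
  if (length(peptides) == 0) {
    return(data.frame(peptide_id = character(0), protein_id = character(0),
                      score = numeric(0), hit = logical(0)))
  }
  if (length(protein_db) == 0) {
    warning("empty protein database: no hits possible")
    return(data.frame(peptide_id = character(0), protein_id = character(0),
                      score = numeric(0), hit = logical(0)))
  }
  if (is.null(names(peptides))) {
    names(peptides) <- sprintf("pep%03d", seq_along(peptides))
  }
  pats <- Biostrings::AAStringSet(peptides)
  out <- list()
  for (pr in names(protein_db)) {
    sc <- Biostrings::pairwiseAlignment(
      pats, Biostrings::AAString(protein_db[[pr]]), type = "local",
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
      scoreOnly = TRUE)
    out[[pr]] <- data.frame(peptide_id = names(peptides), protein_id = pr,
                            score = sc, hit = sc >= min_score,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
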