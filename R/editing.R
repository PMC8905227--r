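# On-target CRISPR amplicon analysis: guide-site location, per-read
# editing-outcome classification against the amplicon reference, and
# per-sample editing-efficiency summaries.
#
# Coordinate convention: the SpCas9 blunt cut falls 3 bp 5' of the PAM;
# cut_pos is a 0-based between-base coordinate (the number of reference
# bases to the left of the cut). Reports print 1-based positions.

#' Locate a single sgRNA target site in an amplicon
#'
#' Searches both strands for the 20-nt spacer followed by an NGG PAM;
#' exactly one site must exist.
#'
#' @param amplicon_ref amplicon reference sequence.
#' @param guide_seq 20-nt spacer sequence (A/C/G/T).
#' @return list of class `guide_site`: guide_seq, pam, strand, pam_start
#'   (0-based start of the PAM trinucleotide on the plus strand), cut_pos
#'   (0-based between-base cut coordinate).
#' @export
locate_guide <- function(amplicon_ref, guide_seq) {
  amplicon_ref <- toupper(as.character(amplicon_ref))
  guide_seq <- toupper(as.character(guide_seq))
  if (nchar(guide_seq) != 20 || grepl("[^ACGT]", guide_seq)) {
    stop("guide must be 20 nt over A/C/G/T")
  }
  n <- nchar(amplicon_ref)
  sites <- list()
  # plus strand: guide + NGG
  hits <- matchall(guide_seq, amplicon_ref)
  for (p in hits) {  # p = 0-based guide start
    pam <- substr(amplicon_ref, p + 21, p + 23)
    if (nchar(pam) == 3 && grepl("^[ACGT]GG$", pam)) {
      sites[[length(sites) + 1L]] <- list(
        guide_seq = guide_seq, pam = pam, strand = "+",
        pam_start = p + 20L, cut_pos = p + 17L)
    }
  }
  # minus strand: CCN + revcomp(guide)
  rcg <- reverse_complement(guide_seq)
  hits <- matchall(rcg, amplicon_ref)
  for (q in hits) {
    if (q < 3) next
    pam_fwd <- substr(amplicon_ref, q - 2, q)  # 1-based q-2..q = CCN
    if (grepl("^CC[ACGT]$", pam_fwd)) {
      sites[[length(sites) + 1L]] <- list(
        guide_seq = guide_seq,
        pam = reverse_complement(pam_fwd), strand = "-",
        pam_start = q - 3L, cut_pos = q + 3L)
    }
  }
  if (length(sites) != 1) {
    pos <- vapply(sites, function(s) s$pam_start, integer(1))
    stop("guide+PAM must occur exactly once; found ", length(sites),
         " site(s)",
         if (length(pos)) paste0(" at PAM position(s) ",
                                 paste(pos + 1, collapse = ", ")) else "")
  }
  structure(sites[[1]], class = "guide_site")
}

# all 0-based start positions of fixed pattern in subject
matchall <- function(pattern, subject) {
  m <- Biostrings::matchPattern(Biostrings::DNAString(pattern),
                                Biostrings::DNAString(subject))
  IRanges::start(m) - 1L
}

#' Classify amplicon reads into editing outcomes
#'
#' Each read is globally aligned to the amplicon reference (match 2,
#' mismatch -2, gap open 6, gap extend 1). Events are judged inside the
#' window cut_pos +/- `window_bp`: a single in-window gap run is a
#' deletion/insertion of that run length; >= `min_sub_count` in-window
#' mismatches with no gap is a substitution; gap plus qualifying
#' mismatches, or multiple gap runs, is "mixed"; anything else (including
#' events wholly outside the window) is WT. Reads scoring below
#' `min_score_frac` of the perfect-match score are "unaligned".
#'
#' @param reads named character vector of reads.
#' @param amplicon_ref amplicon reference sequence.
#' @param site a [locate_guide()] result.
#' @param window_bp window half-width around the cut (default 10).
#' @param min_sub_count in-window mismatches required to call a
#'   substitution (default 2; single mismatches are attributed to
#'   sequencing error).
#' @param min_score_frac alignment-score floor as a fraction of the
#'   perfect score.
#' @return data.frame (read_id, outcome, length, offset_from_cut,
#'   n_mismatch_window, score).
#' @export
classify_reads <- function(reads, amplicon_ref, site, window_bp = 10L,
                           min_sub_count = 2L, min_score_frac = 0.5) {
  amplicon_ref <- toupper(as.character(amplicon_ref))
  if (is.null(names(reads))) {
    names(reads) <- sprintf("read%05d", seq_along(reads))
  }
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -2,
                                                 baseOnly = TRUE)
  floor_score <- min_score_frac * 2 * nchar(amplicon_ref)
  cut <- site$cut_pos
  win_lo <- cut - window_bp        # first in-window base (0-based)
  win_hi <- cut + window_bp - 1L   # last in-window base
  res <- lapply(names(reads), function(id) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(toupper(reads[[id]])),
      Biostrings::DNAString(amplicon_ref), type = "global",
      substitutionMatrix = sm, gapOpening = 6, gapExtension = 1)
    sc <- Biostrings::score(aln)
    if (sc < floor_score) {
      return(data.frame(read_id = id, outcome = "unaligned", length = 0L,
                        offset_from_cut = NA_integer_,
                        n_mismatch_window = NA_integer_, score = sc,
                        stringsAsFactors = FALSE))
    }
    p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    ev <- alignment_events(p, s)
    in_del <- ev$del[ev$del$start <= win_hi & ev$del$end >= win_lo, ,
                     drop = FALSE]
    in_ins <- ev$ins[ev$ins$at >= win_lo & ev$ins$at <= win_hi + 1L, ,
                     drop = FALSE]
    n_mm <- sum(ev$mismatch >= win_lo & ev$mismatch <= win_hi)
    n_runs <- nrow(in_del) + nrow(in_ins)
    out <- if (n_runs >= 2) {
      list("mixed", 0L, NA_integer_)
    } else if (n_runs == 1 && n_mm >= min_sub_count) {
      list("mixed", 0L, NA_integer_)
    } else if (nrow(in_del) == 1) {
      list("deletion", in_del$len[1], in_del$start[1] - cut)
    } else if (nrow(in_ins) == 1) {
      list("insertion", in_ins$len[1], in_ins$at[1] - cut)
    } else if (n_mm >= min_sub_count) {
      list("substitution", 0L, NA_integer_)
    } else {
      list("WT", 0L, NA_integer_)
    }
    data.frame(read_id = id, outcome = out[[1]], length = out[[2]],
               offset_from_cut = out[[3]], n_mismatch_window = n_mm,
               score = sc, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  rownames(res) <- NULL
  res
}

# Parse gapped alignment strings into deletion runs (reference bases
# missing from the read), insertion points (read bases absent from the
# reference, anchored at a between-base reference coordinate) and
# mismatch positions. All coordinates 0-based on the reference.
alignment_events <- function(p, s) {
  ref_pos <- -1L  # last consumed 0-based reference index
  del <- list(); ins <- list(); mm <- integer(0)
  i <- 1L
  n <- length(p)
  while (i <= n) {
    if (p[i] == "-" && s[i] != "-") {        # deletion run
      run_start <- ref_pos + 1L
      len <- 0L
      while (i <= n && p[i] == "-" && s[i] != "-") {
        len <- len + 1L
        ref_pos <- ref_pos + 1L
        i <- i + 1L
      }
      del[[length(del) + 1L]] <- data.frame(start = run_start,
                                            end = ref_pos, len = len)
    } else if (s[i] == "-" && p[i] != "-") { # insertion run
      at <- ref_pos + 1L
      len <- 0L
      while (i <= n && s[i] == "-" && p[i] != "-") {
        len <- len + 1L
        i <- i + 1L
      }
      ins[[length(ins) + 1L]] <- data.frame(at = at, len = len)
    } else {
      ref_pos <- ref_pos + 1L
      if (p[i] != s[i]) mm <- c(mm, ref_pos)
      i <- i + 1L
    }
  }
  list(del = if (length(del)) do.call(rbind, del) else
         data.frame(start = integer(0), end = integer(0), len = integer(0)),
       ins = if (length(ins)) do.call(rbind, ins) else
         data.frame(at = integer(0), len = integer(0)),
       mismatch = mm)
}

#' Summarize per-sample editing outcomes
#'
#' @param calls a [classify_reads()] result for one sample.
#' @param min_reads aligned-read count below which the sample is flagged
#'   low-coverage (default 50).
#' @return list with n_reads (aligned), n_unaligned, n_edited, efficiency
#'   (percent), type_distribution (proportions over aligned reads),
#'   deletion_length_histogram (named counts 1..max length) and
#'   low_coverage flag.
#' @export
summarize_editing <- function(calls, min_reads = 50L) {
  aligned <- calls[calls$outcome != "unaligned", , drop = FALSE]
  if (nrow(aligned) == 0) stop("zero aligned reads")
  edited_types <- c("deletion", "insertion", "substitution", "mixed")
  n <- nrow(aligned)
  n_edited <- sum(aligned$outcome %in% edited_types)
  type_dist <- vapply(c("WT", edited_types), function(t) {
    sum(aligned$outcome == t) / n
  }, numeric(1))
  dl <- aligned$length[aligned$outcome == "deletion"]
  hist <- if (length(dl) > 0) {
    tabulate(dl, nbins = max(dl))
  } else {
    integer(0)
  }
  names(hist) <- seq_along(hist)
  list(n_reads = n, n_unaligned = sum(calls$outcome == "unaligned"),
       n_edited = n_edited, efficiency = 100 * n_edited / n,
       type_distribution = type_dist,
       deletion_length_histogram = hist,
       low_coverage = n < min_reads)
}
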