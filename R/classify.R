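# Class-code assignment and the lncRNA candidate filter cascade.
#
# Assembled transcripts are compared against the reference annotation and
# given cuffcompare-style codes: "u" (intergenic, no overlap with any gene
# span), "i" (entirely within one intron), "x" (exonic overlap with a
# reference exon on the opposite strand) or "overlapping_other" (any
# same-strand or strand-ambiguous exonic/gene-span overlap). Candidates then
# pass a fixed cascade: class code, minimum spliced length (200 nt), maximum
# FPKM over samples (> 0.5 in at least one sample), distance to the nearest
# gene span (> 500 bp) and, optionally, EST support over at least one exon.

#' Filter parameters for lncRNA candidate selection
#'
#' @param min_length minimum spliced transcript length (nt).
#' @param min_fpkm FPKM that must be exceeded (strictly) in >= 1 sample.
#' @param min_gene_distance distance to the nearest annotated gene span
#'   that must be exceeded (strictly), in bp.
#' @param allowed_codes class codes admitted to candidacy. The default
#'   keeps only intergenic transcripts, matching a non-strand-specific
#'   library where antisense calls are unreliable; use c("u","i","x") for
#'   the permissive variant.
#' @param require_est_support if TRUE, a candidate needs >= 1 exon
#'   overlapped by an EST interval.
#' @export
filter_params <- function(min_length = 200L, min_fpkm = 0.5,
                          min_gene_distance = 500L, allowed_codes = "u",
                          require_est_support = TRUE) {
  stopifnot(min_length > 0, min_fpkm > 0, min_gene_distance > 0)
  structure(list(min_length = as.integer(min_length), min_fpkm = min_fpkm,
                 min_gene_distance = as.integer(min_gene_distance),
                 allowed_codes = allowed_codes,
                 require_est_support = isTRUE(require_est_support)),
            class = "filter_params")
}

transcript_spans <- function(exons) {
  sp <- split(exons, exons$transcript_id)
  do.call(rbind, lapply(sp, function(e) {
    data.frame(transcript_id = e$transcript_id[1], chrom = e$chrom[1],
               strand = e$strand[1], start = min(e$start), end = max(e$end),
               spliced_length = sum(e$end - e$start),
               n_exons = nrow(e), stringsAsFactors = FALSE)
  }))
}

#' Assign class codes to assembled transcripts
#'
#' @param assembled exon table of assembled transcripts (0-based half-open).
#' @param reference exon table of the reference annotation; gene spans are
#'   the per-gene ranges over all exons (introns included).
#' @return data.frame with transcript_id, class_code (u/i/x/
#'   overlapping_other or NA on per-record errors), nearest_gene_id,
#'   distance_to_nearest_gene (bp; 0 when overlapping a gene span) and
#'   note (error description for failed records).
#' @export
assign_class_codes <- function(assembled, reference) {
  ref_chroms <- unique(reference$chrom)
  spans <- transcript_spans(assembled)

  # per-gene spans and exon/intron structure
  gene_split <- split(reference, reference$gene_id)
  genes <- do.call(rbind, lapply(gene_split, function(e) {
    data.frame(gene_id = e$gene_id[1], chrom = e$chrom[1],
               strand = e$strand[1], start = min(e$start), end = max(e$end),
               stringsAsFactors = FALSE)
  }))
  genes <- genes[order(genes$gene_id), ]
  gene_introns <- lapply(gene_split, function(e) {
    m <- as.data.frame(IRanges::reduce(
      IRanges::IRanges(start = e$start + 1L, end = e$end)))
    if (nrow(m) < 2) {
      return(data.frame(start = integer(0), end = integer(0)))
    }
    # 1-based inclusive intron intervals between merged exons
    data.frame(start = m$end[-nrow(m)] + 1L, end = m$start[-1] - 1L)
  })

  ref_ex_gr <- exons_to_granges(reference)
  asm_ex_gr <- exons_to_granges(assembled)
  ov <- GenomicRanges::findOverlaps(asm_ex_gr, ref_ex_gr,
                                    ignore.strand = TRUE)
  ov_df <- data.frame(
    tid = S4Vectors::mcols(asm_ex_gr)$transcript_id[S4Vectors::queryHits(ov)],
    asm_strand = as.character(GenomicRanges::strand(asm_ex_gr))[
      S4Vectors::queryHits(ov)],
    ref_strand = as.character(GenomicRanges::strand(ref_ex_gr))[
      S4Vectors::subjectHits(ov)],
    stringsAsFactors = FALSE)

  out <- lapply(seq_len(nrow(spans)), function(i) {
    tr <- spans[i, ]
    rec <- data.frame(transcript_id = tr$transcript_id,
                      class_code = NA_character_,
                      nearest_gene_id = NA_character_,
                      distance_to_nearest_gene = NA_integer_,
                      note = NA_character_, stringsAsFactors = FALSE)
    if (!(tr$chrom %in% ref_chroms)) {
      rec$note <- "unknown chromosome"
      return(rec)
    }
    g <- genes[genes$chrom == tr$chrom, ]
    # distance to nearest gene span (0 on overlap; ties -> lowest gene id)
    if (nrow(g) > 0) {
      gaps <- pmax(0L, pmax(g$start - tr$end, tr$start - g$end))
      best <- which(gaps == min(gaps))[1]  # genes sorted by id
      rec$nearest_gene_id <- g$gene_id[best]
      rec$distance_to_nearest_gene <- gaps[best]
    } else {
      rec$distance_to_nearest_gene <- NA_integer_
    }
    hits <- ov_df[ov_df$tid == tr$transcript_id, ]
    if (nrow(hits) > 0) {
      known <- hits$asm_strand %in% c("+", "-") &
        hits$ref_strand %in% c("+", "-")
      opposite <- known & hits$asm_strand != hits$ref_strand
      if (all(opposite)) {
        rec$class_code <- "x"
      } else {
        rec$class_code <- "overlapping_other"
      }
      rec$distance_to_nearest_gene <- 0L
      return(rec)
    }
    # no exonic overlap: intronic containment or gene-span overlap?
    span_ov <- g[g$start < tr$end & tr$start < g$end, , drop = FALSE]
    if (nrow(span_ov) > 0) {
      rec$distance_to_nearest_gene <- 0L
      rec$nearest_gene_id <- span_ov$gene_id[1]
      in_intron <- any(vapply(span_ov$gene_id, function(gid) {
        intr <- gene_introns[[gid]]
        any(intr$start <= tr$start + 1L & tr$end <= intr$end)
      }, logical(1)))
      rec$class_code <- if (in_intron) "i" else "overlapping_other"
      return(rec)
    }
    rec$class_code <- "u"
    rec
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the lncRNA candidate filter cascade
#'
#' A transcript survives iff its class code is allowed AND spliced length
#' >= min_length AND max-over-samples FPKM > min_fpkm AND distance to the
#' nearest gene span > min_gene_distance AND (when required) at least one
#' exon is overlapped by an EST interval. The ledger records the first
#' failed rule per rejected transcript, in cascade order
#' code -> length -> fpkm -> distance -> est.
#'
#' @param assigned result of [assign_class_codes()].
#' @param transcripts exon table of the assembled transcripts.
#' @param expression `expr_matrix` of FPKM values covering every
#'   transcript id.
#' @param params a [filter_params()].
#' @param est_support data.frame of EST intervals (chrom, start, end;
#'   0-based half-open); may be NULL when EST support is not required.
#' @return list with `candidates` (surviving ids, sorted) and `ledger`
#'   (data.frame transcript_id, rule_failed; "pass" for survivors).
#' @export
filter_candidates <- function(assigned, transcripts, expression, params,
                              est_support = NULL) {
  stopifnot(methods::is(params, "filter_params"))
  fpkm <- if (methods::is(expression, "expr_matrix")) expression$values else
    as.matrix(expression)
  spans <- transcript_spans(transcripts)
  missing <- setdiff(assigned$transcript_id, rownames(fpkm))
  if (length(missing) > 0) {
    stop("expression matrix is missing transcript(s): ",
         paste(head(missing, 5), collapse = ", "))
  }
  if (params$require_est_support && is.null(est_support)) {
    stop("EST support required but no est_support intervals given")
  }

  est_by_chrom <- if (!is.null(est_support)) {
    split(est_support, est_support$chrom)
  } else {
    list()
  }
  has_est <- function(ex) {
    e <- est_by_chrom[[ex$chrom[1]]]
    if (is.null(e)) return(FALSE)
    any(vapply(seq_len(nrow(ex)), function(i) {
      any(e$start < ex$end[i] & ex$start[i] < e$end)
    }, logical(1)))
  }

  ledger <- data.frame(transcript_id = assigned$transcript_id,
                       rule_failed = "pass", stringsAsFactors = FALSE)
  for (i in seq_len(nrow(assigned))) {
    tid <- assigned$transcript_id[i]
    tr <- spans[spans$transcript_id == tid, ]
    rule <- NULL
    if (is.na(assigned$class_code[i]) ||
        !(assigned$class_code[i] %in% params$allowed_codes)) {
      rule <- "code"
    } else if (tr$spliced_length < params$min_length) {
      rule <- "length"
    } else if (max(fpkm[tid, ]) <= params$min_fpkm) {
      rule <- "fpkm"
    } else if (!is.na(assigned$distance_to_nearest_gene[i]) &&
               assigned$distance_to_nearest_gene[i] <= params$min_gene_distance) {
      rule <- "distance"
    } else if (params$require_est_support &&
               !has_est(transcripts[transcripts$transcript_id == tid, ])) {
      rule <- "est"
    }
    if (!is.null(rule)) ledger$rule_failed[i] <- rule
  }
  list(candidates = sort(ledger$transcript_id[ledger$rule_failed == "pass"]),
       ledger = ledger)
}

#' Summarize and compare lncRNA vs mRNA sequence/expression features
#'
#' Per-feature GC content, spliced length, exon count, median FPKM across
#' samples and subgenome label, with two-sided Wilcoxon rank-sum
#' comparisons (lncRNA vs mRNA on every metric; At vs Dt within lncRNAs on
#' GC content). Comparisons with an empty or singleton group are skipped
#' with a notice.
#'
#' @param exons exon table covering all summarized features.
#' @param seqs named character vector of spliced sequences.
#' @param expression `expr_matrix` of FPKM values.
#' @param groups named character vector mapping feature ids to "lncRNA"
#'   or "mRNA".
#' @return list with `features` (per-feature table) and `comparisons`
#'   (metric, groups, medians, Wilcoxon p).
#' @export
summarize_features <- function(exons, seqs, expression, groups) {
  fpkm <- if (methods::is(expression, "expr_matrix")) expression$values else
    as.matrix(expression)
  ids <- names(groups)
  spans <- transcript_spans(exons[exons$transcript_id %in% ids, ])
  spans <- spans[match(ids, spans$transcript_id), ]
  feats <- data.frame(
    feature_id = ids,
    group = unname(groups),
    gc_content = gc_content(unname(seqs[ids])),
    length = spans$spliced_length,
    exon_count = spans$n_exons,
    median_fpkm = apply(fpkm[ids, , drop = FALSE], 1, median),
    subgenome = ifelse(substr(spans$chrom, 1, 1) == "A", "At",
                       ifelse(substr(spans$chrom, 1, 1) == "D", "Dt",
                              "scaffold")),
    stringsAsFactors = FALSE)
  rownames(feats) <- NULL

  cmp <- list()
  add_cmp <- function(metric, x, y, g1, g2) {
    if (length(x) < 2 || length(y) < 2) {
      message("comparison skipped (group with < 2 features): ", metric,
              " ", g1, " vs ", g2)
      return(invisible(NULL))
    }
    p <- suppressWarnings(wilcox.test(x, y, correct = FALSE)$p.value)
    cmp[[length(cmp) + 1L]] <<- data.frame(
      metric = metric, group1 = g1, group2 = g2,
      median1 = median(x), median2 = median(y), p_value = p,
      stringsAsFactors = FALSE)
  }
  lnc <- feats[feats$group == "lncRNA", ]
  mr <- feats[feats$group == "mRNA", ]
  for (m in c("gc_content", "length", "exon_count", "median_fpkm")) {
    add_cmp(m, lnc[[m]], mr[[m]], "lncRNA", "mRNA")
  }
  add_cmp("gc_content", lnc$gc_content[lnc$subgenome == "At"],
          lnc$gc_content[lnc$subgenome == "Dt"], "At", "Dt")
  list(features = feats,
       comparisons = if (length(cmp)) do.call(rbind, cmp) else NULL)
}
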