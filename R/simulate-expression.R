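# Count, annotation and amplicon-read generators layered on simulate_genome.

#' Generate a count matrix with planted differential expression
#'
#' Features are all assembled transcripts plus all reference mRNAs. Counts
#' are negative binomial (variance = mu + alpha mu^2; alpha = 0 gives
#' Poisson). Non-DE features keep one mean across all samples; planted DE
#' features are shifted by `de_log2fc` (alternating up/down) in every
#' post-infestation sample (timepoint_h > 0). Syntenic homolog pair members
#' get a mild down-shift that is stronger for the Dt member, emulating the
#' Dt-biased repression seen under infestation. The low-expression decoys
#' get mean 0 so they fail the FPKM rule.
#'
#' @param sim a `cotton_sim` from [simulate_genome()].
#' @param config simulation config; defaults to `sim$config`.
#' @return list with `expr` (an `expr_matrix` of counts), and `truth`
#'   (the sim truth table extended with true_de, true_log2fc and cluster
#'   columns, plus rows for the reference mRNAs).
#' @export
simulate_counts <- function(sim, config = sim$config) {
  if (nrow(config$design) == 0) stop("empty design")
  with_seed(config$seed + 1L, simulate_counts_impl(sim, config))
}

simulate_counts_impl <- function(sim, cfg) {
  truth <- sim$truth
  mrna_ids <- names(sim$mrna_seqs)
  mrna_rows <- data.frame(
    feature_id = mrna_ids, kind = "mrna", true_class_code = "overlapping",
    true_coding = TRUE, homolog_partner = NA_character_,
    pair_id = NA_character_, syntenic_truth = NA,
    chrom = vapply(mrna_ids, function(tid) {
      sim$reference$chrom[sim$reference$transcript_id == tid][1]
    }, character(1)),
    subgenome = NA_character_,
    length = nchar(sim$mrna_seqs)[mrna_ids],
    true_pass_filter = FALSE, true_pass_all = FALSE,
    cluster = NA_integer_, stringsAsFactors = FALSE)
  mrna_rows$subgenome <- ifelse(substr(mrna_rows$chrom, 1, 1) == "A",
                                "At", "Dt")
  truth <- rbind(truth, mrna_rows)
  rownames(truth) <- NULL

  n_feat <- nrow(truth)
  is_mrna <- truth$kind %in% c("mrna", "mrna_copy")
  base_mean <- numeric(n_feat)
  base_mean[is_mrna] <- rlnorm(sum(is_mrna), log(300), 0.6)
  base_mean[!is_mrna] <- rlnorm(sum(!is_mrna), log(60), 0.6)
  # assembled mRNA copies reuse their reference transcript's mean
  copy_idx <- which(truth$kind == "mrna_copy")
  ref_of_copy <- sub("^asm_", "", truth$feature_id[copy_idx])
  base_mean[copy_idx] <- base_mean[match(ref_of_copy, truth$feature_id)]
  base_mean[truth$kind == "decoy_low_fpkm"] <- 0

  # planted DE: free u lncRNAs at de_fraction, mRNAs at a smaller fraction
  truth$true_de <- FALSE
  truth$true_log2fc <- 0
  free_lnc <- which(truth$kind == "lnc" & truth$true_class_code == "u" &
                      is.na(truth$pair_id))
  n_de_lnc <- round(cfg$de_fraction * length(free_lnc))
  de_lnc <- if (n_de_lnc > 0) sample(free_lnc, n_de_lnc) else integer(0)
  mrna_base <- which(truth$kind == "mrna")
  n_de_mrna <- round(cfg$de_fraction / cfg$mrna_de_shrink * length(mrna_base))
  de_mrna <- if (n_de_mrna > 0) sample(mrna_base, n_de_mrna) else integer(0)
  de_idx <- c(de_lnc, de_mrna)
  signs <- rep(c(1, -1), length.out = length(de_idx))
  truth$true_de[de_idx] <- TRUE
  truth$true_log2fc[de_idx] <- signs * cfg$de_log2fc
  # syntenic pair members: mild down-shift, stronger on Dt
  syn <- which(!is.na(truth$syntenic_truth) & truth$syntenic_truth)
  at_m <- syn[grepl("_at$", truth$feature_id[syn])]
  dt_m <- syn[grepl("_dt$", truth$feature_id[syn])]
  truth$true_log2fc[at_m] <- -1
  truth$true_log2fc[dt_m] <- -2
  truth$cluster <- ifelse(!truth$true_de & truth$true_log2fc == 0, 1L,
                          ifelse(truth$true_log2fc > 0, 2L, 3L))
  # mRNA copies mirror their reference's DE state
  truth$true_de[copy_idx] <- truth$true_de[match(ref_of_copy,
                                                 truth$feature_id)]
  truth$true_log2fc[copy_idx] <- truth$true_log2fc[match(ref_of_copy,
                                                         truth$feature_id)]
  truth$cluster[copy_idx] <- truth$cluster[match(ref_of_copy,
                                                 truth$feature_id)]

  design <- cfg$design
  n_samp <- nrow(design)
  sf <- runif(n_samp, 0.7, 1.3)
  infested <- design$timepoint_h > 0
  counts <- matrix(0L, n_feat, n_samp,
                   dimnames = list(truth$feature_id, design$sample_id))
  for (j in seq_len(n_samp)) {
    mu <- base_mean * sf[j] *
      (if (infested[j]) 2^truth$true_log2fc else 1)
    counts[, j] <- if (cfg$dispersion == 0) {
      stats::rpois(n_feat, mu)
    } else {
      rnbinom(n_feat, mu = mu, size = 1 / cfg$dispersion)
    }
  }
  lengths <- setNames(truth$length, truth$feature_id)
  kind <- setNames(ifelse(is_mrna, "PCG", "lncRNA"), truth$feature_id)
  expr <- expression_matrix(counts, design = design, feature_length = lengths,
                            feature_kind = kind, type = "counts")
  list(expr = expr, truth = truth)
}

#' Generate a gene-to-term annotation table with a planted enriched term
#'
#' Every up-regulated DE mRNA carries the planted "biotic stimulus
#' response"-like term `GO:BIOTIC`; background genes carry it at a low
#' rate. Ten filler terms are scattered uniformly.
#'
#' @param truth truth table from [simulate_counts()].
#' @param config simulation config.
#' @return data.frame with columns feature_id, term_id.
#' @export
simulate_annotation <- function(truth, config) {
  with_seed(config$seed + 2L, {
    genes <- truth$feature_id[truth$kind == "mrna"]
    up <- truth$feature_id[truth$kind == "mrna" & truth$true_de &
                             truth$true_log2fc > 0]
    rows <- list(data.frame(feature_id = up, term_id = "GO:BIOTIC",
                            stringsAsFactors = FALSE))
    bg <- setdiff(genes, up)
    bg_pick <- bg[runif(length(bg)) < 0.05]
    if (length(bg_pick)) {
      rows[[2]] <- data.frame(feature_id = bg_pick, term_id = "GO:BIOTIC",
                              stringsAsFactors = FALSE)
    }
    for (t in sprintf("GO:R%02d", 1:10)) {
      pick <- genes[runif(length(genes)) < 0.10]
      if (length(pick)) {
        rows[[length(rows) + 1L]] <- data.frame(
          feature_id = pick, term_id = t, stringsAsFactors = FALSE)
      }
    }
    ann <- do.call(rbind, rows)
    ann[order(ann$feature_id, ann$term_id), , drop = FALSE]
  })
}

#' Generate amplicon reads with planted CRISPR editing outcomes
#'
#' Each read is a full-length copy of the amplicon carrying one planted
#' outcome at the predicted cut site (3 bp 5' of the PAM): a deletion of the
#' stated length centred on the cut, an insertion of random bases at the
#' cut, a 2-base substitution flanking the cut, or the wild-type sequence.
#' Sequencing noise is substitution-only at `read_error_rate` per base, so
#' truth labels stay unambiguous. Outcome proportions are realized exactly
#' up to largest-remainder rounding.
#'
#' @param amplicon_ref amplicon reference sequence (character).
#' @param guide 20-nt sgRNA spacer; `guide` + NGG must occur exactly once.
#' @param outcome_mix data.frame with columns `type` (WT, deletion,
#'   insertion, substitution), `length` (bp; ignored for WT/substitution)
#'   and `proportion`.
#' @param n_reads number of reads to emit.
#' @param seed RNG seed.
#' @param read_error_rate per-base substitution error probability.
#' @return list with `reads` (named character vector) and `truth`
#'   (data.frame read_id, outcome, length).
#' @export
simulate_amplicons <- function(amplicon_ref, guide, outcome_mix, n_reads,
                               seed = 1L, read_error_rate = 0) {
  stopifnot(is.data.frame(outcome_mix),
            all(c("type", "proportion") %in% names(outcome_mix)))
  if (is.null(outcome_mix$length)) outcome_mix$length <- 0L
  site <- locate_guide(amplicon_ref, guide)
  cut <- site$cut_pos
  with_seed(seed, {
    n_per <- apportion(n_reads, outcome_mix$proportion)
    reads <- character(0)
    truth <- list()
    bases <- c("A", "C", "G", "T")
    ridx <- 0L
    for (i in seq_len(nrow(outcome_mix))) {
      type <- outcome_mix$type[i]
      len <- as.integer(outcome_mix$length[i])
      for (r in seq_len(n_per[i])) {
        ridx <- ridx + 1L
        id <- sprintf("read%05d", ridx)
        s <- amplicon_ref
        if (type == "deletion") {
          del_start <- cut - ceiling(len / 2)  # 0-based
          s <- paste0(substr(s, 1, del_start),
                      substr(s, del_start + len + 1L, nchar(s)))
        } else if (type == "insertion") {
          ins <- paste(sample(bases, len, replace = TRUE), collapse = "")
          s <- paste0(substr(s, 1, cut), ins,
                      substr(s, cut + 1L, nchar(s)))
        } else if (type == "substitution") {
          for (pos in c(cut, cut + 1L)) {  # 1-based positions cut, cut+1
            old <- substr(s, pos, pos)
            substr(s, pos, pos) <- sample(setdiff(bases, old), 1)
          }
        } else if (type != "WT") {
          stop("unknown outcome type: ", type)
        }
        if (read_error_rate > 0) {
          hit <- which(runif(nchar(s)) < read_error_rate)
          for (pos in hit) {
            old <- substr(s, pos, pos)
            substr(s, pos, pos) <- sample(setdiff(bases, old), 1)
          }
        }
        reads[id] <- s
        truth[[ridx]] <- data.frame(read_id = id, outcome = type,
                                    length = if (type %in% c("deletion",
                                                             "insertion"))
                                      len else 0L,
                                    stringsAsFactors = FALSE)
      }
    }
    list(reads = reads, truth = do.call(rbind, truth))
  })
}

#' Write a full simulation to disk as plain-text files
#'
#' Emits genome.fa, reference.gtf, assembled.gtf, transcripts.fa,
#' proteins.fa, est.bed, counts.tsv, design.tsv, truth.tsv,
#' gene_order.tsv and annotation.tsv into `dir`.
#'
#' @param sim `cotton_sim` object.
#' @param counts result of [simulate_counts()].
#' @param annotation result of [simulate_annotation()], or NULL to skip.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, counts = NULL, annotation = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(sim$genome, file.path(dir, "genome.fa"))
  write_gtf(sim$reference, file.path(dir, "reference.gtf"))
  write_gtf(sim$assembled, file.path(dir, "assembled.gtf"))
  write_fasta(sim$transcript_seqs, file.path(dir, "transcripts.fa"))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sim$protein_db),
                              file.path(dir, "proteins.fa"), width = 60L)
  write_bed3(sim$est, file.path(dir, "est.bed"))
  write_tsv(sim$gene_order, file.path(dir, "gene_order.tsv"))
  if (!is.null(counts)) {
    cm <- data.frame(feature_id = rownames(counts$expr$values),
                     counts$expr$values, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write_tsv(cm, file.path(dir, "counts.tsv"))
    write_tsv(counts$expr$design, file.path(dir, "design.tsv"))
    write_tsv(counts$truth, file.path(dir, "truth.tsv"))
  } else {
    write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  }
  if (!is.null(annotation)) {
    write_tsv(annotation, file.path(dir, "annotation.tsv"))
  }
  invisible(dir)
}
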